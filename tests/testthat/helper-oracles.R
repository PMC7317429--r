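# Independent oracles used across the suite. These deliberately avoid
# the package's own computational paths: dense-matrix likelihoods, grid
# searches, and brute-force enumeration.

## Gaussian mixed-model log-likelihood at fixed variance components,
## computed through the dense marginal covariance V = s2a ZZ' + s2e I.
oracle_loglik <- function(y, X, site, s2a, s2e, reml = TRUE) {
  site <- as.factor(site)
  Z <- stats::model.matrix(~ site - 1)
  n <- length(y); p <- ncol(X)
  V <- s2a * tcrossprod(Z) + diag(s2e, n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- drop(t(r) %*% Vi %*% r)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  if (reml) {
    ldx <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * log(2 * pi) + ld + ldx + quad)
  } else {
    -0.5 * (n * log(2 * pi) + ld + quad)
  }
}

## Maximum of the oracle likelihood over a refined 2-D grid in
## (log s2a, log s2e). Three zoom stages of a 21x21 grid.
oracle_grid_max <- function(y, X, site, reml = TRUE) {
  lo <- c(-12, -8); hi <- c(4, 4)
  best <- c(NA, NA); bestll <- -Inf
  for (stage in 1:5) {
    ga <- seq(lo[1], hi[1], length.out = 21)
    ge <- seq(lo[2], hi[2], length.out = 21)
    for (a in ga) for (e in ge) {
      ll <- oracle_loglik(y, X, site, exp(a), exp(e), reml)
      if (ll > bestll) { bestll <- ll; best <- c(a, e) }
    }
    span_a <- (hi[1] - lo[1]) / 20; span_e <- (hi[2] - lo[2]) / 20
    lo <- best - 2 * c(span_a, span_e)
    hi <- best + 2 * c(span_a, span_e)
  }
  list(loglik = bestll, s2a = exp(best[1]), s2e = exp(best[2]))
}

## Brute-force best first split: every predictor, every cut between
## adjacent distinct sorted values, plain loops.
oracle_best_split <- function(X, y, min_leaf) {
  X <- as.matrix(X)
  best <- list(sse = Inf)
  for (j in seq_len(ncol(X))) {
    ux <- sort(unique(X[, j]))
    if (length(ux) < 2) next
    cuts <- (ux[-1] + ux[-length(ux)]) / 2
    for (cut in cuts) {
      L <- y[X[, j] < cut]; R <- y[X[, j] >= cut]
      if (length(L) < min_leaf || length(R) < min_leaf) next
      sse <- sum((L - mean(L))^2) + sum((R - mean(R))^2)
      if (sse < best$sse - 1e-12) {
        best <- list(var = colnames(X)[j], threshold = cut, sse = sse)
      }
    }
  }
  if (is.infinite(best$sse)) NULL else best
}

## Brute-force Kennard-Stone: explicit max-min greedy on the centered
## Euclidean distance matrix.
oracle_kennard_stone <- function(X, fraction) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  m <- ceiling(fraction * n)
  pair <- which(D == max(D), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  sel <- sort(as.integer(pair))
  while (length(sel) < m) {
    cand <- setdiff(seq_len(n), sel)
    mind <- sapply(cand, function(i) min(D[i, sel]))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel[seq_len(m)]
}

## Closed-form OLS slope and intercept.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

## A small balanced dataset with known structure, for LMM fixtures.
## s2a = 0 produces data with *no* between-site signal at all (residuals
## centered within site), so the variance estimate must hit the boundary.
make_lmm_fixture <- function(seed, n_sites = 5, per_site = 20,
                             s2a = 0.5, s2e = 0.3, beta = c(1, -0.5)) {
  withr::with_seed(seed, {
    site <- rep(sprintf("S%02d", seq_len(n_sites)), each = per_site)
    x <- rep_len(c(0, 1), n_sites * per_site)
    a <- rnorm(n_sites, 0, sqrt(max(s2a, 0)))
    e <- rnorm(n_sites * per_site, 0, sqrt(s2e))
    if (s2a == 0) e <- e - ave(e, site)
    y <- beta[1] + beta[2] * x + a[as.integer(factor(site))] + e
    list(y = y, X = cbind(`(Intercept)` = 1, x = x), site = site)
  })
}
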