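# Profiled (RE)ML for the single-random-intercept Gaussian mixed model
#
#   y = X beta + Z b + e,   b ~ N(0, sigma2_site I),  e ~ N(0, sigma2_resid I)
#
# With lambda = sigma2_site / sigma2_resid, V = sigma2 (I + lambda Z Z')
# and W = (I + lambda Z Z')^-1 is block diagonal over sites:
# W_i = I - lambda/(1 + lambda n_i) J. beta and sigma2 have closed forms
# given lambda, so the likelihood is profiled to one dimension and
# maximised over log(lambda).

lmm_prepare <- function(y, X, site) {
  site <- as.factor(site)
  if (nlevels(site) < 2)
    stop("random effect unidentifiable: need >= 2 sites", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  idx <- as.integer(site)
  ni <- tabulate(idx, nlevels(site))
  list(y = y, X = X, idx = idx, ni = ni, n = length(y), p = ncol(X),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y * y),
       Sx = rowsum(X, idx), sy = rowsum(y, idx)[, 1],
       levels = levels(site))
}

## Profile log-likelihood at ratio lambda; returns loglik plus the
## profiled beta and sigma2 so the optimum needs no recomputation.
lmm_profile_eval <- function(d, lambda, method) {
  ci <- lambda / (1 + lambda * d$ni)
  XtWX <- d$XtX - crossprod(d$Sx * ci, d$Sx)
  XtWy <- d$Xty - crossprod(d$Sx * ci, cbind(d$sy))
  ytWy <- d$yty - sum(ci * d$sy^2)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rssw <- max(ytWy - sum(beta * XtWy), 1e-300)
  ld1 <- sum(log1p(lambda * d$ni))
  if (method == "ML") {
    s2 <- rssw / d$n
    ll <- -0.5 * d$n * (log(2 * pi * s2) + 1) - 0.5 * ld1
  } else {
    nm <- d$n - d$p
    s2 <- rssw / nm
    ll <- -0.5 * nm * (log(2 * pi * s2) + 1) - 0.5 * ld1 -
      sum(log(diag(ch)))
  }
  list(loglik = ll, beta = drop(beta), sigma2 = s2, chol = ch,
       lambda = lambda, rssw = rssw)
}

lmm_core_fit <- function(y, X, site, method = c("REML", "ML")) {
  method <- match.arg(method)
  d <- lmm_prepare(y, X, site)
  f <- function(t) lmm_profile_eval(d, exp(t), method)$loglik
  opt <- stats::optimize(f, interval = c(-20, 13), maximum = TRUE,
                         tol = 1e-9)
  cand <- lmm_profile_eval(d, exp(opt$maximum), method)
  at0 <- lmm_profile_eval(d, 0, method)
  best <- if (at0$loglik > cand$loglik) at0 else cand
  vc_beta <- best$sigma2 * chol2inv(best$chol)
  dimnames(vc_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc_beta))
  tval <- best$beta / se
  pval <- 2 * stats::pt(abs(tval), df = d$n - d$p, lower.tail = FALSE)
  lam <- best$lambda
  list(beta = stats::setNames(best$beta, colnames(X)), se = se, t = tval,
       p = pval, vcov = vc_beta,
       sigma2_site = lam * best$sigma2, sigma2_resid = best$sigma2,
       lambda = lam, loglik = best$loglik, n = d$n, p_fixed = d$p,
       method = method, prep = d)
}

## Conditional fitted values and residuals: BLUP of the site intercept is
## shrinkage of the site-mean marginal residual.
lmm_condition <- function(fit) {
  d <- fit$prep
  r <- d$y - drop(d$X %*% fit$beta)
  rbar <- rowsum(r, d$idx)[, 1] / d$ni
  shrink <- fit$lambda * d$ni / (1 + fit$lambda * d$ni)
  blup <- shrink * rbar
  fitted <- drop(d$X %*% fit$beta) + blup[d$idx]
  list(fitted = fitted, residuals = d$y - fitted, blup = blup)
}

## Vectorised profile-(RE)ML slope fitter for many response columns that
## share one design [1, x] and grouping. Used by the dilution null, where
## each of R permutation replicates refits the same mixed model with a
## new response. Maximisation is over a fixed log-lambda grid with
## parabolic refinement; the final slope is recomputed exactly at the
## refined ratio, column by column.
lmm_slope_batch <- function(Y, x, site, method = "REML",
                            grid = seq(-18, 12, length.out = 61)) {
  Y <- as.matrix(Y)
  X <- cbind(1, x)
  site <- as.factor(site)
  idx <- as.integer(site)
  ni <- tabulate(idx, nlevels(site))
  n <- nrow(Y); p <- 2L; R <- ncol(Y)
  XtX <- crossprod(X)
  Sx <- rowsum(X, idx)
  XtY <- crossprod(X, Y)
  SY <- rowsum(Y, idx)
  YtY <- colSums(Y * Y)
  nm <- if (method == "REML") n - p else n

  ll_at <- function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    A <- XtX - crossprod(Sx * ci, Sx)
    det_a <- A[1, 1] * A[2, 2] - A[1, 2]^2
    XtWY <- XtY - crossprod(Sx * ci, SY)
    ytWy <- YtY - colSums(ci * SY^2)
    b1 <- (A[2, 2] * XtWY[1, ] - A[1, 2] * XtWY[2, ]) / det_a
    b2 <- (A[1, 1] * XtWY[2, ] - A[1, 2] * XtWY[1, ]) / det_a
    rssw <- pmax(ytWy - (b1 * XtWY[1, ] + b2 * XtWY[2, ]), 1e-300)
    ld1 <- sum(log1p(lambda * ni))
    ll <- -0.5 * nm * (log(2 * pi * rssw / nm) + 1) - 0.5 * ld1
    if (method == "REML") ll <- ll - 0.5 * log(det_a)
    list(ll = ll, slope = b2)
  }

  LL <- vapply(grid, function(t) ll_at(exp(t))$ll, numeric(R))
  LL <- matrix(LL, nrow = R)              # R x length(grid)
  best <- max.col(LL, ties.method = "first")
  t_hat <- grid[best]
  inner <- best > 1L & best < length(grid)
  if (any(inner)) {                       # parabolic refinement
    i <- best[inner]
    l0 <- LL[cbind(which(inner), i - 1L)]
    l1 <- LL[cbind(which(inner), i)]
    l2 <- LL[cbind(which(inner), i + 1L)]
    h <- grid[2] - grid[1]
    denom <- l0 - 2 * l1 + l2
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * h * (l0 - l2) / denom, 0)
    t_hat[inner] <- grid[i] + pmax(pmin(shift, h), -h)
  }
  ## exact GLS slope at each column's refined ratio; O(n_sites) per column
  slopes <- numeric(R)
  for (r in seq_len(R)) {
    lambda <- exp(t_hat[r])
    ci <- lambda / (1 + lambda * ni)
    A <- XtX - crossprod(Sx * ci, Sx)
    det_a <- A[1, 1] * A[2, 2] - A[1, 2]^2
    xwy <- XtY[, r] - drop(crossprod(Sx * ci, SY[, r]))
    slopes[r] <- (A[1, 1] * xwy[2] - A[1, 2] * xwy[1]) / det_a
  }
  slopes
}
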