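# Chemometric calibration: Kennard-Stone subset selection on NIR
# spectra and PLS1 (NIPALS) regression linking spectra to lab-measured
# Si concentrations, with external validation.

#' Construct a spectra object
#'
#' @param absorbance numeric matrix, samples x wavelengths.
#' @param wavelengths strictly increasing numeric grid (nm).
#' @param sample_ids optional labels (default row numbers).
#' @param reference optional named numeric vector of lab-measured
#'   concentrations (% dry weight) for some or all samples.
#' @return object of class `si_spectra`.
#' @export
spectra_matrix <- function(absorbance, wavelengths, sample_ids = NULL,
                           reference = NULL) {
  absorbance <- as.matrix(absorbance)
  if (anyNA(absorbance)) stop("missing absorbances", call. = FALSE)
  if (length(wavelengths) != ncol(absorbance))
    stop("wavelength grid does not match spectra columns", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  sample_ids <- sample_ids %||% as.character(seq_len(nrow(absorbance)))
  rownames(absorbance) <- sample_ids
  if (!is.null(reference) && is.null(names(reference)))
    names(reference) <- sample_ids
  structure(list(absorbance = absorbance,
                 wavelengths = as.numeric(wavelengths),
                 sample_ids = sample_ids, reference = reference),
            class = "si_spectra")
}

#' @export
print.si_spectra <- function(x, ...) {
  cat(sprintf("NIR spectra: %d samples x %d wavelengths (%g-%g), %d with reference values\n",
              nrow(x$absorbance), ncol(x$absorbance), min(x$wavelengths),
              max(x$wavelengths), length(x$reference)))
  invisible(x)
}

#' Average replicate scans
#'
#' Element-wise mean of replicate spectra (e.g. triplicate scans of each
#' ground sample). All replicates must share the wavelength grid and
#' sample set.
#'
#' @param scans list of `si_spectra` objects.
#' @return a single `si_spectra`.
#' @export
average_replicates <- function(scans) {
  stopifnot(length(scans) >= 1)
  w <- scans[[1]]$wavelengths
  for (s in scans[-1])
    if (!isTRUE(all.equal(s$wavelengths, w)))
      stop("mismatched wavelength grids among replicates", call. = FALSE)
  acc <- Reduce(`+`, lapply(scans, `[[`, "absorbance"))
  spectra_matrix(acc / length(scans), w, scans[[1]]$sample_ids,
                 scans[[1]]$reference)
}

#' Kennard-Stone maximum-variation subset selection
#'
#' Deterministic max-min selection on Euclidean distances between
#' mean-centered spectra: start from the most distant pair, then
#' repeatedly add the sample whose minimum distance to the selected set
#' is largest, until `ceiling(fraction * n)` samples are chosen. Ties are
#' broken by the lowest sample index.
#'
#' @param spectra `si_spectra` or numeric matrix (samples x variables).
#' @param fraction proportion of samples to select, in (0, 1].
#' @return character vector of selected sample ids, in selection order
#'   (integer indices as strings when the input was an unnamed matrix).
#' @export
kennard_stone <- function(spectra, fraction = 0.2) {
  X <- if (inherits(spectra, "si_spectra")) spectra$absorbance else
    as.matrix(spectra)
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  n <- nrow(X)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  D <- as.matrix(stats::dist(Xc))
  if (max(D) == 0) stop("zero-variance spectra matrix", call. = FALSE)
  m <- ceiling(fraction * n)
  start <- which(D == max(D), arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  sel <- sort(as.integer(start))            # lowest-index pair first
  if (m == 1) return(ids[sel[1]])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < m) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)                  # first maximum = lowest index
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  ids[sel]
}

#' Fit a PLS1 calibration model (NIPALS)
#'
#' Partial-least-squares regression of a single response on centered
#' spectra, computed by the NIPALS sequence of weights, scores and
#' loadings. Predictions are linear in the centered spectra.
#'
#' @param spectra `si_spectra` whose `reference` values are the training
#'   responses (all training samples must have one), or a numeric
#'   matrix together with `y`.
#' @param n_components number of latent variables (>= 1, at most the
#'   rank of the centered training matrix).
#' @param y response vector when `spectra` is a bare matrix.
#' @return object of class `si_pls`: coefficients on the original
#'   spectral scale, intercept, weights/loadings per component, training
#'   ids.
#' @export
fit_pls <- function(spectra, n_components, y = NULL) {
  if (inherits(spectra, "si_spectra")) {
    if (is.null(spectra$reference))
      stop("training spectra need reference values", call. = FALSE)
    X <- spectra$absorbance[names(spectra$reference), , drop = FALSE]
    y <- as.numeric(spectra$reference)
  } else X <- as.matrix(spectra)
  stopifnot(length(y) == nrow(X))
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  rk <- qr(E)$rank
  if (n_components > rk)
    stop("n_components (", n_components, ") exceeds the rank (", rk,
         ") of the centered training matrix", call. = FALSE)
  p <- ncol(X); A <- n_components
  W <- matrix(0, p, A); P <- matrix(0, p, A); qv <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    pa <- drop(crossprod(E, t_)) / tt
    qa <- sum(f * t_) / tt
    W[, a] <- w; P[, a] <- pa; qv[a] <- qa
    E <- E - tcrossprod(t_, pa)
    f <- f - qa * t_
  }
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  qv <- qv[seq_len(A)]
  B <- W %*% solve(crossprod(P, W), qv)
  structure(list(coefficients = drop(B), intercept = ym - sum(xm * B),
                 n_components = A, weights = W, x_loadings = P,
                 y_loadings = qv, x_means = xm, y_mean = ym,
                 training_ids = rownames(X)),
            class = "si_pls")
}

#' @export
print.si_pls <- function(x, ...) {
  cat(sprintf("PLS1 calibration: %d component(s), %d wavelengths, %d training samples\n",
              x$n_components, length(x$coefficients),
              length(x$training_ids)))
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' @param object an `si_pls` model.
#' @param newdata `si_spectra` or numeric matrix.
#' @param ... unused.
#' @return named numeric vector of predicted concentrations.
#' @export
predict.si_pls <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "si_spectra")) newdata$absorbance else
    as.matrix(newdata)
  drop(X %*% object$coefficients) + object$intercept
}

#' External validation of a calibration model
#'
#' Predicts the holdout spectra and scores them against their reference
#' values: by default the squared Pearson correlation of predicted
#' versus reference (the conventional reporting of external-validation
#' R2), optionally `1 - SSE/SST`.
#'
#' @param model an `si_pls` model.
#' @param holdout `si_spectra` with reference values for the samples to
#'   score.
#' @param method `"cor"` (default) or `"one_minus_sse"`.
#' @return validation R2 (scalar).
#' @export
validate_pls <- function(model, holdout, method = c("cor", "one_minus_sse")) {
  method <- match.arg(method)
  stopifnot(inherits(holdout, "si_spectra"), !is.null(holdout$reference))
  obs <- holdout$reference
  pred <- predict(model,
                  holdout$absorbance[names(obs), , drop = FALSE])
  if (method == "cor") stats::cor(pred, obs)^2
  else 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Simulate NIR-like spectra with a latent Beer-Lambert structure
#'
#' Generates spectra as nonnegative mixtures of a few Gaussian-peaked
#' pure-component profiles plus a smooth baseline and instrument noise;
#' the reference concentration is a linear function of the latent
#' component amounts plus lab error. The lab-error SD is set from
#' `target_r2`, the squared correlation between the spectrally
#' recoverable signal and the reference value expected in external
#' validation after a max-min (Kennard-Stone) calibration split:
#' because that split sends the spectral extremes to the calibration
#' set, the validation samples retain about two thirds of the signal
#' variance (`restriction` = 0.67 under this concentration model at a
#' 20% split), and the noise level is calibrated against that restricted
#' variance.
#'
#' @param n number of samples.
#' @param n_wavelengths grid size.
#' @param n_latent number of latent chemical components.
#' @param target_r2 external-validation R2 the calibration problem is
#'   tuned to support.
#' @param restriction share of signal variance retained by the
#'   validation set after the max-min calibration split.
#' @param noise_x instrument noise SD on absorbances.
#' @param seed RNG seed.
#' @return `si_spectra` with reference values for every sample.
#' @export
simulate_spectra <- function(n = 500L, n_wavelengths = 200L,
                             n_latent = 3L, target_r2 = 0.83,
                             restriction = 0.67,
                             noise_x = 0.002, seed = 1L) {
  stopifnot(target_r2 > 0, target_r2 <= 1)
  with_seed(seed, {
    wl <- seq(1100, 2500, length.out = n_wavelengths)
    centers <- seq(1300, 2300, length.out = n_latent)
    widths <- stats::runif(n_latent, 60, 140)
    profiles <- vapply(seq_len(n_latent), function(k)
      exp(-(wl - centers[k])^2 / (2 * widths[k]^2)), numeric(n_wavelengths))
    conc <- matrix(stats::rlnorm(n * n_latent, 0, 0.4), n)
    baseline <- outer(stats::runif(n, 0, 0.05), rep(1, n_wavelengths)) +
      outer(stats::runif(n, 0, 2e-5), wl)
    A <- conc %*% t(profiles) + baseline +
      matrix(stats::rnorm(n * n_wavelengths, 0, noise_x), n)
    a <- c(1, seq_len(n_latent - 1) * 0.3)[seq_len(n_latent)]
    signal <- drop(conc %*% a)
    sd_lab <- stats::sd(signal) *
      sqrt(restriction * (1 / target_r2 - 1))
    y <- signal + stats::rnorm(n, 0, sd_lab)
    spectra_matrix(A, wl, sprintf("sample%04d", seq_len(n)),
                   stats::setNames(y, sprintf("sample%04d", seq_len(n))))
  })
}
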