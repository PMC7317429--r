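# Permutation null model for the "stoichiometric dilution effect".
#
# Because element concentrations are percentages of a closed sum, any
# rise in leaf C mechanically depresses every other element. To ask
# whether the Si ~ C slope is steeper than closure alone predicts, each
# sample's focal concentration is replaced by the concentration of one
# of the five nonfocal elements of the *same* sample, drawn uniformly at
# random; the mixed-model slope of that scrambled response on %C is one
# draw from the dilution null. Repeating R times yields the null slope
# distribution against which the observed slope is ranked.

#' Test an element's C-slope against the stoichiometric dilution null
#'
#' Fits the random-intercept mixed model `focal ~ %C + (1|site)` and
#' compares its slope with `R` null slopes obtained by replacing, per
#' sample and independently in every replicate, the focal concentration
#' with that of a uniformly chosen nonfocal element. Empirical p-values
#' use the add-one correction `p = (1 + #{null <= obs}) / (R + 1)`;
#' `p_lower` (observed more negative than the null) is the trade-off
#' direction. Samples are put into a canonical order internally, so the
#' result is invariant to row order of the input.
#'
#' @param samples plot-level sample table with all element columns.
#' @param focal one of `"si"`, `"n"`, `"p"`, `"k"`, `"ca"`, `"mg"`.
#' @param R number of null replicates (default 999).
#' @param seed RNG seed.
#' @param log_focal model the natural log of the focal concentration
#'   (default `FALSE`, the % scale).
#' @return object of class `si_dilution`: focal element, observed slope,
#'   the vector of null slopes, `p_lower`, `p_upper`, `n`, `R`, `seed`.
#' @export
dilution_test <- function(samples, focal = "si", R = 999L, seed = 1L,
                          log_focal = FALSE) {
  focal <- match.arg(focal, setdiff(ELEMENTS, "c"))
  validate_samples(samples)
  if (length(unique(samples$site_id)) < 2)
    stop("need >= 2 sites", call. = FALSE)
  if (R < 99)
    warning("R < 99 null replicates gives a very coarse p-value grid")
  ord <- order(samples$site_id, samples$block_id, samples$npk,
               samples$fence, samples$c, method = "radix")
  samples <- samples[ord, ]
  n <- nrow(samples)
  x <- samples$c
  site <- samples$site_id
  yobs <- samples[[focal]]
  if (log_focal) {
    if (any(yobs <= 0))
      stop("log response requires positive concentrations", call. = FALSE)
    yobs <- log(yobs)
  }
  obs_fit <- lmm_core_fit(yobs, cbind(`(Intercept)` = 1, c = x), site,
                          "REML")
  observed <- unname(obs_fit$beta["c"])
  nonfocal <- setdiff(ELEMENTS, c(focal, "c"))
  M <- as.matrix(samples[nonfocal])
  picks <- with_seed(seed,
    matrix(sample.int(length(nonfocal), n * R, replace = TRUE), n, R))
  Y <- matrix(M[cbind(rep(seq_len(n), R), as.vector(picks))], n, R)
  if (log_focal) Y <- log(pmax(Y, .Machine$double.xmin))
  null_slopes <- lmm_slope_batch(Y, x, site, "REML")
  structure(list(focal = focal, observed_slope = observed,
                 observed_se = unname(obs_fit$se["c"]),
                 null_slopes = null_slopes,
                 p_lower = (1 + sum(null_slopes <= observed)) / (R + 1),
                 p_upper = (1 + sum(null_slopes >= observed)) / (R + 1),
                 n = n, R = as.integer(R), seed = as.integer(seed),
                 log_focal = log_focal),
            class = "si_dilution")
}

#' @export
print.si_dilution <- function(x, ...) {
  q <- stats::quantile(x$null_slopes, c(0.025, 0.975))
  cat(sprintf(
    "Dilution null for %%%s ~ %%C (n = %d, R = %d)\n", toupper(x$focal),
    x$n, x$R))
  cat(sprintf("  observed slope %.4f; null mean %.4f [%.4f, %.4f]\n",
              x$observed_slope, mean(x$null_slopes), q[1], q[2]))
  cat(sprintf("  p_lower = %.4f, p_upper = %.4f\n", x$p_lower, x$p_upper))
  invisible(x)
}

#' Run the dilution test for every element
#'
#' Applies [dilution_test()] to each of Si, N, P, K, Ca and Mg, with an
#' independent per-element seed derived from `seed`.
#'
#' @inheritParams dilution_test
#' @return named list of `si_dilution` objects.
#' @export
run_all_elements <- function(samples, R = 999L, seed = 1L,
                             log_focal = FALSE) {
  focals <- setdiff(ELEMENTS, "c")
  out <- lapply(seq_along(focals), function(i)
    dilution_test(samples, focals[i], R = R,
                  seed = as.integer((as.numeric(seed) * 131 + i * 9973) %%
                                      2147483587),
                  log_focal = log_focal))
  names(out) <- focals
  out
}

#' Summarise dilution-null results as a table
#'
#' @param results list returned by [run_all_elements()] (or a single
#'   `si_dilution`).
#' @return data.frame with observed slope, null mean and 2.5/97.5
#'   percentiles, and both one-sided p-values per element.
#' @export
dilution_summary <- function(results) {
  if (inherits(results, "si_dilution")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    q <- stats::quantile(r$null_slopes, c(0.025, 0.975), names = FALSE)
    data.frame(element = r$focal, observed_slope = r$observed_slope,
               null_mean = mean(r$null_slopes), null_lo = q[1],
               null_hi = q[2], p_lower = r$p_lower, p_upper = r$p_upper,
               n = r$n, R = r$R, stringsAsFactors = FALSE)
  }))
}
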