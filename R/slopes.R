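# Per-site Si ~ C slopes and their second-stage relationship with site
# precipitation: the leaf-level Si-C trade-off is strong and negative at
# arid sites and fades toward zero as MAP increases.

#' Within-site OLS slopes of %Si on %C
#'
#' Ordinary least-squares regression of leaf Si on leaf C within each
#' site (raw % scale). Sites with fewer than `min_n` usable samples, or
#' with constant leaf C, are skipped with a warning.
#'
#' @param samples plot-level sample table.
#' @param sites optional site table; when supplied, the site covariates
#'   `map`, `mat` and `pet` are attached to the result.
#' @param min_n minimum samples per site (default 3).
#' @param controls_only restrict to unfertilised, unfenced plots.
#' @return data.frame of class `si_site_slopes`: site_id, slope,
#'   intercept, se_slope, n_obs (+ climate covariates when available).
#' @export
site_slopes <- function(samples, sites = NULL, min_n = 3L,
                        controls_only = FALSE) {
  stopifnot_cols(samples, c("site_id", "si", "c"), "samples table")
  if (controls_only) samples <- samples[samples$npk == 0 &
                                          samples$fence == 0, ]
  rows <- lapply(split(samples, samples$site_id), function(d) {
    if (nrow(d) < min_n) {
      warning("site ", d$site_id[1], " skipped: fewer than ", min_n,
              " samples", call. = FALSE)
      return(NULL)
    }
    if (stats::sd(d$c) == 0) {
      warning("site ", d$site_id[1], " skipped: constant leaf C",
              call. = FALSE)
      return(NULL)
    }
    m <- stats::lm(si ~ c, data = d)
    cf <- summary(m)$coefficients
    data.frame(site_id = d$site_id[1], slope = cf["c", "Estimate"],
               intercept = cf["(Intercept)", "Estimate"],
               se_slope = cf["c", "Std. Error"], n_obs = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(sites)) {
    m <- match(out$site_id, sites$site_id)
    for (v in intersect(c("map", "mat", "pet"), names(sites)))
      out[[v]] <- sites[[v]][m]
  }
  class(out) <- c("si_site_slopes", "data.frame")
  out
}

#' Regress per-site Si~C slopes on a climate covariate
#'
#' Second-stage OLS of the site slopes on site MAP (or MAT/PET). A
#' positive coefficient on MAP means the negative Si-C trade-off weakens
#' (moves toward zero) with increasing precipitation. By default the
#' first-stage estimation error is ignored (unweighted OLS); inverse
#' variance weighting by `se_slope^-2` is available and reduces to OLS
#' when all slope SEs are equal.
#'
#' @param slopes a [site_slopes()] result containing the covariate
#'   column.
#' @param covariate `"map"` (default), `"mat"` or `"pet"`.
#' @param weighted inverse-variance weighting of sites.
#' @return list with `gamma0` (intercept), `gamma1` (slope per unit of
#'   the covariate), `se`, `t`, `p`, `n_sites`, and the underlying `lm`
#'   fit.
#' @export
slope_vs_map <- function(slopes, covariate = "map", weighted = FALSE) {
  stopifnot_cols(slopes, c("slope", covariate), "slopes table")
  if (nrow(slopes) < 4)
    stop("need >= 4 sites with estimated slopes", call. = FALSE)
  dat <- data.frame(b = slopes$slope, z = slopes[[covariate]])
  w <- if (weighted) 1 / slopes$se_slope^2 else NULL
  m <- stats::lm(b ~ z, data = dat, weights = w)
  cf <- summary(m)$coefficients
  list(gamma0 = cf["(Intercept)", "Estimate"],
       gamma1 = cf["z", "Estimate"],
       se = cf["z", "Std. Error"],
       t = cf["z", "t value"],
       p = cf["z", "Pr(>|t|)"],
       covariate = covariate, n_sites = nrow(slopes), fit = m)
}
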