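#' Canonical simulation-experiment configurations
#'
#' Named generator configurations for the package's standard simulation
#' experiments. Each isolates one question about the machinery, so some
#' switch off parts of the default data-generating process:
#'
#' * `"npk_recovery"` — headline fertilisation-effect recovery: the
#'   default design with the soil-N attenuation disabled (the experiment
#'   probes the estimator, not the threshold mechanism), beta_npk =
#'   -0.49 and residual noise giving a coefficient SE near 0.11.
#' * `"adjusted_means"` — adjusted-mean recovery: control geometric mean
#'   Si 1.72% dw and +NPK mean 1.27% dw (beta_npk = log(1.27/1.72)),
#'   attenuation disabled.
#' * `"tree_threshold"` — threshold detection: a dense 40-site soil-N
#'   gradient whose mean leaf Si drops and whose Si variation and NPK
#'   response collapse above 0.43% soil N; small site effects so the
#'   threshold, not site noise, dominates.
#' * `"dilution_closure"` — exchangeable pure-closure null: all six
#'   elements follow the same passive-dilution law with equal baseline
#'   means and no Si-specific C coupling; the dilution test should
#'   reject at its nominal rate only.
#' * `"dilution_tradeoff"` — as `"dilution_closure"` but with a genuine
#'   Si-C trade-off injected (slope -0.12 log-Si per %C at the arid end).
#' * `"aridity_slopes"` — slope-vs-precipitation recovery: 17 sites, 5
#'   blocks, within-site slope running from about -0.12 (365 mm) to 0
#'   (1,898 mm), moderate noise.
#'
#' @param name scenario name.
#' @param seed RNG seed for the returned configuration.
#' @return a [generator_config()].
#' @export
scenario_config <- function(name = c("npk_recovery", "adjusted_means",
                                     "tree_threshold", "dilution_closure",
                                     "dilution_tradeoff", "aridity_slopes"),
                            seed = 1L) {
  name <- match.arg(name)
  switch(name,
    npk_recovery = generator_config(
      soil_n_threshold = 2, seed = seed),
    adjusted_means = generator_config(
      mu0 = log(1.72), beta_npk = log(1.27 / 1.72),
      soil_n_threshold = 2, seed = seed),
    tree_threshold = generator_config(
      n_sites = 40, blocks_per_site = c(2L, 2L), beta_npk = -0.49,
      beta_soil_n = -1.2, step_high_n = -0.8, site_sd = 0.3,
      resid_sd = 0.3, atten_factor = 0.1, soil_n_threshold = 0.43,
      soil_n_plot_sd = 0.02, slope_intercept = 0, slope_per_map = 0,
      seed = seed),
    dilution_closure = generator_config(
      n_sites = 10, blocks_per_site = c(4L, 4L), mu0 = 0,
      site_sd = 0.3, resid_sd = 0.4,
      elem_means = c(n = 1, p = 1, k = 1, ca = 1, mg = 1),
      elem_site_sd = 0.3, elem_sample_sd = 0.4,
      slope_intercept = 0, slope_per_map = 0, beta_npk = 0,
      beta_soil_n = 0, step_high_n = 0, soil_n_threshold = 2,
      seed = seed),
    dilution_tradeoff = generator_config(
      n_sites = 10, blocks_per_site = c(4L, 4L), mu0 = 0,
      site_sd = 0.3, resid_sd = 0.4,
      elem_means = c(n = 1, p = 1, k = 1, ca = 1, mg = 1),
      elem_site_sd = 0.3, elem_sample_sd = 0.4,
      slope_intercept = -0.12, slope_per_map = 5e-5, beta_npk = 0,
      beta_soil_n = 0, step_high_n = 0, soil_n_threshold = 2,
      seed = seed),
    aridity_slopes = generator_config(
      blocks_per_site = c(5L, 5L), mu0 = log(1.5), site_sd = 0.2,
      resid_sd = 0.3, beta_soil_n = -0.3, step_high_n = 0,
      soil_n_threshold = 2, seed = seed))
}
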