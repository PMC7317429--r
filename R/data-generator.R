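#' Configuration for the synthetic leaf-chemistry generator
#'
#' Builds a validated configuration describing a hierarchical grassland
#' nutrient-addition experiment: sites spanning climate gradients, 2-5
#' replicate blocks per site, and within each block the 2x2 factorial of
#' NPK fertilisation and grazer-exclusion fencing, with one pooled grass
#' sample per plot. Leaf silicon is generated on the natural-log scale as
#'
#'   log Si = mu0 + beta_soil_n (soilN - center) + g (alpha_site + eps)
#'            + g beta_npk NPK + slope(MAP) (C - mid)
#'
#' and exponentiated; every element concentration is then multiplied by a
#' closure factor (100 - C)/(100 - midC) so that rising leaf carbon
#' dilutes all other constituents ("stoichiometric dilution"). The
#' within-site Si~C slope is a linear function of site precipitation,
#' slope(MAP) = slope_intercept + slope_per_map * MAP. For sites whose
#' soil N exceeds `soil_n_threshold`, the attenuation factor `g =
#' atten_factor` collapses both the NPK response and the site's Si
#' variation toward zero; elsewhere `g = 1`.
#'
#' @param n_sites number of sites.
#' @param blocks_per_site integer range (length 2) of blocks per site.
#' @param map_range mean annual precipitation interval, mm/yr.
#' @param mat_range mean annual temperature interval, degrees C.
#' @param soil_n_range site total soil nitrogen interval, % mass.
#' @param c_range leaf carbon interval, % dry weight.
#' @param mu0 baseline log leaf Si (control plots, covariates centered).
#' @param beta_npk NPK fertilisation effect on log Si.
#' @param beta_soil_n soil-N effect on log Si per % soil N (centered at
#'   the midpoint of `soil_n_range`).
#' @param site_sd SD of site random intercepts on log Si.
#' @param resid_sd residual SD on log Si.
#' @param slope_intercept,slope_per_map within-site Si~C slope (log-Si
#'   per % C) as a linear function of MAP.
#' @param soil_n_threshold soil N (%) above which Si variation and the
#'   NPK response are attenuated.
#' @param atten_factor multiplier applied to `beta_npk`, the site
#'   intercept, and the residual, at sites above the threshold.
#' @param step_high_n drop in mean log Si at sites above the soil-N
#'   threshold (on top of the linear `beta_soil_n` trend): above the
#'   threshold leaf Si sits uniformly low with little variation, rather
#'   than continuing the within-gradient decline.
#' @param soil_n_plot_sd SD of plot-level soil N around the site value.
#' @param elem_means baseline concentrations (% dw) of the five
#'   macronutrients N, P, K, Ca, Mg.
#' @param elem_site_sd,elem_sample_sd lognormal SDs of site-level and
#'   sample-level macronutrient variation.
#' @param seed RNG seed.
#' @return an object of class `si_generator_config` (a named list).
#' @examples
#' cfg <- generator_config(n_sites = 5, seed = 1)
#' d <- generate_dataset(cfg)
#' head(d$samples)
#' @export
generator_config <- function(n_sites = 17,
                             blocks_per_site = c(2L, 5L),
                             map_range = c(365, 1898),
                             mat_range = c(0.3, 22.1),
                             soil_n_range = c(0.05, 1.0),
                             c_range = c(38, 48),
                             mu0 = log(1.72),
                             beta_npk = -0.49,
                             beta_soil_n = -1.1,
                             site_sd = 1.2,
                             resid_sd = 0.85,
                             slope_intercept = -0.1486,
                             slope_per_map = 7.828e-05,
                             soil_n_threshold = 0.43,
                             atten_factor = 0.2,
                             step_high_n = -0.65,
                             soil_n_plot_sd = 0.02,
                             elem_means = c(n = 1.5, p = 0.15, k = 1.5,
                                            ca = 0.4, mg = 0.2),
                             elem_site_sd = 0.25,
                             elem_sample_sd = 0.35,
                             seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              blocks_per_site = as.integer(blocks_per_site),
              map_range = as.numeric(map_range),
              mat_range = as.numeric(mat_range),
              soil_n_range = as.numeric(soil_n_range),
              c_range = as.numeric(c_range),
              mu0 = mu0, beta_npk = beta_npk, beta_soil_n = beta_soil_n,
              site_sd = site_sd, resid_sd = resid_sd,
              slope_intercept = slope_intercept,
              slope_per_map = slope_per_map,
              soil_n_threshold = soil_n_threshold,
              atten_factor = atten_factor,
              step_high_n = step_high_n,
              soil_n_plot_sd = soil_n_plot_sd,
              elem_means = elem_means,
              elem_site_sd = elem_site_sd,
              elem_sample_sd = elem_sample_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "si_generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  rng <- function(x, nm) {
    if (length(x) != 2 || !(x[1] < x[2]))
      stop(nm, " must be an interval with lower bound < upper bound",
           call. = FALSE)
  }
  if (length(cfg$blocks_per_site) != 2 ||
      cfg$blocks_per_site[1] > cfg$blocks_per_site[2] ||
      cfg$blocks_per_site[1] < 1)
    stop("blocks_per_site must be an increasing range of counts >= 1",
         call. = FALSE)
  rng(cfg$map_range, "map_range"); rng(cfg$mat_range, "mat_range")
  rng(cfg$soil_n_range, "soil_n_range"); rng(cfg$c_range, "c_range")
  if (cfg$n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (cfg$site_sd <= 0 || cfg$resid_sd <= 0)
    stop("site_sd and resid_sd must be > 0", call. = FALSE)
  if (cfg$c_range[1] <= 0 || cfg$c_range[2] >= 100)
    stop("infeasible composition: c_range must lie inside (0, 100)",
         call. = FALSE)
  if (cfg$map_range[1] <= 0) stop("map_range must be positive", call. = FALSE)
  if (cfg$soil_n_range[1] < 0)
    stop("infeasible composition: soil_n_range must be non-negative",
         call. = FALSE)
  if (cfg$atten_factor < 0 || cfg$atten_factor > 1)
    stop("atten_factor must be in [0, 1]", call. = FALSE)
  if (any(cfg$elem_means <= 0) ||
      !identical(sort(names(cfg$elem_means)), sort(c("n","p","k","ca","mg"))))
    stop("elem_means must be positive and named n, p, k, ca, mg",
         call. = FALSE)
  if (sum(cfg$elem_means) + cfg$c_range[2] >= 100)
    stop("infeasible composition: baseline element sum reaches closure",
         call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic leaf-chemistry dataset
#'
#' Draws one complete dataset under a [generator_config()]: a site table
#' of climate and soil covariates and a plot-level sample table with the
#' 2x2 NPK x FENCE design and element concentrations (% dry weight).
#' Identical seeds give identical output. Compositional closure (element
#' sum < 100%) is enforced by redrawing the stochastic parts of any
#' offending sample from the same RNG stream.
#'
#' @param config a [generator_config()].
#' @return a list with components `samples` (one row per plot: site_id,
#'   block_id, npk, fence, soil_n (plot level), si, c, n, p, k, ca, mg),
#'   `sites` (site_id, map, mat, pet, soil_n, soil_c, ph, sand, om,
#'   grazing_index), and `truth` (the latent quantities used: site
#'   intercepts, per-site Si~C slopes, attenuation flags).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "si_generator_config"))
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  ns <- cfg$n_sites
  site_id <- sprintf("S%02d", seq_len(ns))
  map  <- runif(ns, cfg$map_range[1], cfg$map_range[2])
  mat  <- runif(ns, cfg$mat_range[1], cfg$mat_range[2])
  pet  <- pmax(50, 500 + 55 * mat + rnorm(ns, 0, 100))
  soil_n <- runif(ns, cfg$soil_n_range[1], cfg$soil_n_range[2])
  soil_c <- pmax(0.05, 11 * soil_n + rnorm(ns, 0, 0.4))
  ph   <- runif(ns, 4.5, 8.0)
  sand <- runif(ns, 10, 90)
  om   <- pmin(100, soil_c * 1.72)
  grazing_index <- sample(0:29, ns, replace = TRUE)
  nblocks <- if (cfg$blocks_per_site[1] == cfg$blocks_per_site[2])
    rep(cfg$blocks_per_site[1], ns)
  else sample(seq(cfg$blocks_per_site[1], cfg$blocks_per_site[2]),
              ns, replace = TRUE)
  alpha <- rnorm(ns, 0, cfg$site_sd)
  g <- ifelse(soil_n > cfg$soil_n_threshold, cfg$atten_factor, 1)
  slope_site <- cfg$slope_intercept + cfg$slope_per_map * map

  sites <- data.frame(site_id = site_id, map = map, mat = mat, pet = pet,
                      soil_n = soil_n, soil_c = soil_c, ph = ph,
                      sand = sand, om = om, grazing_index = grazing_index,
                      stringsAsFactors = FALSE)

  ## plot grid: per site, blocks x {(npk,fence) in (0,0),(0,1),(1,0),(1,1)}
  idx <- rep(seq_len(ns), nblocks * 4L)
  block <- unlist(lapply(nblocks, function(b) rep(seq_len(b), each = 4L)))
  npk   <- rep(c(0L, 0L, 1L, 1L), sum(nblocks))
  fence <- rep(c(0L, 1L, 0L, 1L), sum(nblocks))
  n_obs <- length(idx)

  sn_center <- mean(cfg$soil_n_range)
  c_mid <- mean(cfg$c_range)
  soil_n_plot <- pmax(0.005, soil_n[idx] +
                        if (cfg$soil_n_plot_sd > 0)
                          rnorm(n_obs, 0, cfg$soil_n_plot_sd) else 0)
  cc  <- runif(n_obs, cfg$c_range[1], cfg$c_range[2])
  eps <- rnorm(n_obs, 0, cfg$resid_sd)
  en  <- names(cfg$elem_means)
  site_elem <- matrix(rnorm(ns * length(en), 0, cfg$elem_site_sd), ns,
                      dimnames = list(NULL, en))
  elem_noise <- matrix(rnorm(n_obs * length(en), 0, cfg$elem_sample_sd),
                       n_obs, dimnames = list(NULL, en))

  compose <- function(cc, eps, elem_noise) {
    dil <- (100 - cc) / (100 - c_mid)
    eta <- cfg$mu0 +
      cfg$beta_soil_n * (soil_n_plot - sn_center) +
      cfg$step_high_n * (soil_n_plot > cfg$soil_n_threshold) +
      g[idx] * (alpha[idx] + eps) +
      g[idx] * cfg$beta_npk * npk +
      slope_site[idx] * (cc - c_mid)
    conc <- matrix(0, n_obs, length(en), dimnames = list(NULL, en))
    for (j in en)
      conc[, j] <- cfg$elem_means[[j]] *
        exp(site_elem[idx, j] + elem_noise[, j]) * dil
    list(si = exp(eta) * dil, conc = conc)
  }

  out <- compose(cc, eps, elem_noise)
  total <- out$si + cc + rowSums(out$conc)
  tries <- 0L
  while (any(bad <- total >= 100)) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("infeasible composition: closure cannot be satisfied",
           call. = FALSE)
    nb <- sum(bad)
    ## redraw the stochastic parts of offending samples; if a site's
    ## intercept alone makes closure impossible, redraw it too (site-
    ## level rejection, vanishingly rare under realistic settings)
    if (tries > 25L) {
      bad_sites <- unique(idx[bad])
      alpha[bad_sites] <- rnorm(length(bad_sites), 0, cfg$site_sd)
    }
    eps[bad] <- rnorm(nb, 0, cfg$resid_sd)
    elem_noise[bad, ] <- rnorm(nb * length(en), 0, cfg$elem_sample_sd)
    out <- compose(cc, eps, elem_noise)
    total <- out$si + cc + rowSums(out$conc)
  }

  samples <- data.frame(site_id = site_id[idx],
                        block_id = sprintf("B%d", block),
                        npk = npk, fence = fence,
                        soil_n = soil_n_plot,
                        si = out$si, c = cc,
                        n = out$conc[, "n"], p = out$conc[, "p"],
                        k = out$conc[, "k"], ca = out$conc[, "ca"],
                        mg = out$conc[, "mg"],
                        stringsAsFactors = FALSE)

  list(samples = samples, sites = sites,
       truth = list(alpha = stats::setNames(alpha, site_id),
                    slope_site = stats::setNames(slope_site, site_id),
                    attenuated = stats::setNames(g < 1, site_id),
                    config = cfg))
}
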