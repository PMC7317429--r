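test_that("generation is deterministic and respects the factorial design", {
  cfg <- generator_config(n_sites = 6, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$sites, d2$sites)
  d3 <- generate_dataset(generator_config(n_sites = 6, seed = 100))
  expect_false(identical(d1$samples$si, d3$samples$si))
  ## one record per site x block x treatment cell
  cells <- with(d1$samples, table(site_id, block_id, npk, fence))
  expect_true(all(cells %in% c(0L, 1L)))
  per_site <- table(d1$samples$site_id)
  expect_true(all(per_site %% 4 == 0))
  expect_setequal(unique(d1$samples$npk), c(0L, 1L))
})

test_that("compositional closure and positivity hold across seeds", {
  for (s in 1:5) {
    d <- generate_dataset(generator_config(seed = s))
    conc <- d$samples[c("si", "c", "n", "p", "k", "ca", "mg")]
    expect_true(all(conc > 0))
    expect_true(all(rowSums(conc) < 100))
  }
})

test_that("site covariates respect their documented ranges", {
  d <- generate_dataset(generator_config(n_sites = 50, seed = 2))
  expect_true(all(d$sites$map >= 365 & d$sites$map <= 1898))
  expect_true(all(d$sites$mat >= 0.3 & d$sites$mat <= 22.1))
  expect_true(all(d$sites$grazing_index %in% 0:29))
  expect_true(all(d$sites$pet > 0))
  expect_true(all(d$sites$soil_n >= 0 & d$sites$soil_n <= 100))
})

test_that("degenerate noise recovers the NPK effect exactly per cell", {
  cfg <- generator_config(n_sites = 4, blocks_per_site = c(2L, 2L),
                          beta_npk = -0.49, site_sd = 1e-9,
                          resid_sd = 1e-9, slope_intercept = 0,
                          slope_per_map = 0, soil_n_plot_sd = 0,
                          c_range = c(43 - 1e-9, 43 + 1e-9),
                          soil_n_threshold = 2, seed = 1)
  d <- generate_dataset(cfg)
  ag <- stats::aggregate(log(si) ~ site_id + npk, data = d$samples, mean)
  w <- reshape(ag, idvar = "site_id", timevar = "npk", direction = "wide")
  expect_equal(w[["log(si).1"]] - w[["log(si).0"]],
               rep(-0.49, nrow(w)), tolerance = 1e-6)
})

test_that("null configuration decouples Si from C and NPK", {
  cfg <- generator_config(n_sites = 12, beta_npk = 0, slope_intercept = 0,
                          slope_per_map = 0, beta_soil_n = 0,
                          step_high_n = 0, soil_n_threshold = 2, seed = 3)
  d <- generate_dataset(cfg)
  fit <- fit_lmm(model_spec("npk"), d$samples, d$sites)
  npk <- fit$coefficients[fit$coefficients$term == "npk", ]
  expect_lt(abs(npk$estimate), 3 * npk$se)
  ## residual Si-C association beyond closure is absent: regress log si
  ## (which carries no slope term) on centered C within sites
  s <- d$samples
  r <- stats::residuals(stats::lm(log(si / ((100 - c) / 57)) ~ site_id,
                                  data = s))
  ct <- stats::cor.test(r, s$c)
  expect_gt(ct$p.value, 0.01)
})

test_that("Si is right-skewed and leaf C spans its configured interval", {
  cfg <- generator_config(n_sites = 120, blocks_per_site = c(5L, 5L),
                          seed = 8)
  d <- generate_dataset(cfg)   # 2400 samples
  si <- d$samples$si
  skew <- mean((si - mean(si))^3) / stats::sd(si)^3
  expect_gt(skew, 0.5)
  expect_true(all(d$samples$c >= 38 & d$samples$c <= 48))
  dg <- diagnostics(si)
  expect_lt(dg$ad_pvalue, 0.001)     # raw Si clearly non-normal
})

test_that("site-level log-Si mean SD matches site_sd at 100 sites", {
  cfg <- generator_config(n_sites = 100, blocks_per_site = c(4L, 4L),
                          site_sd = 0.8, resid_sd = 0.05,
                          beta_npk = 0, beta_soil_n = 0, step_high_n = 0,
                          slope_intercept = 0, slope_per_map = 0,
                          soil_n_threshold = 2, seed = 21)
  d <- generate_dataset(cfg)
  sm <- tapply(log(d$samples$si), d$samples$site_id, mean)
  sd_hat <- stats::sd(sm)
  se_sd <- 0.8 / sqrt(2 * (100 - 1))   # large-sample SE of an SD
  expect_lt(abs(sd_hat - 0.8), 3 * se_sd)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(c_range = c(48, 38)), "lower bound")
  expect_error(generator_config(c_range = c(38, 120)), "infeasible")
  expect_error(generator_config(site_sd = 0), "site_sd")
  expect_error(generator_config(elem_means = c(n = 40, p = 30, k = 20,
                                               ca = 5, mg = 5)),
               "infeasible")
  expect_error(generator_config(map_range = c(-10, 100)), "positive")
})

test_that("tables round-trip bit-exactly through CSV", {
  d <- generate_dataset(generator_config(n_sites = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_leaf_tables(d$samples, d$sites, dir)
  back <- read_leaf_tables(dir)
  expect_identical(back$samples, d$samples)
  expect_identical(back$sites, d$sites)
})

test_that("table validation raises named errors", {
  d <- generate_dataset(generator_config(n_sites = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_leaf_tables(d$samples, d$sites, dir)

  bad <- d$samples; bad$si <- NULL
  expect_error(write_leaf_tables(bad, d$sites, dir), "si")

  tab <- utils::read.csv(file.path(dir, "samples.csv"))
  tab$si[1] <- -1
  utils::write.csv(tab, file.path(dir, "samples.csv"), row.names = FALSE)
  expect_error(read_leaf_tables(dir), "negative")

  tab$si[1] <- 1
  tab$p <- "oops"
  utils::write.csv(tab, file.path(dir, "samples.csv"), row.names = FALSE)
  expect_error(read_leaf_tables(dir), "not numeric")

  write_leaf_tables(d$samples, d$sites, dir)
  sites2 <- rbind(d$sites, d$sites[1, ])
  expect_error(write_leaf_tables(d$samples, sites2, dir), "duplicate")
})

test_that("generator configs read back from YAML and JSON", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  writeLines(c("n_sites: 4", "seed: 11", "beta_npk: -0.3"), yml)
  cfg <- read_generator_config(yml)
  expect_equal(cfg$n_sites, 4L)
  expect_equal(cfg$beta_npk, -0.3)
  cfg2 <- read_generator_config(yml, seed = 99)
  expect_equal(cfg2$seed, 99L)
  js <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n_sites = 4, seed = 11), js, auto_unbox = TRUE)
  expect_equal(read_generator_config(js)$n_sites, 4L)
  writeLines(c("n_sites: 4", "bogus_field: 1"), yml)
  expect_error(read_generator_config(yml), "bogus_field")
})
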