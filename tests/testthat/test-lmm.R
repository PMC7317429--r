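test_that("profile optimum matches the 2-D grid-search oracle", {
  for (seed in c(1, 2, 3)) {
    fx <- make_lmm_fixture(seed)
    for (reml in c(TRUE, FALSE)) {
      fit <- grassSi:::lmm_core_fit(fx$y, fx$X, fx$site,
                                    if (reml) "REML" else "ML")
      gr <- oracle_grid_max(fx$y, fx$X, fx$site, reml)
      expect_equal(fit$loglik, gr$loglik, tolerance = 1e-4)
      expect_gte(fit$loglik, gr$loglik - 1e-4)
    }
  }
})

test_that("vanishing site variance degenerates to OLS", {
  fx <- make_lmm_fixture(7, s2a = 0)
  fit <- grassSi:::lmm_core_fit(fx$y, fx$X, fx$site, "REML")
  expect_lt(fit$sigma2_site, 1e-6)
  ols <- stats::lm.fit(fx$X, fx$y)
  expect_equal(unname(fit$beta), unname(ols$coefficients),
               tolerance = 1e-8)
})

test_that("fit agrees with lme4 on coefficients, components and logLik", {
  skip_if_not_installed("lme4")
  d <- generate_dataset(generator_config(n_sites = 8, seed = 11))
  s <- grassSi:::merge_site_covariates(d$samples, d$sites, "soil_c")
  s$logsi <- log(s$si)
  fit <- fit_lmm(model_spec(c("npk", "fence", "soil_c")),
                 d$samples, d$sites)
  m <- lme4::lmer(logsi ~ npk + fence + soil_c + (1 | site_id), data = s,
                  REML = TRUE)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(m)),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma2_site, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(as.matrix(stats::vcov(m))))),
               tolerance = 1e-5)
  mlfit <- fit_lmm(model_spec(c("npk", "fence", "soil_c")),
                   d$samples, d$sites, method = "ML")
  m2 <- lme4::lmer(logsi ~ npk + fence + soil_c + (1 | site_id), data = s,
                   REML = FALSE)
  expect_equal(mlfit$aic, stats::AIC(m2), tolerance = 1e-5)
})

test_that("REML and ML fixed effects agree on balanced designs", {
  fx <- make_lmm_fixture(13)
  reml <- grassSi:::lmm_core_fit(fx$y, fx$X, fx$site, "REML")
  ml <- grassSi:::lmm_core_fit(fx$y, fx$X, fx$site, "ML")
  expect_equal(reml$beta, ml$beta, tolerance = 1e-6)
})

test_that("adding a fixed term never decreases the ML log-likelihood", {
  d <- generate_dataset(generator_config(n_sites = 10, seed = 17))
  terms <- list(character(), "npk", c("npk", "fence"),
                c("npk", "fence", "soil_c"),
                c("npk", "fence", "soil_c", "map"))
  lls <- vapply(terms, function(tt)
    fit_lmm(model_spec(tt), d$samples, d$sites, method = "ML")$loglik,
    numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("rank deficiency and single-site data raise errors", {
  d <- generate_dataset(generator_config(n_sites = 5, seed = 1))
  d$sites$soil_c <- 2 * d$sites$soil_n + 1   # aliased site covariates
  d$samples$soil_n <- NULL                   # force site-level soil N
  expect_error(fit_lmm(model_spec(c("soil_n", "soil_c")),
                       d$samples, d$sites), "aliased")
  one <- d$samples[d$samples$site_id == "S01", ]
  expect_error(fit_lmm(model_spec("npk"), one, d$sites), "2 sites")
})

test_that("model specs validate their terms", {
  expect_error(model_spec("npk", "npk:soil_n"), "fixed terms")
  expect_error(model_spec(c("npk", "npk")), "duplicate")
  expect_error(model_spec("elevation"), "unknown predictor")
  expect_equal(format(model_spec(c("npk", "soil_n"), "npk:soil_n")),
               "logSi ~ npk + soil_n + npk:soil_n + (1|site)")
})

test_that("adjusted means equal back-transformed raw means when balanced", {
  cfg <- generator_config(n_sites = 6, blocks_per_site = c(3L, 3L),
                          soil_n_threshold = 2, seed = 23)
  d <- generate_dataset(cfg)
  fit <- fit_lmm(model_spec("npk"), d$samples, d$sites)
  am <- adjusted_means(fit, "npk")
  raw <- tapply(log(d$samples$si), d$samples$npk, mean)
  ## balanced design: GLS estimate of the npk contrast equals the raw
  ## group-mean contrast, so adjusted means match on the ratio scale
  expect_equal(am$mean[2] / am$mean[1],
               unname(exp(raw["1"] - raw["0"])), tolerance = 1e-8)
  expect_error(adjusted_means(fit, "fence"), "not a fixed term")
  sub <- d$samples[d$samples$npk == 0, ]
  fit0 <- try(fit_lmm(model_spec("npk"), sub, d$sites), silent = TRUE)
  expect_true(inherits(fit0, "try-error"))  # constant npk is aliased
})

test_that("Nakagawa-Schielzeth identities hold", {
  expect_equal(unname(r2_components(1, 1, 2)), c(0.25, 0.5))
  expect_equal(unname(r2_components(0, 3, 2))[1], 0)
  d <- generate_dataset(generator_config(n_sites = 8, seed = 31))
  fit <- fit_lmm(model_spec(c("npk", "soil_n")), d$samples, d$sites)
  r2 <- r2_nakagawa(fit)
  expect_lte(r2[["r2_marginal"]], r2[["r2_conditional"]])
  expect_gte(r2[["r2_marginal"]], 0)
  expect_lte(r2[["r2_conditional"]], 1)
  expect_equal(unname(r2_nakagawa(fit)),
               unname(r2_components(fit$sigma2_fixed, fit$sigma2_site,
                                    fit$sigma2_resid)))
})

test_that("Anderson-Darling test holds its level and detects skew", {
  ## level: fraction of nominal rejections over seeded normal samples
  pvals <- vapply(1:200, function(s) withr::with_seed(s, {
    diagnostics(rnorm(500))$ad_pvalue
  }), numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)
  ## designed alternative: log-normal is flagged hard
  p_skew <- withr::with_seed(4, diagnostics(rlnorm(1000))$ad_pvalue)
  expect_lt(p_skew, 1e-3)
})

test_that("variance score test matches car::ncvTest and has power", {
  skip_if_not_installed("car")
  df <- withr::with_seed(9, {
    x <- runif(300); y <- 1 + 2 * x + rnorm(300, 0, 0.3 + 0.9 * x)
    data.frame(x = x, y = y)
  })
  m <- stats::lm(y ~ x, data = df)
  ours <- diagnostics(stats::residuals(m), stats::fitted(m))
  ref <- car::ncvTest(m)
  expect_equal(ours$ncv_chisq, unname(ref$ChiSquare), tolerance = 1e-6)
  expect_equal(ours$ncv_pvalue, unname(ref$p), tolerance = 1e-6)
  ## power under variance proportional to the mean, n = 500
  rej <- vapply(1:60, function(s) withr::with_seed(s, {
    x <- runif(500, 1, 3)
    y <- x + rnorm(500, 0, 0.4 * sqrt(x))
    m <- stats::lm(y ~ x)
    diagnostics(stats::residuals(m), stats::fitted(m))$ncv_pvalue < 0.05
  }), logical(1))
  expect_gte(mean(rej), 0.8)
  expect_error(diagnostics(rep(1, 20)), "constant")
  expect_error(diagnostics(rnorm(5)), ">= 8")
})

test_that("batched slope fitter agrees with the one-at-a-time fit", {
  d <- generate_dataset(generator_config(n_sites = 7, seed = 41))
  s <- d$samples
  Y <- withr::with_seed(2, matrix(rnorm(nrow(s) * 12, 1.5, 0.4) +
                                    0.01 * s$c, ncol = 12))
  batch <- grassSi:::lmm_slope_batch(Y, s$c, s$site_id)
  single <- vapply(seq_len(ncol(Y)), function(j)
    unname(grassSi:::lmm_core_fit(Y[, j], cbind(1, c = s$c), s$site_id,
                                  "REML")$beta[2]), numeric(1))
  expect_equal(batch, single, tolerance = 1e-3)
})
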