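SITE_PREDICTORS <- c("map", "mat", "pet", "sand", "ph", "om",
                     "soil_c", "soil_n", "grazing_index")
PLOT_PREDICTORS <- c("npk", "fence")

#' Specify a random-intercept mixed model for leaf chemistry
#'
#' Declares the fixed-effect structure of a model with leaf Si (by
#' default natural-log transformed) as the response and a site random
#' intercept, which is always present. Fixed terms are drawn from the
#' treatment flags (`npk`, `fence`) and the site covariates (`map`,
#' `mat`, `pet`, `sand`, `ph`, `om`, `soil_c`, `soil_n`,
#' `grazing_index`); two-way interactions are written `"a:b"` and are
#' only legal when both parents are among the fixed terms.
#'
#' @param fixed character vector of main-effect terms (may be empty for
#'   the intercept-only model).
#' @param interactions character vector of `"a:b"` interaction terms.
#' @param response element column used as response (default `"si"`).
#' @param log_response log-transform the response? (natural log).
#' @return an object of class `si_model_spec`.
#' @export
model_spec <- function(fixed = character(), interactions = character(),
                       response = "si", log_response = TRUE) {
  fixed <- as.character(fixed); interactions <- as.character(interactions)
  allowed <- c(PLOT_PREDICTORS, SITE_PREDICTORS)
  bad <- setdiff(fixed, allowed)
  if (length(bad))
    stop("unknown predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(fixed) || anyDuplicated(interactions))
    stop("duplicate terms in model spec", call. = FALSE)
  for (ia in interactions) {
    parents <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parents) != 2 || !all(parents %in% fixed))
      stop("interaction '", ia,
           "' must name two predictors present among the fixed terms",
           call. = FALSE)
  }
  structure(list(fixed = fixed, interactions = interactions,
                 response = response, log_response = log_response),
            class = "si_model_spec")
}

#' @export
format.si_model_spec <- function(x, ...) {
  lhs <- if (x$log_response) paste0("log", toupper(substring(x$response, 1, 1)),
                                    substring(x$response, 2)) else x$response
  rhs <- c(x$fixed, x$interactions)
  paste0(lhs, " ~ ", if (length(rhs)) paste(rhs, collapse = " + ") else "1",
         " + (1|site)")
}

#' @export
print.si_model_spec <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

spec_formula <- function(spec) {
  rhs <- c(spec$fixed, spec$interactions)
  stats::as.formula(paste("~", if (length(rhs))
    paste(rhs, collapse = " + ") else "1"))
}

#' Attach site covariates to the sample table
#'
#' Copies the requested site-level covariates onto the plot-level sample
#' table by `site_id`. Plot-level columns already present in the samples
#' (e.g. plot soil N) take precedence over the site value.
#'
#' @param samples plot-level sample table.
#' @param sites site covariate table.
#' @param vars covariate names required downstream.
#' @return the samples table with the covariate columns attached.
#' @export
merge_site_covariates <- function(samples, sites, vars) {
  need <- setdiff(intersect(vars, SITE_PREDICTORS), names(samples))
  if (length(need)) {
    if (is.null(sites))
      stop("site covariate(s) ", paste(need, collapse = ", "),
           " needed but no sites table supplied", call. = FALSE)
    m <- match(samples$site_id, sites$site_id)
    if (anyNA(m)) stop("samples reference unknown site_id", call. = FALSE)
    for (v in need) samples[[v]] <- sites[[v]][m]
  }
  samples
}

#' Fit a random-intercept linear mixed model
#'
#' Fits the model declared by a [model_spec()] with a site random
#' intercept, by restricted (default) or full maximum likelihood. The
#' variance ratio sigma2_site/sigma2_resid is profiled so the
#' optimisation is one-dimensional; the boundary sigma2_site = 0 is
#' checked explicitly. AIC is always computed from the ML criterion
#' (refitting when `method = "REML"`) because candidate models differ in
#' their fixed effects; the parameter count follows the convention
#' intercept + fixed terms + two variance components.
#'
#' @param spec a [model_spec()].
#' @param samples plot-level sample table.
#' @param sites site covariate table (may be `NULL` when all predictors
#'   are present in `samples`).
#' @param method `"REML"` (default) or `"ML"`.
#' @return an object of class `si_lmm` with coefficient table, variance
#'   components, log-likelihood, AIC, and Nakagawa-Schielzeth R2.
#' @examples
#' d <- generate_dataset(generator_config(n_sites = 6, seed = 1))
#' fit <- fit_lmm(model_spec(c("npk", "soil_n")), d$samples, d$sites)
#' summary(fit)
#' @export
fit_lmm <- function(spec, samples, sites = NULL,
                    method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "si_model_spec"))
  vars <- unique(c(spec$fixed,
                   unlist(strsplit(spec$interactions, ":", fixed = TRUE))))
  frame <- merge_site_covariates(samples, sites, vars)
  y <- frame[[spec$response]]
  if (is.null(y)) stop("response column '", spec$response, "' not found",
                       call. = FALSE)
  if (spec$log_response) {
    if (any(y <= 0))
      stop("log response requires positive concentrations", call. = FALSE)
    y <- log(y)
  }
  X <- stats::model.matrix(spec_formula(spec), frame)
  core <- lmm_core_fit(y, X, frame$site_id, method)
  mlcore <- if (method == "ML") core else
    lmm_core_fit(y, X, frame$site_id, "ML")
  df <- core$p_fixed + 2L
  cond <- lmm_condition(core)
  fixed_pred <- drop(X %*% core$beta)
  sigma2_fixed <- stats::var(fixed_pred)
  r2 <- r2_components(sigma2_fixed, core$sigma2_site, core$sigma2_resid)
  fit <- list(spec = spec, method = method,
              coefficients = data.frame(term = names(core$beta),
                                        estimate = unname(core$beta),
                                        se = unname(core$se),
                                        t = unname(core$t),
                                        p = unname(core$p),
                                        stringsAsFactors = FALSE),
              vcov = core$vcov,
              sigma2_site = core$sigma2_site,
              sigma2_resid = core$sigma2_resid,
              sigma2_fixed = sigma2_fixed,
              lambda = core$lambda,
              loglik = core$loglik,
              loglik_ml = mlcore$loglik,
              aic = -2 * mlcore$loglik + 2 * df,
              df = df, n = core$n,
              r2_marginal = r2[["r2_marginal"]],
              r2_conditional = r2[["r2_conditional"]],
              fitted = cond$fitted, residuals = cond$residuals,
              blup = stats::setNames(cond$blup, core$prep$levels),
              frame = frame, X = X, y = y)
  class(fit) <- "si_lmm"
  fit
}

#' @export
print.si_lmm <- function(x, ...) {
  cat("Random-intercept LMM (", x$method, "): ", format(x$spec), "\n",
      sep = "")
  cat(sprintf("n = %d, df = %d, logLik = %.3f, AIC(ML) = %.3f\n",
              x$n, x$df, x$loglik, x$aic))
  invisible(x)
}

#' @export
summary.si_lmm <- function(object, ...) {
  print(object)
  cat(sprintf("sigma2_site = %.4f, sigma2_resid = %.4f, R2m = %.3f, R2c = %.3f\n",
              object$sigma2_site, object$sigma2_resid,
              object$r2_marginal, object$r2_conditional))
  print(object$coefficients, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.si_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.si_lmm <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' Adjusted (least-squares) treatment means on the concentration scale
#'
#' Model-predicted response for each level of a binary treatment factor,
#' evaluated with every other model term held at its observed average,
#' then back-transformed from the log scale by plain exponentiation (no
#' bias correction). Standard errors are delta-method transformed.
#'
#' @param fit an [fit_lmm()] object.
#' @param factor `"npk"` or `"fence"` (must be a fixed term of the fit).
#' @return data.frame with columns level, mean, se (on the % dry weight
#'   scale when the model used a log response).
#' @export
adjusted_means <- function(fit, factor = "npk") {
  stopifnot(inherits(fit, "si_lmm"))
  if (!factor %in% fit$spec$fixed)
    stop("factor '", factor, "' is not a fixed term of this model",
         call. = FALSE)
  obs <- unique(fit$frame[[factor]])
  missing_lv <- setdiff(c(0, 1), obs)
  if (length(missing_lv))
    stop("level ", paste(missing_lv, collapse = ", "), " of '", factor,
         "' absent from the data", call. = FALSE)
  vars <- unique(c(fit$spec$fixed,
                   unlist(strsplit(fit$spec$interactions, ":", fixed = TRUE))))
  base <- as.data.frame(lapply(fit$frame[vars], mean))
  grid <- base[rep(1, 2), , drop = FALSE]
  grid[[factor]] <- c(0, 1)
  Xg <- stats::model.matrix(spec_formula(fit$spec), grid)
  eta <- drop(Xg %*% coef(fit))
  se_eta <- sqrt(diag(Xg %*% fit$vcov %*% t(Xg)))
  if (fit$spec$log_response) {
    mean_resp <- exp(eta); se_resp <- exp(eta) * se_eta
  } else {
    mean_resp <- eta; se_resp <- se_eta
  }
  data.frame(factor = factor, level = c(0L, 1L), mean = mean_resp,
             se = se_resp, stringsAsFactors = FALSE)
}

#' Nakagawa-Schielzeth R-squared from variance components
#'
#' Marginal R2 is the fixed-effect share of the total variance,
#' `sigma2_f / (sigma2_f + sigma2_site + sigma2_resid)`; conditional R2
#' adds the site variance to the numerator. `sigma2_f` is the variance of
#' the fixed-effect linear predictor over the observed design.
#'
#' @param sigma2_fixed,sigma2_site,sigma2_resid variance components.
#' @return named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_components <- function(sigma2_fixed, sigma2_site, sigma2_resid) {
  tot <- sigma2_fixed + sigma2_site + sigma2_resid
  c(r2_marginal = sigma2_fixed / tot,
    r2_conditional = (sigma2_fixed + sigma2_site) / tot)
}

#' @rdname r2_components
#' @param fit an [fit_lmm()] object.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "si_lmm"))
  r2_components(fit$sigma2_fixed, fit$sigma2_site, fit$sigma2_resid)
}

#' Distributional diagnostics: normality and non-constant variance
#'
#' Anderson-Darling test of composite normality (parameters estimated
#' from the data) on the residuals or supplied vector, plus a
#' Cook-Weisberg/Breusch-Pagan score test for variance increasing with
#' the fitted values: squared standardised residuals are regressed on the
#' fitted values and half the regression sum of squares is referred to a
#' chi-squared distribution with 1 df.
#'
#' @param x an [fit_lmm()] object (conditional residuals and fitted
#'   values are used) or a numeric vector.
#' @param fitted fitted values matching `x` when `x` is a vector; when
#'   omitted the variance test is skipped (`NA`).
#' @return list with `ad_statistic`, `ad_pvalue`, `ncv_chisq`,
#'   `ncv_pvalue`.
#' @export
diagnostics <- function(x, fitted = NULL) {
  if (inherits(x, "si_lmm")) {
    fitted <- x$fitted
    x <- x$residuals
  }
  x <- as.numeric(x)
  if (length(x) < 8)
    stop("diagnostics require >= 8 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant input: diagnostics undefined", call. = FALSE)
  ad <- nortest::ad.test(x)
  out <- list(ad_statistic = unname(ad$statistic),
              ad_pvalue = unname(ad$p.value),
              ncv_chisq = NA_real_, ncv_pvalue = NA_real_)
  if (!is.null(fitted)) {
    u <- x^2 / mean(x^2)
    m <- stats::lm(u ~ fitted)
    s <- sum((stats::fitted(m) - mean(u))^2) / 2
    out$ncv_chisq <- s
    out$ncv_pvalue <- stats::pchisq(s, df = 1, lower.tail = FALSE)
  }
  out
}
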