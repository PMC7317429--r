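#' Enumerate the candidate model set
#'
#' All subsets of the supplied main effects (the intercept-only model is
#' always included), augmented with whitelisted pairwise interactions —
#' an interaction enters only in models that contain both of its parents,
#' and every subset of the applicable interactions is generated. Order is
#' deterministic: subsets in binary counting order over the predictor
#' list, interaction subsets likewise.
#'
#' @param predictors character vector of main-effect names.
#' @param interaction_whitelist character vector of `"a:b"` pairs that
#'   may interact.
#' @param response,log_response passed to [model_spec()].
#' @return list of [model_spec()] objects.
#' @export
enumerate_candidates <- function(predictors,
                                 interaction_whitelist = character(),
                                 response = "si", log_response = TRUE) {
  if (!length(predictors)) stop("empty predictor list", call. = FALSE)
  if (anyDuplicated(predictors))
    stop("duplicate predictors", call. = FALSE)
  parents <- lapply(interaction_whitelist, function(ia)
    strsplit(ia, ":", fixed = TRUE)[[1]])
  for (i in seq_along(parents))
    if (length(parents[[i]]) != 2 ||
        !all(parents[[i]] %in% predictors))
      stop("interaction '", interaction_whitelist[i],
           "' references a predictor absent from the candidate set",
           call. = FALSE)
  k <- length(predictors)
  specs <- list()
  for (m in 0:(2^k - 1)) {
    main <- predictors[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
    ok <- which(vapply(parents, function(pp) all(pp %in% main), logical(1)))
    subsets <- list(character())
    if (length(ok)) {
      subsets <- lapply(0:(2^length(ok) - 1), function(s)
        interaction_whitelist[ok[bitwAnd(s, bitwShiftL(1L,
          seq_along(ok) - 1L)) > 0]])
    }
    for (ia in subsets)
      specs[[length(specs) + 1L]] <-
        model_spec(main, ia, response, log_response)
  }
  ## deduplicate on the canonical formula string
  specs[!duplicated(vapply(specs, format, character(1)))]
}

#' Rank fitted models by AIC with Akaike weights
#'
#' Sorts a candidate set ascending by AIC, computes dAIC relative to the
#' set minimum and Akaike weights `w_i = exp(-d_i/2) / sum_j exp(-d_j/2)`
#' over exactly the set supplied (the caller controls full-set versus
#' subset semantics), and flags models with dAIC < 2 as `"equivalent"`
#' to the best and dAIC > 7 as `"poor"`. Ties in AIC are broken by fewer
#' parameters, then by the model string.
#'
#' @param fits list of [fit_lmm()] objects (all on the same response and
#'   fitted with the same method), or a numeric vector of AIC values.
#' @param df optional parameter counts when `fits` is numeric.
#' @param model optional model labels when `fits` is numeric.
#' @return data.frame of class `si_model_ranking` with columns model, df,
#'   aic, delta_aic, weight, r2_marginal, r2_conditional, flag.
#' @examples
#' rank_models(c(166.02, 168.64, 169.60, 169.60))
#' @export
rank_models <- function(fits, df = NULL, model = NULL) {
  if (is.numeric(fits)) {
    tab <- data.frame(model = model %||% paste0("model", seq_along(fits)),
                      df = df %||% NA_integer_, aic = as.numeric(fits),
                      r2_marginal = NA_real_, r2_conditional = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    if (!length(fits) || !all(vapply(fits, inherits, logical(1), "si_lmm")))
      stop("fits must be si_lmm objects or a numeric AIC vector",
           call. = FALSE)
    meth <- unique(vapply(fits, `[[`, character(1), "method"))
    if (length(meth) > 1)
      stop("mixed ML/REML fits in one candidate set", call. = FALSE)
    resp <- unique(vapply(fits, function(f)
      paste(f$spec$response, f$spec$log_response), character(1)))
    if (length(resp) > 1)
      stop("fits are not all on the same response", call. = FALSE)
    ns <- unique(vapply(fits, `[[`, numeric(1), "n"))
    if (length(ns) > 1)
      stop("fits are not all on the same data", call. = FALSE)
    tab <- data.frame(model = vapply(fits, function(f) format(f$spec),
                                     character(1)),
                      df = vapply(fits, `[[`, numeric(1), "df"),
                      aic = vapply(fits, `[[`, numeric(1), "aic"),
                      r2_marginal = vapply(fits, `[[`, numeric(1),
                                           "r2_marginal"),
                      r2_conditional = vapply(fits, `[[`, numeric(1),
                                              "r2_conditional"),
                      stringsAsFactors = FALSE)
  }
  delta <- tab$aic - min(tab$aic)
  w <- exp(-delta / 2)
  tab$delta_aic <- delta
  tab$weight <- w / sum(w)
  tab$flag <- ifelse(tab$delta_aic < 2, "equivalent",
                     ifelse(tab$delta_aic > 7, "poor", ""))
  ord <- order(tab$aic, tab$df, tab$model)
  tab <- tab[ord, c("model", "df", "aic", "delta_aic", "weight",
                    "r2_marginal", "r2_conditional", "flag")]
  rownames(tab) <- NULL
  class(tab) <- c("si_model_ranking", "data.frame")
  tab
}

#' Fit and rank a whole candidate set
#'
#' Convenience wrapper: enumerates candidates, fits each by ML (the AIC
#' basis), and ranks them.
#'
#' @inheritParams enumerate_candidates
#' @param samples,sites data tables as in [fit_lmm()].
#' @return an `si_model_ranking` with the fitted models in
#'   `attr(, "fits")`.
#' @export
select_models <- function(predictors, samples, sites,
                          interaction_whitelist = character(),
                          response = "si", log_response = TRUE) {
  specs <- enumerate_candidates(predictors, interaction_whitelist,
                                response, log_response)
  fits <- lapply(specs, fit_lmm, samples = samples, sites = sites,
                 method = "ML")
  rk <- rank_models(fits)
  attr(rk, "fits") <- fits
  rk
}
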