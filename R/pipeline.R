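PIPELINE_STAGES <- c("generate", "diagnostics", "twoway", "select",
                     "tree", "dilution", "slopes", "chemcal")

#' Configure a full pipeline run
#'
#' @param out_dir output directory for stage tables and the manifest.
#' @param generator a [generator_config()], or `NULL` with `input_path`
#'   pointing at existing `samples.csv`/`sites.csv`.
#' @param input_path directory with input tables (overrides `generator`).
#' @param stages subset of generate, diagnostics, twoway, select, tree,
#'   dilution, slopes, chemcal.
#' @param R dilution-null replicates (default 999).
#' @param k_folds cross-validation folds for tree pruning.
#' @param seed master seed; every stage derives its own independent
#'   substream, so adding or removing a stage never perturbs another.
#' @param select_predictors main effects for the model-selection stage.
#' @param select_interactions interaction whitelist.
#' @param tree_predictors predictors for the regression-tree stage.
#' @param chem list of chemometrics settings (n samples, calibration
#'   fraction, PLS components).
#' @return object of class `si_run_config`.
#' @export
run_config <- function(out_dir,
                       generator = generator_config(),
                       input_path = NULL,
                       stages = PIPELINE_STAGES,
                       R = 999L, k_folds = 10L, seed = 42L,
                       select_predictors = c("npk", "fence", "soil_n",
                                             "soil_c", "ph", "map"),
                       select_interactions = c("npk:soil_n"),
                       tree_predictors = c("soil_n", "npk", "fence",
                                           "map", "mat"),
                       chem = list(n = 400L, fraction = 0.2,
                                   n_components = 4L)) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(out_dir = out_dir, generator = generator,
                 input_path = input_path, stages = stages, R = as.integer(R),
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 select_predictors = select_predictors,
                 select_interactions = select_interactions,
                 tree_predictors = tree_predictors, chem = chem),
            class = "si_run_config")
}

#' Run the leaf-silicon analysis pipeline
#'
#' Executes the requested stages in dependency order: data generation or
#' ingestion, response diagnostics, the two-way NPK x FENCE mixed model
#' with adjusted means, AIC model selection, the soil-N threshold
#' regression tree, the stoichiometric-dilution permutation null, the
#' per-site slope ~ precipitation analysis, and the chemometric
#' calibration exercise. Every stage writes its tables under `out_dir`;
#' a JSON manifest records seeds and parameters. Reruns with the same
#' configuration are bit-identical.
#'
#' @param config an [run_config()].
#' @return invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "si_run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- stats::setNames(
    lapply(PIPELINE_STAGES, function(s) stage_seed(config$seed, s)),
    PIPELINE_STAGES)
  res <- list()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible())
    message("[stage] ", name)
    r <- tryCatch(fun(), error = function(e) {
      writeLines(c(paste("stage:", name), paste("error:", conditionMessage(e))),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res[[name]] <<- r
    invisible()
  }

  ## -- data -----------------------------------------------------------
  run_stage("generate", function() {
    d <- if (!is.null(config$input_path)) {
      read_leaf_tables(config$input_path)
    } else {
      gen <- config$generator
      gen$seed <- seeds$generate
      generate_dataset(gen)
    }
    write_leaf_tables(d$samples, d$sites, out)
    d
  })
  dat <- res$generate
  needs_data <- c("diagnostics", "twoway", "select", "tree", "dilution",
                  "slopes")
  if (is.null(dat) && any(config$stages %in% needs_data)) {
    if (!is.null(config$input_path))
      dat <- read_leaf_tables(config$input_path)
    else stop("non-generate stages need data: include the 'generate' ",
              "stage or set input_path", call. = FALSE)
  }

  run_stage("diagnostics", function() {
    dg <- diagnostics(dat$samples$si)
    dg_log <- diagnostics(log(dat$samples$si))
    r <- list(raw_si = dg, log_si = dg_log)
    jsonlite::write_json(r, file.path(out, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    r
  })

  run_stage("twoway", function() {
    fit <- fit_lmm(model_spec(c("npk", "fence"), "npk:fence"),
                   dat$samples, dat$sites)
    utils::write.csv(fit$coefficients,
                     file.path(out, "twoway_coefficients.csv"),
                     row.names = FALSE)
    am <- rbind(adjusted_means(fit, "npk"), adjusted_means(fit, "fence"))
    utils::write.csv(am, file.path(out, "adjusted_means.csv"),
                     row.names = FALSE)
    resid_diag <- diagnostics(fit)
    jsonlite::write_json(resid_diag,
                         file.path(out, "twoway_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    list(fit = fit, adjusted_means = am, residual_diagnostics = resid_diag)
  })

  run_stage("select", function() {
    rk <- select_models(config$select_predictors, dat$samples, dat$sites,
                        config$select_interactions)
    utils::write.csv(as.data.frame(rk),
                     file.path(out, "model_ranking.csv"),
                     row.names = FALSE)
    rk
  })

  run_stage("tree", function() {
    sdat <- merge_site_covariates(dat$samples, dat$sites,
                                  config$tree_predictors)
    tr <- grow_tree(sdat[config$tree_predictors], log(sdat$si),
                    site = sdat$site_id)
    pr <- prune_one_se(tr, k_folds = config$k_folds, seed = seeds$tree)
    utils::write.csv(pr$cp_table, file.path(out, "tree_cp_table.csv"),
                     row.names = FALSE)
    tree_to_json(pr, file.path(out, "tree.json"))
    txt <- utils::capture.output(print(pr))
    writeLines(txt, file.path(out, "tree.txt"))
    pr
  })

  run_stage("dilution", function() {
    dl <- run_all_elements(dat$samples, R = config$R,
                           seed = seeds$dilution)
    utils::write.csv(dilution_summary(dl), file.path(out, "dilution.csv"),
                     row.names = FALSE)
    dl
  })

  run_stage("slopes", function() {
    sl <- site_slopes(dat$samples, dat$sites)
    utils::write.csv(as.data.frame(sl), file.path(out, "site_slopes.csv"),
                     row.names = FALSE)
    sv <- slope_vs_map(sl)
    utils::write.csv(data.frame(covariate = sv$covariate,
                                gamma0 = sv$gamma0, gamma1 = sv$gamma1,
                                se = sv$se, t = sv$t, p = sv$p,
                                n_sites = sv$n_sites),
                     file.path(out, "slope_vs_map.csv"), row.names = FALSE)
    list(slopes = sl, second_stage = sv)
  })

  run_stage("chemcal", function() {
    sp <- simulate_spectra(n = config$chem$n, seed = seeds$chemcal)
    cal_ids <- kennard_stone(sp, config$chem$fraction)
    train <- spectra_matrix(sp$absorbance[cal_ids, , drop = FALSE],
                            sp$wavelengths, cal_ids,
                            sp$reference[cal_ids])
    hold_ids <- setdiff(sp$sample_ids, cal_ids)
    holdout <- spectra_matrix(sp$absorbance[hold_ids, , drop = FALSE],
                              sp$wavelengths, hold_ids,
                              sp$reference[hold_ids])
    model <- fit_pls(train, config$chem$n_components)
    r2 <- validate_pls(model, holdout)
    r <- list(n_calibration = length(cal_ids),
              n_validation = length(hold_ids),
              n_components = model$n_components, validation_r2 = r2)
    jsonlite::write_json(r, file.path(out, "chemcal.json"),
                         auto_unbox = TRUE, digits = NA)
    c(r, list(model = model))
  })

  manifest <- list(
    package = "grassSi",
    version = as.character(utils::packageVersion("grassSi")),
    master_seed = config$seed,
    stage_seeds = seeds[config$stages[config$stages %in% PIPELINE_STAGES]],
    stages = config$stages,
    parameters = list(R = config$R, k_folds = config$k_folds,
                      select_predictors = config$select_predictors,
                      select_interactions = config$select_interactions,
                      tree_predictors = config$tree_predictors,
                      chem = config$chem,
                      generator = if (is.null(config$input_path))
                        unclass(config$generator) else NULL,
                      input_path = config$input_path))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(pipeline_summary(res, config), file.path(out, "summary.txt"))
  invisible(res)
}

pipeline_summary <- function(res, config) {
  lines <- c("grass leaf Si analysis pipeline",
             sprintf("master seed: %d", config$seed),
             sprintf("stages: %s", paste(config$stages, collapse = ", ")))
  if (!is.null(res$twoway)) {
    cf <- res$twoway$fit$coefficients
    npk <- cf[cf$term == "npk", ]
    lines <- c(lines, sprintf(
      "two-way model NPK effect on log Si: %.3f (SE %.3f, t %.2f)",
      npk$estimate, npk$se, npk$t))
  }
  if (!is.null(res$select))
    lines <- c(lines, sprintf("top model: %s (w = %.3f)",
                              res$select$model[1], res$select$weight[1]))
  if (!is.null(res$tree)) {
    nd <- res$tree$nodes[[1]]
    lines <- c(lines, if (!is.na(nd$var))
      sprintf("tree first split: %s < %.3f (selected cp %.4f)", nd$var,
              nd$threshold, res$tree$selected_cp)
      else "tree pruned to root")
  }
  if (!is.null(res$dilution)) {
    ds <- dilution_summary(res$dilution)
    lines <- c(lines, sprintf(
      "dilution null: Si slope %.4f (p_lower %.3f)",
      ds$observed_slope[ds$element == "si"],
      ds$p_lower[ds$element == "si"]))
  }
  if (!is.null(res$slopes))
    lines <- c(lines, sprintf(
      "slope ~ MAP: gamma1 = %.3g (p = %.3g) over %d sites",
      res$slopes$second_stage$gamma1, res$slopes$second_stage$p,
      res$slopes$second_stage$n_sites))
  if (!is.null(res$chemcal))
    lines <- c(lines, sprintf("chemometrics validation R2: %.3f",
                              res$chemcal$validation_r2))
  lines
}
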