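#' Write sample and site tables to CSV
#'
#' Writes `samples.csv` and `sites.csv` into `path` (created if needed).
#' Numeric columns are serialised with 17 significant digits so that a
#' round trip through [read_leaf_tables()] reproduces the doubles
#' bit-exactly; labels and treatment flags round-trip verbatim.
#'
#' @param samples plot-level sample table (see [generate_dataset()]).
#' @param sites site covariate table.
#' @param path output directory.
#' @return invisibly, the two file paths.
#' @export
write_leaf_tables <- function(samples, sites, path) {
  validate_samples(samples)
  validate_sites(sites)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fs <- file.path(path, "samples.csv")
  ft <- file.path(path, "sites.csv")
  utils::write.csv(format_numeric(samples), fs, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(format_numeric(sites), ft, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(samples = fs, sites = ft))
}

format_numeric <- function(df) {
  for (j in names(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Read sample and site tables from CSV
#'
#' Reads and validates `samples.csv` and `sites.csv` from a directory, as
#' written by [write_leaf_tables()]. Missing required columns, duplicated
#' site ids, non-numeric concentrations, negative concentrations and
#' closure violations (element sum >= 100% dry weight) raise named
#' errors.
#'
#' @param path directory holding `samples.csv` and `sites.csv`.
#' @return `list(samples = <data.frame>, sites = <data.frame>)`.
#' @export
read_leaf_tables <- function(path) {
  fs <- file.path(path, "samples.csv")
  ft <- file.path(path, "sites.csv")
  for (f in c(fs, ft))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  samples <- utils::read.csv(fs, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  sites <- utils::read.csv(ft, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  validate_samples(samples)
  validate_sites(sites)
  list(samples = samples, sites = sites)
}

validate_samples <- function(samples) {
  stopifnot_cols(samples, c("site_id", "block_id", "npk", "fence", ELEMENTS),
                 "samples table")
  for (j in ELEMENTS) {
    if (!is.numeric(samples[[j]]))
      stop("samples column '", j, "' is not numeric", call. = FALSE)
    if (anyNA(samples[[j]]))
      stop("samples column '", j, "' has missing values", call. = FALSE)
    if (any(samples[[j]] < 0))
      stop("invariant violation: samples column '", j,
           "' has negative concentrations", call. = FALSE)
  }
  if (!all(samples$npk %in% c(0, 1)) || !all(samples$fence %in% c(0, 1)))
    stop("npk and fence must be binary 0/1 flags", call. = FALSE)
  tot <- rowSums(samples[ELEMENTS])
  if (any(tot >= 100))
    stop("invariant violation: element percentages sum to >= 100 in ",
         sum(tot >= 100), " sample(s)", call. = FALSE)
  invisible(samples)
}

validate_sites <- function(sites) {
  stopifnot_cols(sites, c("site_id", "map", "mat", "pet", "soil_n", "soil_c",
                          "ph", "sand", "om", "grazing_index"), "sites table")
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id in sites table", call. = FALSE)
  num <- setdiff(names(sites), "site_id")
  for (j in num)
    if (!is.numeric(sites[[j]]))
      stop("sites column '", j, "' is not numeric", call. = FALSE)
  if (any(sites$map <= 0) || any(sites$pet <= 0))
    stop("invariant violation: map and pet must be positive", call. = FALSE)
  if (any(sites$grazing_index < 0 | sites$grazing_index > 29))
    stop("invariant violation: grazing_index outside 0-29", call. = FALSE)
  for (j in c("soil_n", "soil_c", "sand", "om"))
    if (any(sites[[j]] < 0 | sites[[j]] > 100))
      stop("invariant violation: sites column '", j,
           "' outside [0, 100]", call. = FALSE)
  invisible(sites)
}

#' Read a generator configuration from YAML or JSON
#'
#' The file holds a mapping whose keys mirror the arguments of
#' [generator_config()]; absent keys fall back to the defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param seed optional seed overriding the file's value.
#' @return a [generator_config()].
#' @export
read_generator_config <- function(path, seed = NULL) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(seed)) vals$seed <- seed
  if (!is.null(vals$elem_means)) vals$elem_means <- unlist(vals$elem_means)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown generator config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(generator_config, vals)
}
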