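# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a local RNG state: seeds the Mersenne-Twister stream,
## restores whatever state the caller had on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(code)
}

## Derive a per-stage seed from a master seed. Offsets are fixed per stage
## name so adding a stage never perturbs another stage's stream; result is
## kept inside the 32-bit integer range.
stage_seed <- function(master, stage) {
  offsets <- c(generate = 101L, diagnostics = 211L, twoway = 307L,
               select = 401L, tree = 503L, dilution = 601L,
               slopes = 701L, chemcal = 809L)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master) * 97 + off) %% 2147483587)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

## elements tracked on every leaf sample (% dry weight)
ELEMENTS <- c("si", "c", "n", "p", "k", "ca", "mg")
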