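# Classed conditions so callers (and tests) can distinguish bad input from
# numerical failure from inconsistent measurements.

input_error <- function(msg) {
  errorCondition(msg, class = c("rugatecam_input_error", "rugatecam_error"))
}

numeric_error <- function(msg) {
  errorCondition(msg, class = c("rugatecam_numeric_error", "rugatecam_error"))
}

data_error <- function(msg) {
  errorCondition(msg, class = c("rugatecam_data_error", "rugatecam_error"))
}

inconsistent_error <- function(msg) {
  errorCondition(msg, class = c("rugatecam_inconsistent_error", "rugatecam_error"))
}

rugatecam_warning <- function(msg, class) {
  warningCondition(msg, class = c(class, "rugatecam_warning"))
}

# Run `expr` with the RNG seeded by `seed` (when non-NULL) and the caller's
# RNG state restored afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
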