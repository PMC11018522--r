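`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a local RNG stream so callers' .Random.seed survives.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# structured (stage, key, value) log line; suppress with options(pbeqtl.quiet = TRUE)
log_stage <- function(stage, key, value) {
  if (isTRUE(getOption("pbeqtl.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s = %s", stage, key, paste(value, collapse = ",")))
}

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)
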