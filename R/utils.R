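# internal helpers shared across modules

.datatable.aware <- TRUE

#' Evaluate an expression under a local, restored RNG state
#'
#' All randomized operations in the package draw from explicitly seeded local
#' streams so that a global seed fans out deterministically and user RNG state
#' is never clobbered.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stage seed derivation from one global seed; kept below
# .Machine$integer.max so the result is always a valid R seed
stage_seed <- function(global_seed, stage) {
  (as.numeric(global_seed) * 7919 + stage * 1000003) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)
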