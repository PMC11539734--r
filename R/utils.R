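# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
rf_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "rf_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# All ids are character tokens; premise slots are character vectors treated as
# sets (order irrelevant, no duplicates after validation).
#' @keywords internal
#' @noRd
as_id_set <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  unique(as.character(x))
}

#' @keywords internal
#' @noRd
set_equal <- function(a, b) setequal(as.character(a), as.character(b))

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# sample() without its length-1 surprise.
#' @keywords internal
#' @noRd
sample_ids <- function(x, size) {
  if (size == 0L) return(x[0])
  x[sample.int(length(x), size)]
}
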