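# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded pipeline stages do not perturb user code.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage offset, kept < 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483587)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_field(field, sprintf("must be a single integer >= %s", min))
  }
  invisible(as.integer(x))
}
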