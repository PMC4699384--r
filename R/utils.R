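# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

#' Check a scalar is a single finite number
#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower)
    stop_bad("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_bad("'%s' must be >= %g", name, lower)
  if (x > upper)
    stop_bad("'%s' must be <= %g", name, upper)
  invisible(x)
}

#' @noRd
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < 1)
    stop_bad("'%s' must be a positive integer", name)
  as.integer(x)
}

#' @noRd
check_prob <- function(x, name) check_number(x, name, lower = 0, upper = 1)

#' @noRd
check_seed <- function(seed) {
  if (is.null(seed)) stop_bad("'seed' is required")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stop_bad("'seed' must be a single integer")
  as.integer(seed)
}

#' Evaluate an expression with a locally seeded RNG, restoring global state.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed (stable, < 2^31) from a base seed and a stream label.
#' @noRd
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 1000L + (abs(sum(utf8ToInt(stream))) %% 1000L)
}
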