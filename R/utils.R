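#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state so callers never perturb the user's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) stop(sprintf("'%s' must be finite", name), call. = FALSE)
  invisible(x)
}

stop_if_not_positive <- function(x, name) {
  stop_if_not_finite(x, name)
  if (any(x <= 0)) stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# nearest odd integer >= 3, used for filter window lengths
odd_window <- function(n) {
  n <- max(3L, as.integer(round(n)))
  if (n %% 2L == 0L) n + 1L else n
}
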