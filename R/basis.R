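#' Raised-cosine basis set
#'
#' Builds `n` half-overlapping raised-cosine bumps spanning a support
#' interval. Event kernels use a time-lag domain sampled at the session bin
#' size; tuning kernels use a grid of value-bin indices (position or speed
#' bins). Bump centres are linearly spaced with the first and last centre at
#' the support edges; each bump has a half-width of twice the centre spacing,
#' so on the interior of the support the bumps sum to a constant.
#'
#' @param n number of bumps (>= 1).
#' @param support numeric length-2 window. For event kernels, the time-lag
#'   window in seconds (may be acausal, e.g. `c(-2, 0)` for anticipatory
#'   kernels). For tuning kernels, the inclusive range of value-bin indices.
#' @param step grid step. Bin size in seconds for event kernels; 1 for
#'   tuning kernels.
#' @param kind `"event"` or `"tuning"`.
#' @return an object of class `raised_cosine_basis` with elements `n`,
#'   `kind`, `support`, `step`, `grid` (domain samples), `centres`,
#'   `spacing`, and `B`, the `length(grid) x n` matrix of bump values.
#' @examples
#' b <- raised_cosine_basis(10, c(0, 0.46), 0.01)
#' colSums(b$B > 0)            # every bump covers part of the window
#' @export
raised_cosine_basis <- function(n, support, step = 1, kind = c("event", "tuning")) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  stop_if_not_finite(support, "support")
  if (length(support) != 2L || diff(support) <= 0) {
    stop("'support' must be an increasing length-2 interval", call. = FALSE)
  }
  stop_if_not_positive(step, "step")
  if (kind == "event") {
    L <- max(1L, as.integer(round(diff(support) / step)))
    grid <- support[1] + step * (seq_len(L) - 1L)
  } else {
    grid <- seq(support[1], support[2], by = step)
    L <- length(grid)
  }
  if (n > L) {
    stop(sprintf("cannot place %d bumps on a grid of %d points", n, L), call. = FALSE)
  }
  if (n == 1L) {
    centres <- mean(support)
    spacing <- diff(support) / 2
  } else {
    centres <- seq(grid[1], grid[L], length.out = n)
    spacing <- (grid[L] - grid[1]) / (n - 1)
  }
  obj <- structure(
    list(n = n, kind = kind, support = support, step = step,
         grid = grid, centres = centres, spacing = spacing),
    class = "raised_cosine_basis")
  obj$B <- basis_eval(obj, grid)
  obj
}

#' Evaluate raised-cosine bumps at arbitrary domain points
#'
#' @param basis a [raised_cosine_basis()] object.
#' @param x numeric vector of domain points (time lags or value-bin indices).
#' @return a `length(x) x n` matrix of bump values in `[0, 1]`.
#' @export
basis_eval <- function(basis, x) {
  stopifnot(inherits(basis, "raised_cosine_basis"))
  half <- if (basis$n == 1L) basis$spacing else 2 * basis$spacing
  B <- vapply(basis$centres, function(cc) {
    d <- x - cc
    v <- 0.5 * (1 + cos(pi * d / half))
    v[abs(d) >= half] <- 0
    v
  }, numeric(length(x)))
  matrix(B, nrow = length(x), ncol = basis$n)
}

#' Reconstruct a kernel from basis coefficients
#'
#' @param basis a [raised_cosine_basis()] object.
#' @param w coefficient vector of length `basis$n`.
#' @return numeric kernel values on `basis$grid`.
#' @export
basis_kernel <- function(basis, w) {
  stopifnot(inherits(basis, "raised_cosine_basis"), length(w) == basis$n)
  as.numeric(basis$B %*% w)
}

#' Project a kernel onto a basis (least squares)
#'
#' @param basis a [raised_cosine_basis()] object.
#' @param k kernel values on `basis$grid`.
#' @return coefficient vector minimizing the squared residual.
#' @export
basis_project <- function(basis, k) {
  stopifnot(inherits(basis, "raised_cosine_basis"), length(k) == length(basis$grid))
  as.numeric(qr.solve(basis$B, k))
}

#' @export
print.raised_cosine_basis <- function(x, ...) {
  cat(sprintf("<raised_cosine_basis> %d %s bumps on [%g, %g], %d grid points\n",
              x$n, x$kind, x$support[1], x$support[2], length(x$grid)))
  invisible(x)
}
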