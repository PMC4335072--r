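#' Restore a single removed cell from remembered distances
#'
#' Closed-form counterpart of the engine for the simplest amputation:
#' with cells off-lattice (continuous positions), removing one cell C
#' leaves each remaining control cell with a signal deficit
#' f(d_iC). Because the kernel is strictly decreasing, matching the old
#' signal forces the distance from each control cell i back to its old
#' value d_iC, i.e. C must lie on the circle of radius d_iC around i.
#' With two control cells the two circles generically intersect in two
#' points (one the original position, the other its mirror image across
#' the line joining the controls); with three or more non-collinear
#' controls the common intersection is generically unique.
#'
#' @param controls numeric matrix (or data frame) with columns `x`, `y`:
#'   positions of at least two distinct control cells.
#' @param distances positive remembered distances, one per control cell.
#' @param tol relative tolerance for tangency classification and for
#'   membership of a point on the remaining circles (default `1e-9`).
#' @return numeric matrix with columns `x`, `y`: 0, 1 or 2 candidate
#'   positions. Zero rows means the distance constraints are
#'   inconsistent (no common intersection) — a result, not an error.
#' @examples
#' restore_single_cell(rbind(c(0, 0), c(2, 0)), c(sqrt(2), sqrt(2)))
#' # two candidates: (1, 1) and (1, -1)
#' @export
restore_single_cell <- function(controls, distances, tol = 1e-9) {
  p <- as.matrix(as.data.frame(controls))
  if (ncol(p) < 2L) stop("controls must have x and y columns", call. = FALSE)
  p <- p[, 1:2, drop = FALSE]
  m <- nrow(p)
  if (m < 2L) stop("need at least two control cells", call. = FALSE)
  if (length(distances) != m || any(distances <= 0)) {
    stop("one positive distance per control cell is required", call. = FALSE)
  }
  if (anyDuplicated(paste(p[, 1], p[, 2]))) {
    stop("control cells must be at distinct positions", call. = FALSE)
  }

  cand <- circle_intersection(p[1, ], distances[1], p[2, ], distances[2], tol)
  if (m > 2L && nrow(cand) > 0L) {
    # keep points lying (within tol, relative to the radius) on every
    # remaining circle: the common intersection of all m circles
    keep <- rep(TRUE, nrow(cand))
    for (j in 3:m) {
      dj <- sqrt((cand[, 1] - p[j, 1])^2 + (cand[, 2] - p[j, 2])^2)
      keep <- keep & abs(dj - distances[j]) <= tol * max(1, distances[j])
    }
    cand <- cand[keep, , drop = FALSE]
  }
  colnames(cand) <- c("x", "y")
  cand
}

# standard two-circle intersection; returns a 0-, 1- or 2-row matrix
circle_intersection <- function(c1, r1, c2, r2, tol = 1e-9) {
  dx <- c2[1] - c1[1]; dy <- c2[2] - c1[2]
  d <- sqrt(dx * dx + dy * dy)
  scale <- max(1, r1, r2, d)
  none <- matrix(numeric(0), ncol = 2L)
  if (d > r1 + r2 + tol * scale) return(none)        # separate
  if (d < abs(r1 - r2) - tol * scale) return(none)   # one inside the other
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r1^2 - a^2
  mx <- c1[1] + a * dx / d
  my <- c1[2] + a * dy / d
  if (h2 <= (tol * scale)^2) {                       # tangency: one point
    return(matrix(c(mx, my), ncol = 2L))
  }
  h <- sqrt(h2)
  rbind(c(mx + h * dy / d, my - h * dx / d),
        c(mx - h * dy / d, my + h * dx / d))
}

#' Steady state of the nonlinear diffusion problem with power-law decay
#'
#' Signals decaying polynomially with distance arise as steady states of
#' a diffusion equation with concentration-dependent diffusivity
#' \eqn{a(u) = u^{-k}} and linear consumption:
#' \deqn{(a(u) u')' - b u = 0, \quad x > 0, \quad u(0) = 1,}
#' with u decaying at infinity. The closed-form solution is
#' \deqn{u(x) = (1 + c x)^{-2/k}, \qquad
#'       c = \frac{k}{2} \sqrt{\frac{2b}{2-k}},}
#' which exists for any \eqn{0 < k < 2} and decays like \eqn{x^{-2/k}} —
#' any polynomial rate \eqn{x^{-n}} with n > 1, covering the decay rates
#' used by the lattice kernels.
#'
#' @param k nonlinearity exponent, in the open interval (0, 2).
#' @param b positive consumption rate.
#' @return an object of class `diffusion_solution`: list with `k`, `b`,
#'   the derived constant `c`, and `u`, the solution as a vectorized
#'   function of `x >= 0`.
#' @examples
#' sol <- diffusion_solution(k = 1, b = 1)
#' sol$c        # sqrt(2)/2 = 0.70711...
#' sol$u(0)     # 1
#' @export
diffusion_solution <- function(k, b) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k >= 2) {
    stop("k must lie strictly between 0 and 2", call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || b <= 0) {
    stop("b must be positive", call. = FALSE)
  }
  cc <- (k / 2) * sqrt(2 * b / (2 - k))
  u <- function(x) {
    if (any(x < 0)) stop("solution is defined on x >= 0", call. = FALSE)
    (1 + cc * x)^(-2 / k)
  }
  structure(list(k = k, b = b, c = cc, u = u), class = "diffusion_solution")
}

#' @export
print.diffusion_solution <- function(x, ...) {
  cat(sprintf("<diffusion_solution> u(x) = (1 + %.6g x)^(-%.6g), k = %g, b = %g\n",
              x$c, 2 / x$k, x$k, x$b))
  invisible(x)
}

#' Residual of the diffusion ODE for a closed-form solution
#'
#' Evaluates \eqn{|(a(u)u')' - b u|} on a grid using the exact
#' derivatives of the closed form: with \eqn{u = (1+cx)^{-2/k}},
#' \eqn{a(u) u' = -(2c/k)(1+cx)^{1-2/k}} and
#' \eqn{(a(u)u')' = (2c^2/k)(2/k - 1)(1+cx)^{-2/k}}. For the correct
#' constant c the residual is zero up to floating-point rounding; a
#' perturbed c fails by a visible margin.
#'
#' @param solution a [diffusion_solution()].
#' @param x strictly positive, finite evaluation grid.
#' @return the maximum absolute residual over the grid.
#' @export
ode_residual <- function(solution, x) {
  stopifnot(inherits(solution, "diffusion_solution"))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("grid must be strictly positive and finite", call. = FALSE)
  }
  k <- solution$k; b <- solution$b; cc <- solution$c
  flux_deriv <- (2 * cc^2 / k) * (2 / k - 1) * (1 + cc * x)^(-2 / k)
  max(abs(flux_deriv - b * solution$u(x)))
}
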