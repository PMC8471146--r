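#' Quadratic spline interpolation
#'
#' Interpolates `(x, y)` with a C1 piecewise-quadratic (order-2 B-spline)
#' curve and evaluates it at `xout`. Interior knots sit at the midpoints of
#' the data abscissae (the conventional choice for even-degree interpolating
#' splines), so the spline passes exactly through every data point and
#' reproduces polynomials of degree <= 2 without error.
#'
#' @param x strictly increasing abscissae (length >= 3).
#' @param y ordinates, same length as `x`.
#' @param xout evaluation points; must lie within `[min(x), max(x)]`.
#' @return numeric vector of interpolated values at `xout`.
#' @examples
#' x <- seq(0, 1, by = 0.1)
#' quad_spline(x, x^2, c(0.05, 0.55))  # exact: 0.0025, 0.3025
#' @export
quad_spline <- function(x, y, xout) {
  x <- as.numeric(x); y <- as.numeric(y); xout <- as.numeric(xout)
  n <- length(x)
  if (n < 3L)
    prv_error("prvkit_too_few_samples", "quadratic spline needs at least 3 points")
  if (length(y) != n)
    prv_error("prvkit_invalid_argument", "x and y lengths differ")
  if (any(diff(x) <= 0))
    prv_error("prvkit_invalid_argument", "x must be strictly increasing")
  if (any(xout < x[1] - 1e-9) || any(xout > x[n] + 1e-9))
    prv_error("prvkit_invalid_argument", "xout outside the data range")

  # Knot vector: triple boundary knots + interior midpoints (drop the first
  # and last midpoint) => n + 3 knots, n basis functions; Schoenberg-Whitney
  # holds, so the collocation system is nonsingular.
  mid <- (x[-1] + x[-n]) / 2
  interior <- if (n >= 4L) mid[seq(2L, n - 2L)] else numeric(0)
  knots <- c(rep(x[1], 3L), interior, rep(x[n], 3L))

  basis <- quad_bspline_basis(x, knots, n)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 3L),
    j = c(basis$j0, basis$j0 + 1L, basis$j0 + 2L),
    x = c(basis$b0, basis$b1, basis$b2),
    dims = c(n, n)
  )
  coef <- as.numeric(Matrix::solve(A, y))

  bo <- quad_bspline_basis(pmin(pmax(xout, x[1]), x[n]), knots, n)
  bo$b0 * coef[bo$j0] + bo$b1 * coef[bo$j0 + 1L] + bo$b2 * coef[bo$j0 + 2L]
}

# Evaluate the three nonzero quadratic B-spline basis functions at each u.
# Returns j0 (index of the first nonzero basis function, 1-based) and the
# basis values b0, b1, b2 for indices j0, j0+1, j0+2. de Boor's triangular
# scheme, unrolled for degree 2 and vectorized over u.
quad_bspline_basis <- function(u, knots, n_basis) {
  m <- findInterval(u, knots)          # knots[m] <= u < knots[m+1]
  m[m < 3L] <- 3L                      # clamp into the valid span range
  m[m > n_basis] <- n_basis            # right-closed at the last point

  left1 <- u - knots[m];      right1 <- knots[m + 1L] - u
  left2 <- u - knots[m - 1L]; right2 <- knots[m + 2L] - u

  # degree 1
  t1 <- 1 / (right1 + left1)
  N0 <- right1 * t1
  N1 <- left1 * t1
  # degree 2
  t2 <- N0 / (right1 + left2)
  B0 <- right1 * t2
  s <- left2 * t2
  t3 <- N1 / (right2 + left1)
  B1 <- s + right2 * t3
  B2 <- left1 * t3

  list(j0 = m - 2L, b0 = B0, b1 = B1, b2 = B2)
}

#' Resample a BVP signal with a quadratic spline
#'
#' Re-grids a BVP signal onto a finer uniform grid at `fs_target` using
#' [quad_spline()]. The new grid starts at the original first sample and
#' spans the same time range; original sample instants reproduce the
#' original values exactly. Used to bring the 30 Hz camera channel up to the
#' 255 Hz contact rate before peak detection, so both channels offer the
#' same peak-timing resolution.
#'
#' @param bvp a [bvp_signal()].
#' @param fs_target target sampling rate in Hz; must exceed `bvp$fs`.
#' @return a `bvp_signal` at `fs_target`.
#' @export
resample_quadratic_spline <- function(bvp, fs_target) {
  stopifnot(inherits(bvp, "bvp_signal"))
  if (length(bvp$samples) < 3L)
    prv_error("prvkit_too_few_samples", "resampling needs at least 3 samples")
  if (fs_target <= bvp$fs)
    prv_error("prvkit_invalid_argument", "fs_target must exceed the input rate")
  t_rel <- (seq_along(bvp$samples) - 1) / bvp$fs
  t_end <- t_rel[length(t_rel)]
  t_new <- seq(0, t_end, by = 1 / fs_target)
  bvp_signal(quad_spline(t_rel, bvp$samples, t_new), fs = fs_target, t0 = bvp$t0)
}
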