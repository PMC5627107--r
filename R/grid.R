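#' Build a cell-centered space-time grid
#'
#' Constructs the uniform tensor grid used by every solver in the package: a
#' cell-centered discretization of a rectangular domain
#' \eqn{\Omega = [a_1,b_1]\times[a_2,b_2]} together with a uniform time grid on
#' \eqn{[0,T]} containing both endpoints. All spatial integrals in the package
#' are midpoint (cell-center times cell-area) sums, which pairs naturally with
#' the conservative finite-volume flux discretization of the forward solver.
#'
#' @param bounds Domain bounds: a list of two length-2 numeric vectors
#'   \code{list(c(a1, b1), c(a2, b2))}, or a 2x2 matrix with one row per axis.
#' @param n_cells Number of cells per axis; a single integer (same on both
#'   axes) or a length-2 integer vector. Must be >= 4.
#' @param horizon Time horizon \code{T > 0}.
#' @param n_steps Number of uniform time steps \code{M >= 2}; the grid carries
#'   \code{M + 1} time nodes \eqn{t_0 = 0, \dots, t_M = T}.
#'
#' @return An object of class \code{"fp_grid"}: a list with elements
#'   \code{bounds} (2x2 matrix), \code{n_cells}, \code{h} (cell widths),
#'   \code{centers} (list of per-axis cell-center vectors), \code{cell_area},
#'   \code{horizon}, \code{n_steps}, \code{dt}, \code{times} (length
#'   \code{n_steps + 1}).
#'
#' @examples
#' g <- build_grid(list(c(-3, 3), c(-3, 3)), n_cells = 50, horizon = 3, n_steps = 50)
#' g$h        # 0.12 0.12
#' g$dt       # 0.06
#' @export
build_grid <- function(bounds, n_cells, horizon, n_steps) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- matrix(as.numeric(bounds), nrow = 2L)
  if (nrow(bounds) != 2L || ncol(bounds) != 2L || any(!is.finite(bounds)))
    stop("`bounds` must give two finite intervals, one per spatial axis")
  if (any(bounds[, 2L] <= bounds[, 1L]))
    stop("dimension error: each axis interval must have positive length")
  n_cells <- rep_len(as.integer(n_cells), 2L)
  if (any(n_cells < 4L)) stop("dimension error: need at least 4 cells per axis")
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("dimension error: need at least 2 time steps")
  if (!is.finite(horizon) || horizon <= 0) stop("dimension error: horizon must be > 0")

  len <- bounds[, 2L] - bounds[, 1L]
  h <- len / n_cells
  centers <- lapply(1:2, function(d)
    bounds[d, 1L] + h[d] * (seq_len(n_cells[d]) - 0.5))
  dt <- horizon / n_steps
  structure(list(
    bounds    = bounds,
    n_cells   = n_cells,
    h         = h,
    centers   = centers,
    cell_area = prod(h),
    horizon   = horizon,
    n_steps   = n_steps,
    dt        = dt,
    times     = dt * (0:n_steps)
  ), class = "fp_grid")
}

#' @export
print.fp_grid <- function(x, ...) {
  cat(sprintf("<fp_grid> Omega = [%g, %g] x [%g, %g], %d x %d cells (h = %g, %g)\n",
              x$bounds[1, 1], x$bounds[1, 2], x$bounds[2, 1], x$bounds[2, 2],
              x$n_cells[1], x$n_cells[2], x$h[1], x$h[2]))
  cat(sprintf("          T = %g, %d steps (dt = %g)\n", x$horizon, x$n_steps, x$dt))
  invisible(x)
}

# trapezoid weights on the time grid (dt/2 at endpoints, dt inside)
time_weights <- function(grid) {
  w <- rep(grid$dt, grid$n_steps + 1L)
  w[c(1L, grid$n_steps + 1L)] <- grid$dt / 2
  w
}

# coerce a field argument to a plain cell matrix at one time node
slice_at <- function(field, grid, time_index) {
  if (inherits(field, "fp_field")) {
    m <- dim(field$values)[1L]
    if (time_index < 1L || time_index > m)
      stop("time_index out of range [1, ", m, "]")
    matrix(field$values[time_index, , ], grid$n_cells[1L], grid$n_cells[2L])
  } else {
    f <- as.matrix(field)
    if (!identical(dim(f), as.integer(grid$n_cells)))
      stop("shape error: field dimensions do not match the grid")
    f
  }
}

#' Total probability mass of a density slice
#'
#' Cell-sum quadrature \eqn{\sum_c f(x_c)\, h_1 h_2} of a field at one time
#' node. For a valid probability density this equals 1.
#'
#' @param field An \code{fp_field} (see [solve_fp()]) or a cell matrix.
#' @param grid The \code{fp_grid} the field lives on.
#' @param time_index 1-based time-node index (ignored for a plain matrix).
#' @return Scalar mass.
#' @export
mass <- function(field, grid, time_index = 1L) {
  sum(slice_at(field, grid, time_index)) * grid$cell_area
}

#' Mean position of a density slice
#'
#' First moment \eqn{\sum_c x_c f(x_c) h_1 h_2} of a (unit-mass) density at a
#' time node; the quantity whose trajectory the scenario reports track.
#'
#' @inheritParams mass
#' @return Length-2 numeric vector (the mean position in \eqn{\Omega}).
#' @export
mean_position <- function(field, grid, time_index = 1L) {
  f <- slice_at(field, grid, time_index)
  m <- sum(f) * grid$cell_area
  if (m <= .Machine$double.eps)
    stop("undefined mean: field has (numerically) zero mass")
  c(sum(grid$centers[[1L]] * rowSums(f)),
    sum(grid$centers[[2L]] * colSums(f))) * grid$cell_area / m
}

#' Spatial overlap of two densities
#'
#' Cell quadrature of \eqn{\int_\Omega f^{(1)} f^{(2)}\,dx} at one time node;
#' the building block of the collision cost and of the small-radius collision
#' probability.
#'
#' @param field1,field2 Two fields on the same grid.
#' @inheritParams mass
#' @return Nonnegative scalar; zero iff the supports are disjoint at the
#'   quadrature resolution.
#' @export
overlap <- function(field1, field2, grid, time_index = 1L) {
  f1 <- slice_at(field1, grid, time_index)
  f2 <- slice_at(field2, grid, time_index)
  sum(f1 * f2) * grid$cell_area
}

# constructor for space-time fields (densities, adjoints)
fp_field <- function(values, grid, role = "density") {
  structure(list(values = values, grid = grid, role = role), class = "fp_field")
}

#' @export
print.fp_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fp_field: %s> %d time nodes on %d x %d cells\n",
              x$role, d[1], d[2], d[3]))
  invisible(x)
}

#' Mean trajectory of a density field
#'
#' @param field An \code{fp_field} density.
#' @param grid Its grid.
#' @return Matrix with \code{n_steps + 1} rows and columns \code{x}, \code{y}.
#' @export
mean_trajectory <- function(field, grid = field$grid) {
  m <- dim(field$values)[1L]
  out <- t(vapply(seq_len(m), function(k) mean_position(field, grid, k),
                  numeric(2)))
  colnames(out) <- c("x", "y")
  out
}
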