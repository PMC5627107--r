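# Forward Fokker-Planck solver with drift-decomposed transport.
#
# The drift of each pedestrian is b(t) = v + u(t) with a constant base
# velocity v and a purely time-dependent control u.  The two parts are
# propagated differently:
#
#   * v is advanced by EXACT translation: the accumulated displacement
#     v dt / h is split into integer-cell shifts (applied to the stored
#     field, with mirror folding at the reflecting walls) and a fractional
#     phase that is rendered only at output time nodes by a conservative
#     two-point blend.  This carries no cumulative numerical diffusion, so
#     the density keeps its physical width along the path.
#
#   * diffusion and the control drift u(t) are advanced by an exponentially
#     fitted (Chang-Cooper / Scharfetter-Gummel) finite-volume scheme with
#     implicit Euler and dimensional splitting.  With the Bernoulli function
#     B(w) = w/(e^w - 1) the face flux F = (sigma^2/2) d_x f - u f uses
#         F_{i+1/2} = C1 f_{i+1} + C0 f_i,
#         C1 = (D/h) B(w),  C0 = -(D/h) B(-w),  w = u h / D,  D = sigma^2/2,
#     with zero-flux boundary faces.  C1 >= 0 and -C0 >= 0 for every u, so
#     each implicit step matrix is an M-matrix with unit column sums:
#     positivity and exact discrete mass conservation hold unconditionally.
#
# Every operator in the chain is linear; the adjoint solver applies the
# exact transposes, which makes the reduced gradient exact to solver
# precision (see adjoint.R).

# B(w) = w/(e^w - 1), stable for small and large |w|
bernoulli_fn <- function(w) {
  out <- numeric(length(w))
  small <- abs(w) < 1e-5
  out[small] <- 1 - w[small] / 2 + w[small]^2 / 12
  big_pos <- w >= 40
  out[big_pos] <- w[big_pos] * exp(-w[big_pos])
  big_neg <- w <= -40
  out[big_neg] <- -w[big_neg]
  mid <- !small & !big_pos & !big_neg
  out[mid] <- w[mid] / expm1(w[mid])
  out
}

# B'(w) = (e^w - 1 - w e^w)/(e^w - 1)^2, same branch structure
bernoulli_dfn <- function(w) {
  out <- numeric(length(w))
  small <- abs(w) < 1e-5
  out[small] <- -0.5 + w[small] / 6
  big_pos <- w >= 40
  out[big_pos] <- (1 - w[big_pos]) * exp(-w[big_pos])
  big_neg <- w <= -40
  out[big_neg] <- -1
  mid <- !small & !big_pos & !big_neg
  e <- expm1(w[mid])
  out[mid] <- (e - w[mid] * (e + 1)) / e^2
  out
}

# 1-D finite-volume operator L (dense tridiagonal) for constant drift b
# along an axis with spacing h, such that df/dt = L f is the semi-discrete
# zero-flux FP equation.  deriv = TRUE returns dL/db instead.
axis_operator <- function(n, h, b, sigma, deriv = FALSE) {
  D <- sigma^2 / 2
  w <- b * h / D
  if (deriv) {
    c1 <- bernoulli_dfn(w)          # dC1/db
    c0 <- bernoulli_dfn(-w)         # dC0/db
  } else {
    c1 <- (D / h) * bernoulli_fn(w)
    c0 <- -(D / h) * bernoulli_fn(-w)
  }
  L <- matrix(0, n, n)
  idx <- seq_len(n - 1L)
  L[cbind(idx, idx + 1L)] <- c1 / h        # super-diagonal
  L[cbind(idx + 1L, idx)] <- -c0 / h       # sub-diagonal
  L[cbind(1:n, 1:n)] <- (c0 - c1) / h
  L[1L] <- c0 / h                          # zero-flux face below cell 1
  L[n * n] <- -c1 / h                      # zero-flux face above cell n
  L
}

# implicit Euler step matrix I - dt L along one axis, built directly
axis_step_matrix <- function(n, h, b, sigma, dt) {
  D <- sigma^2 / 2
  w <- b * h / D
  c1 <- (D / h) * bernoulli_fn(w)
  c0 <- -(D / h) * bernoulli_fn(-w)
  r <- dt / h
  A <- matrix(0, n, n)
  idx <- seq_len(n - 1L)
  A[cbind(idx, idx + 1L)] <- -r * c1
  A[cbind(idx + 1L, idx)] <- r * c0
  A[cbind(1:n, 1:n)] <- 1 - r * (c0 - c1)
  A[1L] <- 1 - r * c0
  A[n * n] <- 1 + r * c1
  A
}

# integer and fractional decomposition of the base-drift displacement:
# phases[k, j] is the fractional cell offset of the stored field at node k,
# shifts[k, j] the integer cell shift applied during step k (node k -> k+1)
drift_phases <- function(v, grid) {
  m <- grid$n_steps
  rate <- v * grid$dt / grid$h             # cells per step, per axis
  phases <- matrix(0, m + 1L, 2L)
  shifts <- matrix(0L, m, 2L)
  phi <- c(0, 0)
  for (k in seq_len(m)) {
    raw <- phi + rate
    s <- trunc(raw)
    phi <- raw - s
    shifts[k, ] <- as.integer(s)
    phases[k + 1L, ] <- phi
  }
  list(phases = phases, shifts = shifts)
}

# reflected (mirror-folded) row index for a shift landing at j on 1..n
fold_index <- function(j, n) {
  j <- ifelse(j < 1L, 2L - j, j)           # mirror about the lower wall
  j <- ifelse(j > n, 2L * n + 1L - j, j)   # mirror about the upper wall
  if (any(j < 1L | j > n)) fold_index(j, n) else j
}

# shift a field by an integer number of cells along one axis, folding mass
# that crosses a wall back inside (reflecting-barrier translation)
shift_fold_axis <- function(f, s, axis) {
  if (s == 0L) return(f)
  n <- dim(f)[axis]
  dest <- fold_index(seq_len(n) + s, n)
  out <- f * 0
  if (axis == 1L) {
    for (i in seq_len(n)) out[dest[i], ] <- out[dest[i], ] + f[i, ]
  } else {
    for (i in seq_len(n)) out[, dest[i]] <- out[, dest[i]] + f[, i]
  }
  out
}

# transpose of shift_fold_axis (out[i] = in[dest(i)])
shift_fold_axis_t <- function(f, s, axis) {
  if (s == 0L) return(f)
  n <- dim(f)[axis]
  dest <- fold_index(seq_len(n) + s, n)
  if (axis == 1L) f[dest, , drop = FALSE] else f[, dest, drop = FALSE]
}

shift_fold <- function(f, s) {
  f <- shift_fold_axis(f, s[1L], 1L)
  shift_fold_axis(f, s[2L], 2L)
}

shift_fold_t <- function(f, s) {
  f <- shift_fold_axis_t(f, s[2L], 2L)
  shift_fold_axis_t(f, s[1L], 1L)
}

# render the stored field at its fractional phase: conservative two-point
# blend (1 - |phi|) f + |phi| shift(f, sign(phi)); exact for the mean
render_axis <- function(f, phi, axis) {
  if (phi == 0) return(f)
  s <- if (phi > 0) 1L else -1L
  (1 - abs(phi)) * f + abs(phi) * shift_fold_axis(f, s, axis)
}

render_axis_t <- function(f, phi, axis) {
  if (phi == 0) return(f)
  s <- if (phi > 0) 1L else -1L
  (1 - abs(phi)) * f + abs(phi) * shift_fold_axis_t(f, s, axis)
}

render_field <- function(f, phi) {
  f <- render_axis(f, phi[1L], 1L)
  render_axis(f, phi[2L], 2L)
}

render_field_t <- function(f, phi) {
  f <- render_axis_t(f, phi[2L], 2L)
  render_axis_t(f, phi[1L], 1L)
}

#' Initial density of a player
#'
#' Isotropic Gaussian \eqn{\hat C \exp(-|x - D|^2 / w)} centered at the
#' player's departure point, evaluated at cell centers and normalized to unit
#' cell-quadrature mass.
#'
#' @param player A [player_spec()].
#' @param grid An [build_grid()] grid.
#' @return Cell matrix (\code{n_cells[1]} x \code{n_cells[2]}), nonnegative,
#'   with \code{mass(., grid) == 1}.
#' @export
initial_density <- function(player, grid) {
  check_inside(player$depart, grid, "departure point")
  x1 <- grid$centers[[1L]] - player$depart[1L]
  x2 <- grid$centers[[2L]] - player$depart[2L]
  f <- exp(-outer(x1^2, x2^2, `+`) / player$width)
  f / (sum(f) * grid$cell_area)
}

#' Drift field at a time node
#'
#' The drift of the controlled motion is the player's base velocity plus the
#' (purely time-dependent) control: \eqn{b(x,t) = v + u(t)}. With a constant
#' base velocity the field is spatially constant, which the solvers exploit.
#'
#' @param player A [player_spec()].
#' @param control Control matrix (\code{n_steps + 1} rows, 2 columns), or
#'   \code{NULL} for zero control.
#' @param time_index 1-based time-node index.
#' @param grid Grid (used to resolve a defaulted straight-line drift).
#' @return Length-2 drift vector at that time node.
#' @export
assemble_drift <- function(player, control, time_index, grid) {
  v <- player_drift(player, grid$horizon)
  u <- if (is.null(control)) c(0, 0) else as.numeric(control[time_index, ])
  v + u
}

#' Zero control trajectory
#'
#' @param grid An \code{fp_grid}.
#' @return \code{(n_steps + 1) x 2} matrix of zeros (columns ux, uy).
#' @export
zero_control <- function(grid) {
  matrix(0, grid$n_steps + 1L, 2L, dimnames = list(NULL, c("ux", "uy")))
}

#' Solve the forward Fokker-Planck equation for one player
#'
#' Advances the player's position density under the controlled
#' convection-diffusion equation with zero-flux (reflecting) boundary
#' conditions, from the Gaussian initial density at the departure point to
#' the horizon. Transport by the constant base drift is handled by exact
#' translation (no cumulative numerical diffusion); diffusion and the control
#' drift are handled by an exponentially fitted finite-volume scheme with
#' implicit Euler stepping, which conserves unit mass exactly and preserves
#' positivity for every admissible control and any step size. Each implicit
#' step uses the control at the step's right (new) time node.
#'
#' @param player A [player_spec()].
#' @param control Control matrix (\code{n_steps + 1} x 2) or \code{NULL}.
#' @param params A [game_params()] (\code{sigma} resolved if \code{NULL}).
#' @param grid An \code{fp_grid}.
#' @param keep_intermediates Keep the per-step internal states needed by
#'   the exact discrete gradient; enabled by the optimizer.
#' @param f0 Optional initial cell matrix overriding [initial_density()]
#'   (must be unit mass).
#' @return An \code{fp_field} of role \code{"density"} with \code{values} of
#'   dimension \code{(n_steps + 1, n_cells[1], n_cells[2])}, plus elements
#'   \code{mass_history}, \code{min_value}, \code{player}, \code{control} and
#'   (optionally) \code{intermediates}.
#' @export
solve_fp <- function(player, control, params, grid,
                     keep_intermediates = FALSE, f0 = NULL) {
  params <- resolve_sigma(params, grid)
  n1 <- grid$n_cells[1L]; n2 <- grid$n_cells[2L]
  m <- grid$n_steps
  if (is.null(control)) control <- zero_control(grid)
  stopifnot(nrow(control) == m + 1L, ncol(control) == 2L)

  v <- player_drift(player, grid$horizon)
  ph <- drift_phases(v, grid)
  g <- if (is.null(f0)) initial_density(player, grid) else as.matrix(f0)
  values <- array(0, dim = c(m + 1L, n1, n2))
  values[1L, , ] <- g
  inter <- if (keep_intermediates)
    list(gstar = array(0, dim = c(m, n1, n2)),
         gaxes = array(0, dim = c(m, n1, n2)))

  for (k in seq_len(m)) {
    u <- control[k + 1L, ]
    A1 <- axis_step_matrix(n1, grid$h[1L], u[1L], params$sigma, grid$dt)
    A2 <- axis_step_matrix(n2, grid$h[2L], u[2L], params$sigma, grid$dt)
    gstar <- solve(A1, g)                  # sweep along axis 1
    gaxes <- t(solve(A2, t(gstar)))        # sweep along axis 2
    if (keep_intermediates) {
      inter$gstar[k, , ] <- gstar
      inter$gaxes[k, , ] <- gaxes
    }
    g <- shift_fold(gaxes, ph$shifts[k, ])
    values[k + 1L, , ] <- render_field(g, ph$phases[k + 1L, ])
  }

  mass_hist <- colSums(matrix(aperm(values, c(2L, 3L, 1L)), n1 * n2)) *
    grid$cell_area
  min_val <- min(values)
  if (min_val < -1e-12)
    stop("internal-consistency error: negative density ", min_val)
  if (max(abs(mass_hist - 1)) > 1e-8)
    stop("internal-consistency error: mass drift ", max(abs(mass_hist - 1)))

  out <- fp_field(values, grid, role = "density")
  out$mass_history <- mass_hist
  out$min_value <- min_val
  out$player <- player
  out$control <- control
  out$params <- params
  out$intermediates <- inter
  out
}
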