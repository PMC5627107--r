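# Discrete adjoint of the forward solver (discretize-then-optimize): the
# backward recursion applies the exact transposes of every linear operator in
# the forward chain - the transposed implicit sweeps for diffusion and
# control drift, the transposed integer-shift translation of the base drift,
# and the transposed fractional-phase rendering - so the reduced gradient
# assembled from it matches finite differences of the discrete cost to
# solver precision.  In the vanishing-mesh limit the recursion discretizes
# the backward transport-diffusion equation
#     -dp/dt - (sigma^2/2) Lap p - b . grad p + rho f_other = 0,
# marched from t = T with terminal data -alpha V(x - x_T).

# quadratic terminal potential V(x - arrive) = |x - arrive|^2 at cell centers
terminal_potential <- function(player, grid) {
  outer((grid$centers[[1L]] - player$arrive[1L])^2,
        (grid$centers[[2L]] - player$arrive[2L])^2, `+`)
}

#' Solve the backward adjoint equation for one player
#'
#' Computes the adjoint (costate) field supplying gradient information for
#' the player's control. The recursion is the exact transpose of the forward
#' time-step chain built from the same drift \eqn{b = v + u(t)} at matching
#' time levels; the interaction source \eqn{\rho f^{(-p)}} enters through the
#' opponent's density, and the terminal slice carries
#' \eqn{-\alpha V(x - x_T)} (plus the trapezoid endpoint weight of the
#' interaction term when \eqn{\rho > 0}).
#'
#' @param player The player whose control the adjoint serves.
#' @param other_density The opponent's \code{fp_field} density on the same
#'   grid (required whenever \code{rho > 0}).
#' @param control The player's control matrix.
#' @param params A [game_params()].
#' @param grid The grid.
#' @return An \code{fp_field} of role \code{"adjoint"} whose \code{values}
#'   hold \eqn{p(x, t_k)} at all time nodes, plus the transposed-step
#'   intermediates used by [reduced_gradient()].
#' @export
solve_adjoint <- function(player, other_density, control, params, grid) {
  params <- resolve_sigma(params, grid)
  n1 <- grid$n_cells[1L]; n2 <- grid$n_cells[2L]
  m <- grid$n_steps
  area <- grid$cell_area
  if (is.null(control)) control <- zero_control(grid)
  if (params$rho > 0 && is.null(other_density))
    stop("dependency error: rho > 0 requires the opponent's density")
  tw <- time_weights(grid)
  ph <- drift_phases(player_drift(player, grid$horizon), grid)

  # explicit cost sensitivity dJ/df at node k (nodal, includes the cell
  # area), pulled back through the rendering onto the stored field
  g_at <- function(k) {
    g <- matrix(0, n1, n2)
    if (params$rho > 0)
      g <- g + params$rho * tw[k] * area * slice_at(other_density, grid, k)
    if (k == m + 1L)
      g <- g + params$alpha * area * terminal_potential(player, grid)
    render_field_t(g, ph$phases[k, ])
  }

  q <- g_at(m + 1L)
  values <- array(0, dim = c(m + 1L, n1, n2))
  values[m + 1L, , ] <- -q / area
  y1s <- array(0, dim = c(m, n1, n2))
  y2s <- array(0, dim = c(m, n1, n2))

  for (k in m:1L) {
    u <- control[k + 1L, ]
    A1 <- axis_step_matrix(n1, grid$h[1L], u[1L], params$sigma, grid$dt)
    A2 <- axis_step_matrix(n2, grid$h[2L], u[2L], params$sigma, grid$dt)
    qt <- shift_fold_t(q, ph$shifts[k, ])  # transpose of the translation
    y2 <- t(solve(t(A2), t(qt)))           # transpose of the axis-2 sweep
    y1 <- solve(t(A1), y2)                 # transpose of the axis-1 sweep
    y1s[k, , ] <- y1
    y2s[k, , ] <- y2
    q <- g_at(k) + y1
    values[k, , ] <- -q / area
  }

  out <- fp_field(values, grid, role = "adjoint")
  out$player <- player
  out$control <- control
  out$params <- params
  out$y1 <- y1s
  out$y2 <- y2s
  out
}
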