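#' Terminal cost of a player
#'
#' \eqn{\alpha \int_\Omega V(x - x_T) f(x, T)\,dx} with the quadratic
#' potential \eqn{V(y) = |y|^2}: the expected squared distance of the final
#' position from the arrival point, weighted by \code{alpha}.
#'
#' @param density The player's \code{fp_field} density.
#' @param player The [player_spec()] providing the arrival point.
#' @param alpha Terminal weight.
#' @param grid The grid.
#' @return Nonnegative scalar.
#' @export
terminal_cost <- function(density, player, alpha, grid = density$grid) {
  m <- dim(density$values)[1L]
  fT <- slice_at(density, grid, m)
  alpha * sum(terminal_potential(player, grid) * fT) * grid$cell_area
}

#' H1 control cost
#'
#' \eqn{(\nu/2)\,(\int_0^T |u|^2 dt + \int_0^T |u'|^2 dt)}, discretized with
#' the trapezoid rule for the zeroth-order term and forward differences for
#' the derivative term. Penalizes both control effort and fast variation,
#' yielding continuous, slowly varying strategies.
#'
#' @param u Control matrix (\code{n_steps + 1} x 2).
#' @param grid The grid (provides the time step).
#' @param nu Weight \eqn{\nu > 0}.
#' @return Nonnegative scalar, zero iff \code{u} is identically zero.
#' @export
control_cost <- function(u, grid, nu = 1) {
  tw <- time_weights(grid)
  l2 <- sum(tw * rowSums(u^2))
  du <- diff(u)
  h1 <- sum(du^2) / grid$dt
  (nu / 2) * (l2 + h1)
}

#' Interaction (collision) cost of two densities
#'
#' \eqn{\rho \int_0^T \int_\Omega f^{(1)}(x,t) f^{(2)}(x,t)\,dx\,dt}
#' (trapezoid in time): the small-radius approximation of the accumulated
#' probability that the two pedestrians occupy the same location.
#'
#' @param f1,f2 Density \code{fp_field}s on the same grid.
#' @param rho Interaction strength \eqn{\rho \ge 0}.
#' @param grid The grid.
#' @return Nonnegative scalar; 0 when \code{rho = 0} or supports never meet.
#' @export
interaction_cost <- function(f1, f2, rho, grid = f1$grid) {
  if (rho == 0) return(0)
  if (!identical(dim(f1$values), dim(f2$values)))
    stop("grid mismatch between the two density fields")
  tw <- time_weights(grid)
  ov <- vapply(seq_along(tw), function(k) overlap(f1, f2, grid, k), numeric(1))
  rho * sum(tw * ov)
}

#' Instantaneous collision probability
#'
#' Small-radius approximation
#' \eqn{\mathrm{Prob}\{|X^{(2)} - X^{(1)}| < r\} \approx
#' r^D \int_\Omega f^{(1)} f^{(2)}\,dx} (here \eqn{D = 2}), valid when the
#' overcrowding radius \code{r} is small against the densities' length
#' scales and the two processes are independent.
#'
#' @param f1,f2 Density fields on the same grid.
#' @param r Overcrowding radius.
#' @param grid The grid.
#' @param time_index Time node at which to evaluate.
#' @return Nonnegative scalar probability estimate.
#' @export
collision_probability <- function(f1, f2, r, grid = f1$grid, time_index = 1L) {
  r^2 * overlap(f1, f2, grid, time_index)
}

#' Composite game cost and its breakdown
#'
#' Runs both forward Fokker-Planck solves under the given controls and
#' evaluates the composite functional \eqn{\hat J = G_1 + G_2 + W}, where
#' \eqn{G_p} is player p's terminal-plus-control cost and \eqn{W} the shared
#' interaction cost. A minimizer of \eqn{\hat J} is a Nash equilibrium of the
#' separable game with individual costs \eqn{J_p = G_p + W}.
#'
#' @param u1,u2 Control matrices for players 1 and 2.
#' @param players List of two [player_spec()]s.
#' @param params A [game_params()].
#' @param grid The grid.
#' @param keep_intermediates Passed to [solve_fp()] (gradient use).
#' @param densities Optional precomputed list \code{list(f1, f2)} to reuse.
#' @return List with \code{Jhat}, per-player \code{terminal}, \code{control},
#'   \code{G} (= terminal + control), \code{W}, \code{J1}, \code{J2}
#'   (\eqn{J_p = G_p + W}, so \eqn{J_1 + J_2 = \hat J + W}) and the two
#'   densities \code{f1}, \code{f2}.
#' @export
composite_cost <- function(u1, u2, players, params, grid,
                           keep_intermediates = FALSE, densities = NULL) {
  params <- resolve_sigma(params, grid)
  if (is.null(densities)) {
    f1 <- solve_fp(players[[1L]], u1, params, grid, keep_intermediates)
    f2 <- solve_fp(players[[2L]], u2, params, grid, keep_intermediates)
  } else {
    f1 <- densities[[1L]]; f2 <- densities[[2L]]
  }
  term <- c(terminal_cost(f1, players[[1L]], params$alpha, grid),
            terminal_cost(f2, players[[2L]], params$alpha, grid))
  ctrl <- c(control_cost(u1, grid, params$nu),
            control_cost(u2, grid, params$nu))
  W <- interaction_cost(f1, f2, params$rho, grid)
  G <- term + ctrl
  list(Jhat = sum(G) + W, terminal = term, control = ctrl, G = G, W = W,
       J1 = G[1L] + W, J2 = G[2L] + W, f1 = f1, f2 = f2)
}
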