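#' Reduced cost gradient with respect to one player's control
#'
#' Assembles the gradient of the composite cost as a function of the player's
#' control alone: the control-cost part \eqn{\nu u - \nu u''} (distributional
#' time Laplacian via second differences) plus the forward-adjoint coupling
#' term, which on the continuous level is
#' \eqn{-\int_\Omega (\partial p / \partial x_k)\, f\,dx}. The coupling is
#' evaluated through the exact derivative of the discrete time-step operator
#' (discretize-then-optimize), so the returned gradient matches finite
#' differences of [composite_cost()] to solver precision. Endpoints are
#' excluded: controls are pinned to zero at \eqn{t = 0, T}.
#'
#' @param density The player's forward solve with
#'   \code{keep_intermediates = TRUE}.
#' @param adjoint The matching [solve_adjoint()] field.
#' @param u The player's control matrix.
#' @param params A [game_params()].
#' @param grid The grid.
#' @return \code{(n_steps + 1) x 2} matrix: the L2(0, T) gradient at the time
#'   nodes (zero at the endpoints), with the nodal gradient (the derivative
#'   with respect to the node values of \code{u}) in attribute
#'   \code{"nodal"}.
#' @export
reduced_gradient <- function(density, adjoint, u, params, grid = density$grid) {
  params <- resolve_sigma(params, grid)
  m <- grid$n_steps
  if (is.null(density$intermediates))
    stop("forward solve must be run with keep_intermediates = TRUE")
  if (!identical(dim(adjoint$values), dim(density$values)))
    stop("mismatched time grids between density and adjoint")
  n1 <- grid$n_cells[1L]; n2 <- grid$n_cells[2L]
  player <- density$player
  tw <- time_weights(grid)

  nodal <- matrix(0, m + 1L, 2L)
  # control-cost part: d/du_k of (nu/2) (trapezoid |u|^2 + sum |du|^2 / dt)
  for (j in 1:2) {
    lap <- (u[1:(m - 1L), j] - 2 * u[2:m, j] + u[3:(m + 1L), j]) / grid$dt
    nodal[2:m, j] <- params$nu * (tw[2:m] * u[2:m, j] - lap)
  }
  # PDE coupling: step k-1 (node k-1 -> k) uses the control at node k; only
  # the implicit sweeps depend on u, so their operator derivatives supply
  # the whole coupling term
  for (k in 2:(m + 1L)) {
    dL1 <- axis_operator(n1, grid$h[1L], u[k, 1L], params$sigma, deriv = TRUE)
    dL2 <- axis_operator(n2, grid$h[2L], u[k, 2L], params$sigma, deriv = TRUE)
    gstar <- matrix(density$intermediates$gstar[k - 1L, , ], n1, n2)
    gaxes <- matrix(density$intermediates$gaxes[k - 1L, , ], n1, n2)
    y1 <- matrix(adjoint$y1[k - 1L, , ], n1, n2)
    y2 <- matrix(adjoint$y2[k - 1L, , ], n1, n2)
    nodal[k, 1L] <- nodal[k, 1L] + grid$dt * sum(y1 * (dL1 %*% gstar))
    nodal[k, 2L] <- nodal[k, 2L] + grid$dt * sum(y2 * (gaxes %*% t(dL2)))
  }
  nodal[c(1L, m + 1L), ] <- 0

  g <- nodal
  g[2:m, ] <- g[2:m, ] / tw[2:m]   # L2 Riesz representative on the interior
  attr(g, "nodal") <- nodal
  g
}

#' Sobolev (H1) gradient smoothing
#'
#' Lifts an L2(0, T) gradient to the H1 representative by solving the
#' two-point boundary-value problem \eqn{-w'' + w = g} on \eqn{(0, T)} with
#' \eqn{w(0) = w(T) = 0} (second-order finite differences, one tridiagonal
#' solve per component). The result is the smooth, endpoint-vanishing descent
#' direction used for control updates.
#'
#' @param g Gradient matrix (\code{n_steps + 1} x 2), endpoints ignored.
#' @param grid The grid.
#' @return Matrix of the same shape with zero endpoints.
#' @export
h1_smooth <- function(g, grid) {
  g <- as.matrix(g)
  m <- grid$n_steps
  n <- m - 1L                      # interior nodes
  A <- diag(1 + 2 / grid$dt^2, n)
  idx <- seq_len(n - 1L)
  A[cbind(idx, idx + 1L)] <- -1 / grid$dt^2
  A[cbind(idx + 1L, idx)] <- -1 / grid$dt^2
  w <- g * 0
  w[2:m, ] <- solve(A, g[2:m, , drop = FALSE])
  w
}

#' Project a control onto the admissible set
#'
#' Componentwise clip to the box \code{[u_a, u_b]} with the endpoint values
#' forced to zero (strategies switch on at \eqn{t = 0} and off at
#' \eqn{t = T}). Idempotent.
#'
#' @param u Control matrix.
#' @param bounds Length-2 \code{c(u_a, u_b)}.
#' @return Projected control matrix.
#' @export
project_control <- function(u, bounds) {
  u <- pmin(pmax(u, bounds[1L]), bounds[2L])
  u[c(1L, nrow(u)), ] <- 0
  u
}

#' Optimizer settings
#'
#' @param max_iters Maximum outer projected-gradient iterations.
#' @param tol Relative H1-gradient-norm tolerance: stop when the H1 norm of
#'   the smoothed gradient drops below \code{tol * (1 + |Jhat|)}.
#' @param armijo_c Armijo sufficient-decrease slope.
#' @param shrink Backtracking shrink factor.
#' @param step0 Initial line-search step.
#' @param max_backtracks Maximum backtracking halvings per iteration.
#' @return List of settings for [solve_nash()].
#' @export
nash_control <- function(max_iters = 200L, tol = 1e-5, armijo_c = 1e-4,
                         shrink = 0.5, step0 = 1, max_backtracks = 30L) {
  list(max_iters = max_iters, tol = tol, armijo_c = armijo_c,
       shrink = shrink, step0 = step0, max_backtracks = max_backtracks)
}

# one gradient evaluation for the current iterate: costs, L2/H1 gradients
nash_gradient_state <- function(u1, u2, players, params, grid) {
  cost <- composite_cost(u1, u2, players, params, grid,
                         keep_intermediates = TRUE)
  adj1 <- solve_adjoint(players[[1L]], cost$f2, u1, params, grid)
  adj2 <- solve_adjoint(players[[2L]], cost$f1, u2, params, grid)
  g1 <- reduced_gradient(cost$f1, adj1, u1, params, grid)
  g2 <- reduced_gradient(cost$f2, adj2, u2, params, grid)
  w1 <- h1_smooth(g1, grid)
  w2 <- h1_smooth(g2, grid)
  tw <- time_weights(grid)
  gradnorm <- sqrt(sum(tw * rowSums(w1 * g1)) + sum(tw * rowSums(w2 * g2)))
  list(cost = cost, g1 = g1, g2 = g2, w1 = w1, w2 = w2, gradnorm = gradnorm)
}

#' Compute a Nash equilibrium by composite-cost minimization
#'
#' Minimizes the composite functional \eqn{\hat J = G_1 + G_2 + W} jointly
#' over both controls with a projected H1-gradient method and Armijo
#' backtracking, starting from zero controls. A minimizer of \eqn{\hat J} is
#' a Nash equilibrium of the underlying separable game, so the returned
#' control pair is an equilibrium candidate certifiable with
#' [verify_nash()].
#'
#' @param scenario An [load_scenario()] object, or a list with elements
#'   \code{players}, \code{params}, \code{grid}.
#' @param settings Optimizer settings from [nash_control()].
#' @param quiet Suppress the stalled-line-search warning.
#' @return Object of class \code{"nash_solution"}: equilibrium controls
#'   \code{u1}, \code{u2}, cost breakdown \code{cost} (including \code{J1},
#'   \code{J2}, \code{Jhat} and components), mean trajectories \code{mean1},
#'   \code{mean2}, iteration \code{history} (data frame: iter, Jhat,
#'   gradnorm, step), \code{converged}, and the inputs.
#' @export
solve_nash <- function(scenario, settings = nash_control(), quiet = FALSE) {
  players <- scenario$players
  params <- resolve_sigma(scenario$params, scenario$grid)
  grid <- scenario$grid
  bounds <- params$bounds

  u1 <- zero_control(grid)
  u2 <- zero_control(grid)
  st <- nash_gradient_state(u1, u2, players, params, grid)
  history <- data.frame(iter = 0L, Jhat = st$cost$Jhat,
                        gradnorm = st$gradnorm, step = NA_real_)
  converged <- FALSE
  stalled <- FALSE
  step <- settings$step0

  for (it in seq_len(settings$max_iters)) {
    if (st$gradnorm < settings$tol * (1 + abs(st$cost$Jhat))) {
      converged <- TRUE
      break
    }
    n1 <- attr(st$g1, "nodal"); n2 <- attr(st$g2, "nodal")
    s <- min(step * 2, 1e3)
    accepted <- FALSE
    for (bt in seq_len(settings$max_backtracks)) {
      u1t <- project_control(u1 - s * st$w1, bounds)
      u2t <- project_control(u2 - s * st$w2, bounds)
      pred <- sum(n1 * (u1 - u1t)) + sum(n2 * (u2 - u2t))
      if (pred <= 0) break   # projected stationary point
      trial <- composite_cost(u1t, u2t, players, params, grid)
      if (trial$Jhat <= st$cost$Jhat - settings$armijo_c * pred) {
        accepted <- TRUE
        break
      }
      s <- s * settings$shrink
    }
    if (!accepted) {
      stalled <- TRUE
      break
    }
    step <- s
    u1 <- u1t; u2 <- u2t
    st <- nash_gradient_state(u1, u2, players, params, grid)
    history <- rbind(history, data.frame(iter = it, Jhat = st$cost$Jhat,
                                         gradnorm = st$gradnorm, step = s))
  }
  if (!converged && st$gradnorm < settings$tol * (1 + abs(st$cost$Jhat)))
    converged <- TRUE
  if (stalled && !converged && !quiet)
    warning("line search stalled before reaching the gradient tolerance; ",
            "returning the best iterate")

  f1 <- st$cost$f1; f2 <- st$cost$f2
  structure(list(
    u1 = u1, u2 = u2, cost = st$cost[c("Jhat", "terminal", "control", "G",
                                       "W", "J1", "J2")],
    f1 = f1, f2 = f2,
    mean1 = mean_trajectory(f1, grid), mean2 = mean_trajectory(f2, grid),
    history = history, converged = converged, gradnorm = st$gradnorm,
    players = players, params = params, grid = grid,
    scenario_name = scenario$name %||% "custom"
  ), class = "nash_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nash_solution <- function(x, ...) {
  cat(sprintf("<nash_solution> %s: Jhat = %.6g (J1 = %.6g, J2 = %.6g, W = %.4g)\n",
              x$scenario_name, x$cost$Jhat, x$cost$J1, x$cost$J2, x$cost$W))
  cat(sprintf("  %d iterations, final H1 gradient norm %.3g, converged: %s\n",
              max(x$history$iter), x$gradnorm, x$converged))
  mt <- meeting_time(x$mean1, x$mean2, x$grid$times)
  cat(sprintf("  minimal inter-mean distance %.4g at t = %.4g\n",
              mt$distance, mt$time))
  invisible(x)
}

#' Solve one player's decoupled optimal control problem
#'
#' The single-pedestrian problem obtained at \eqn{\rho = 0}: minimize the
#' player's terminal-plus-control cost alone. Used to exhibit the separable
#' structure of the game (at \eqn{\rho = 0} the joint solve decomposes into
#' two of these).
#'
#' @param player A [player_spec()].
#' @param params A [game_params()] (its \code{rho} is ignored; 0 is used).
#' @param grid The grid.
#' @param settings Optimizer settings.
#' @return A \code{nash_solution} for a degenerate game in which both slots
#'   hold the same player; its \code{u1} is the optimal control.
#' @export
solve_single <- function(player, params, grid, settings = nash_control()) {
  params$rho <- 0
  sc <- list(players = list(player, player), params = params, grid = grid,
             name = "single-player")
  solve_nash(sc, settings, quiet = TRUE)
}

#' Certify a Nash equilibrium by random unilateral deviations
#'
#' Probes the equilibrium property directly: for each player separately,
#' draws random admissible control perturbations (smooth sine-mode mixtures,
#' vanishing at the endpoints, projected into the box) and checks that no
#' unilateral deviation lowers that player's own cost
#' \eqn{J_p = G_p + W} by more than \code{tol_factor * |J_p|}.
#'
#' @param sol A converged [solve_nash()] solution.
#' @param n_probes Perturbations per player (default 50).
#' @param probe_scale Typical amplitude of a perturbation (default 0.25).
#' @param seed RNG seed for reproducible probes.
#' @param tol_factor Relative tolerance on an admissible cost decrease.
#' @return List with \code{pass}, \code{n_violations},
#'   \code{max_improvement} (most negative allowed-exceeding decrease, 0 if
#'   none), and a \code{probes} data frame (player, probe, J_base, J_probe,
#'   improvement, violation).
#' @export
verify_nash <- function(sol, n_probes = 50L, probe_scale = 0.25, seed = 1L,
                        tol_factor = 1e-6) {
  grid <- sol$grid
  params <- sol$params
  players <- sol$players
  bounds <- params$bounds
  tgrid <- grid$times / grid$horizon   # in [0, 1]
  set.seed(seed)

  random_probe <- function() {
    modes <- 4L
    d <- matrix(0, grid$n_steps + 1L, 2L)
    for (j in 1:2) {
      a <- stats::rnorm(modes, sd = probe_scale / seq_len(modes))
      d[, j] <- colSums(a * t(outer(tgrid, seq_len(modes),
                                    function(t, m) sin(pi * m * t))))
    }
    d
  }

  base_controls <- list(sol$u1, sol$u2)
  base_densities <- list(sol$f1, sol$f2)
  base_J <- c(sol$cost$J1, sol$cost$J2)

  rows <- vector("list", 2L * n_probes)
  i <- 0L
  for (p in 1:2) {
    other <- 3L - p
    for (k in seq_len(n_probes)) {
      up <- project_control(base_controls[[p]] + random_probe(), bounds)
      fp <- solve_fp(players[[p]], up, params, grid)
      Jp <- terminal_cost(fp, players[[p]], params$alpha, grid) +
        control_cost(up, grid, params$nu) +
        interaction_cost(fp, base_densities[[other]], params$rho, grid)
      impr <- base_J[p] - Jp          # > 0 means the deviation improves
      i <- i + 1L
      rows[[i]] <- data.frame(player = p, probe = k, J_base = base_J[p],
                              J_probe = Jp, improvement = impr,
                              violation = impr > tol_factor * abs(base_J[p]))
    }
  }
  probes <- do.call(rbind, rows)
  viol <- probes$improvement[probes$violation]
  list(pass = !any(probes$violation), n_violations = sum(probes$violation),
       max_improvement = if (length(viol)) max(viol) else 0,
       probes = probes)
}
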