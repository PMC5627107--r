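#' Specify one pedestrian (player)
#'
#' A player is described by a departure point \eqn{D}, an arrival point
#' \eqn{A}, a base drift \eqn{v} (the preferred velocity in the absence of any
#' interaction) and the width of the initial Gaussian density. When \code{v}
#' is omitted it defaults to the straight line \eqn{(A - D)/T}, the velocity
#' that carries the mean from departure to arrival exactly over the horizon.
#' The terminal potential is quadratic, \eqn{V(y) = |y|^2}, with minimum at
#' the arrival point.
#'
#' @param depart Length-2 departure point, strictly inside the domain.
#' @param arrive Length-2 arrival point, strictly inside the domain.
#' @param drift Optional explicit constant base velocity; default
#'   \code{(arrive - depart) / horizon}, filled in by [load_scenario()] or
#'   [solve_fp()] when a grid is known.
#' @param width Width parameter \code{w > 0} of the initial density
#'   \eqn{\exp(-|x - D|^2 / w)} (default 0.5).
#' @return An object of class \code{"player_spec"}.
#' @export
player_spec <- function(depart, arrive, drift = NULL, width = 0.5) {
  depart <- as.numeric(depart); arrive <- as.numeric(arrive)
  stopifnot(length(depart) == 2L, length(arrive) == 2L, width > 0)
  if (!is.null(drift)) {
    drift <- as.numeric(drift)
    stopifnot(length(drift) == 2L)
  }
  structure(list(depart = depart, arrive = arrive, drift = drift,
                 width = width), class = "player_spec")
}

# resolved constant drift for a player on a given horizon
player_drift <- function(player, horizon) {
  if (is.null(player$drift)) (player$arrive - player$depart) / horizon
  else player$drift
}

check_inside <- function(pt, grid, what = "point") {
  if (any(pt <= grid$bounds[, 1L]) || any(pt >= grid$bounds[, 2L]))
    stop("configuration error: ", what, " (", paste(pt, collapse = ", "),
         ") is not strictly inside the domain")
  invisible(pt)
}

#' Game parameters
#'
#' Collects the scalar parameters of the two-player avoidance game: the
#' dispersion \code{sigma} of the Brownian perturbation, the terminal weight
#' \code{alpha}, the control-cost weight \code{nu}, the interaction strength
#' \code{rho} and the control box bounds. \code{rho} may alternatively be
#' given through an overcrowding radius \code{r} and relative strength
#' \code{C} as \eqn{\rho = C r^D} with \eqn{D = 2}.
#'
#' @param sigma Dispersion coefficient (> 0). If \code{NULL} it is resolved to
#'   \code{0.05 * min(domain side)} once a grid is known (see
#'   [resolve_sigma()]).
#' @param alpha Terminal-cost weight (default 100).
#' @param nu Control-cost weight (default 1).
#' @param rho Interaction strength (default 0.01).
#' @param r,C Optional overcrowding radius and strength; when both are given
#'   they override \code{rho} via \code{rho = C * r^2}.
#' @param bounds Length-2 control box \code{c(u_a, u_b)}, default
#'   \code{c(-5, 5)}.
#' @return An object of class \code{"game_params"}.
#' @export
game_params <- function(sigma = NULL, alpha = 100, nu = 1, rho = 0.01,
                        r = NULL, C = NULL, bounds = c(-5, 5)) {
  if (!is.null(r) && !is.null(C)) {
    stopifnot(r > 0, C >= 0)
    rho <- C * r^2
  }
  stopifnot(is.null(sigma) || sigma > 0, nu > 0, alpha >= 0, rho >= 0,
            length(bounds) == 2L, bounds[1L] < bounds[2L])
  structure(list(sigma = sigma, alpha = alpha, nu = nu, rho = rho,
                 r = r, C = C, bounds = as.numeric(bounds)),
            class = "game_params")
}

#' Resolve the dispersion coefficient
#'
#' The default dispersion is 0.1 model length units per square-root time
#' unit, a pedestrian-scale variability (the benchmark domains are
#' room-scale): it keeps the stochastic spread accumulated over the benchmark
#' horizons subordinate to the initial-position uncertainty (width 0.5), so
#' the densities stay coherent blobs whose mean trajectories carry the
#' dynamics.
#'
#' @param params A \code{game_params}.
#' @param grid An \code{fp_grid} (unused by the default rule; kept so
#'   alternative resolution rules can depend on the domain).
#' @return \code{params} with a concrete numeric \code{sigma}.
#' @export
resolve_sigma <- function(params, grid) {
  if (is.null(params$sigma)) params$sigma <- 0.1
  params
}

# ---- scenario registry -------------------------------------------------

scenario_table <- function() {
  list(
    "huber-135" = list(
      label   = "Huber-135 (trajectories crossing at 135 degrees)",
      bounds  = list(c(-3, 3), c(-3, 3)), horizon = 3,
      p1 = list(depart = c(-1, 0), arrive = c(2, 0),  drift = c(1, 0)),
      p2 = list(depart = c(1, 1),  arrive = c(-2, -2), drift = c(-1, -1)),
      rho_low = 0.01, rho_high = 200, control_bounds = c(-5, 5)),
    "turnwald-1c-a3" = list(
      label   = "Turnwald 1C-A3 (symmetric oblique crossing)",
      bounds  = list(c(-1, 8), c(-1, 8)), horizon = 5,
      p1 = list(depart = c(1, 1), arrive = c(6, 4), drift = NULL),
      p2 = list(depart = c(6, 1), arrive = c(1, 4), drift = NULL),
      rho_low = 0.01, rho_high = 200, control_bounds = c(-5, 5)),
    "turnwald-1c-b2" = list(
      label   = "Turnwald 1C-B2 (near head-on in a corridor)",
      bounds  = list(c(-1, 1), c(-3, 3)), horizon = 5,
      p1 = list(depart = c(0, -2.5),    arrive = c(0, 2.5),    drift = NULL),
      p2 = list(depart = c(-0.5, 2.5),  arrive = c(0.5, -2.5), drift = NULL),
      rho_low = 0.01, rho_high = 150, control_bounds = c(-5, 5)),
    "gait-posture" = list(
      label   = "Gait and Posture (blind diagonal crossing, short horizon)",
      bounds  = list(c(-10, 10), c(-10, 10)), horizon = 1,
      p1 = list(depart = c(-7.5, -7.5), arrive = c(7.5, 7.5),  drift = NULL),
      p2 = list(depart = c(-7.5, 7.5),  arrive = c(7.5, -7.5), drift = NULL),
      rho_low = 0.01, rho_high = 200, control_bounds = c(-40, 40))
  )
}

#' Names of the shipped benchmark scenarios
#' @return Character vector of registry keys.
#' @export
scenario_names <- function() names(scenario_table())

#' Load a benchmark scenario
#'
#' Resolves one of the four shipped two-pedestrian crossing benchmarks into a
#' fully specified configuration: domain, horizon, player specs (straight-line
#' drifts filled in where only endpoints are given), grid sizes and game
#' parameters. Every field can be overridden.
#'
#' @param name Registry key (see [scenario_names()]).
#' @param overrides Named list of overrides; recognized names:
#'   \code{rho}, \code{sigma}, \code{alpha}, \code{nu}, \code{bounds}
#'   (control box), \code{horizon}, \code{n_cells}, \code{n_steps},
#'   \code{width}.
#' @param n_cells,n_steps Grid resolution (defaults 50 and 50).
#' @return An object of class \code{"fp_scenario"}: list with \code{name},
#'   \code{label}, \code{grid}, \code{players} (list of two
#'   \code{player_spec}), \code{params} (with \code{rho} set to the scenario's
#'   low value unless overridden), \code{rho_low}, \code{rho_high}.
#' @examples
#' sc <- load_scenario("huber-135")
#' sc$players[[1]]$drift   # (1, 0)
#' @export
load_scenario <- function(name, overrides = list(), n_cells = 50L,
                          n_steps = 50L) {
  reg <- scenario_table()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  sc <- reg[[name]]
  take <- function(key, default) if (!is.null(overrides[[key]])) overrides[[key]] else default

  horizon <- take("horizon", sc$horizon)
  n_cells <- take("n_cells", n_cells)
  n_steps <- take("n_steps", n_steps)
  grid <- build_grid(sc$bounds, n_cells = n_cells, horizon = horizon,
                     n_steps = n_steps)

  width <- take("width", 0.5)
  mk <- function(p) {
    ps <- player_spec(p$depart, p$arrive, drift = p$drift, width = width)
    if (is.null(ps$drift)) ps$drift <- player_drift(ps, horizon)
    check_inside(ps$depart, grid, "departure point")
    check_inside(ps$arrive, grid, "arrival point")
    ps
  }
  players <- list(mk(sc$p1), mk(sc$p2))

  params <- game_params(
    sigma  = take("sigma", NULL),
    alpha  = take("alpha", 100),
    nu     = take("nu", 1),
    rho    = take("rho", sc$rho_low),
    bounds = take("bounds", sc$control_bounds))
  params <- resolve_sigma(params, grid)

  structure(list(name = name, label = sc$label, grid = grid,
                 players = players, params = params,
                 rho_low = sc$rho_low, rho_high = sc$rho_high),
            class = "fp_scenario")
}

#' @export
print.fp_scenario <- function(x, ...) {
  cat("<fp_scenario>", x$name, "-", x$label, "\n")
  print(x$grid)
  for (p in 1:2) {
    pl <- x$players[[p]]
    cat(sprintf("  player %d: D = (%g, %g) -> A = (%g, %g), v = (%g, %g)\n",
                p, pl$depart[1], pl$depart[2], pl$arrive[1], pl$arrive[2],
                pl$drift[1], pl$drift[2]))
  }
  cat(sprintf("  sigma = %g, alpha = %g, nu = %g, rho = %g, u in [%g, %g]\n",
              x$params$sigma, x$params$alpha, x$params$nu, x$params$rho,
              x$params$bounds[1], x$params$bounds[2]))
  invisible(x)
}

#' Meeting time of two mean trajectories
#'
#' The discrete time node at which the two mean-position trajectories attain
#' their minimal mutual distance, with ties broken toward the earlier node.
#'
#' @param mean1,mean2 Trajectory matrices (rows = time nodes, columns x, y)
#'   on the same time grid, as returned by [mean_trajectory()].
#' @param times Time-node vector; defaults to node indices 0, 1, ...
#' @return List with \code{time}, \code{distance}, and the node \code{index}.
#' @export
meeting_time <- function(mean1, mean2, times = NULL) {
  mean1 <- as.matrix(mean1); mean2 <- as.matrix(mean2)
  if (nrow(mean1) == 0L || nrow(mean1) != nrow(mean2))
    stop("trajectories must be nonempty and on the same time nodes")
  if (is.null(times)) times <- seq_len(nrow(mean1)) - 1
  d <- sqrt(rowSums((mean1 - mean2)^2))
  k <- which.min(d)  # which.min takes the first (earliest) minimizer
  list(time = times[k], distance = d[k], index = k)
}
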