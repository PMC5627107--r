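# Plain-text exports of solver artifacts: CSV for trajectories, controls and
# iteration history, long-format CSV for field snapshots, JSON for summaries.

#' Write the mean trajectories of a solution to CSV
#'
#' Columns: t, mx1, my1, mx2, my2.
#' @param sol A \code{nash_solution}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_means_csv <- function(sol, path) {
  df <- data.frame(t = sol$grid$times,
                   mx1 = sol$mean1[, "x"], my1 = sol$mean1[, "y"],
                   mx2 = sol$mean2[, "x"], my2 = sol$mean2[, "y"])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the equilibrium controls of a solution to CSV
#'
#' Columns: t, u1x, u1y, u2x, u2y.
#' @inheritParams write_means_csv
#' @export
write_controls_csv <- function(sol, path) {
  df <- data.frame(t = sol$grid$times,
                   u1x = sol$u1[, 1L], u1y = sol$u1[, 2L],
                   u2x = sol$u2[, 1L], u2y = sol$u2[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# read controls back from a write_controls_csv() file
read_controls_csv <- function(path) {
  df <- utils::read.csv(path)
  list(u1 = as.matrix(df[, c("u1x", "u1y")]),
       u2 = as.matrix(df[, c("u2x", "u2y")]))
}

#' Export a density (or adjoint) field to long-format CSV
#'
#' One row per (time node, cell): columns t, x, y, value. Intended for small
#' diagnostic snapshots; pass \code{time_indices} to subset.
#'
#' @param field An \code{fp_field}.
#' @param path Output path.
#' @param grid The grid.
#' @param time_indices Which time nodes to export (default: all).
#' @export
write_field_csv <- function(field, path, grid = field$grid,
                            time_indices = NULL) {
  m <- dim(field$values)[1L]
  if (is.null(time_indices)) time_indices <- seq_len(m)
  xs <- rep(grid$centers[[1L]], times = grid$n_cells[2L])
  ys <- rep(grid$centers[[2L]], each = grid$n_cells[1L])
  rows <- lapply(time_indices, function(k)
    data.frame(t = grid$times[k], x = xs, y = ys,
               value = as.vector(slice_at(field, grid, k))))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export an ensemble's trajectories to CSV
#'
#' Columns: particle_id, t, x, y.
#' @param ensemble An \code{mc_ensemble}.
#' @param path Output path.
#' @param max_particles Cap on exported particles (default 1000).
#' @export
write_ensemble_csv <- function(ensemble, path, max_particles = 1000L) {
  n <- min(ensemble$n_particles, max_particles)
  m1 <- dim(ensemble$positions)[1L]
  df <- data.frame(
    particle_id = rep(seq_len(n), each = m1),
    t = rep(ensemble$grid$times, times = n),
    x = as.vector(ensemble$positions[, seq_len(n), 1L]),
    y = as.vector(ensemble$positions[, seq_len(n), 2L]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# resolved-parameter log for provenance
resolved_params_list <- function(scenario) {
  p <- scenario$params
  list(scenario = scenario$name, label = scenario$label,
       bounds_x = scenario$grid$bounds[1L, ], bounds_y = scenario$grid$bounds[2L, ],
       n_cells = scenario$grid$n_cells, n_steps = scenario$grid$n_steps,
       horizon = scenario$grid$horizon, dt = scenario$grid$dt,
       h = scenario$grid$h,
       sigma = p$sigma, alpha = p$alpha, nu = p$nu, rho = p$rho,
       control_bounds = p$bounds,
       players = lapply(scenario$players, function(pl)
         list(depart = pl$depart, arrive = pl$arrive, drift = pl$drift,
              width = pl$width)))
}

#' Write all artifacts of a solved run into a directory
#'
#' Creates \code{means.csv}, \code{controls.csv}, \code{history.csv},
#' \code{params.json} (every resolved parameter) and \code{summary.json}
#' (costs, meeting time, convergence).
#'
#' @param sol A \code{nash_solution}.
#' @param scenario The scenario it was solved from.
#' @param dir Output directory (created if missing).
#' @param extra Named list merged into the summary (e.g. a certificate).
#' @return The summary list, invisibly.
#' @export
write_run_outputs <- function(sol, scenario, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_means_csv(sol, file.path(dir, "means.csv"))
  write_controls_csv(sol, file.path(dir, "controls.csv"))
  utils::write.csv(sol$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(resolved_params_list(scenario),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mt <- meeting_time(sol$mean1, sol$mean2, sol$grid$times)
  summary <- c(list(
    scenario = scenario$name, rho = scenario$params$rho,
    Jhat = sol$cost$Jhat, J1 = sol$cost$J1, J2 = sol$cost$J2,
    W = sol$cost$W,
    terminal = sol$cost$terminal, control_cost = sol$cost$control,
    iterations = max(sol$history$iter), converged = sol$converged,
    gradnorm = sol$gradnorm,
    meeting_time = mt$time, min_mean_distance = mt$distance
  ), extra)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
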