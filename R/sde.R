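# fold a coordinate into [lo, hi] by repeated mirror reflection; valid for
# arbitrary overshoot (period-2L triangular map)
fold_reflect <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  y <- ifelse(y > L, 2 * L - y, y)
  lo + y
}

#' Simulate a particle ensemble of the controlled SDE
#'
#' Euler-Maruyama integration of
#' \eqn{dX = (v + u(t))\,dt + \sigma\,dB} with reflecting barriers at the
#' domain walls (coordinate-wise folding reflection). Initial positions are
#' sampled from the player's Gaussian initial density, rejection-resampled
#' into the domain. The control is interpolated linearly to the step
#' midpoint, which makes the ensemble's cumulative mean drift consistent with
#' the forward Fokker-Planck solver's.
#'
#' @param player A [player_spec()].
#' @param control Control matrix or \code{NULL}.
#' @param params A [game_params()].
#' @param grid The grid (supplies domain, horizon and step).
#' @param n_particles Ensemble size (>= 1).
#' @param seed RNG seed; the ensemble is bit-reproducible for a fixed seed.
#' @return Object of class \code{"mc_ensemble"}: \code{positions} array of
#'   dimension \code{(n_steps + 1, n_particles, 2)}, plus \code{seed},
#'   \code{player}, \code{control}, \code{params}, \code{grid}.
#' @export
simulate_ensemble <- function(player, control, params, grid,
                              n_particles = 10000L, seed = 1L) {
  params <- resolve_sigma(params, grid)
  stopifnot(n_particles >= 1L)
  if (is.null(control)) control <- zero_control(grid)
  m <- grid$n_steps
  lo <- grid$bounds[, 1L]; hi <- grid$bounds[, 2L]
  v <- player_drift(player, grid$horizon)
  sdev <- sqrt(player$width / 2)   # exp(-|x - D|^2 / w) has variance w/2

  set.seed(seed)
  X <- matrix(stats::rnorm(2L * n_particles, mean = rep(player$depart,
                                                        each = n_particles),
                           sd = sdev), n_particles, 2L)
  for (j in 1:2) {
    bad <- which(X[, j] <= lo[j] | X[, j] >= hi[j])
    while (length(bad)) {
      X[bad, j] <- stats::rnorm(length(bad), player$depart[j], sdev)
      bad <- bad[X[bad, j] <= lo[j] | X[bad, j] >= hi[j]]
    }
  }

  pos <- array(0, dim = c(m + 1L, n_particles, 2L))
  pos[1L, , ] <- X
  root_dt <- sqrt(grid$dt)
  for (k in seq_len(m)) {
    u_mid <- (control[k, ] + control[k + 1L, ]) / 2
    b <- v + u_mid
    X <- X + matrix(b * grid$dt, n_particles, 2L, byrow = TRUE) +
      params$sigma * root_dt * matrix(stats::rnorm(2L * n_particles),
                                      n_particles, 2L)
    for (j in 1:2) X[, j] <- fold_reflect(X[, j], lo[j], hi[j])
    pos[k + 1L, , ] <- X
  }

  structure(list(positions = pos, seed = seed, n_particles = n_particles,
                 player = player, control = control, params = params,
                 grid = grid), class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  cat(sprintf("<mc_ensemble> %d particles, %d time nodes (seed %d)\n",
              x$n_particles, dim(x$positions)[1L], x$seed))
  invisible(x)
}

# bin particle positions onto the grid cells -> empirical density matrix
ensemble_histogram <- function(ensemble, grid, time_index) {
  X <- ensemble$positions[time_index, , , drop = FALSE]
  dim(X) <- dim(X)[2:3]
  i1 <- pmin(pmax(ceiling((X[, 1L] - grid$bounds[1L, 1L]) / grid$h[1L]), 1L),
             grid$n_cells[1L])
  i2 <- pmin(pmax(ceiling((X[, 2L] - grid$bounds[2L, 1L]) / grid$h[2L]), 1L),
             grid$n_cells[2L])
  counts <- matrix(0, grid$n_cells[1L], grid$n_cells[2L])
  tab <- table(factor(i1, levels = seq_len(grid$n_cells[1L])),
               factor(i2, levels = seq_len(grid$n_cells[2L])))
  counts[] <- as.numeric(tab)
  counts / (nrow(X) * grid$cell_area)
}

#' Compare a particle ensemble against a Fokker-Planck density
#'
#' Weak-convergence diagnostic: at every time node, the ensemble mean (with
#' its standard errors) is compared to the Fokker-Planck mean, and the
#' total-variation distance between the cell histogram of the particles and
#' the grid density is recorded. The mean check passes when every axis at
#' every node agrees within \code{se_mult} standard errors.
#'
#' @param ensemble An [simulate_ensemble()] ensemble.
#' @param density The matching \code{fp_field} density.
#' @param grid The shared grid.
#' @param se_mult Standard-error multiple for the pass criterion (default 3).
#' @return List with \code{pass}, \code{max_z} (worst standardized mean
#'   discrepancy), \code{table} (per-node data frame: t, mc_x, mc_y, fp_x,
#'   fp_y, se_x, se_y, z_x, z_y, tv) and \code{se_mult}.
#' @export
compare_to_fp <- function(ensemble, density, grid = density$grid,
                          se_mult = 3) {
  m1 <- dim(density$values)[1L]
  if (dim(ensemble$positions)[1L] != m1)
    stop("grid mismatch: ensemble and density have different time grids")
  n <- ensemble$n_particles
  rows <- lapply(seq_len(m1), function(k) {
    X <- ensemble$positions[k, , , drop = FALSE]
    dim(X) <- dim(X)[2:3]
    mc <- colMeans(X)
    se <- apply(X, 2L, stats::sd) / sqrt(n)
    se[is.na(se)] <- Inf   # a single particle carries no precision
    fp <- mean_position(density, grid, k)
    z <- abs(mc - fp) / pmax(se, .Machine$double.eps)
    tv <- 0.5 * sum(abs(ensemble_histogram(ensemble, grid, k) -
                          slice_at(density, grid, k))) * grid$cell_area
    data.frame(t = grid$times[k], mc_x = mc[1L], mc_y = mc[2L],
               fp_x = fp[1L], fp_y = fp[2L], se_x = se[1L], se_y = se[2L],
               z_x = z[1L], z_y = z[2L], tv = tv)
  })
  tab <- do.call(rbind, rows)
  max_z <- max(tab$z_x, tab$z_y)
  list(pass = is.finite(max_z) && max_z <= se_mult, max_z = max_z,
       table = tab, se_mult = se_mult)
}
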