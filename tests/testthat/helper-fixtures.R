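# Shared small fixtures and a cache for expensive solves reused across tests.

# coarse grid for fast PDE tests
tiny_grid <- function(n_cells = 8L, n_steps = 8L, bounds = list(c(-3, 3), c(-3, 3)),
                      horizon = 3) {
  build_grid(bounds, n_cells = n_cells, horizon = horizon, n_steps = n_steps)
}

# a Gaussian cell matrix centered at `center` with width w, unit mass
gaussian_field <- function(grid, center, width = 0.5) {
  initial_density(player_spec(center, center, drift = c(0, 0), width = width),
                  grid)
}

# deterministic pseudo-random admissible control on a grid
random_control <- function(grid, scale = 0.5, bounds = c(-5, 5), seed = 1L) {
  set.seed(seed)
  u <- matrix(stats::rnorm(2L * (grid$n_steps + 1L), sd = scale),
              grid$n_steps + 1L, 2L)
  project_control(u, bounds)
}

# wrap a (time, cells, cells) array as a density field
fp_field_from_array <- function(values, grid) {
  f <- fpnash:::fp_field(values, grid, role = "density")
  f
}

# wrap a single cell matrix as a one-slice density field
fp_dummy_field <- function(mat, grid) {
  fp_field_from_array(array(mat, dim = c(1L, nrow(mat), ncol(mat))), grid)
}

# session-level cache so acceptance tests can share converged solutions
.solve_cache <- new.env(parent = emptyenv())

cached_nash <- function(name, rho = NULL, max_iters = 200L) {
  key <- paste0(name, "@", if (is.null(rho)) "low" else rho, "@", max_iters)
  if (!is.null(.solve_cache[[key]])) return(.solve_cache[[key]])
  overrides <- if (is.null(rho)) list() else list(rho = rho)
  sc <- load_scenario(name, overrides)
  sol <- solve_nash(sc, nash_control(max_iters = max_iters), quiet = TRUE)
  .solve_cache[[key]] <- list(scenario = sc, sol = sol)
  .solve_cache[[key]]
}
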