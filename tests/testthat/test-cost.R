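test_that("terminal cost vanishes at the target and matches Gaussian moments", {
  g <- tiny_grid(50)
  pl <- player_spec(c(-1, 0), c(1, 0.5))
  # point mass at the arrival point: potential minimum
  i <- which.min(abs(g$centers[[1]] - 1))
  j <- which.min(abs(g$centers[[2]] - 0.5))
  pt <- matrix(0, 50, 50); pt[i, j] <- 1 / g$cell_area
  f <- fp_dummy_field(pt, g)
  expect_lt(terminal_cost(f, pl, alpha = 100, g), 100 * 2 * (g$h[1] / 2)^2 + 1e-9)
  expect_equal(terminal_cost(f, pl, alpha = 0, g), 0)
  # Gaussian centered at the arrival point with per-axis variance s^2
  w <- 0.3   # variance w/2 per axis
  fg <- fp_dummy_field(gaussian_field(g, c(1, 0.5), width = w), g)
  expect_equal(terminal_cost(fg, pl, alpha = 100, g), 100 * 2 * (w / 2),
               tolerance = 1e-3 * 100 * w)
})

test_that("control cost is an H1 quadrature with the right scalings", {
  g <- build_grid(list(c(0, 1), c(0, 1)), 8, horizon = 3, n_steps = 200)
  expect_equal(control_cost(zero_control(g), g, nu = 1), 0)
  u <- zero_control(g)
  u[, 1] <- sin(pi * g$times / g$horizon)
  exact <- 0.5 * (g$horizon / 2 + pi^2 / (2 * g$horizon))
  expect_equal(control_cost(u, g, nu = 1), exact, tolerance = 1e-3 * exact)
  # quadratic homogeneity
  expect_equal(control_cost(2 * u, g, nu = 1), 4 * control_cost(u, g, nu = 1))
  expect_equal(control_cost(u, g, nu = 3), 3 * control_cost(u, g, nu = 1))
})

test_that("interaction cost integrates the overlap in time", {
  g <- build_grid(list(c(-3, 3), c(-3, 3)), 10, horizon = 3, n_steps = 6)
  uni <- array(1 / 36, dim = c(7, 10, 10))
  f1 <- fp_field_from_array(uni, g)
  f2 <- fp_field_from_array(uni, g)
  # static identical uniform densities, |Omega| = 36, T = 3, rho = 1
  expect_equal(interaction_cost(f1, f2, rho = 1, g), 3 / 36, tolerance = 1e-12)
  expect_equal(interaction_cost(f1, f2, rho = 0, g), 0)
  disj <- array(0, dim = c(7, 10, 10)); disj[, 1:3, ] <- 1
  expect_equal(interaction_cost(f1, fp_field_from_array(0 * uni, g), 1, g), 0)
})

test_that("collision probability approximates the small-radius double integral", {
  g <- build_grid(list(c(-3, 3), c(-3, 3)), 10, horizon = 1, n_steps = 2)
  uni <- fp_field_from_array(array(1 / 36, dim = c(3, 10, 10)), g)
  expect_equal(collision_probability(uni, uni, r = 0.6, g, 1L), 0.01,
               tolerance = 1e-12)
  # disjoint supports
  a <- array(0, dim = c(3, 10, 10)); a[, 1:3, ] <- 0.5
  b <- array(0, dim = c(3, 10, 10)); b[, 7:10, ] <- 0.5
  expect_equal(collision_probability(fp_field_from_array(a, g),
                                     fp_field_from_array(b, g), 0.5, g, 1L), 0)
  # two Gaussians vs the closed-form double integral over |y - x| < r:
  # for independent Gaussians the difference is Gaussian, so the collision
  # probability is a noncentral chi-square tail (exact oracle)
  g2 <- build_grid(list(c(-3, 3), c(-3, 3)), 48, horizon = 1, n_steps = 2)
  mu1 <- c(0.3, 0); mu2 <- c(-0.2, 0.2); w <- 1   # per-axis variance w/2
  f1m <- gaussian_field(g2, mu1, width = w)
  f2m <- gaussian_field(g2, mu2, width = w)
  r <- 0.25
  st2 <- 2 * (w / 2)                              # variance of the difference
  exact <- stats::pchisq(r^2 / st2, df = 2, ncp = sum((mu2 - mu1)^2) / st2)
  approx <- r^2 * overlap(f1m, f2m, g2)
  # r^2 x overlap carries the r^D convention of the collision cost; the geometric ball
  # factor pi relates it to the true probability
  expect_equal(approx * pi, exact, tolerance = 0.1)
})

test_that("composite cost separates at rho = 0 and obeys the bookkeeping", {
  sc <- load_scenario("huber-135", n_cells = 10, n_steps = 8)
  g <- sc$grid; pl <- sc$players
  u1 <- random_control(g, 0.3, seed = 1)
  u2 <- random_control(g, 0.3, seed = 2)
  p0 <- sc$params; p0$rho <- 0; p0$alpha <- 0
  cc0 <- composite_cost(zero_control(g), zero_control(g), pl, p0, g)
  expect_equal(cc0$Jhat, 0)
  # J1 + J2 = Jhat + W for any controls
  pr <- sc$params; pr$rho <- 5
  cc <- composite_cost(u1, u2, pl, pr, g)
  expect_equal(cc$J1 + cc$J2, cc$Jhat + cc$W, tolerance = 1e-10)
  expect_equal(cc$Jhat, sum(cc$terminal) + sum(cc$control) + cc$W,
               tolerance = 1e-10)
  # at rho = 0 the value is the sum of two independent single-player costs
  ps <- sc$params; ps$rho <- 0
  ccs <- composite_cost(u1, u2, pl, ps, g)
  f1 <- solve_fp(pl[[1]], u1, ps, g)
  f2 <- solve_fp(pl[[2]], u2, ps, g)
  solo <- terminal_cost(f1, pl[[1]], ps$alpha, g) +
    control_cost(u1, g, ps$nu) +
    terminal_cost(f2, pl[[2]], ps$alpha, g) + control_cost(u2, g, ps$nu)
  expect_equal(ccs$Jhat, solo, tolerance = 1e-10)
})
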