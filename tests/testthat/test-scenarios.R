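# frozen benchmark settings (departure/arrival/drift geometry)
benchmark_registry <- list(
  "huber-135" = list(bounds = rbind(c(-3, 3), c(-3, 3)), horizon = 3,
                     d1 = c(-1, 0), a1 = c(2, 0), v1 = c(1, 0),
                     d2 = c(1, 1), a2 = c(-2, -2), v2 = c(-1, -1)),
  "turnwald-1c-a3" = list(bounds = rbind(c(-1, 8), c(-1, 8)), horizon = 5,
                          d1 = c(1, 1), a1 = c(6, 4), v1 = c(1, 0.6),
                          d2 = c(6, 1), a2 = c(1, 4), v2 = c(-1, 0.6)),
  "turnwald-1c-b2" = list(bounds = rbind(c(-1, 1), c(-3, 3)), horizon = 5,
                          d1 = c(0, -2.5), a1 = c(0, 2.5), v1 = c(0, 1),
                          d2 = c(-0.5, 2.5), a2 = c(0.5, -2.5), v2 = c(0.2, -1)),
  "gait-posture" = list(bounds = rbind(c(-10, 10), c(-10, 10)), horizon = 1,
                        d1 = c(-7.5, -7.5), a1 = c(7.5, 7.5), v1 = c(15, 15),
                        d2 = c(-7.5, 7.5), a2 = c(7.5, -7.5), v2 = c(15, -15))
)

test_that("the registry ships exactly the four benchmarks with their settings", {
  expect_setequal(scenario_names(), names(benchmark_registry))
  for (nm in names(benchmark_registry)) {
    ref <- benchmark_registry[[nm]]
    sc <- load_scenario(nm)
    expect_equal(unname(sc$grid$bounds), unname(ref$bounds), info = nm)
    expect_equal(sc$grid$horizon, ref$horizon, info = nm)
    expect_equal(sc$players[[1]]$depart, ref$d1, info = nm)
    expect_equal(sc$players[[1]]$arrive, ref$a1, info = nm)
    expect_equal(sc$players[[1]]$drift, ref$v1, info = nm)
    expect_equal(sc$players[[2]]$depart, ref$d2, info = nm)
    expect_equal(sc$players[[2]]$arrive, ref$a2, info = nm)
    expect_equal(sc$players[[2]]$drift, ref$v2, info = nm)
    expect_equal(sc$grid$n_cells, c(50L, 50L), info = nm)
    expect_equal(sc$grid$n_steps, 50L, info = nm)
    expect_equal(sc$params$alpha, 100)
    expect_equal(sc$params$nu, 1)
    expect_equal(sc$params$rho, 0.01)
  }
  expect_equal(load_scenario("gait-posture")$params$bounds, c(-40, 40))
  expect_error(load_scenario("nope"), "unknown scenario")
})

test_that("overrides are honoured and rho can be set through (r, C)", {
  sc <- load_scenario("turnwald-1c-b2", list(rho = 150))
  expect_equal(sc$params$rho, 150)
  sc2 <- load_scenario("huber-135", list(sigma = 0.42, n_steps = 10))
  expect_equal(sc2$params$sigma, 0.42)
  expect_equal(sc2$grid$n_steps, 10L)
  gp <- game_params(r = 0.5, C = 800)
  expect_equal(gp$rho, 200)
})

test_that("meeting time is the earliest minimizer of the inter-mean distance", {
  t <- seq(0, 3, by = 0.1)
  m1 <- cbind(-1 + t, 0 * t)
  m2 <- cbind(1 - t, 1 - t)
  mt <- meeting_time(m1, m2, t)
  expect_equal(mt$time, 1)
  expect_lt(mt$distance, 1e-12)
  # identical trajectories: first node, distance zero
  mt2 <- meeting_time(m1, m1, t)
  expect_equal(mt2$time, 0)
  expect_equal(mt2$distance, 0)
  # constant separation: earliest node wins the tie
  m3 <- cbind(0 * t, t); m4 <- cbind(0 * t + 2, t)
  mt3 <- meeting_time(m3, m4, t)
  expect_equal(mt3$time, 0)
  expect_equal(mt3$distance, 2)
  expect_error(meeting_time(m1[0, ], m2, t), "nonempty")
})

test_that("solve subcommand writes a complete, deterministic run directory", {
  dir1 <- withr::local_tempdir()
  args <- c("solve", "--scenario", "huber-135", "--grid", "10", "--steps",
            "10", "--max-iters", "5", "--out", dir1)
  expect_equal(suppressMessages(fpnash_cli(args)), 0L, ignore_attr = TRUE)
  for (f in c("means.csv", "controls.csv", "history.csv", "summary.json",
              "params.json"))
    expect_true(file.exists(file.path(dir1, f)), info = f)
  s1 <- jsonlite::read_json(file.path(dir1, "summary.json"))
  expect_equal(s1$scenario, "huber-135")
  # a second identical run reproduces the summary exactly
  dir2 <- withr::local_tempdir()
  args2 <- c("solve", "--scenario", "huber-135", "--grid", "10", "--steps",
             "10", "--max-iters", "5", "--out", dir2)
  suppressMessages(fpnash_cli(args2))
  s2 <- jsonlite::read_json(file.path(dir2, "summary.json"))
  expect_identical(s1[setdiff(names(s1), "scenario")],
                   s2[setdiff(names(s2), "scenario")])
})

test_that("a YAML config resolves a scenario with overrides", {
  cfg <- file.path(withr::local_tempdir(), "game.yaml")
  writeLines(c("scenario: turnwald-1c-b2", "rho: 150", "sigma: 0.2"), cfg)
  sc <- fpnash:::cli_scenario(list(config = cfg))
  expect_equal(sc$name, "turnwald-1c-b2")
  expect_equal(sc$params$rho, 150)
  expect_equal(sc$params$sigma, 0.2)
})

test_that("field and ensemble exports produce well-formed CSV", {
  g <- tiny_grid()
  pl <- player_spec(c(-1, 0), c(1, 0))
  f <- solve_fp(pl, NULL, game_params(sigma = 0.3), g)
  path <- file.path(withr::local_tempdir(), "f.csv")
  write_field_csv(f, path, g, time_indices = c(1L, 9L))
  df <- utils::read.csv(path)
  expect_named(df, c("t", "x", "y", "value"))
  expect_equal(nrow(df), 2 * 64)
  expect_equal(sum(df$value[df$t == 0]) * g$cell_area, 1, tolerance = 1e-8)
  ens <- simulate_ensemble(pl, NULL, game_params(sigma = 0.3), g, 10, seed = 2)
  path2 <- file.path(withr::local_tempdir(), "e.csv")
  write_ensemble_csv(ens, path2)
  de <- utils::read.csv(path2)
  expect_named(de, c("particle_id", "t", "x", "y"))
  expect_equal(nrow(de), 10 * 9)
})

test_that("report on a missing run directory fails cleanly", {
  expect_equal(suppressMessages(
    fpnash_cli(c("report", "--out", file.path(tempdir(), "no-such-run")))),
    1L, ignore_attr = TRUE)
  expect_equal(suppressMessages(fpnash_cli(c("frobnicate"))), 1L,
               ignore_attr = TRUE)
})

test_that("simulate and verify subcommands run against a stored solve", {
  dir <- withr::local_tempdir()
  suppressMessages(fpnash_cli(c("solve", "--scenario", "huber-135", "--grid",
                                "10", "--steps", "10", "--max-iters", "40",
                                "--rho", "0", "--tol", "1e-6", "--out", dir)))
  expect_equal(suppressMessages(fpnash_cli(
    c("simulate", "--out", dir, "--particles", "200"))), 0L,
    ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "ensemble_player1.csv")))
  expect_equal(suppressMessages(fpnash_cli(c("verify", "--out", dir))), 0L,
               ignore_attr = TRUE)
})
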