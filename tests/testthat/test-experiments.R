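test_that("damping metrics handle constant, damped and decaying trajectories", {
  p <- fig2_params()
  e3 <- equilibria2(p)$E3
  st <- solver_settings(h = 0.01, t_end = 20)
  n <- 2001L
  times <- st$h * (0:(n - 1L))

  const <- structure(list(times = times,
                          states = matrix(rep(e3$coords, each = n), n, 2,
                                          dimnames = list(NULL, c("x", "y"))),
                          alpha = 1, settings = st, params = p),
                     class = "fraclv_trajectory")
  m <- damping_metrics(const, e3)
  expect_identical(m$tail_amplitude_max, 0)
  expect_identical(m$settling_time, 0)
  expect_false(m$extinct)

  # synthetic damped oscillation around a scalar target x* = 1:
  # envelope 0.2 exp(-t/10) crosses delta * x* at t = 10 log(0.2/delta)
  tt <- seq(0, 100, by = 0.01)
  xs <- 1 + exp(-tt / 10) * 0.2 * cos(tt)
  osc <- structure(list(times = tt, states = matrix(xs, ncol = 1,
                                                    dimnames = list(NULL, "x")),
                        alpha = 1, settings = st, params = NULL),
                   class = "fraclv_trajectory")
  mo <- damping_metrics(osc, 1, delta = 0.01)
  t_pred <- 10 * log(0.2 / 0.01)
  # the last envelope touch below delta happens within one oscillation
  # period of the envelope crossing (the cosine phase discretizes it)
  expect_lt(abs(mo$settling_time - t_pred), pi)
  expect_false(mo$extinct)

  dec <- structure(list(times = tt,
                        states = cbind(x = exp(-tt), y = rep(1, length(tt))),
                        alpha = 1, settings = st, params = NULL),
                   class = "fraclv_trajectory")
  md <- damping_metrics(dec, c(0, 1))
  expect_true(md$extinct)
})

test_that("scenario runs converge to the co-existence point with shrinking oscillations", {
  st <- solver_settings(h = 0.02, t_end = 100)
  cfg <- fig_fixture("fig2", alpha = c(1, 0.9, 0.8), settings = st)
  res <- run_scenario(cfg)
  e3 <- equilibria2(cfg$params)$E3
  for (k in names(res$trajectories)) {
    expect_identical(res$targets[[k]]$label, "E3")
    term <- res$trajectories[[k]]$states[nrow(res$trajectories[[k]]$states), ]
    expect_lt(max(abs(term - e3$coords)), 0.01)
  }
  # full-horizon oscillation range shrinks as the order decreases
  ranges <- vapply(res$trajectories, function(tr)
    diff(range(tr$states[, 1])), numeric(1))
  expect_true(all(diff(ranges[order(cfg$alpha, decreasing = TRUE)]) < 0))
})

test_that("a trajectory started at the target settles immediately", {
  st <- solver_settings(h = 0.02, t_end = 50)
  p <- fig2_params()
  e3 <- equilibria2(p)$E3
  cfg <- scenario_config(p, 0.9, e3$coords, st)
  res <- run_scenario(cfg)
  m <- res$metrics[[1L]]
  expect_identical(m$settling_time, 0)
  expect_lt(m$tail_amplitude_max, 1e-8)
})

test_that("alpha_sweep summarizes single and multiple orders", {
  st <- solver_settings(h = 0.02, t_end = 100)
  cfg <- fig_fixture("fig2", alpha = 1, settings = st)
  sw1 <- alpha_sweep(cfg, alphas = 0.9)
  expect_identical(nrow(sw1), 1L)
  expect_true(attr(sw1, "tail_amplitude_nonincreasing"))

  sw <- alpha_sweep(cfg, alphas = c(1, 0.9))
  expect_identical(nrow(sw), 2L)
  expect_true(is.logical(attr(sw, "settling_nonincreasing")))
  expect_identical(sw$alpha, c(1, 0.9))
})

test_that("harvest_sweep flags extinction cells and handles empty grids", {
  st <- solver_settings(h = 0.02, t_end = 100)
  cfg <- fig_fixture("fig4", alpha = 1, settings = st)

  empty <- harvest_sweep(cfg, data.frame(eps1 = numeric(0),
                                         eps2 = numeric(0)))
  expect_identical(nrow(empty), 0L)

  sw <- suppressWarnings(
    harvest_sweep(cfg, data.frame(eps1 = c(0.4, 1.2), eps2 = c(1, 1))))
  expect_false(sw$prey_overharvested[1L])
  expect_true(sw$prey_overharvested[2L])
  expect_true(sw$extinct[2L])
  # over the extinction threshold the origin is the stable attractor
  res2 <- attr(sw, "results")[[2L]]
  expect_identical(res2$reports[[1L]]$E1$verdict, "stable")
  expect_error(harvest_sweep(cfg, data.frame(eps1 = -0.1, eps2 = 0)),
               "nonnegative")
})

test_that("identical configs give byte-identical CSV outputs", {
  st <- solver_settings(h = 0.02, t_end = 20)
  cfg <- fig_fixture("fig2", alpha = 0.9, settings = st)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  run_scenario(cfg, outdir = d1)
  run_scenario(cfg, outdir = d2)
  f1 <- file.path(d1, "fig2_alpha0.9.csv")
  f2 <- file.path(d2, "fig2_alpha0.9.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reproduce_figure writes trajectories, phase samples and reports", {
  st <- solver_settings(h = 0.02, t_end = 50)
  out <- tempfile()
  on.exit(unlink(out, recursive = TRUE))
  res <- reproduce_figure("fig2", outdir = out, settings = st,
                          alpha = c(1, 0.9))
  files <- basename(res$files)
  expect_true("fig2_alpha1.csv" %in% files)
  expect_true("fig2_alpha0.9.csv" %in% files)
  expect_true("fig2_phase_alpha0.9.csv" %in% files)
  expect_true("fig2_report.json" %in% files)
  rep <- jsonlite::read_json(file.path(out, "fig2_report.json"))
  expect_identical(rep$model, "2sp")
  expect_named(rep$equilibria, c("E1", "E2", "E3"))

  out5 <- tempfile()
  on.exit(unlink(out5, recursive = TRUE), add = TRUE)
  res5 <- reproduce_figure("fig5", outdir = out5, settings = st)
  expect_true(res5$extras$condition_15$holds)
  expect_true(file.exists(file.path(out5, "fig5_criterion.json")))
})

test_that("scenario configs round-trip through YAML and drive the CLI", {
  st <- solver_settings(h = 0.02, t_end = 30)
  cfg <- fig_fixture("fig3", alpha = c(0.9, 0.8), settings = st)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_scenario_config(cfg, tmp)
  cfg2 <- read_scenario_config(tmp)
  expect_identical(cfg2$model, "3sp")
  expect_equal(unclass(cfg2$params), unclass(cfg$params), tolerance = 1e-15)
  expect_identical(cfg2$alpha, c(0.9, 0.8))
  expect_identical(cfg2$x0, unname(cfg$x0))
  expect_identical(cfg2$settings$h, 0.02)

  outdir <- tempfile()
  on.exit(unlink(outdir, recursive = TRUE), add = TRUE)
  status <- fraclv_cli(c("simulate", "--config", tmp, "--alpha", "0.9",
                         "--t-end", "20", "--out", outdir))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(outdir, "fig3_alpha0.9.csv")))

  expect_identical(fraclv_cli(c("equilibria", "--config", tmp,
                                "--out", file.path(outdir, "eq.json"))), 0L)
  eq <- jsonlite::read_json(file.path(outdir, "eq.json"))
  expect_true(all(c("E1", "E2", "E3", "E4") %in% names(eq)))
  expect_identical(fraclv_cli("nonsense"), 1L)
})
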