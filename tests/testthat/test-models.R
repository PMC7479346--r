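test_that("rhs2 matches hand evaluation and vanishes at fixed points", {
  p <- fig2_params()
  expect_identical(rhs2(c(0, 0), p), c(0, 0))
  expect_equal(rhs2(c(0.2, 0.25), p), c(0.03, 0.75 / 1.4 - 0.5),
               tolerance = 1e-14)
  e3 <- equilibria2(p)$E3
  expect_lt(max(abs(rhs2(e3$coords, p))), 1e-12)
  expect_error(rhs2(c(NA, 0.1), p), "finite")
  expect_error(rhs2(c(0.1, Inf), p), "finite")
  expect_error(rhs2(c(0.1, 0.1, 0.1), p), "length 2")
})

test_that("rhs3 matches hand evaluation and vanishes at computed equilibria", {
  p <- fig3_params()
  expect_identical(rhs3(c(0, 0, 0), p), c(0, 0, 0))
  f <- rhs3(c(0.2, 0.3, 0.3), p)
  expect_equal(f[1], -0.005, tolerance = 1e-12)
  expect_equal(f[2], 0.078 / 1.28 - 0.129, tolerance = 1e-12)
  expect_equal(f[3], 7 * 0.2 * 0.3 * 0.31 / 1.004 - 0.018, tolerance = 1e-12)
  for (eq in equilibria3(p)) {
    if (all(is.finite(eq$coords)))
      expect_lt(max(abs(rhs3(eq$coords, p))), 1e-8)
  }
  expect_error(rhs3(c(0.1, NaN, 0.1), p), "finite")
})

test_that("nondimensionalize reproduces the transform definitions", {
  nd <- nondimensionalize(dim_params2(r = 0.5, K = 100, a = 0.03,
                                      sigma = 0.02, k = 0.1,
                                      h1 = 0.04, h2 = 0.1))
  expect_s3_class(nd$params, "params2")
  expect_equal(unclass(nd$params),
               list(rho = 5, psi = 30, phi = 2, eps1 = 0.4, eps2 = 1),
               tolerance = 1e-15)
  expect_equal(unname(nd$state_scale), c(100, 0.1 / 0.03))
  expect_equal(nd$time_scale, 10)

  # rho = r/k and eps1 = h1/k by definition
  nd2 <- nondimensionalize(dim_params2(r = 0.3, K = 10, a = 0.1,
                                       sigma = 0.1, k = 0.3))
  expect_equal(nd2$params$rho, 1)
  expect_equal(nd2$params$eps1, 0)

  # three species: eps2 folds in the natural death term
  nd3 <- nondimensionalize(dim_params3(r = 1, K = 10, a = 0.2, b = 0.1,
                                       xi = 0.05, sigma1 = 0.1,
                                       sigma2 = 0.05, k1 = 0.5, k2 = 0.2))
  expect_identical(nd3$params$eps2, 1)
  expect_equal(nd3$params$eps3, 0.2 / 0.5)
  expect_equal(nd3$params$eta, 0.2 * 0.1 / (0.05 * 0.5))
})

test_that("degenerate dimensional inputs raise informative errors", {
  expect_error(dim_params2(r = 1, K = 0, a = 1, sigma = 1, k = 1), "K")
  expect_error(nondimensionalize(structure(list(r = 1, K = 1, a = 1,
                                                sigma = 1, k = 0,
                                                h1 = 0, h2 = 0),
                                           class = "dim_params2")), "'k'")
  expect_error(nondimensionalize(structure(list(r = 1, K = 1, a = 1, b = 1,
                                                xi = 0, sigma1 = 1,
                                                sigma2 = 1, k1 = 1, k2 = 1,
                                                h1 = 0, h2 = 0, h3 = 0),
                                           class = "dim_params3")), "'xi'")
})

test_that("dimensionless trajectory maps back onto a dimensional simulation", {
  dp <- dim_params2(r = 0.5, K = 100, a = 0.03, sigma = 0.02, k = 0.1,
                    h1 = 0.04, h2 = 0.1)
  nd <- nondimensionalize(dp)
  # dimensional vector field written out independently of the package
  rhs_dim <- function(S) {
    X <- S[1]; Y <- S[2]
    c(dp$r * X * (1 - X / dp$K) - dp$a * X * Y - dp$h1 * X,
      dp$a * X * Y / (1 + dp$sigma * X) - dp$k * Y - dp$h2 * Y)
  }
  t_nd <- 10
  x0_nd <- c(0.3, 0.4)
  tr_nd <- reference_solve(make_rhs(nd$params), x0_nd,
                           solver_settings(h = 0.01, t_end = t_nd))
  X0 <- nd$state_scale * x0_nd
  tr_dim <- reference_solve(rhs_dim, X0,
                            solver_settings(h = 0.01 * nd$time_scale,
                                            t_end = t_nd * nd$time_scale))
  mapped <- sweep(tr_nd$states, 2L, nd$state_scale, `*`)
  expect_equal(mapped, tr_dim$states, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("lipschitz bounds match their closed forms and the 1-norm inequality", {
  lb <- lipschitz_bounds(fig2_params(), M = 2)
  expect_equal(lb$L1, 5.4)
  expect_equal(lb$L2, 152)
  expect_equal(lb$L, 152)
  # M -> 0 limit
  p <- fig2_params()
  lb0 <- lipschitz_bounds(p, M = 1e-12)
  expect_equal(lb0$L1, p$rho + p$eps1, tolerance = 1e-9)
  expect_equal(lb0$L2, 1 + p$eps2, tolerance = 1e-9)
  expect_error(lipschitz_bounds(p, M = 0), "positive")

  # Monte-Carlo verification of ||F(X)-F(Xb)||_1 <= L ||X-Xb||_1
  set.seed(42)
  M <- 2
  for (ps in list(fig2_params(), fig3_params())) {
    d <- if (inherits(ps, "params2")) 2L else 3L
    L <- lipschitz_bounds(ps, M)$L
    f <- make_rhs(ps)
    for (i in 1:1000) {
      X <- runif(d, 0, M); Xb <- runif(d, 0, M)
      lhs <- sum(abs(f(X) - f(Xb)))
      expect_lte(lhs, L * sum(abs(X - Xb)) + 1e-12)
    }
  }
})

test_that("parameter config round-trips and rejects unknown keys", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  p <- fig3_params()
  write_params_config(p, tmp)
  p2 <- read_params_config(tmp)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-15)
  writeLines(c("model: 2sp", "rho: 1", "psi: 10", "phi: 1", "epsilon1: 0.1"),
             tmp)
  expect_error(read_params_config(tmp), "unknown parameter key")
})
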