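test_that("matignon_check covers the sector geometry", {
  expect_identical(matignon_check(-1, 0.3), "stable")
  expect_identical(matignon_check(-1, 1), "stable")
  expect_identical(matignon_check(complex(real = 0, imaginary = c(1, -1)), 1),
                   "marginal")
  eig <- complex(real = 1, imaginary = c(1, -1))
  expect_identical(matignon_check(eig, 0.4), "stable")
  expect_identical(matignon_check(eig, 0.6), "unstable")
  expect_identical(matignon_check(c(0, -1), 0.5), "indeterminate")
})

test_that("critical_alpha reproduces its closed cases", {
  expect_identical(critical_alpha(c(-2, -0.5)), 1)
  expect_equal(critical_alpha(complex(real = 1, imaginary = c(1, -1))), 0.5)
  expect_identical(critical_alpha(c(2, -1)), 0)
  expect_warning(ca <- critical_alpha(c(0, -1)), "indeterminate")
  expect_true(is.na(ca))
  # benchmark co-existence spectrum: stable for every order
  p <- fig2_params()
  eig <- eigen(unclass(jacobian(p, equilibria2(p)$E3$coords)))$values
  expect_identical(critical_alpha(eig), 1)
})

test_that("matignon properties: monotone in alpha, classical limit at alpha = 1", {
  set.seed(101)
  for (i in 1:500) {
    eig <- sample_spectrum()
    a2 <- runif(1, 0.05, 1)
    a1 <- runif(1, 0.01, a2)
    if (matignon_check(eig, a2) == "stable")
      expect_identical(matignon_check(eig, a1), "stable")
    if (min(abs(abs(Arg(eig)) - pi / 2)) > 1e-9) {
      cls <- if (all(Re(eig) < 0)) "stable" else "unstable"
      expect_identical(matignon_check(eig, 1), cls)
    }
    # verdict flips across the critical order
    ca <- critical_alpha(eig)
    if (ca > 1e-6 && ca < 1 - 1e-6) {
      expect_identical(matignon_check(eig, ca - 1e-9), "stable")
      expect_false(identical(matignon_check(eig, min(1, ca + 1e-9)),
                             "stable"))
    }
  }
})

test_that("rh_classify_2x2 matches eigenvalue classification", {
  expect_identical(rh_classify_2x2(-1, 1), "stable")
  expect_identical(rh_classify_2x2(5, -1), "saddle")
  expect_identical(rh_classify_2x2(1, 1), "unstable")
  expect_identical(rh_classify_2x2(0, 1), "marginal")
  set.seed(17)
  for (i in 1:500) {
    tr <- runif(1, -3, 3); dt <- runif(1, -3, 3)
    if (abs(dt) < 1e-6 || abs(tr) < 1e-6) next
    lam <- polyroot(c(dt, -tr, 1))
    cls <- rh_classify_2x2(tr, dt)
    if (dt < 0) {
      expect_identical(cls, "saddle")
      expect_true(prod(sign(Re(lam))) < 0)
    } else {
      expect_identical(cls, if (tr < 0) "stable" else "unstable")
      expect_identical(all(Re(lam) < 0), cls == "stable")
    }
  }
})

test_that("cubic discriminant matches worked examples and a root oracle", {
  r <- cubic_discriminant(-6, 11, -6)
  expect_identical(r$D, 4)
  expect_identical(r$roots_label, "three distinct real")
  r2 <- cubic_discriminant(0, 0, -1)
  expect_identical(r2$D, -27)
  expect_identical(r2$roots_label, "one real + conjugate pair")
  expect_identical(cubic_discriminant(-3, 3, -1)$D, 0)

  set.seed(23)
  for (i in 1:500) {
    a <- runif(3, -3, 3)
    r <- cubic_discriminant(a[1], a[2], a[3])
    if (abs(r$D) <= 1e-8) next
    roots <- polyroot(c(a[3], a[2], a[1], 1))
    n_real <- sum(abs(Im(roots)) < 1e-7 * pmax(1, abs(roots)))
    expect_identical(r$roots_label,
                     if (n_real == 3) "three distinct real"
                     else "one real + conjugate pair")
  }
})

test_that("lemma32_conditions evaluates printed branches against the root oracle", {
  r1 <- lemma32_conditions(2, 0.5)
  expect_true(r1$branch[["a1_positive"]])
  expect_identical(r1$verdict, "stable")
  expect_true(r1$agree)

  # roots (1 +/- i sqrt(3))/2, |arg| = pi/3: stable iff alpha < 2/3
  for (a in c(0.5, 0.8)) {
    r2 <- lemma32_conditions(c(-1, 1), a)
    expect_identical(r2$verdict, if (a < 2 / 3) "stable" else "unstable")
    expect_true(r2$agree)
  }

  # cubic branch: printed direction is compared, not asserted
  r3 <- lemma32_conditions(c(-1, -1, 0.5), 0.9)
  expect_true(is.logical(r3$agree) || is.na(r3$agree))
  expect_identical(r3$verdict,
                   matignon_check(polyroot(c(0.5, -1, -1, 1)), 0.9))
  # necessary condition a_n > 0
  expect_false(lemma32_conditions(c(1, 1, -2), 0.5)$necessary_an)
})

test_that("classify_equilibrium agrees with the closed-form inequality sets", {
  # extinction point: stable iff prey harvest outstrips growth
  p_hi <- params2(0.5, 10, 1, eps1 = 0.6, eps2 = 0.2)
  r <- classify_equilibrium(p_hi, 0.7, equilibria2(p_hi)$E1)
  expect_identical(r$verdict, "stable")
  expect_true(r$conditions[["rho_lt_eps1"]])
  expect_true(r$agree)

  p_lo <- fig2_params()
  r2 <- classify_equilibrium(p_lo, 0.7, equilibria2(p_lo)$E1)
  expect_identical(r2$verdict, "unstable")
  expect_identical(r2$critical_alpha, 0)
  expect_true(r2$agree)

  # benchmark co-existence point at fractional order
  r3 <- classify_equilibrium(p_lo, 0.9, equilibria2(p_lo)$E3)
  expect_identical(r3$verdict, "stable")
  expect_identical(r3$critical_alpha, 1)
  expect_true(r3$agree)

  # infeasible points still get classified
  p3 <- fig3_params()
  eq3 <- equilibria3(p3)
  r4 <- classify_equilibrium(p3, 0.9, eq3$E3)
  expect_identical(r4$verdict, "unstable")
})

test_that("three-species memory threshold: co-existence stable only below critical order", {
  p3 <- fig3_params()
  eq <- equilibria3(p3)
  e5 <- Filter(function(e) e$feasible &&
                 classify_equilibrium(p3, 0.9, e)$verdict == "stable",
               eq[grepl("^E5", names(eq))])
  expect_length(e5, 1L)
  r <- classify_equilibrium(p3, 0.9, e5[[1L]])
  expect_lt(r$critical_alpha, 1)
  expect_gt(r$critical_alpha, 0.9)
  expect_identical(classify_equilibrium(p3, 1, e5[[1L]])$verdict, "unstable")
})

test_that("oscillation criterion evaluates and coincides with complex eigenvalues", {
  # unharvested weak-saturation fixture: criterion holds as printed
  crit <- check_condition_15(fig5_params())
  expect_true(crit$holds_printed)
  expect_true(crit$holds)
  expect_lt(crit$left, crit$right)

  # with no harvesting the printed left side reduces to rho^2
  set.seed(31)
  for (i in 1:20) {
    p <- params2(runif(1, 0.5, 2), runif(1, 5, 30), runif(1, 0.1, 2))
    expect_equal(check_condition_15(p)$left, p$rho^2, tolerance = 1e-12)
  }

  # derived discriminant form coincides with eigenvalues being complex
  for (p in sample_params2(100, seed = 5)) {
    if (p$psi == p$phi * (1 + p$eps2)) next
    eq <- equilibria2(p)$E3
    if (!all(is.finite(eq$coords))) next
    eig <- eigen(unclass(jacobian(p, eq$coords)))$values
    expect_identical(check_condition_15(p)$holds, any(Im(eig) != 0))
  }

  expect_error(check_condition_15(params2(1, 4, 2, 0, 1)), "undefined")
})

test_that("stability verdicts predict the simulated dynamics", {
  set.seed(57)
  st <- solver_settings(h = 0.02, t_end = 500)
  n_checked <- 0
  for (p in sample_params2(40, seed = 57)) {
    eq <- equilibria2(p)$E3
    if (!eq$feasible || !all(is.finite(eq$coords)) ||
        min(eq$coords) < 0.05) next
    r <- classify_equilibrium(p, 0.9, eq)
    if (r$verdict != "stable") next
    x0 <- eq$coords * 1.05
    tr <- solve_fde(make_rhs(p), x0, 0.9, st)
    offset0 <- sqrt(sum((x0 - eq$coords)^2))
    term <- sqrt(sum((tr$states[nrow(tr$states), ] - eq$coords)^2))
    expect_lt(term, 0.01 * offset0)
    n_checked <- n_checked + 1
    if (n_checked >= 15) break
  }
  expect_gte(n_checked, 10)

  # unstable at integer order: the perturbation does not decay to the point
  p3 <- fig3_params()
  eq <- equilibria3(p3)
  e5 <- eq$E5
  r <- classify_equilibrium(p3, 1, e5)
  expect_identical(r$verdict, "unstable")
  x0 <- e5$coords * 1.05
  tr <- solve_fde(make_rhs(p3), x0, 1, solver_settings(h = 0.02, t_end = 500))
  offset0 <- sqrt(sum((x0 - e5$coords)^2))
  term <- sqrt(sum((tr$states[nrow(tr$states), ] - e5$coords)^2))
  expect_gt(term, 0.01 * offset0)
})
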