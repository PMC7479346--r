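matignon_tie_tol <- 1e-12

#' Matignon stability condition
#'
#' An equilibrium of a Caputo fractional system of order `alpha` is
#' asymptotically stable when every Jacobian eigenvalue satisfies
#' `|arg(lambda)| > alpha * pi / 2`: the stability sector widens as the
#' order decreases, so memory enlarges the stable region.  Verdicts:
#' `"stable"` when the condition holds strictly for all eigenvalues,
#' `"unstable"` when violated for some eigenvalue, `"marginal"` when
#' the minimum argument sits on the sector boundary (within 1e-12 --
#' asymptotic stability cannot be asserted there), and
#' `"indeterminate"` when an eigenvalue is zero (linearization is
#' silent).
#'
#' @param eigs Complex (or numeric) vector of eigenvalues, non-empty.
#' @param alpha Fractional order in (0, 1].
#' @return One of `"stable"`, `"unstable"`, `"marginal"`,
#'   `"indeterminate"`.
#' @examples
#' matignon_check(complex(real = 1, imaginary = c(1, -1)), 0.4)  # stable
#' matignon_check(complex(real = 1, imaginary = c(1, -1)), 0.6)  # unstable
#' @export
matignon_check <- function(eigs, alpha) {
  if (length(eigs) == 0L) stop("'eigs' must be non-empty", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  eigs <- as.complex(eigs)
  if (any(eigs == 0)) return("indeterminate")
  m <- min(abs(Arg(eigs)))
  thr <- alpha * pi / 2
  if (abs(m - thr) < matignon_tie_tol) "marginal"
  else if (m > thr) "stable"
  else "unstable"
}

#' Critical fractional order of a spectrum
#'
#' The largest order at which the Matignon condition holds:
#' `min(1, (2/pi) * min |arg(lambda)|)`.  The equilibrium is
#' asymptotically stable for every `alpha` below this value.  A
#' positive real eigenvalue (argument zero) gives 0: no fractional
#' order stabilizes it.  A zero eigenvalue makes linearization
#' indeterminate: the function returns `NA` with a warning.
#'
#' @param eigs Complex (or numeric) vector of eigenvalues.
#' @return A value in `[0, 1]`, or `NA` for a zero eigenvalue.
#' @examples
#' critical_alpha(c(-2, -0.1))                      # 1
#' critical_alpha(complex(real = 1, imaginary = c(1, -1)))  # 0.5
#' @export
critical_alpha <- function(eigs) {
  if (length(eigs) == 0L) stop("'eigs' must be non-empty", call. = FALSE)
  eigs <- as.complex(eigs)
  if (any(eigs == 0)) {
    warning("zero eigenvalue: critical order indeterminate by linearization")
    return(NA_real_)
  }
  min(1, (2 / pi) * min(abs(Arg(eigs))))
}

#' Routh-Hurwitz classification of a planar equilibrium
#'
#' Standard trace/determinant criterion for a 2x2 Jacobian:
#' `det < 0` is a saddle; `det > 0` with `trace < 0` is asymptotically
#' stable; `det > 0` with `trace > 0` is unstable; a vanishing trace or
#' determinant is marginal (a center or degenerate case that
#' linearization cannot decide).
#'
#' @param trace,det Finite reals.
#' @return One of `"saddle"`, `"stable"`, `"unstable"`, `"marginal"`.
#' @export
rh_classify_2x2 <- function(trace, det) {
  if (!is.finite(trace) || !is.finite(det))
    stop("'trace' and 'det' must be finite", call. = FALSE)
  if (det < 0) "saddle"
  else if (det == 0 || trace == 0) "marginal"
  else if (trace < 0) "stable"
  else "unstable"
}

#' Discriminant of a monic cubic and its root structure
#'
#' For `f(x) = x^3 + a1 x^2 + a2 x + a3`, evaluates
#' \deqn{D(f) = 18 a_1 a_2 a_3 + (a_1 a_2)^2 - 4 a_3 a_1^3 - 4 a_2^3
#'  - 27 a_3^2.}
#' `D > 0`: three distinct real roots; `D < 0`: one real root plus a
#' complex-conjugate pair; `D = 0`: a repeated root.
#'
#' @param a1,a2,a3 Coefficients of the monic cubic.
#' @return List with `D` and `roots_label` (one of
#'   `"three distinct real"`, `"one real + conjugate pair"`,
#'   `"repeated root"`).
#' @examples
#' cubic_discriminant(-6, 11, -6)  # (x-1)(x-2)(x-3): D = 4
#' cubic_discriminant(0, 0, -1)    # x^3 - 1: D = -27
#' @export
cubic_discriminant <- function(a1, a2, a3) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(a3))
  D <- 18 * a1 * a2 * a3 + (a1 * a2)^2 - 4 * a3 * a1^3 - 4 * a2^3 -
    27 * a3^2
  label <- if (D > 0) "three distinct real"
           else if (D < 0) "one real + conjugate pair"
           else "repeated root"
  list(D = D, roots_label = label)
}

#' Coefficient conditions for fractional stability of a polynomial
#'
#' Evaluates the classical printed coefficient branches for the
#' characteristic polynomial `lambda^n + a1 lambda^(n-1) + ... + an`
#' (degree 1 to 3) alongside the ground-truth Matignon verdict obtained
#' from numerically computed roots, and reports whether the two agree.
#' Branches evaluated as printed in the fractional-stability
#' literature:
#'
#' * `n = 1`: `a1 > 0`.
#' * `n = 2`: the Routh-Hurwitz pair `a1 > 0, a2 > 0` (stable for all
#'   orders), or the complex-root branch `a1 < 0`, `4 a2 > a1^2`,
#'   `|atan(sqrt(4 a2 - a1^2) / a1)| > alpha pi / 2`.
#' * `n = 3`: sign branches on the discriminant: `D < 0`,
#'   `a1 < 0, a2 < 0, a3 > 0` is claimed to satisfy the sector
#'   condition for `alpha > 2/3`; `D > 0` with the same sign pattern
#'   for all `alpha` in (0, 1).
#' * any degree: `an > 0` is necessary.
#'
#' The cubic branch as printed contradicts the monotone-in-order
#' geometry of the Matignon sector (satisfaction at some order implies
#' satisfaction at every smaller order), so disagreement with the
#' root-based verdict is expected there; the function reports it
#' rather than asserting the printed claim.  The root-based verdict is
#' authoritative.
#'
#' @param coeffs Numeric vector `c(a1, ..., an)`, `n` in 1..3.
#' @param alpha Fractional order in (0, 1].
#' @return List with `roots`, `verdict` (root-based Matignon verdict),
#'   `necessary_an` (`an > 0`), `branch` (named logical conditions of
#'   the applicable printed branch), `branch_claims_stable` (logical or
#'   `NA` when no printed branch applies) and `agree`.
#' @export
lemma32_conditions <- function(coeffs, alpha) {
  n <- length(coeffs)
  if (n < 1L || n > 3L)
    stop("'coeffs' must have length 1, 2 or 3", call. = FALSE)
  if (!all(is.finite(coeffs))) stop("coefficients must be finite", call. = FALSE)
  roots <- polyroot(c(rev(coeffs), 1))
  verdict <- matignon_check(roots, alpha)
  an <- coeffs[n]
  branch <- NULL
  claim <- NA
  if (n == 1L) {
    branch <- c(a1_positive = coeffs[1] > 0)
    claim <- unname(branch[1])
  } else if (n == 2L) {
    a1 <- coeffs[1]; a2 <- coeffs[2]
    rh <- a1 > 0 && a2 > 0
    disc <- 4 * a2 - a1^2
    arct <- a1 < 0 && disc > 0 &&
      abs(atan(sqrt(disc) / a1)) > alpha * pi / 2
    branch <- c(routh_hurwitz = rh, arctan_branch = arct)
    claim <- rh || arct
  } else {
    a1 <- coeffs[1]; a2 <- coeffs[2]; a3 <- coeffs[3]
    D <- cubic_discriminant(a1, a2, a3)$D
    signs <- a1 < 0 && a2 < 0 && a3 > 0
    b_neg <- D < 0 && signs && alpha > 2 / 3
    b_pos <- D > 0 && signs
    branch <- c(disc_negative_branch = b_neg, disc_positive_branch = b_pos)
    claim <- if (signs && (D < 0 || D > 0)) b_neg || b_pos else NA
  }
  agree <- if (is.na(claim)) NA else identical(claim, verdict == "stable")
  list(roots = roots, verdict = verdict, necessary_an = an > 0,
       branch = branch, branch_claims_stable = claim, agree = agree)
}

# -- closed-form stability condition sets per labelled point ----------------

paper_conditions2 <- function(label, p) {
  eqs <- NULL
  switch(label,
    E1 = list(conditions = c(rho_lt_eps1 = p$rho < p$eps1),
              all_alpha = TRUE, alpha1 = NA_real_),
    E2 = {
      ok1 <- p$eps1 < p$rho
      # predator invasion eigenvalue psi x/(1 + phi x) - (1 + eps2) < 0
      ok2 <- if (ok1) {
        p$psi * (p$rho - p$eps1) <
          (1 + p$eps2) * (p$rho + p$phi * (p$rho - p$eps1))
      } else NA
      list(conditions = c(eps1_lt_rho = ok1, predator_cannot_invade = ok2),
           all_alpha = TRUE, alpha1 = NA_real_)
    },
    E3 = {
      denom <- p$psi - p$phi * (1 + p$eps2)
      if (denom == 0)
        return(list(conditions = c(exists = FALSE), all_alpha = TRUE,
                    alpha1 = NA_real_))
      omega <- (1 + p$eps2) / denom
      gam <- p$rho * (1 - omega) - p$eps1
      # omega < 1 - eps1/rho  <=>  gamma > 0: positive predator density,
      # which also forces trace < 0 and det > 0 (classical stability).
      list(conditions = c(omega_positive = omega > 0,
                          omega_below_prey_only = gam > 0),
           all_alpha = TRUE, alpha1 = NA_real_)
    },
    list(conditions = NULL, all_alpha = NA, alpha1 = NA_real_))
}

complex_pair_alpha1 <- function(trace, det) {
  # critical order of the quadratic block lambda^2 - trace lambda + det
  disc <- trace^2 - 4 * det
  if (disc >= 0) {
    lam <- (trace + c(-1, 1) * sqrt(disc)) / 2
    if (any(lam == 0)) return(NA_real_)
    return(min(1, (2 / pi) * min(abs(Arg(as.complex(lam))))))
  }
  lam <- complex(real = trace / 2, imaginary = sqrt(-disc) / 2)
  min(1, (2 / pi) * abs(Arg(lam)))
}

paper_conditions3 <- function(label, p, coords = NULL) {
  switch(label,
    E1 = list(conditions = c(rho_lt_eps1 = p$rho < p$eps1),
              all_alpha = TRUE, alpha1 = NA_real_),
    E2 = {
      ok1 <- p$eps1 < p$rho
      xs <- 1 - p$eps1 / p$rho
      ok2 <- p$eps2 > p$psi * (p$rho - p$eps1) /
        (p$rho + p$phi * (p$rho - p$eps1))
      ok3 <- p$eps3 > p$beta * p$eta * (p$rho - p$eps1) /
        (p$rho + p$phi1 * (p$rho - p$eps1))
      list(conditions = c(eps1_lt_rho = ok1,
                          first_predator_cannot_invade = ok2,
                          second_predator_cannot_invade = ok3),
           all_alpha = TRUE, alpha1 = NA_real_)
    },
    E3 = {
      d <- p$psi - p$eps2 * p$phi
      if (d == 0)
        return(list(conditions = c(exists = FALSE), all_alpha = FALSE,
                    alpha1 = NA_real_))
      omega <- p$eps2 / d
      gam <- p$rho * (1 - omega) - p$eps1
      # planar block: trace -rho omega, det psi omega gam / (1+phi omega)^2
      tr <- -p$rho * omega
      dt <- p$psi * omega * gam / (1 + p$phi * omega)^2
      a1 <- complex_pair_alpha1(tr, dt)
      c3 <- p$eps3 > p$beta * omega * (p$eta + gam) / (1 + p$phi1 * omega)
      list(conditions = c(eps1_lt_rho_1mo = p$eps1 < p$rho * (1 - omega),
                          eps2_lt_psi_over_phi = p$eps2 < p$psi / p$phi,
                          second_predator_cannot_invade = c3),
           all_alpha = FALSE, alpha1 = a1)
    },
    E4 = {
      d <- p$eta * p$beta - p$phi1 * p$eps3
      if (d == 0)
        return(list(conditions = c(exists = FALSE), all_alpha = FALSE,
                    alpha1 = NA_real_))
      omega <- p$eps3 / d
      gam <- p$rho * (1 - omega) - p$eps1
      tr <- -p$rho * omega
      dt <- p$eta * p$beta * omega * gam / (1 + p$phi1 * omega)^2
      a1 <- complex_pair_alpha1(tr, dt)
      zst <- gam / p$eta
      c2 <- p$eps2 > p$psi * omega * (1 + zst) / (1 + p$phi * omega)
      list(conditions = c(eps1_lt_rho_1mo = p$eps1 < p$rho * (1 - omega),
                          first_predator_cannot_invade = c2,
                          eps3_lt_eta_beta_over_phi1 =
                            p$eps3 < p$eta * p$beta / p$phi1),
           all_alpha = FALSE, alpha1 = a1)
    },
    E5 = {
      if (is.null(coords) || !all(is.finite(coords)))
        return(list(conditions = NULL, all_alpha = NA, alpha1 = NA_real_))
      xs <- coords[[1L]]
      gam <- p$eps3 * (1 + p$phi1 * xs) / (p$beta * xs)
      gam1 <- p$eps2 * (1 + p$phi * xs) / (p$psi * xs)
      o1 <- 1 - (gam * gam1 + p$eps1 - p$eta) / p$rho
      list(conditions = c(
        eps1_bound = p$eps1 < p$rho + p$eta - gam * gam1,
        eps2_bound = p$eps2 > p$psi * o1 / (1 + p$phi * o1),
        eps3_bound = p$eps3 > p$eta * p$beta * o1 / (1 + p$phi1 * o1)),
        all_alpha = TRUE, alpha1 = NA_real_)
    },
    list(conditions = NULL, all_alpha = NA, alpha1 = NA_real_))
}

#' Fractional stability classification of an equilibrium
#'
#' Builds the analytic Jacobian at an equilibrium, computes its
#' eigenvalues, and applies the Matignon sector condition at the
#' requested fractional order together with the critical order
#' ([critical_alpha()]).  The closed-form inequality set associated
#' with the labelled point (extinction threshold `rho < eps1` for E1,
#' invasion conditions for the boundary points, and so on) is evaluated
#' alongside, and an agreement flag records whether the inequality
#' route and the eigenvalue route reach the same verdict.  The
#' eigenvalue computation is authoritative: several printed inequality
#' sets in the source literature contain typographical inconsistencies
#' (see the package vignette), so disagreements are surfaced rather
#' than silently reconciled.
#'
#' @param params A [params2()] or [params3()] bundle.
#' @param alpha Fractional order in (0, 1].
#' @param eq A `fraclv_equilibrium` (from [equilibria2()] /
#'   [equilibria3()]).
#' @return An object of class `spectral_report`: list with `label`,
#'   `eigenvalues`, `min_abs_arg`, `critical_alpha`, `alpha`,
#'   `verdict`, `conditions` (named logicals or `NULL`),
#'   `conditions_claim_stable`, `agree`.
#' @examples
#' p <- params2(1, 15, 2, 0.4, 1)
#' classify_equilibrium(p, 0.9, equilibria2(p)$E3)
#' @export
classify_equilibrium <- function(params, alpha, eq) {
  stopifnot(inherits(eq, "fraclv_equilibrium"))
  if (!all(is.finite(eq$coords)))
    return(structure(list(label = eq$label, eigenvalues = complex(0),
                          min_abs_arg = NA_real_,
                          critical_alpha = NA_real_, alpha = alpha,
                          verdict = "indeterminate", conditions = NULL,
                          conditions_claim_stable = NA, agree = NA),
                     class = "spectral_report"))
  J <- jacobian(params, eq$coords)
  eigs <- eigen(unclass(J), only.values = TRUE)$values
  verdict <- matignon_check(eigs, alpha)
  ca <- if (any(as.complex(eigs) == 0)) NA_real_
        else min(1, (2 / pi) * min(abs(Arg(as.complex(eigs)))))
  pc <- if (inherits(params, "params2"))
    paper_conditions2(eq$label, params)
  else paper_conditions3(eq$label, params, eq$coords)
  claim <- if (is.null(pc$conditions) || anyNA(pc$conditions)) NA
  else {
    all_hold <- all(pc$conditions)
    if (isTRUE(pc$all_alpha)) all_hold
    else all_hold && is.finite(pc$alpha1) && alpha < pc$alpha1
  }
  agree <- if (is.na(claim) || verdict %in% c("marginal", "indeterminate"))
    NA else identical(claim, verdict == "stable")
  structure(list(label = eq$label, eigenvalues = as.complex(eigs),
                 min_abs_arg = min(abs(Arg(as.complex(eigs)))),
                 critical_alpha = ca, alpha = alpha, verdict = verdict,
                 conditions = pc$conditions,
                 conditions_claim_stable = claim, agree = agree),
            class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat(sprintf("%s @ alpha = %g: %s (critical order %s)\n", x$label,
              x$alpha, x$verdict,
              if (is.na(x$critical_alpha)) "indeterminate"
              else signif(x$critical_alpha, 6)))
  if (length(x$eigenvalues))
    cat("  eigenvalues:", paste(format(signif(x$eigenvalues, 6)),
                                collapse = ", "), "\n")
  if (!is.null(x$conditions)) {
    cat("  closed-form conditions:",
        paste(sprintf("%s=%s", names(x$conditions), x$conditions),
              collapse = ", "), "\n")
    cat("  agreement with eigenvalue verdict:", x$agree, "\n")
  }
  invisible(x)
}

#' Oscillation criterion for the two-species co-existence point
#'
#' Necessary condition for the fractional order to matter at the
#' co-existence point: its Jacobian eigenvalues must be a complex
#' conjugate pair, i.e. the discriminant of the characteristic
#' quadratic must be negative, `trace^2 < 4 det`.  Two evaluations are
#' returned.  `holds_printed` uses the inequality exactly as printed in
#' the source analysis,
#' \deqn{\big((\rho+\varepsilon_1\phi)(1+\varepsilon_2)-
#'  \varepsilon_1\psi\big)^2 <
#'  \frac{4\psi\rho(1+\varepsilon_2)}{(\psi-\phi(1+\varepsilon_2))^2}
#'  \big[(1-\varepsilon_1)(\psi-\phi(1+\varepsilon_2)) -
#'  (1+\varepsilon_2)\big],}
#' with `left` and `right` its two sides.  `holds` is the discriminant
#' condition derived directly from the co-existence Jacobian
#' (`trace = -rho omega`,
#' `det = psi omega gamma / (1 + phi omega)^2`), which is the form
#' whose truth coincides with the eigenvalues being complex; the
#' printed flattening differs from it away from `rho = 1`,
#' `eps1 = 0` (see the vignette), so the derived form governs.
#'
#' @param params A [params2()] bundle with
#'   `psi != phi (1 + eps2)` (otherwise the co-existence point, and the
#'   criterion, is undefined).
#' @return List with `holds` (derived discriminant condition,
#'   `trace^2 < 4 det`), `holds_printed`, `left`, `right` (sides of the
#'   printed inequality), `trace`, `det`.
#' @examples
#' check_condition_15(params2(1, 50, 0.02, 0, 0))
#' @export
check_condition_15 <- function(params) {
  stopifnot(inherits(params, "params2"))
  p <- params
  s <- p$psi - p$phi * (1 + p$eps2)
  if (s == 0)
    stop("criterion undefined: psi = phi (1 + eps2)", call. = FALSE)
  left <- ((p$rho + p$eps1 * p$phi) * (1 + p$eps2) - p$eps1 * p$psi)^2
  right <- 4 * p$psi * p$rho * (1 + p$eps2) / s^2 *
    ((1 - p$eps1) * s - (1 + p$eps2))
  omega <- (1 + p$eps2) / s
  gam <- p$rho * (1 - omega) - p$eps1
  # at the co-existence point the equilibrium relation collapses the
  # (1,1) Jacobian entry to -rho*omega, so trace = -rho*omega
  tr <- -p$rho * omega
  dt <- p$psi * omega * gam / (1 + p$phi * omega)^2
  list(holds = tr^2 < 4 * dt, holds_printed = left < right,
       left = left, right = right, trace = tr, det = dt)
}

#' Stability report for all equilibria of a model
#'
#' Runs [classify_equilibrium()] over every stationary point and
#' returns a JSON-ready structure: per point the label, coordinates,
#' feasibility, eigenvalues (re/im), minimum argument, critical order,
#' verdict at the requested order, closed-form condition evaluations
#' and the agreement flag.
#'
#' @param params A [params2()] or [params3()] bundle.
#' @param alpha Fractional order in (0, 1].
#' @return A list of per-equilibrium report lists.
#' @export
stability_report <- function(params, alpha) {
  eqs <- if (inherits(params, "params2")) equilibria2(params)
         else equilibria3(params)
  lapply(eqs, function(e) {
    r <- classify_equilibrium(params, alpha, e)
    list(label = e$label, coords = as.list(e$coords),
         feasible = e$feasible, notes = e$notes,
         eigenvalues = lapply(r$eigenvalues, function(l)
           list(re = Re(l), im = Im(l))),
         min_abs_arg = r$min_abs_arg, critical_alpha = r$critical_alpha,
         alpha = alpha, verdict = r$verdict,
         conditions = as.list(r$conditions),
         conditions_claim_stable = r$conditions_claim_stable,
         agree = r$agree)
  })
}
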