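new_equilibrium <- function(label, coords, feasible, notes = "",
                            residual = NA_real_) {
  structure(list(label = label, coords = coords, feasible = feasible,
                 notes = notes, residual = residual),
            class = "fraclv_equilibrium")
}

#' @export
print.fraclv_equilibrium <- function(x, ...) {
  cat(sprintf("%s: (%s)  feasible: %s", x$label,
              paste(signif(x$coords, 8), collapse = ", "),
              x$feasible))
  if (nzchar(x$notes)) cat("  [", x$notes, "]", sep = "")
  cat("\n")
  invisible(x)
}

finish_eq <- function(eq, params) {
  rhs <- if (inherits(params, "params2")) rhs2 else rhs3
  if (all(is.finite(eq$coords)))
    eq$residual <- max(abs(rhs(eq$coords, params)))
  eq
}

feas_tol <- 1e-12

#' Stationary points of the two-species model
#'
#' Returns the three closed-form equilibria: `E1 = (0, 0)` (total
#' extinction), `E2 = (1 - eps1/rho, 0)` (predator extinction), and the
#' co-existence point `E3 = (omega, rho (1 - omega) - eps1)` with
#' `omega = (1 + eps2) / (psi - phi (1 + eps2))`.  Points with a
#' negative or undefined coordinate are still returned, flagged
#' infeasible, because their eigenvalues remain of interest for the
#' stability discussion.  Increasing prey harvest `eps1` lowers the E2
#' prey density; increasing predator harvest `eps2` raises the E3 prey
#' density.
#'
#' @param params A [params2()] bundle.
#' @return Named list of `fraclv_equilibrium` objects (`E1`, `E2`,
#'   `E3`), each with coordinates, feasibility flag, notes and the
#'   max-norm RHS residual.
#' @examples
#' equilibria2(params2(1, 15, 2, 0.4, 1))
#' @export
equilibria2 <- function(params) {
  stopifnot(inherits(params, "params2"))
  p <- params
  e1 <- new_equilibrium("E1", c(x = 0, y = 0), TRUE,
                        "total extinction", 0)

  x2 <- 1 - p$eps1 / p$rho
  n2 <- if (x2 < 0) "infeasible: eps1 > rho (prey harvested to extinction)"
        else if (x2 == 0) "coincides with E1 (eps1 = rho)"
        else "predator extinction"
  e2 <- finish_eq(new_equilibrium("E2", c(x = x2, y = 0),
                                  x2 >= -feas_tol, n2), p)

  denom <- p$psi - p$phi * (1 + p$eps2)
  if (denom == 0) {
    e3 <- new_equilibrium("E3", c(x = NA_real_, y = NA_real_), FALSE,
                          "nonexistent: psi = phi (1 + eps2), omega undefined")
  } else {
    omega <- (1 + p$eps2) / denom
    ystar <- p$rho * (1 - omega) - p$eps1
    feas <- omega >= -feas_tol && ystar >= -feas_tol
    notes <- if (omega < 0)
      "infeasible: psi < phi (1 + eps2) (omega negative)"
    else if (ystar < 0)
      "infeasible: rho (1 - omega) < eps1 (predator density negative)"
    else "co-existence"
    e3 <- finish_eq(new_equilibrium("E3", c(x = omega, y = ystar),
                                    feas, notes), p)
  }
  list(E1 = e1, E2 = e2, E3 = e3)
}

#' Stationary points of the three-species model
#'
#' Returns the five equilibria: `E1 = (0,0,0)`, prey-only
#' `E2 = (1 - eps1/rho, 0, 0)`, the two partial co-existence points
#' `E3 = (x, rho(1-x) - eps1, 0)` with `x = eps2 / (psi - eps2 phi)`
#' and `E4 = (x, 0, (rho(1-x) - eps1)/eta)` with
#' `x = eps3 / (eta beta - phi1 eps3)`, and the full co-existence point
#' `E5` whose prey density solves the self-consistency relation
#' \deqn{x = 1 - \frac{1}{\rho}\Big[
#'   \frac{\varepsilon_2\varepsilon_3 (1+\phi x)(1+\phi_1 x)}
#'        {\beta\psi x^2} + \varepsilon_1 - \eta\Big],}
#' with `y = eps3 (1 + phi1 x)/(beta x) - eta` and
#' `z = eps2 (1 + phi x)/(psi x) - 1`.  The relation is solved by
#' scanning `(1e-6, 1]` for sign changes and bisecting each bracket;
#' every root found is reported as its own `E5` entry (suffixed when
#' there are several) and residual-checked against [rhs3()].  If no
#' root exists in the bracket, `E5` is reported absent with the scanned
#' range in its notes.
#'
#' @param params A [params3()] bundle.
#' @return Named list of `fraclv_equilibrium` objects.
#' @export
equilibria3 <- function(params) {
  stopifnot(inherits(params, "params3"))
  p <- params
  out <- list()
  out$E1 <- new_equilibrium("E1", c(x = 0, y = 0, z = 0), TRUE,
                            "total extinction", 0)

  x2 <- 1 - p$eps1 / p$rho
  out$E2 <- finish_eq(new_equilibrium(
    "E2", c(x = x2, y = 0, z = 0), x2 >= -feas_tol,
    if (x2 < 0) "infeasible: eps1 > rho" else "prey only"), p)

  d3 <- p$psi - p$eps2 * p$phi
  if (d3 == 0) {
    out$E3 <- new_equilibrium("E3", c(x = NA_real_, y = NA_real_, z = 0),
                              FALSE, "nonexistent: psi = eps2 phi")
  } else {
    x3 <- p$eps2 / d3
    y3 <- p$rho * (1 - x3) - p$eps1
    feas <- x3 >= -feas_tol && y3 >= -feas_tol
    notes <- if (x3 < 0) "infeasible: x < 0 (psi < eps2 phi)"
             else if (y3 < 0) "infeasible: y < 0 (rho (1 - x) < eps1)"
             else "prey + first predator"
    out$E3 <- finish_eq(new_equilibrium("E3", c(x = x3, y = y3, z = 0),
                                        feas, notes), p)
  }

  d4 <- p$eta * p$beta - p$phi1 * p$eps3
  if (d4 == 0) {
    out$E4 <- new_equilibrium("E4", c(x = NA_real_, y = 0, z = NA_real_),
                              FALSE, "nonexistent: eta beta = phi1 eps3")
  } else {
    x4 <- p$eps3 / d4
    z4 <- (p$rho * (1 - x4) - p$eps1) / p$eta
    feas <- x4 >= -feas_tol && z4 >= -feas_tol
    notes <- if (x4 < 0) "infeasible: x < 0 (eta beta < phi1 eps3)"
             else if (z4 < 0) "infeasible: z < 0 (rho (1 - x) < eps1)"
             else "prey + second predator"
    out$E4 <- finish_eq(new_equilibrium("E4", c(x = x4, y = 0, z = z4),
                                        feas, notes), p)
  }

  roots <- e5_roots(p)
  if (length(roots) == 0L) {
    out$E5 <- new_equilibrium(
      "E5", c(x = NA_real_, y = NA_real_, z = NA_real_), FALSE,
      "absent: no root of the self-consistency relation in (1e-06, 1]")
  } else {
    for (i in seq_along(roots)) {
      xs <- roots[[i]]
      ys <- p$eps3 * (1 + p$phi1 * xs) / (p$beta * xs) - p$eta
      zs <- p$eps2 * (1 + p$phi * xs) / (p$psi * xs) - 1
      feas <- ys >= -feas_tol && zs >= -feas_tol
      notes <- if (!feas) "infeasible: negative predator density"
               else "full co-existence"
      if (length(roots) > 1L)
        notes <- paste0(notes, sprintf(" (root %d of %d)", i, length(roots)))
      nm <- if (i == 1L) "E5" else paste0("E5.", i)
      out[[nm]] <- finish_eq(new_equilibrium(
        "E5", c(x = xs, y = ys, z = zs), feas, notes), p)
    }
  }
  out
}

# sign-change scan + bisection for the E5 prey density on (1e-6, 1]
e5_roots <- function(p) {
  g <- function(x)
    x - 1 + (p$eps2 * p$eps3 * (1 + p$phi * x) * (1 + p$phi1 * x) /
               (p$beta * p$psi * x^2) + p$eps1 - p$eta) / p$rho
  grid <- unique(c(seq(1e-6, 0.01, by = 1e-4), seq(0.01, 1, length.out = 2000)))
  gv <- vapply(grid, g, numeric(1))
  roots <- list()
  for (i in seq_len(length(grid) - 1L)) {
    if (!is.finite(gv[i]) || !is.finite(gv[i + 1L])) next
    if (gv[i] == 0) { roots[[length(roots) + 1L]] <- grid[i]; next }
    if (gv[i] * gv[i + 1L] < 0) {
      r <- uniroot(g, lower = grid[i], upper = grid[i + 1L], tol = 1e-14)
      roots[[length(roots) + 1L]] <- r$root
    }
  }
  if (length(grid) && gv[length(grid)] == 0)
    roots[[length(roots) + 1L]] <- grid[length(grid)]
  roots
}

#' Analytic Jacobian of the model vector fields
#'
#' Partial derivatives of [rhs2()] / [rhs3()] at an arbitrary state,
#' derived symbolically from the right-hand sides (single source of
#' truth).  At the two-species co-existence point the (2,2) entry
#' vanishes identically: `(psi - phi) x - 1)/(1 + phi x) - eps2 = 0`
#' exactly at `x = omega`.
#'
#' @param params A [params2()] or [params3()] bundle.
#' @param point State vector (finite), e.g. the `coords` of an
#'   equilibrium.
#' @return A d x d numeric matrix with attributes `trace` and `det`.
#' @examples
#' p <- params2(1, 15, 2, 0.4, 1)
#' jacobian(p, equilibria2(p)$E3$coords)
#' @export
jacobian <- function(params, point) {
  if (!is.numeric(point) || !all(is.finite(point)))
    stop("'point' must be a finite numeric vector", call. = FALSE)
  UseMethod("jacobian")
}

#' @export
jacobian.params2 <- function(params, point) {
  p <- params
  if (length(point) != 2L) stop("'point' must have length 2", call. = FALSE)
  x <- point[[1L]]; y <- point[[2L]]
  q <- 1 + p$phi * x
  J <- matrix(c(p$rho * (1 - 2 * x) - y - p$eps1, -x,
                p$psi * y / q^2, p$psi * x / q - 1 - p$eps2),
              nrow = 2, byrow = TRUE)
  structure(J, trace = sum(diag(J)), det = J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
}

#' @export
jacobian.params3 <- function(params, point) {
  p <- params
  if (length(point) != 3L) stop("'point' must have length 3", call. = FALSE)
  x <- point[[1L]]; y <- point[[2L]]; z <- point[[3L]]
  q <- 1 + p$phi * x
  q1 <- 1 + p$phi1 * x
  J <- matrix(c(
    p$rho * (1 - 2 * x) - (y * (1 + z) + p$eta * z + p$eps1),
    -x * (1 + z),
    -x * (p$eta + y),
    p$psi * y * (1 + z) / q^2,
    p$psi * x * (1 + z) / q - p$eps2,
    p$psi * x * y / q,
    p$beta * z * (p$eta + y) / q1^2,
    p$beta * x * z / q1,
    p$beta * x * (p$eta + y) / q1 - p$eps3), nrow = 3, byrow = TRUE)
  structure(J, trace = sum(diag(J)), det = det(J))
}

#' Equilibrium report
#'
#' Assembles a structured, JSON-ready report of every stationary point
#' of a model: label, coordinates, feasibility, RHS residual norm and
#' notes.
#'
#' @param params A [params2()] or [params3()] bundle.
#' @return A list of per-equilibrium lists.
#' @seealso [equilibria2()], [equilibria3()], [stability_report()]
#' @export
equilibrium_report <- function(params) {
  eqs <- if (inherits(params, "params2")) equilibria2(params)
         else equilibria3(params)
  lapply(eqs, function(e)
    list(label = e$label, coords = as.list(e$coords),
         feasible = e$feasible, residual = e$residual, notes = e$notes))
}
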