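#' Right-hand side of the two-species model
#'
#' Evaluates the dimensionless vector field
#' \deqn{\big(\rho x(1-x) - xy - \varepsilon_1 x,\;
#'       \psi x y/(1+\phi x) - y - \varepsilon_2 y\big).}
#' The field is defined for all nonnegative states, including prey
#' densities beyond carrying capacity (`x > 1`); no clamping is
#' applied.
#'
#' @param state Numeric vector `c(x, y)` of nonnegative densities.
#' @param params A [params2()] bundle.
#' @return Numeric vector of length 2.
#' @examples
#' p <- params2(1, 15, 2, 0.4, 1)
#' rhs2(c(0, 0), p)        # origin is a fixed point
#' rhs2(c(0.2, 0.25), p)
#' @export
rhs2 <- function(state, params) {
  stopifnot(inherits(params, "params2"))
  if (length(state) != 2L || !is.numeric(state) || !all(is.finite(state)))
    stop("'state' must be a finite numeric vector of length 2", call. = FALSE)
  x <- state[[1L]]; y <- state[[2L]]
  c(params$rho * x * (1 - x) - x * y - params$eps1 * x,
    params$psi * x * y / (1 + params$phi * x) - y - params$eps2 * y)
}

#' Right-hand side of the three-species model
#'
#' Evaluates the dimensionless vector field of the mutualistic
#' predation system
#' \deqn{\big(\rho x(1-x) - x(y + \eta z + yz) - \varepsilon_1 x,\;
#'       \psi x y(1+z)/(1+\phi x) - \varepsilon_2 y,\;
#'       \beta x z(\eta+y)/(1+\phi_1 x) - \varepsilon_3 z\big).}
#' The `yz` and `(1+z)`, `(eta+y)` couplings encode the mutual boost
#' each predator gives the other's intake.
#'
#' @param state Numeric vector `c(x, y, z)` of nonnegative densities.
#' @param params A [params3()] bundle.
#' @return Numeric vector of length 3.
#' @export
rhs3 <- function(state, params) {
  stopifnot(inherits(params, "params3"))
  if (length(state) != 3L || !is.numeric(state) || !all(is.finite(state)))
    stop("'state' must be a finite numeric vector of length 3", call. = FALSE)
  x <- state[[1L]]; y <- state[[2L]]; z <- state[[3L]]
  c(params$rho * x * (1 - x) - x * (y + params$eta * z + y * z) -
      params$eps1 * x,
    params$psi * x * y * (1 + z) / (1 + params$phi * x) - params$eps2 * y,
    params$beta * x * z * (params$eta + y) / (1 + params$phi1 * x) -
      params$eps3 * z)
}

#' Build an autonomous RHS closure for a parameter bundle
#'
#' Convenience wrapper returning `function(state)` suitable for
#' [solve_fde()] and [reference_solve()].
#'
#' @param params A [params2()] or [params3()] bundle.
#' @return A function of a single state vector.
#' @export
make_rhs <- function(params) {
  if (inherits(params, "params2")) function(state) rhs2(state, params)
  else if (inherits(params, "params3")) function(state) rhs3(state, params)
  else stop("expected a 'params2' or 'params3' object", call. = FALSE)
}

#' Map dimensional parameters to the dimensionless bundles
#'
#' Applies the rescalings that reduce the dimensional models to their
#' dimensionless form.  Two species: `X = K x`, `Y = (k/a) y`,
#' `T = t/k`.  Three species: `X = K x`, `Y = (k1/a) y`,
#' `Z = (a/xi) z`, `T = t/k1`.  The returned scale factors map a
#' dimensionless trajectory back to dimensional units:
#' dimensional state = `state_scale * state`, dimensional time =
#' `time_scale * t`.
#'
#' @param dim_params A [dim_params2()] or [dim_params3()] bundle.
#' @return A list with elements `params` (a [params2()]/[params3()]
#'   bundle), `state_scale` (named numeric vector) and `time_scale`
#'   (scalar, equal to one over the reference death rate).
#' @examples
#' nondimensionalize(dim_params2(r = 0.5, K = 100, a = 0.03,
#'                               sigma = 0.02, k = 0.1,
#'                               h1 = 0.04, h2 = 0.1))
#' @export
nondimensionalize <- function(dim_params) {
  UseMethod("nondimensionalize")
}

#' @export
nondimensionalize.dim_params2 <- function(dim_params) {
  d <- dim_params
  if (d$k == 0)
    stop("division by zero: predator death rate 'k' is zero", call. = FALSE)
  list(params = params2(rho = d$r / d$k, psi = d$a * d$K / d$k,
                        phi = d$K * d$sigma,
                        eps1 = d$h1 / d$k, eps2 = d$h2 / d$k),
       state_scale = c(x = d$K, y = d$k / d$a),
       time_scale = 1 / d$k)
}

#' @export
nondimensionalize.dim_params3 <- function(dim_params) {
  d <- dim_params
  if (d$k1 == 0)
    stop("division by zero: predator death rate 'k1' is zero", call. = FALSE)
  if (d$xi == 0)
    stop("division by zero: mutualism rate 'xi' is zero", call. = FALSE)
  list(params = params3(rho = d$r / d$k1, psi = d$a * d$K / d$k1,
                        beta = d$b * d$K / d$k1,
                        eta = d$a * d$b / (d$xi * d$k1),
                        phi = d$sigma1 * d$K, phi1 = d$sigma2 * d$K,
                        eps1 = d$h1 / d$k1, eps2 = 1 + d$h2 / d$k1,
                        eps3 = (d$k2 + d$h3) / d$k1),
       state_scale = c(x = d$K, y = d$k1 / d$a, z = d$a / d$xi),
       time_scale = 1 / d$k1)
}

#' @export
nondimensionalize.default <- function(dim_params) {
  stop("expected a 'dim_params2' or 'dim_params3' object", call. = FALSE)
}

#' Lipschitz bounds for the model vector fields
#'
#' Closed-form local Lipschitz constants on the box `[0, M]^d`, used to
#' establish existence and uniqueness of solutions.  Two species:
#' `L1 = rho + eps1 + (rho + 1) M`,
#' `L2 = 1 + eps2 + psi (1 + phi M) M`.  Three species:
#' `L1 = rho + eps1 + (rho + eta) M + M^2`,
#' `L2 = 1 + eps2 + psi (1 + (1 + phi) M + phi M^2) M`,
#' `L3 = eps3 + beta (1 + eta + eta phi1 M + phi1 M^2) M`.
#' The overall constant is `L = max(L_i)`, for the 1-norm inequality
#' `||F(X) - F(Xbar)||_1 <= L ||X - Xbar||_1`.
#'
#' @param params A [params2()] or [params3()] bundle.
#' @param M Positive bound on the state box.
#' @return An object of class `lipschitz_bounds`: list with `M`, the
#'   per-component constants `L1`, `L2` (and `L3` for three species)
#'   and `L = max(Li)`.
#' @examples
#' lipschitz_bounds(params2(1, 15, 2, 0.4, 1), M = 2)
#' @export
lipschitz_bounds <- function(params, M) {
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0)
    stop("'M' must be a positive finite scalar", call. = FALSE)
  UseMethod("lipschitz_bounds")
}

#' @export
lipschitz_bounds.params2 <- function(params, M) {
  p <- params
  L1 <- p$rho + p$eps1 + (p$rho + 1) * M
  L2 <- 1 + p$eps2 + p$psi * (1 + p$phi * M) * M
  structure(list(M = M, L1 = L1, L2 = L2, L = max(L1, L2)),
            class = "lipschitz_bounds")
}

#' @export
lipschitz_bounds.params3 <- function(params, M) {
  p <- params
  L1 <- p$rho + p$eps1 + (p$rho + p$eta) * M + M^2
  L2 <- 1 + p$eps2 + p$psi * (1 + (1 + p$phi) * M + p$phi * M^2) * M
  L3 <- p$eps3 + p$beta * (1 + p$eta + p$eta * p$phi1 * M + p$phi1 * M^2) * M
  structure(list(M = M, L1 = L1, L2 = L2, L3 = L3, L = max(L1, L2, L3)),
            class = "lipschitz_bounds")
}

#' @export
print.lipschitz_bounds <- function(x, ...) {
  cat("Lipschitz bounds on [0, M]^d, M =", x$M, "\n")
  print(unlist(x[setdiff(names(x), "M")]))
  invisible(x)
}
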