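#' Dimensionless parameters of the two-species model
#'
#' Bundles the five dimensionless parameters of the harvested
#' predator-prey system
#' \deqn{D^\alpha x = \rho x(1-x) - xy - \varepsilon_1 x, \qquad
#'       D^\alpha y = \frac{\psi x y}{1+\phi x} - y - \varepsilon_2 y,}
#' where `x` is prey density (scaled by carrying capacity) and `y`
#' predator density.  In terms of the dimensional rates (see
#' [dim_params2()]): `rho = r/k` (prey growth over predator death),
#' `psi = a*K/k` (scaled feeding rate), `phi = K*sigma` (saturation of
#' the Holling type II response), and `eps1 = h1/k`, `eps2 = h2/k`
#' (scaled constant-effort harvest rates for prey and predator).
#'
#' @param rho,psi,phi Strictly positive reals.
#' @param eps1,eps2 Nonnegative harvest efforts.
#' @return An object of class `params2`.
#' @seealso [params3()], [nondimensionalize()], [rhs2()]
#' @examples
#' p <- params2(rho = 1, psi = 15, phi = 2, eps1 = 0.4, eps2 = 1)
#' rhs2(c(0.2, 0.25), p)
#' @export
params2 <- function(rho, psi, phi, eps1 = 0, eps2 = 0) {
  p <- list(rho = rho, psi = psi, phi = phi, eps1 = eps1, eps2 = eps2)
  check_scalars(p)
  if (rho <= 0 || psi <= 0 || phi <= 0)
    stop("'rho', 'psi' and 'phi' must be strictly positive", call. = FALSE)
  if (eps1 < 0 || eps2 < 0)
    stop("harvest efforts 'eps1', 'eps2' must be nonnegative", call. = FALSE)
  structure(p, class = "params2")
}

#' Dimensionless parameters of the three-species model
#'
#' Bundles the nine dimensionless parameters of the three-species
#' system (one prey, two mutualistic predators):
#' \deqn{D^\alpha x = \rho x(1-x) - x(y + \eta z + yz) - \varepsilon_1 x,}
#' \deqn{D^\alpha y = \frac{\psi x y (1+z)}{1+\phi x} - \varepsilon_2 y,}
#' \deqn{D^\alpha z = \frac{\beta x z (\eta+y)}{1+\phi_1 x} - \varepsilon_3 z.}
#' In terms of dimensional rates (see [dim_params3()]):
#' `rho = r/k1`, `psi = a*K/k1`, `beta = b*K/k1`, `eta = a*b/(xi*k1)`,
#' `phi = sigma1*K`, `phi1 = sigma2*K`, `eps1 = h1/k1`,
#' `eps2 = 1 + h2/k1` (the first predator's natural death is folded into
#' its loss term, so transform-derived bundles have `eps2 >= 1`) and
#' `eps3 = (k2 + h3)/k1`.  The constructor itself only requires
#' `eps2 > 0` so that parameter sets quoted directly on the
#' dimensionless scale can be represented.
#'
#' @param rho,psi,beta,eta,phi,phi1 Strictly positive reals.
#' @param eps1 Nonnegative prey harvest effort.
#' @param eps2,eps3 Strictly positive predator loss rates.
#' @return An object of class `params3`.
#' @seealso [params2()], [rhs3()], [equilibria3()]
#' @export
params3 <- function(rho, psi, beta, eta, phi, phi1, eps1 = 0, eps2 = 1,
                    eps3) {
  p <- list(rho = rho, psi = psi, beta = beta, eta = eta, phi = phi,
            phi1 = phi1, eps1 = eps1, eps2 = eps2, eps3 = eps3)
  check_scalars(p)
  if (rho <= 0 || psi <= 0 || beta <= 0 || eta <= 0 || phi <= 0 || phi1 <= 0)
    stop("'rho', 'psi', 'beta', 'eta', 'phi', 'phi1' must be strictly positive",
         call. = FALSE)
  if (eps1 < 0) stop("'eps1' must be nonnegative", call. = FALSE)
  if (eps2 <= 0 || eps3 <= 0)
    stop("'eps2' and 'eps3' must be strictly positive", call. = FALSE)
  structure(p, class = "params3")
}

#' Dimensional parameters of the two-species model
#'
#' The harvested predator-prey model on the dimensional scale,
#' \deqn{D^\alpha X = rX(1-X/K) - aXY - h_1 X, \qquad
#'       D^\alpha Y = \frac{aXY}{1+\sigma X} - kY - h_2 Y.}
#'
#' @param r Prey intrinsic growth rate (1/time).
#' @param K Prey carrying capacity (density).
#' @param a Predator feeding rate (1/(density time)).
#' @param sigma Predator growth saturation factor (1/density).
#' @param k Predator death rate (1/time).
#' @param h1,h2 Constant harvest efforts (1/time), nonnegative.
#' @return An object of class `dim_params2`.
#' @seealso [nondimensionalize()]
#' @export
dim_params2 <- function(r, K, a, sigma, k, h1 = 0, h2 = 0) {
  p <- list(r = r, K = K, a = a, sigma = sigma, k = k, h1 = h1, h2 = h2)
  check_scalars(p)
  pos <- c("r", "K", "a", "sigma", "k")
  bad <- pos[vapply(p[pos], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("dimensional parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (h1 < 0 || h2 < 0)
    stop("harvest efforts must be nonnegative", call. = FALSE)
  structure(p, class = "dim_params2")
}

#' Dimensional parameters of the three-species model
#'
#' @param r,K As in [dim_params2()].
#' @param a,b,xi Feeding/mutualism rates of the two predators
#'   (`xi` couples the joint hunting term), strictly positive.
#' @param sigma1,sigma2 Saturation factors of the two predators.
#' @param k1,k2 Predator death rates (1/time).
#' @param h1,h2,h3 Constant harvest efforts (1/time), nonnegative.
#' @return An object of class `dim_params3`.
#' @seealso [nondimensionalize()]
#' @export
dim_params3 <- function(r, K, a, b, xi, sigma1, sigma2, k1, k2,
                        h1 = 0, h2 = 0, h3 = 0) {
  p <- list(r = r, K = K, a = a, b = b, xi = xi, sigma1 = sigma1,
            sigma2 = sigma2, k1 = k1, k2 = k2, h1 = h1, h2 = h2, h3 = h3)
  check_scalars(p)
  pos <- c("r", "K", "a", "b", "xi", "sigma1", "sigma2", "k1", "k2")
  bad <- pos[vapply(p[pos], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("dimensional parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (h1 < 0 || h2 < 0 || h3 < 0)
    stop("harvest efforts must be nonnegative", call. = FALSE)
  structure(p, class = "dim_params3")
}

check_scalars <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  invisible(p)
}

model_dim <- function(params) {
  if (inherits(params, "params2")) 2L
  else if (inherits(params, "params3")) 3L
  else stop("expected a 'params2' or 'params3' object", call. = FALSE)
}

#' @export
print.params2 <- function(x, ...) {
  cat("Two-species dimensionless parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.params3 <- function(x, ...) {
  cat("Three-species dimensionless parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.dim_params2 <- function(x, ...) {
  cat("Two-species dimensional parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.dim_params3 <- function(x, ...) {
  cat("Three-species dimensional parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}
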