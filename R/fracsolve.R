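#' Caputo memory weight function
#'
#' The power-law kernel `w(t) = t^(-alpha) / Gamma(1 - alpha)` that the
#' Caputo derivative convolves with the integer-order derivative; it
#' stores the system's memory of past states.  Larger `alpha` puts more
#' weight near the current time, smaller `alpha` retains more of the
#' past.
#'
#' @param t Positive time (vectorized).
#' @param alpha Fractional order in the open interval (0, 1); the
#'   kernel has a Gamma-function pole at `alpha = 1`.
#' @return `t^(-alpha) / Gamma(1 - alpha)`.
#' @examples
#' caputo_weight(1, 0.5)  # 1/sqrt(pi)
#' @export
caputo_weight <- function(t, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1); the weight has a pole at alpha = 1",
         call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be strictly positive", call. = FALSE)
  t^(-alpha) / gamma(1 - alpha)
}

#' Two-parameter Mittag-Leffler function
#'
#' Evaluates \eqn{E_{\alpha,\beta}(x) = \sum_{k \ge 0} x^k /
#' \Gamma(k\alpha + \beta)} by its power series with a term-magnitude
#' stopping rule.  Special cases: `E_{1,1}(x) = exp(x)`,
#' `E_{2,1}(x) = cosh(sqrt(x))`; `E_alpha(-t^alpha)` solves the linear
#' Caputo equation `D^alpha x = -x`.
#'
#' Evaluation is restricted to `|x| <= 50`.  For alternating series
#' (negative `x`) the accumulated cancellation is estimated from the
#' sum of absolute terms; if the result cannot be guaranteed to about
#' `1e-12` accuracy an explicit error is raised rather than returning a
#' silently wrong value.
#'
#' @param alpha Positive series order.
#' @param beta Nonnegative second parameter (default 1).
#' @param x Numeric argument (vectorized), `|x| <= 50`.
#' @return Numeric vector of function values.
#' @examples
#' mittag_leffler(1, 1, 1)   # exp(1)
#' mittag_leffler(2, 1, 1)   # cosh(1)
#' @export
mittag_leffler <- function(alpha, beta = 1, x) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("'alpha' must be a positive scalar", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("'beta' must be a nonnegative scalar", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  vapply(x, ml_scalar, numeric(1), alpha = alpha, beta = beta)
}

ml_scalar <- function(x, alpha, beta) {
  if (abs(x) > 50)
    stop("mittag_leffler: |x| = ", format(abs(x)),
         " is outside the reliable evaluation domain |x| <= 50",
         call. = FALSE)
  if (x == 0) return(1 / gamma(beta))
  kmax <- 700L
  k <- 0:kmax
  logterm <- k * log(abs(x)) - lgamma(alpha * k + beta)
  # guard against terms that overflow double precision
  if (max(logterm) > 700)
    stop("mittag_leffler: series terms overflow for alpha = ", alpha,
         ", x = ", format(x), "; not converged", call. = FALSE)
  mag <- exp(logterm)
  # truncation control: magnitudes must have decayed to negligible size
  if (mag[kmax + 1L] > 1e-18)
    stop("mittag_leffler: series not converged within ", kmax,
         " terms for alpha = ", alpha, ", x = ", format(x), call. = FALSE)
  terms <- if (x > 0) mag else mag * (1 - 2 * (k %% 2L))
  s <- sum(terms)
  # cancellation estimate for alternating series
  cancel <- .Machine$double.eps * sum(mag)
  if (cancel > 1e-10 * max(1, abs(s)))
    stop("mittag_leffler: catastrophic cancellation for x = ", format(x),
         "; result not reliable to the requested accuracy", call. = FALSE)
  s
}

#' Solver settings for the fractional and reference integrators
#'
#' @param h Step size on the uniform grid (dimensionless time), default
#'   0.01.
#' @param t_end Time horizon, default 200 dimensionless units.
#' @param corrector_iters Number of corrector sweeps per step (default
#'   1).
#' @param reference_tol Relative/absolute tolerance for the adaptive
#'   classical reference integrator (default 1e-10).
#' @param startup_window,startup_substeps Startup refinement of the
#'   fractional scheme: Caputo solutions behave like `t^alpha` at the
#'   origin, and the one-step scheme otherwise commits an
#'   `O(h^(2 alpha))` error there.  The coarse steps inside
#'   `[0, startup_window]` (default 0.1 time units, the region where
#'   the singular term dominates) are therefore computed by the same
#'   scheme on a grid refined by `startup_substeps` (default 10), and
#'   the uniform-grid recursion then continues with that warm-started
#'   history.  Being a fixed time window, the refined region shrinks
#'   in step count as `h` does, preserving the scheme's convergence
#'   order.  Set `startup_substeps = 1` to disable.  Ignored at
#'   `alpha = 1`, where solutions are smooth at the origin.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(h = 0.01, t_end = 200, corrector_iters = 1L,
                            reference_tol = 1e-10, startup_window = 0.1,
                            startup_substeps = 10L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a positive scalar", call. = FALSE)
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) ||
      t_end < h)
    stop("'t_end' must be finite and at least one step 'h'", call. = FALSE)
  if (corrector_iters < 1)
    stop("'corrector_iters' must be a positive integer", call. = FALSE)
  if (reference_tol <= 0)
    stop("'reference_tol' must be positive", call. = FALSE)
  if (startup_window < 0 || startup_substeps < 1)
    stop("'startup_window' must be >= 0 and 'startup_substeps' >= 1",
         call. = FALSE)
  structure(list(h = h, t_end = t_end,
                 corrector_iters = as.integer(corrector_iters),
                 reference_tol = reference_tol,
                 startup_window = startup_window,
                 startup_substeps = as.integer(startup_substeps)),
            class = "solver_settings")
}

new_trajectory <- function(times, states, alpha, settings, params = NULL) {
  structure(list(times = times, states = states, alpha = alpha,
                 settings = settings, params = params),
            class = "fraclv_trajectory")
}

state_colnames <- function(x0) {
  d <- length(x0)
  if (!is.null(names(x0)) && all(nzchar(names(x0)))) return(names(x0))
  if (d <= 3L) c("x", "y", "z")[seq_len(d)] else paste0("x", seq_len(d))
}

#' Solve a Caputo fractional initial-value problem
#'
#' Integrates `D^alpha x = rhs(x)`, `x(0) = x0`, with the
#' Adams-Bashforth-Moulton predictor-corrector scheme (fractional
#' rectangle-rule predictor, fractional trapezoidal corrector) on the
#' uniform grid `t_n = n h`.  The full history is retained -- no
#' short-memory truncation -- since the retained memory is exactly what
#' drives the damping this package studies.  At `alpha = 1` the weights
#' reduce to the classical one-step Euler/trapezoid pair, so the same
#' code path covers the integer-order case.
#'
#' @param rhs Function of a single state vector returning the
#'   derivative vector (see [make_rhs()]).
#' @param x0 Initial state (finite numeric vector).
#' @param alpha Fractional order in (0, 1].
#' @param settings A [solver_settings()] object.
#' @param params Optional parameter bundle stored with the trajectory
#'   for bookkeeping.
#' @return An object of class `fraclv_trajectory`: list with `times`
#'   (grid), `states` (matrix, one row per grid point), `alpha`,
#'   `settings`, `params`.
#' @examples
#' tr <- solve_fde(function(s) -s, x0 = 1, alpha = 0.8,
#'                 settings = solver_settings(h = 0.05, t_end = 2))
#' tail(tr$states)
#' @export
solve_fde <- function(rhs, x0, alpha, settings = solver_settings(),
                      params = NULL) {
  stopifnot(is.function(rhs), inherits(settings, "solver_settings"))
  if (!is.numeric(x0) || !all(is.finite(x0)))
    stop("'x0' must be a finite numeric vector", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  n_steps <- as.integer(round(settings$t_end / settings$h))
  f <- function(s) as.numeric(rhs(s))
  x0n <- as.numeric(x0)
  no_warm <- matrix(numeric(0), 0L, 0L)
  s <- min(ceiling(settings$startup_window / settings$h), n_steps - 1L)
  if (alpha < 1 && settings$startup_substeps > 1L && s > 0L) {
    m <- settings$startup_substeps
    fine <- abm_core(f, x0n, alpha, settings$h / m, s * m,
                     settings$corrector_iters, no_warm, no_warm)
    warm_x <- fine[1L + m * (0:s), , drop = FALSE]
    warm_f <- t(apply(warm_x, 1L, f))
    if (length(x0n) == 1L) warm_f <- matrix(as.numeric(warm_f), ncol = 1L)
    states <- abm_core(f, x0n, alpha, settings$h, n_steps,
                       settings$corrector_iters, warm_x, warm_f)
  } else {
    states <- abm_core(f, x0n, alpha, settings$h, n_steps,
                       settings$corrector_iters, no_warm, no_warm)
  }
  colnames(states) <- state_colnames(x0)
  new_trajectory(times = settings$h * (0:n_steps), states = states,
                 alpha = alpha, settings = settings, params = params)
}

#' Classical adaptive reference solution at integer order
#'
#' Solves `dx/dt = rhs(x)` with an adaptive high-accuracy classical
#' integrator (`deSolve::ode`, lsoda) and samples the solution on the
#' same uniform grid that [solve_fde()] uses, providing the
#' integer-order oracle against which the fractional scheme at
#' `alpha = 1` is validated.
#'
#' @inheritParams solve_fde
#' @return A `fraclv_trajectory` with `alpha = 1`.
#' @export
reference_solve <- function(rhs, x0, settings = solver_settings(),
                            params = NULL) {
  stopifnot(is.function(rhs), inherits(settings, "solver_settings"))
  if (!is.numeric(x0) || !all(is.finite(x0)))
    stop("'x0' must be a finite numeric vector", call. = FALSE)
  n_steps <- as.integer(round(settings$t_end / settings$h))
  times <- settings$h * (0:n_steps)
  sol <- try(deSolve::ode(y = as.numeric(x0), times = times,
                          func = function(t, y, p) list(as.numeric(rhs(y))),
                          parms = NULL, method = "lsoda",
                          rtol = settings$reference_tol,
                          atol = settings$reference_tol), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("reference integrator failed: ", attr(sol, "condition")$message,
         call. = FALSE)
  states <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  if (nrow(states) != length(times))
    stop("reference integrator returned an incomplete solution grid",
         call. = FALSE)
  colnames(states) <- state_colnames(x0)
  new_trajectory(times = times, states = states, alpha = 1,
                 settings = settings, params = params)
}

#' @export
print.fraclv_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d points, t in [0, %g], alpha = %g, dim = %d\n",
              length(x$times), max(x$times), x$alpha, ncol(x$states)))
  cat("terminal state:", signif(x$states[nrow(x$states), ], 6), "\n")
  invisible(x)
}

#' Write / read a trajectory as CSV
#'
#' The CSV has header `t,x,y[,z]` and one row per grid point, written
#' at full double precision (`%.17g`) so that reading the file back
#' reproduces the in-memory values exactly.  A structured-text metadata
#' sidecar (`<path>.meta.yaml`) records `alpha`, the solver settings
#' and, when present, the parameter bundle.
#'
#' @param traj A `fraclv_trajectory`.
#' @param path Output CSV path.
#' @param meta Write the metadata sidecar? Default `TRUE`.
#' @return `write_trajectory()`: the path, invisibly.
#'   `read_trajectory()`: a `fraclv_trajectory` (with metadata when the
#'   sidecar exists).
#' @export
write_trajectory <- function(traj, path, meta = TRUE) {
  stopifnot(inherits(traj, "fraclv_trajectory"))
  m <- cbind(t = traj$times, traj$states)
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(colnames(m), collapse = ","), txt), path)
  if (meta) {
    info <- list(alpha = traj$alpha,
                 h = traj$settings$h, t_end = traj$settings$t_end,
                 corrector_iters = traj$settings$corrector_iters)
    if (!is.null(traj$params)) {
      info$model <- if (inherits(traj$params, "params2")) "2sp" else "3sp"
      info$params <- unclass(traj$params)
    }
    yaml::write_yaml(info, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "t")
    stop("not a trajectory CSV: first column must be 't'", call. = FALSE)
  states <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(states) <- list(NULL, names(df)[-1L])
  metapath <- paste0(path, ".meta.yaml")
  alpha <- NA_real_; settings <- NULL; params <- NULL
  if (file.exists(metapath)) {
    info <- yaml::read_yaml(metapath)
    alpha <- info$alpha
    settings <- solver_settings(h = info$h, t_end = info$t_end,
                                corrector_iters = info$corrector_iters)
    if (!is.null(info$params)) {
      params <- if (identical(info$model, "2sp"))
        do.call(params2, info$params) else do.call(params3, info$params)
    }
  }
  new_trajectory(times = df$t, states = states, alpha = alpha,
                 settings = settings, params = params)
}
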