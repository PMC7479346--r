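params_keys2 <- c("rho", "psi", "phi", "eps1", "eps2")
params_keys3 <- c("rho", "psi", "beta", "eta", "phi", "phi1",
                  "eps1", "eps2", "eps3")

params_from_list <- function(lst, model = NULL) {
  keys <- setdiff(names(lst), "model")
  if (is.null(model)) model <- lst$model
  if (is.null(model))
    model <- if (any(c("beta", "eta", "phi1", "eps3") %in% keys))
      "3sp" else "2sp"
  allowed <- if (model == "2sp") params_keys2 else params_keys3
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown parameter key(s) for model ", model, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ctor <- if (model == "2sp") params2 else params3
  do.call(ctor, lst[intersect(allowed, keys)])
}

#' Read / write parameter bundles as flat structured config
#'
#' Parameters serialize to a flat YAML mapping whose keys are the
#' spelled-out symbol names (`rho`, `psi`, `phi`, `phi1`, `beta`,
#' `eta`, `eps1`, `eps2`, `eps3`) plus a `model` tag (`"2sp"` or
#' `"3sp"`).  Unknown keys are errors, so typos never pass silently.
#'
#' @param params A [params2()] or [params3()] bundle.
#' @param path File path.
#' @return `write_params_config()`: the path, invisibly;
#'   `read_params_config()`: a parameter bundle.
#' @export
write_params_config <- function(params, path) {
  model <- if (inherits(params, "params2")) "2sp"
           else if (inherits(params, "params3")) "3sp"
           else stop("expected a 'params2' or 'params3' object", call. = FALSE)
  yaml::write_yaml(c(list(model = model), unclass(params)), path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.list(lst) || is.null(names(lst)))
    stop("config must be a flat key: value mapping", call. = FALSE)
  params_from_list(lst)
}

#' Read / write scenario configurations
#'
#' A scenario file is a flat YAML mapping holding the model tag, the
#' parameter keys, the fractional order(s) `alpha`, the initial state
#' `x0`, and optionally the solver settings `h`, `t_end`,
#' `corrector_iters`.
#'
#' @param config A [scenario_config()].
#' @param path File path.
#' @return `write_scenario_config()`: the path, invisibly;
#'   `read_scenario_config()`: a [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  lst <- c(list(model = config$model), unclass(config$params),
           list(alpha = as.numeric(config$alpha),
                x0 = as.numeric(config$x0),
                h = config$settings$h, t_end = config$settings$t_end,
                corrector_iters = config$settings$corrector_iters))
  if (!is.null(config$label)) lst$label <- config$label
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lst <- yaml::read_yaml(path)
  meta <- c("model", "alpha", "x0", "h", "t_end", "corrector_iters", "label")
  if (is.null(lst$alpha) || is.null(lst$x0))
    stop("scenario config must provide 'alpha' and 'x0'", call. = FALSE)
  params <- params_from_list(lst[setdiff(names(lst), setdiff(meta, "model"))])
  settings <- solver_settings(
    h = lst$h %||% 0.01, t_end = lst$t_end %||% 200,
    corrector_iters = lst$corrector_iters %||% 1L)
  scenario_config(params, as.numeric(unlist(lst$alpha)),
                  as.numeric(unlist(lst$x0)), settings, label = lst$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
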