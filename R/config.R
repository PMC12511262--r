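# YAML configuration for model parameters, variability and thresholds.
# Units must be stated explicitly; a config without them is refused.

EXPECTED_UNITS <- c(dose = "mg", volume = "L", clearance = "L/h",
                    absorption_rate = "1/h", concentration = "ng/mL",
                    time = "h")

#' Read a model-parameter configuration
#'
#' The YAML file must declare a `units` block matching the package-wide unit
#' convention (dose mg, volume L, clearance L/h, absorption rate 1/h,
#' concentration ng/mL, time h) and a `parameters` block with the eight
#' structural parameters; optional `iiv` (omega variances, residual SDs) and
#' `thresholds` blocks populate the random-effects model and the gate
#' configuration.
#'
#' @param path YAML file path.
#' @return A list: `params` ([pk_parameters()]), `model` ([random_effects()]
#'   or NULL), `thresholds` ([threshold_config()] or NULL).
#' @export
read_param_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$units)) {
    stop("config refused: no 'units' block; units must be stated explicitly",
         call. = FALSE)
  }
  for (u in names(EXPECTED_UNITS)) {
    if (is.null(cfg$units[[u]]) ||
        !identical(cfg$units[[u]], unname(EXPECTED_UNITS[u]))) {
      stop(sprintf("config refused: unit '%s' must be declared as '%s'",
                   u, EXPECTED_UNITS[u]), call. = FALSE)
    }
  }
  if (is.null(cfg$parameters)) stop("config has no 'parameters' block",
                                    call. = FALSE)
  params <- do.call(pk_parameters, cfg$parameters)
  model <- NULL
  if (!is.null(cfg$iiv)) {
    model <- random_effects(omega = unlist(cfg$iiv$omega),
                            sigma_prop = cfg$iiv$sigma_prop %||% 0,
                            sigma_add = cfg$iiv$sigma_add %||% 0)
  }
  thresholds <- if (!is.null(cfg$thresholds)) {
    do.call(threshold_config, cfg$thresholds)
  }
  list(params = params, model = model, thresholds = thresholds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model-parameter configuration
#'
#' @param params A [pk_parameters()] object.
#' @param path Output YAML path.
#' @param model Optional [random_effects()] object.
#' @export
write_param_config <- function(params, path, model = NULL) {
  stopifnot(inherits(params, "pk_parameters"))
  cfg <- list(units = as.list(EXPECTED_UNITS),
              parameters = unclass(params))
  if (!is.null(model)) {
    cfg$iiv <- list(omega = as.list(stats::setNames(diag(model$omega),
                                                    model$eta_names)),
                    sigma_prop = model$sigma_prop,
                    sigma_add = model$sigma_add)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
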