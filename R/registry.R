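# Model registry: the contract through which every generic toxicokinetic
# model declares its state variables, parameter names, output ordering,
# units and phase per compartment, dosing routes, data requirements, and
# steady-state / Monte Carlo capabilities.  Core functions (solving, steady
# state, Monte Carlo, eligibility filtering) interact with models only
# through this registry.

.registry <- new.env(parent = emptyenv())

#' Construct a model information record
#'
#' @param name Model name (unique in the registry).
#' @param state_vars Ordered character vector of state variables (amounts in
#'   umol unless declared otherwise).
#' @param param_names Ordered character vector of the full parameter set.
#' @param required_params Parameters that must be resolvable from data.
#' @param derivative_output_names Ordered names of everything the derivative
#'   routine emits: the state derivatives (same order as `state_vars`)
#'   followed by the auxiliary outputs.  Must match the routine's actual
#'   ordering; [validate_model()] probes this.
#' @param compartment_units Named map output -> unit.
#' @param compartment_state Named map output -> `"gas"` or `"liquid"`.
#' @param routes Named character vector route -> dosed state variable
#'   (`"inhalation"` maps to the forcing name).
#' @param input_var_names Names of forcing series (empty if none).
#' @param default_monitor_vars Columns returned by default from a solve.
#' @param data_requirements List: `required_params` (chemical fields),
#'   `exclude_fup_zero`, `log_henry_threshold`, `chem_class_filter`.
#' @param solve_capable Does the model have an ODE system?
#' @param steady_state Optional list: `analytic_css_func`,
#'   `steady_state_compartment`, `steady_state_units`, `css_dosing_param`.
#' @param mc Optional list: `calcpc`, `firstpass`, `httkpop_params`,
#'   `propagateuv_func`, `invitro_params`.
#' @param parameterize_func Name of the parameterization function.
#' @param derivative_func Name of the derivative routine (if solve-capable).
#' @return A `model_info` list.
#' @export
model_info <- function(name, state_vars, param_names, required_params,
                       derivative_output_names, compartment_units,
                       compartment_state, routes, input_var_names = character(0),
                       default_monitor_vars, data_requirements,
                       solve_capable = TRUE, steady_state = NULL, mc = NULL,
                       parameterize_func, derivative_func = NULL) {
  info <- list(name = name, state_vars = state_vars,
               param_names = param_names, required_params = required_params,
               derivative_output_names = derivative_output_names,
               compartment_units = compartment_units,
               compartment_state = compartment_state, routes = routes,
               input_var_names = input_var_names,
               default_monitor_vars = default_monitor_vars,
               data_requirements = data_requirements,
               solve_capable = solve_capable, steady_state = steady_state,
               mc = mc, parameterize_func = parameterize_func,
               derivative_func = derivative_func)
  if (solve_capable && !all(state_vars %in% derivative_output_names))
    abort("derivative_output_names must contain every state variable")
  if (!length(data_requirements$required_params))
    abort("data_requirements$required_params must be non-empty")
  structure(info, class = "model_info")
}

#' Register a model
#'
#' @param info A [model_info()] record.
#' @param overwrite Allow replacing an existing entry (used only by the
#'   package's own reload logic); duplicate names are otherwise an error.
#' @return The registered name, invisibly.
#' @export
register_model <- function(info, overwrite = FALSE) {
  stopifnot(inherits(info, "model_info"))
  if (!overwrite && !is.null(.registry[[info$name]]))
    abort(sprintf("model '%s' is already registered", info$name),
          class = "pbtksim_registry_error")
  assign(info$name, info, envir = .registry)
  invisible(info$name)
}

#' Retrieve a registered model's information record
#'
#' @param model Model name.
#' @return The [model_info()] record.
#' @export
get_model_info <- function(model) {
  info <- .registry[[model]]
  if (is.null(info))
    abort(sprintf("model '%s' is not registered (available: %s)", model,
                  paste(list_models(), collapse = ", ")),
          class = "pbtksim_registry_error")
  info
}

#' List registered models
#'
#' @return Character vector of model names.
#' @export
list_models <- function() sort(ls(.registry))

#' Validate a registered model against its declared contract
#'
#' Checks (a) that the declared `derivative_output_names` agree, in order,
#' with what the derivative routine actually emits on a probe evaluation
#' with distinct sentinel state values -- the mislabeling failure mode in
#' which a permuted declaration silently assigns outputs the wrong units;
#' (b) that every declared output has a unit and a phase; (c) that every
#' dosing route maps to a state variable (or forcing); (d) that required
#' parameters are a subset of `param_names`.
#'
#' @param model Model name.
#' @param params Optional `parameter_set` used for the probe evaluation;
#'   defaults to parameterizing a built-in probe chemical.
#' @return List with `ok` (logical) and `failures` (character vector).
#' @export
validate_model <- function(model, params = NULL) {
  info <- get_model_info(model)
  failures <- character(0)
  if (!all(info$required_params %in% info$param_names))
    failures <- c(failures, sprintf(
      "required params not among param_names: %s",
      paste(setdiff(info$required_params, info$param_names), collapse = ", ")))
  outs <- info$derivative_output_names
  missing_units <- setdiff(outs, names(info$compartment_units))
  if (length(missing_units))
    failures <- c(failures, sprintf("outputs lacking a declared unit: %s",
                                    paste(missing_units, collapse = ", ")))
  missing_state <- setdiff(outs, names(info$compartment_state))
  if (length(missing_state))
    failures <- c(failures, sprintf("outputs lacking a declared phase: %s",
                                    paste(missing_state, collapse = ", ")))
  if (info$solve_capable) {
    for (r in names(info$routes)) {
      target <- info$routes[[r]]
      ok <- target %in% info$state_vars ||
        (r == "inhalation" && target %in% info$input_var_names)
      if (!ok)
        failures <- c(failures, sprintf(
          "route '%s' targets '%s' which is neither a state nor a forcing",
          r, target))
    }
    if (is.null(params)) params <- .probe_params(model)
    state <- stats::setNames(seq_along(info$state_vars) * 0.1,
                             info$state_vars)
    probe <- evaluate_derivative(model, t = 0.5, state = state,
                                 params = params)
    actual <- c(names(probe$dstate), names(probe$aux))
    if (!identical(actual, outs))
      failures <- c(failures, sprintf(
        "derivative output ordering mismatch: declared [%s] but routine emits [%s]",
        paste(outs, collapse = ", "), paste(actual, collapse = ", ")))
  }
  list(ok = length(failures) == 0L, failures = failures)
}

# A fixed, fully characterized probe chemical used for contract validation.
.probe_chem <- function() {
  list(dtxsid = "PROBE-0001", casrn = NA, name = "probe",
       MW = 200, logP = 2, pKa_donor = numeric(0), pKa_accept = numeric(0),
       logHenry = -3, caco2_papp = 5, Fabs_measured = NA,
       chem_class = character(0),
       Clint.Human = "10", fup.Human = "0.1",
       Rblood2plasma.Human = NA_real_)
}

.probe_params <- function(model) {
  parameterize_model(model, .probe_chem())
}
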