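# Analytic and numerical quasi-steady-state plasma concentration.
#
# "Steady state" here is the quasi-steady state of a repeated discrete
# dosing scenario: concentrations eventually oscillate around a constant
# average.  For a linear model the time-average of that oscillation equals
# the steady state of the equivalent constant infusion, which is what the
# analytic solutions compute.

# dose_rate (mg/kg/day) -> umol/day for a given parameter set
.rate_umol_day <- function(dose_rate, params) {
  s <- scale_dosing(dose_rate, "mg/kg/day", params[["BW"]])
  convert_units(s$value, "mg", "umol", MW = params[["MW"]])
}

css_analytic_1compartment <- function(params, dose_rate = 1) {
  rate <- .rate_umol_day(dose_rate, params)
  cl <- params[["kelim"]] * params[["Vdist"]] * params[["BW"]]   # L/day
  if (cl <= 0)
    abort("non-clearing chemical: total clearance is zero, Css is unbounded",
          class = "pbtksim_nonclearing_error")
  rate * params[["Fabsgut"]] / cl
}

css_analytic_3compartmentss <- function(params, dose_rate = 1) {
  rate <- .rate_umol_day(dose_rate, params)
  cl <- params[["fup"]] * params[["Qgfr"]] + params[["CLh"]]     # L/day
  if (cl <= 0)
    abort("non-clearing chemical: total clearance is zero, Css is unbounded",
          class = "pbtksim_nonclearing_error")
  rate * params[["Fabs"]] * params[["Fgut"]] * params[["Fhep"]] / cl
}

# pbtk: the ODE system is linear in the state, so the infusion steady state
# solves J x = -b exactly, with J assembled column-by-column from the
# derivative routine itself (no separately transcribed formula to get out of
# step with the ODEs) and b the constant oral infusion into the gut lumen.
css_analytic_pbtk <- function(params, dose_rate = 1) {
  rate <- .rate_umol_day(dose_rate, params)
  info <- get_model_info("pbtk")
  dyn <- setdiff(info$state_vars,
                 c("Atubules", "Ametabolized", "Aunabsorbed", "AUC"))
  p <- as.list(params); names(p) <- names(params)
  nd <- length(dyn)
  J <- matrix(0, nd, nd, dimnames = list(dyn, dyn))
  for (j in seq_len(nd)) {
    y <- stats::setNames(rep(0, length(info$state_vars)), info$state_vars)
    y[dyn[j]] <- 1
    d <- deriv_pbtk(0, unname(y), p)$dstate
    J[, j] <- d[dyn]
  }
  b <- stats::setNames(rep(0, nd), dyn)
  b[["Agutlumen"]] <- rate
  x <- tryCatch(solve(J, -b), error = function(e)
    abort("non-clearing chemical: steady-state system is singular",
          class = "pbtksim_nonclearing_error"))
  x[["Aven"]] / params[["Vven"]] / params[["Rblood2plasma"]]   # plasma, uM
}

#' Analytic quasi-steady-state plasma concentration
#'
#' Calls the model-specific analytic solution declared in the registry
#' (closed-form for the one-compartment and steady-state three-compartment
#' models; an exact linear-system solve for the PBTK model).  Css scales
#' linearly with the dose rate.
#'
#' @param model Registered model name declaring a steady-state descriptor.
#' @param chem Chemical record or identifier (ignored when `params` given).
#' @param params Optional pre-built `parameter_set`.
#' @param species Species name.
#' @param dose_rate Oral dose rate in mg/kg/day (default 1).
#' @param output_units `"uM"` (default) or `"mg/L"`.
#' @param lib Optional [chem_library()].
#' @param ... Options for the parameterizer.
#' @return Steady-state concentration in `output_units` for the model's
#'   declared steady-state compartment (plasma).
#' @export
calc_analytic_css <- function(model, chem = NULL, params = NULL,
                              species = "Human", dose_rate = 1,
                              output_units = "uM", lib = NULL, ...) {
  info <- get_model_info(model)
  if (is.null(info$steady_state))
    abort(sprintf("model '%s' has no analytic steady-state solution", model),
          class = "pbtksim_capability_error")
  if (is.null(params)) {
    if (is.null(chem)) abort("either a chemical or a parameter_set is required")
    params <- parameterize_model(model, chem, species = species, lib = lib, ...)
  }
  fn <- get(info$steady_state$analytic_css_func, mode = "function")
  css <- fn(params, dose_rate = dose_rate)
  convert_units(css, info$steady_state$steady_state_units, output_units,
                MW = params[["MW"]])
}

#' Numerical quasi-steady-state concentration under repeated dosing
#'
#' Simulates repeated oral dosing (default three doses per day) and tracks
#' the day-averaged plasma concentration (computed exactly from the AUC
#' accumulator).  Steady state is declared at the first day whose average
#' differs from the previous day's by less than `tolerance` (relative);
#' day-averaging makes the detection robust to the dosing phase within the
#' day.  If the horizon is exhausted the partial result is returned flagged
#' as not converged.
#'
#' @param model Registered, solve-capable model name.
#' @param chem Chemical record or identifier (ignored when `params` given).
#' @param params Optional pre-built `parameter_set`.
#' @param species Species name.
#' @param daily_dose Total daily oral dose, mg/kg/day (default 1).
#' @param doses_per_day Dose events per day (default 3).
#' @param tolerance Relative day-to-day change declaring steady state
#'   (default 1%).
#' @param max_days Simulation horizon in days (default 100).
#' @param lib Optional [chem_library()].
#' @param ... Options for the parameterizer / solver.
#' @return A `steady_state_result` list: `css` (uM, day-average at steady
#'   state), `avg_conc`, `days_to_steady`, `converged`, `compartment`,
#'   `ratio_avg_to_analytic` (when an analytic solution exists),
#'   `daily_avg` (the full per-day trace), `dose_log`.
#' @export
calc_css <- function(model, chem = NULL, params = NULL, species = "Human",
                     daily_dose = 1, doses_per_day = 3, tolerance = 0.01,
                     max_days = 100, lib = NULL, ...) {
  info <- get_model_info(model)
  if (!info$solve_capable)
    abort(sprintf("model '%s' is not solve-capable", model),
          class = "pbtksim_capability_error")
  if (is.null(params)) {
    if (is.null(chem)) abort("either a chemical or a parameter_set is required")
    params <- parameterize_model(model, chem, species = species, lib = lib, ...)
  }
  regimen <- dose_regimen(route = "oral", daily_dose = daily_dose,
                          doses_per_day = doses_per_day,
                          input_units = "mg/kg/day")
  times <- seq(0, max_days, by = 1)
  res <- solve_model(model, params = params, times = times, regimen = regimen,
                     monitor_vars = intersect(c("AUC"), info$state_vars), ...)
  auc <- res$AUC
  daily_avg <- diff(auc)                       # uM*day over 1 day -> uM
  days <- seq_along(daily_avg)
  conv_day <- NA_integer_
  for (d in days[-1]) {
    prev <- daily_avg[d - 1]; cur <- daily_avg[d]
    if (cur <= 0) next
    if (abs(cur - prev) / cur < tolerance) { conv_day <- d; break }
  }
  converged <- !is.na(conv_day)
  if (!converged) {
    warning(sprintf("steady state not reached within %d days (tolerance %g)",
                    max_days, tolerance))
    conv_use <- length(daily_avg)
  } else conv_use <- conv_day
  css <- daily_avg[conv_use]
  ratio <- NA_real_
  if (!is.null(info$steady_state)) {
    analytic <- calc_analytic_css(model, params = params,
                                  dose_rate = daily_dose)
    ratio <- css / analytic
  }
  structure(list(css = css, avg_conc = css,
                 days_to_steady = if (converged) conv_day else NA_integer_,
                 converged = converged,
                 compartment = if (!is.null(info$steady_state))
                   info$steady_state$steady_state_compartment else "Cplasma",
                 ratio_avg_to_analytic = ratio, daily_avg = daily_avg,
                 dose_log = attr(res, "dose_log")),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("<steady_state_result> Css = %.4g uM (day-average, %s)\n",
              x$css, x$compartment))
  cat(sprintf("  days to steady state: %s (converged: %s)\n",
              x$days_to_steady, x$converged))
  if (!is.na(x$ratio_avg_to_analytic))
    cat(sprintf("  ratio to analytic Css: %.4f\n", x$ratio_avg_to_analytic))
  invisible(x)
}
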