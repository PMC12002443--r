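# Registration of the built-in model suite:
#   1compartment   -- empirical one-compartment model with first-order
#                     absorption and elimination
#   3compartmentss -- steady-state-only IVIVE model (no ODE system)
#   pbtk           -- perfusion-limited PBTK (gut lumen, gut, liver, kidney,
#                     lung, rest, arterial and venous blood)
#   gas_pbtk       -- pbtk extended with steady-state alveolar gas exchange,
#                     an exhaled stream and an upper-respiratory mucus
#                     compartment

.req_liquid <- function() list(
  required_params = c("MW", "logP", "fup", "Clint"),
  exclude_fup_zero = FALSE,
  log_henry_threshold = -4.5,   # log10(atm*m^3/mol); more volatile -> excluded
  chem_class_filter = character(0))

.req_gas <- function() list(
  required_params = c("MW", "logP", "fup", "Clint", "logHenry"),
  exclude_fup_zero = FALSE,
  log_henry_threshold = NULL,
  chem_class_filter = "PFAS")

.amount_units <- function(vars) {
  u <- stats::setNames(rep("umol", length(vars)), vars)
  if ("AUC" %in% vars) u[["AUC"]] <- "uM*day"
  u
}

.register_builtins <- function(overwrite = FALSE) {
  st1 <- c("Agutlumen", "Acompartment", "Aeliminated", "Aunabsorbed", "AUC")
  register_model(overwrite = overwrite, model_info(
    name = "1compartment",
    state_vars = st1,
    param_names = c("BW", "MW", "fup", "Vdist", "kelim", "kgutabs",
                    "Fabsgut", "Rblood2plasma"),
    required_params = c("BW", "MW", "Vdist", "kelim"),
    derivative_output_names = c(st1, "Ccompartment"),
    compartment_units = c(.amount_units(st1), Ccompartment = "uM"),
    compartment_state = stats::setNames(rep("liquid", length(st1) + 1L),
                                        c(st1, "Ccompartment")),
    routes = c(oral = "Agutlumen", iv = "Acompartment"),
    default_monitor_vars = c(st1, "Ccompartment"),
    data_requirements = .req_liquid(),
    steady_state = list(analytic_css_func = "css_analytic_1compartment",
                        steady_state_compartment = "Ccompartment",
                        steady_state_units = "uM",
                        css_dosing_param = "daily_dose"),
    mc = list(calcpc = TRUE, firstpass = TRUE,
              httkpop_params = c("BW", "Vdist", "kelim"),
              propagateuv_func = "propagate_invitrouv_1compartment",
              invitro_params = c("Clint", "fup")),
    parameterize_func = "parameterize_1compartment_params",
    derivative_func = "deriv_1compartment"))

  register_model(overwrite = overwrite, model_info(
    name = "3compartmentss",
    state_vars = character(0),
    param_names = c("BW", "MW", "fup", "Clint", "Clint_whole", "CLh",
                    "Qgfr", "Qliver_total", "Rblood2plasma", "Fabs",
                    "Fgut", "Fhep"),
    required_params = c("BW", "MW", "fup", "CLh", "Qgfr"),
    derivative_output_names = character(0),
    compartment_units = c(Cplasma = "uM"),
    compartment_state = c(Cplasma = "liquid"),
    routes = c(oral = ""),
    default_monitor_vars = character(0),
    data_requirements = list(
      required_params = c("MW", "logP", "fup", "Clint"),
      exclude_fup_zero = FALSE, log_henry_threshold = -4.5,
      chem_class_filter = character(0)),
    solve_capable = FALSE,
    steady_state = list(analytic_css_func = "css_analytic_3compartmentss",
                        steady_state_compartment = "Cplasma",
                        steady_state_units = "uM",
                        css_dosing_param = "daily_dose"),
    mc = list(calcpc = FALSE, firstpass = TRUE,
              httkpop_params = c("BW", "Qgfr", "Qliver_total"),
              propagateuv_func = NULL,
              invitro_params = c("Clint", "fup")),
    parameterize_func = "parameterize_3compartmentss_params"))

  stp <- c("Agutlumen", "Agut", "Aliver", "Akidney", "Alung", "Arest",
           "Aart", "Aven", "Atubules", "Ametabolized", "Aunabsorbed", "AUC")
  aux_p <- c("Cplasma", "Cgut", "Cliver", "Ckidney", "Clung", "Crest",
             "Cart", "Cven")
  pbtk_flows <- c("Qcardiac", "Qgut", "Qliver", "Qkidney", "Qrest", "Qgfr")
  pbtk_vols <- c("Vgut", "Vliver", "Vkidney", "Vlung", "Vrest", "Vart", "Vven")
  pbtk_kps <- paste0("Kp.", c("gut", "liver", "kidney", "lung", "rest"))
  pbtk_params <- c("BW", "MW", "fup", "Clint", "Clint_whole",
                   "Rblood2plasma", "hematocrit", "kgutabs", "Fabs", "Fgut",
                   pbtk_flows, pbtk_vols, pbtk_kps)
  register_model(overwrite = overwrite, model_info(
    name = "pbtk",
    state_vars = stp,
    param_names = pbtk_params,
    required_params = c("BW", "MW", "fup", "Clint_whole", pbtk_flows,
                        pbtk_vols, pbtk_kps, "Rblood2plasma"),
    derivative_output_names = c(stp, aux_p),
    compartment_units = c(.amount_units(stp),
                          stats::setNames(rep("uM", length(aux_p)), aux_p)),
    compartment_state = stats::setNames(rep("liquid", length(stp) + length(aux_p)),
                                        c(stp, aux_p)),
    routes = c(oral = "Agutlumen", iv = "Aven"),
    default_monitor_vars = c(stp, "Cplasma"),
    data_requirements = .req_liquid(),
    steady_state = list(analytic_css_func = "css_analytic_pbtk",
                        steady_state_compartment = "Cplasma",
                        steady_state_units = "uM",
                        css_dosing_param = "daily_dose"),
    mc = list(calcpc = TRUE, firstpass = TRUE,
              httkpop_params = c("BW", pbtk_flows, pbtk_vols),
              propagateuv_func = NULL,
              invitro_params = c("Clint", "fup")),
    parameterize_func = "parameterize_pbtk_params",
    derivative_func = "deriv_pbtk"))

  stg <- c("Agutlumen", "Agut", "Aliver", "Akidney", "Alung", "Arest",
           "Aart", "Aven", "Amucus", "Atubules", "Ametabolized",
           "Aunabsorbed", "Ainhaled", "Aexhaled", "AUC")
  aux_g <- c(aux_p, "Cexh", "Cexh_ppmv", "Cinh")
  gas_params <- c(pbtk_params, "Qalv", "Kblood2air", "Kwater2air", "f_urt",
                  "k_mucus", "body_temperature")
  cu_g <- c(.amount_units(stg),
            stats::setNames(rep("uM", length(aux_p)), aux_p),
            Cexh = "uM", Cexh_ppmv = "ppmv", Cinh = "uM")
  cs_g <- c(stats::setNames(rep("liquid", length(stg) + length(aux_p)),
                            c(stg, aux_p)),
            Cexh = "gas", Cexh_ppmv = "gas", Cinh = "gas")
  register_model(overwrite = overwrite, model_info(
    name = "gas_pbtk",
    state_vars = stg,
    param_names = gas_params,
    required_params = c("BW", "MW", "fup", "Clint_whole", pbtk_flows,
                        pbtk_vols, pbtk_kps, "Rblood2plasma", "Qalv",
                        "Kblood2air"),
    derivative_output_names = c(stg, aux_g),
    compartment_units = cu_g,
    compartment_state = cs_g,
    routes = c(oral = "Agutlumen", iv = "Aven", inhalation = "Cinh"),
    input_var_names = "Cinh",
    default_monitor_vars = c(stg, "Cplasma", "Cexh", "Cexh_ppmv"),
    data_requirements = .req_gas(),
    steady_state = NULL,   # no analytic steady state for the gas model
    mc = list(calcpc = TRUE, firstpass = TRUE,
              httkpop_params = c("BW", pbtk_flows, pbtk_vols, "Qalv"),
              propagateuv_func = NULL,
              invitro_params = c("Clint", "fup")),
    parameterize_func = "parameterize_gas_pbtk_params",
    derivative_func = "deriv_gas_pbtk"))
  invisible(list_models())
}

.onLoad <- function(libname, pkgname) {
  .register_builtins(overwrite = TRUE)
}
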