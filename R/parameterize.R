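# Resolution of a chemical record + species physiology into a complete,
# unit-consistent parameter set for each registered model.
#
# Internal conventions: time in days, amounts in umol, volumes in L, flows
# in L/day.  Flows, ventilation and glomerular filtration scale
# allometrically as reference * BW^0.75 (the standard 3/4-power rule;
# exponent configurable).

.ALLOMETRIC_EXP <- 0.75
.FUP_DEFAULT <- 0.005       # assumed when the binding assay failed (fup = 0)
.GUT_CLINT_FRACTION <- 0.01 # gut intrinsic clearance = 1% of hepatic
.KGUTABS_DEFAULT <- 24      # 1/day (first-order oral absorption, ~1/h)

# Lumping schemes per model: explicit compartments; everything else -> rest.
.pbtk_scheme <- list(gut = "gut", liver = "liver", kidney = "kidney",
                     lung = "lung", rest = character(0))
.gas_scheme <- .pbtk_scheme

#' Fraction unbound in the hepatocyte clearance assay
#'
#' Lipophilic chemicals bind assay constituents, depressing the apparent
#' intrinsic clearance.  An association model in logP is used:
#' `fu_hep = 1 / (1 + density * 10^(slope * logP + intercept))`, decreasing
#' in logP and approaching 1 for hydrophilic chemicals and vanishing assay
#' density.
#'
#' @param logP log10 octanol:water partition coefficient.
#' @param assay_density Hepatocyte density in 10^6 cells/mL (default 1).
#' @param slope,intercept Association constants (defaults 0.56, -1.41).
#' @return Fraction unbound in the incubation, in (0, 1].
#' @export
calc_hep_fu <- function(logP, assay_density = 1, slope = 0.56,
                        intercept = -1.41) {
  stopifnot(is_scalar_number(logP), assay_density >= 0)
  1 / (1 + assay_density * 10^(slope * logP + intercept))
}

#' Scale intrinsic clearance to whole-liver hepatic clearance
#'
#' Two stages: (1) scale the per-cell in vitro rate to the whole liver,
#' `Clint_w (L/h) = Clint / fu_hep * hepatocellularity * liver_mass_frac *
#' BW * 60 / 1e6`; (2) apply the hepatic extraction model.  Under the
#' well-stirred model `CLh = Q_liver * fup * Clint_w / (Q_liver + fup *
#' Clint_w)`, which is bounded above by liver blood flow.
#'
#' @param Clint Intrinsic clearance in uL/min/10^6 hepatocytes (>= 0).
#' @param fup Fraction unbound in plasma.
#' @param Q_liver Total liver blood flow in L/h.
#' @param BW Body weight (kg).
#' @param hepatocellularity 10^6 cells per g liver.
#' @param liver_mass_frac g liver per kg body weight.
#' @param fu_hep Fraction unbound in the hepatocyte assay (from
#'   [calc_hep_fu()]; 1 disables the adjustment).
#' @param model Hepatic extraction model; only `"well-stirred"` is
#'   implemented.
#' @return List with `CLh` (L/h), `Clint_whole` (L/h) and the inputs used.
#' @export
calc_hep_clearance <- function(Clint, fup, Q_liver, BW = 70,
                               hepatocellularity = 110,
                               liver_mass_frac = 24.1, fu_hep = 1,
                               model = "well-stirred") {
  stopifnot(Clint >= 0, fup >= 0, Q_liver > 0)
  if (!identical(model, "well-stirred"))
    abort(sprintf("unknown hepatic clearance scaling model '%s'", model),
          class = "pbtksim_argument_error")
  clint_w <- (Clint / fu_hep) * hepatocellularity * liver_mass_frac * BW *
    60 / 1e6
  clh <- Q_liver * fup * clint_w / (Q_liver + fup * clint_w)
  if (!is.finite(clh)) clh <- 0
  list(CLh = clh, Clint_whole = clint_w, Q_liver = Q_liver, fup = fup)
}

#' Oral bioavailability components
#'
#' `Fabs` is the fraction absorbed from the gut lumen: a measured in vivo
#' value when available, otherwise a logistic curve in log10 of the Caco-2
#' apparent permeability, otherwise 1.  `Fgut` is the fraction surviving gut
#' metabolism, computed with a gut intrinsic clearance equal to 1% of the
#' scaled hepatic intrinsic clearance:
#' `Fgut = Q_gut / (Q_gut + fup * 0.01 * Clint_w)`.  `Fhep` is the fraction
#' surviving first-pass hepatic extraction,
#' `Fhep = Q_liver / (Q_liver + fup * Clint_w / Rb2p)`.
#'
#' @param chem Chemical record (optional fields `Fabs_measured`,
#'   `caco2_papp`).
#' @param fup Fraction unbound in plasma.
#' @param Clint_w Whole-liver intrinsic clearance (L/h).
#' @param Q_liver,Q_gut Blood flows (L/h).
#' @param Rb2p Blood:plasma ratio.
#' @param caco2_midpoint,caco2_slope Logistic curve constants on log10
#'   Papp (10^-6 cm/s).
#' @return List `Fabs`, `Fgut`, `Fhep`, `gut_clint` (the 1% gut clearance
#'   actually used, L/h), and `provenance` describing the Fabs source.
#' @export
calc_oral_bioavailability <- function(chem = NULL, fup, Clint_w, Q_liver,
                                      Q_gut, Rb2p = 1,
                                      caco2_midpoint = 0.2,
                                      caco2_slope = 1) {
  fabs_meas <- chem$Fabs_measured
  papp <- chem$caco2_papp
  if (!is.null(fabs_meas) && !is.na(fabs_meas)) {
    Fabs <- as.numeric(fabs_meas); prov <- "measured_in_vivo"
  } else if (!is.null(papp) && !is.na(papp) && papp > 0) {
    Fabs <- 1 / (1 + 10^(-caco2_slope * (log10(papp) - caco2_midpoint)))
    prov <- "caco2_curve"
  } else {
    Fabs <- 1; prov <- "default_complete_absorption"
  }
  gut_clint <- .GUT_CLINT_FRACTION * Clint_w
  Fgut <- Q_gut / (Q_gut + fup * gut_clint)
  Fhep <- Q_liver / (Q_liver + fup * Clint_w / Rb2p)
  list(Fabs = Fabs, Fgut = Fgut, Fhep = Fhep, gut_clint = gut_clint,
       provenance = prov)
}

# Shared resolution of chemical inputs (fup/Clint points, default
# substitution, corrections) and physiology-driven flows/volumes.
.resolve_common <- function(chem, species, lib, physiology, tissues,
                            default_to_human = TRUE,
                            substitute_fup_zero = TRUE,
                            adjust_fup = FALSE, adjust_clint = TRUE,
                            calibration = NULL) {
  phys <- get_physiology(species, physiology)
  getf <- function(field) {
    col <- paste0(field, ".", species)
    v <- chem[[col]]
    if ((is.null(v) || is.na(v)) && default_to_human) v <- chem[[paste0(field, ".Human")]]
    if (is.null(v) || is.na(v))
      abort(sprintf("chemical '%s' lacks required field '%s' for species %s",
                    chem$dtxsid %||% "?", field, species),
            class = "pbtksim_eligibility_error")
    v
  }
  fup_uv <- parse_uncertainty_tuple(getf("fup"), "fup")
  clint_uv <- parse_uncertainty_tuple(getf("Clint"), "clint")
  fup <- fup_uv$point
  fup_defaulted <- FALSE
  if (fup == 0) {
    if (!substitute_fup_zero)
      abort(sprintf("chemical '%s' has fup recorded as 0 and substitution is disabled",
                    chem$dtxsid %||% "?"), class = "pbtksim_eligibility_error")
    fup <- .FUP_DEFAULT
    fup_defaulted <- TRUE
  }
  if (adjust_fup) fup <- calc_fup_correction(fup, chem = chem)

  BW <- phys$BW
  QC <- phys$QC * BW^.ALLOMETRIC_EXP * 24    # L/day
  GFR <- phys$GFR * BW^.ALLOMETRIC_EXP * 24  # L/day
  Qalv <- phys$Qalv * BW^.ALLOMETRIC_EXP * 24

  kp <- predict_partitioning_schmitt(chem, fup = fup, tissues = tissues,
                                     calibration = calibration)
  rb <- resolve_rblood2plasma(chem, species = species, lib = lib, fup = fup,
                              hct = phys$hct, tissues = tissues)
  fu_hep <- if (adjust_clint && is_scalar_number(chem$logP))
    calc_hep_fu(chem$logP) else 1
  hep <- calc_hep_clearance(clint_uv$point, fup,
                            Q_liver = QC / 24 * sum(tissues$flow_frac_QC[
                              tissues$tissue %in% c("liver", "gut")]),
                            BW = BW,
                            hepatocellularity = phys$hepatocellularity,
                            liver_mass_frac = phys$liver_mass_frac,
                            fu_hep = fu_hep)
  list(phys = phys, fup = fup, fup_defaulted = fup_defaulted,
       Clint = clint_uv$point, clint_uv = clint_uv, fup_uv = fup_uv,
       fu_hep = fu_hep, Clint_whole = hep$Clint_whole, CLh = hep$CLh,
       BW = BW, QC = QC, GFR = GFR, Qalv = Qalv, kp = kp, Rb2p = rb$Rb2p,
       rb2p_provenance = rb$provenance)
}

.param_set <- function(model, species, values, units, provenance = list()) {
  minfo <- get_model_info(model)
  want <- minfo$param_names
  missing <- setdiff(want, names(values))
  extra <- setdiff(names(values), want)
  if (length(missing) || length(extra))
    abort(sprintf("parameter set for '%s' does not match registry contract (missing: %s; extra: %s)",
                  model, paste(missing, collapse = ","),
                  paste(extra, collapse = ",")))
  values <- values[want]
  if (!all(vapply(values, is_scalar_number, logical(1))))
    abort("non-finite value in parameter set")
  bad_units <- setdiff(unname(unlist(units)), c(.unit_vocab, "unitless", "1/day", "L/day"))
  if (length(bad_units))
    abort(sprintf("parameter units outside vocabulary: %s",
                  paste(bad_units, collapse = ", ")))
  structure(values, class = "parameter_set", model = model, species = species,
            units = units, provenance = provenance)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> model %s, species %s\n",
              attr(x, "model"), attr(x, "species")))
  units <- attr(x, "units")
  for (nm in names(x))
    cat(sprintf("  %-16s %12.6g %s\n", nm, x[[nm]], units[[nm]] %||% ""))
  invisible(x)
}

# ---- model-specific parameterizers -----------------------------------------

parameterize_pbtk_params <- function(chem, species = "Human", lib = NULL,
                                     physiology = NULL,
                                     tissues = load_tissue_data(), ...) {
  cm <- .resolve_common(chem, species, lib, physiology, tissues, ...)
  lump <- lump_tissues(cm$kp, tissues, .pbtk_scheme)
  BW <- cm$BW
  V <- lump$vol_frac_BW * BW
  Qfrac <- lump$flow_frac_QC
  Qgut <- Qfrac[["gut"]] * cm$QC
  Qliver_art <- Qfrac[["liver"]] * cm$QC
  Qkidney <- Qfrac[["kidney"]] * cm$QC
  Qrest <- cm$QC - Qgut - Qliver_art - Qkidney  # rest absorbs the remainder
  blood_v <- cm$phys$blood_vol_frac * BW
  oral <- calc_oral_bioavailability(chem, cm$fup, cm$Clint_whole,
                                    Q_liver = (Qliver_art + Qgut) / 24,
                                    Q_gut = Qgut / 24, Rb2p = cm$Rb2p)
  values <- list(
    BW = BW, MW = chem$MW, fup = cm$fup, Clint = cm$Clint,
    Clint_whole = cm$Clint_whole * 24, Rblood2plasma = cm$Rb2p,
    hematocrit = cm$phys$hct,
    kgutabs = .KGUTABS_DEFAULT, Fabs = oral$Fabs, Fgut = oral$Fgut,
    Qcardiac = cm$QC, Qgut = Qgut, Qliver = Qliver_art, Qkidney = Qkidney,
    Qrest = Qrest, Qgfr = cm$GFR,
    Vgut = V[["gut"]], Vliver = V[["liver"]], Vkidney = V[["kidney"]],
    Vlung = V[["lung"]], Vrest = V[["rest"]],
    Vart = blood_v / 3, Vven = blood_v * 2 / 3,
    Kp.gut = lump$Kp[["gut"]], Kp.liver = lump$Kp[["liver"]],
    Kp.kidney = lump$Kp[["kidney"]], Kp.lung = lump$Kp[["lung"]],
    Kp.rest = lump$Kp[["rest"]]
  )
  units <- c(BW = "kg", MW = "unitless", fup = "unitless", Clint = "unitless",
             Clint_whole = "L/day", Rblood2plasma = "unitless",
             hematocrit = "unitless", kgutabs = "1/day", Fabs = "unitless",
             Fgut = "unitless",
             stats::setNames(rep("L/day", 6),
                             c("Qcardiac", "Qgut", "Qliver", "Qkidney",
                               "Qrest", "Qgfr")),
             stats::setNames(rep("L", 7),
                             c("Vgut", "Vliver", "Vkidney", "Vlung", "Vrest",
                               "Vart", "Vven")),
             stats::setNames(rep("unitless", 5), paste0("Kp.",
                             c("gut", "liver", "kidney", "lung", "rest"))))
  .param_set("pbtk", species, values, as.list(units),
             provenance = list(fup_defaulted = cm$fup_defaulted,
                               rb2p = cm$rb2p_provenance,
                               fu_hep = cm$fu_hep,
                               gut_clint = oral$gut_clint * 24,
                               fabs = oral$provenance,
                               clint_uv = cm$clint_uv, fup_uv = cm$fup_uv))
}

parameterize_gas_pbtk_params <- function(chem, species = "Human", lib = NULL,
                                         physiology = NULL,
                                         tissues = load_tissue_data(),
                                         f_urt = 0.02, k_mucus = 24, ...) {
  if (is.null(chem$logHenry) || is.na(chem$logHenry))
    abort(sprintf("chemical '%s' lacks a Henry's law constant (logHenry) required by the gas model",
                  chem$dtxsid %||% "?"), class = "pbtksim_eligibility_error")
  base <- parameterize_pbtk_params(chem, species, lib, physiology, tissues, ...)
  prov <- attr(base, "provenance")
  phys <- get_physiology(species, physiology)
  Tb <- phys$body_temperature
  HLC <- 10^chem$logHenry                      # atm*m^3/mol
  Kwater2air <- HLC / (8.2057e-5 * Tb)         # dimensionless air:water Henry ratio
  hct <- phys$hct
  fup <- base[["fup"]]
  kp <- predict_partitioning_schmitt(chem, fup = fup, tissues = tissues)
  krbc <- kp[["red blood cells"]]
  Kblood2water <- (1 - hct) / fup + hct * krbc
  Kblood2air <- Kblood2water / Kwater2air
  if (Kblood2air > 1e8)
    warning(sprintf("Kblood2air = %.3g: chemical is effectively non-volatile and out of the gas model's domain",
                    Kblood2air))
  Qalv <- phys$Qalv * base[["BW"]]^.ALLOMETRIC_EXP * 24
  values <- c(as.list(base), list(Qalv = Qalv, Kblood2air = Kblood2air,
                                  Kwater2air = Kwater2air, f_urt = f_urt,
                                  k_mucus = k_mucus,
                                  body_temperature = Tb))
  units <- attr(base, "units")
  units <- c(units, list(Qalv = "L/day", Kblood2air = "unitless",
                         Kwater2air = "unitless", f_urt = "unitless",
                         k_mucus = "1/day", body_temperature = "unitless"))
  .param_set("gas_pbtk", species, values, units, provenance = prov)
}

parameterize_1compartment_params <- function(chem, species = "Human",
                                             lib = NULL, physiology = NULL,
                                             tissues = load_tissue_data(),
                                             ...) {
  cm <- .resolve_common(chem, species, lib, physiology, tissues, ...)
  BW <- cm$BW
  body <- tissues[tissues$tissue != "red blood cells", ]
  kp_body <- cm$kp[body$tissue]
  # plasma-referenced volume of distribution (L/kg)
  Vdist <- cm$phys$blood_vol_frac * cm$Rb2p +
    sum(body$vol_frac_BW * kp_body * cm$fup)
  CL_total <- cm$fup * cm$GFR + cm$CLh * 24    # L/day
  kelim <- CL_total / (Vdist * BW)
  Qgut <- sum(tissues$flow_frac_QC[tissues$tissue == "gut"]) * cm$QC
  Qliver_tot <- sum(tissues$flow_frac_QC[
    tissues$tissue %in% c("liver", "gut")]) * cm$QC
  oral <- calc_oral_bioavailability(chem, cm$fup, cm$Clint_whole,
                                    Q_liver = Qliver_tot / 24,
                                    Q_gut = Qgut / 24, Rb2p = cm$Rb2p)
  Fabsgut <- oral$Fabs * oral$Fgut * oral$Fhep
  values <- list(BW = BW, MW = chem$MW, fup = cm$fup,
                 Vdist = Vdist, kelim = kelim, kgutabs = .KGUTABS_DEFAULT,
                 Fabsgut = Fabsgut, Rblood2plasma = cm$Rb2p)
  units <- list(BW = "kg", MW = "unitless", fup = "unitless", Vdist = "L",
                kelim = "1/day", kgutabs = "1/day", Fabsgut = "unitless",
                Rblood2plasma = "unitless")
  .param_set("1compartment", species, values, units,
             provenance = list(fup_defaulted = cm$fup_defaulted,
                               rb2p = cm$rb2p_provenance,
                               fu_hep = cm$fu_hep,
                               gut_clint = oral$gut_clint * 24,
                               CLh = cm$CLh * 24,
                               clint_uv = cm$clint_uv, fup_uv = cm$fup_uv))
}

parameterize_3compartmentss_params <- function(chem, species = "Human",
                                               lib = NULL, physiology = NULL,
                                               tissues = load_tissue_data(),
                                               ...) {
  cm <- .resolve_common(chem, species, lib, physiology, tissues, ...)
  Qgut <- sum(tissues$flow_frac_QC[tissues$tissue == "gut"]) * cm$QC
  Qliver_tot <- sum(tissues$flow_frac_QC[
    tissues$tissue %in% c("liver", "gut")]) * cm$QC
  oral <- calc_oral_bioavailability(chem, cm$fup, cm$Clint_whole,
                                    Q_liver = Qliver_tot / 24,
                                    Q_gut = Qgut / 24, Rb2p = cm$Rb2p)
  values <- list(BW = cm$BW, MW = chem$MW, fup = cm$fup, Clint = cm$Clint,
                 Clint_whole = cm$Clint_whole * 24, CLh = cm$CLh * 24,
                 Qgfr = cm$GFR, Qliver_total = Qliver_tot,
                 Rblood2plasma = cm$Rb2p,
                 Fabs = oral$Fabs, Fgut = oral$Fgut, Fhep = oral$Fhep)
  units <- list(BW = "kg", MW = "unitless", fup = "unitless",
                Clint = "unitless", Clint_whole = "L/day", CLh = "L/day",
                Qgfr = "L/day", Qliver_total = "L/day",
                Rblood2plasma = "unitless", Fabs = "unitless",
                Fgut = "unitless", Fhep = "unitless")
  .param_set("3compartmentss", species, values, units,
             provenance = list(fup_defaulted = cm$fup_defaulted,
                               rb2p = cm$rb2p_provenance,
                               fu_hep = cm$fu_hep, fabs = oral$provenance,
                               gut_clint = oral$gut_clint * 24,
                               clint_uv = cm$clint_uv, fup_uv = cm$fup_uv))
}

#' Parameterize a registered model for a chemical
#'
#' Dispatches to the model's registered parameterization function.  The
#' chemical may be given as a record list (see [chem_record()]) or as an
#' identifier resolved against `lib`.  When the binding assay failed (fup
#' recorded 0) and substitution is permitted, the default fraction unbound
#' of 0.5% is assumed.  Parameterization is deterministic: the same inputs
#' always give the same parameter set, whose names match the model's
#' registered `param_names` exactly.
#'
#' @param model Registered model name.
#' @param chem Chemical record list or identifier string.
#' @param species Species name.
#' @param lib Optional [chem_library()] (required when `chem` is an id).
#' @param ... Options passed to the model parameterizer:
#'   `default_to_human`, `substitute_fup_zero`, `adjust_fup`,
#'   `adjust_clint`, `calibration`, `physiology`, `tissues`.
#' @return A `parameter_set` (named numeric values with unit metadata).
#' @export
parameterize_model <- function(model, chem, species = "Human", lib = NULL,
                               ...) {
  minfo <- get_model_info(model)
  if (is.character(chem)) {
    if (is.null(lib))
      abort("a chem_library is required to resolve a chemical identifier")
    chem <- chem_record(lib, chem)
  }
  fn <- get(minfo$parameterize_func, mode = "function")
  fn(chem, species = species, lib = lib, ...)
}

#' Parameterize the gas-inhalation PBTK model
#'
#' Convenience wrapper for `parameterize_model("gas_pbtk", ...)`; requires a
#' Henry's law constant, from which the dimensionless air:water ratio
#' `Kwater2air = HLC / (R * T_body)` and the blood:air partition coefficient
#' `Kblood2air = Kblood2water / Kwater2air` are derived.
#'
#' @inheritParams parameterize_model
#' @return A `parameter_set` for the gas model.
#' @export
parameterize_gas_model <- function(chem, species = "Human", lib = NULL, ...) {
  parameterize_model("gas_pbtk", chem, species = species, lib = lib, ...)
}
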