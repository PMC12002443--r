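# Centralized unit conversion and body-weight dose scaling.
#
# All conversions are exact dimensional relations; concentration <-> amount
# hops require a volume, and ppmv is only meaningful for gas-phase
# compartments.  A controlled vocabulary is used instead of a free-form unit
# parser: silent unit mistakes are the historically worst bug class in
# toxicokinetic software, so an unknown unit is an error, never a guess.

# Ideal-gas constant in L*atm/(mol*K).
R_ATM <- 0.0820573

.unit_vocab <- c("mg", "umol", "mg/L", "uM", "ppmv",
                 "mg/kg", "mg/kg/day", "mg/L/day", "uM/day", "L", "kg")

.unit_class <- function(unit) {
  switch(unit,
    "mg" = , "umol" = "amount",
    "mg/L" = , "uM" = , "ppmv" = "conc",
    "mg/L/day" = , "uM/day" = "conc_rate",
    "mg/kg" = , "mg/kg/day" = "dose_per_kg",
    "L" = "volume",
    "kg" = "mass",
    abort(sprintf("unit '%s' is not in the controlled vocabulary (%s)",
                  unit, paste(.unit_vocab, collapse = ", ")),
          class = "pbtksim_unit_error")
  )
}

#' Supported unit vocabulary
#'
#' @return Character vector of the units understood by [convert_units()].
#' @export
unit_vocabulary <- function() .unit_vocab

# value in `unit` -> value in the canonical unit of its class
# (umol for amounts, uM for concentrations, uM/day for concentration rates).
.to_canonical <- function(value, unit, MW, temperature, state) {
  cls <- .unit_class(unit)
  if (unit == "ppmv" && !identical(state, "gas"))
    abort("ppmv conversion requires a gas-phase compartment (state = 'gas')",
          class = "pbtksim_unit_error")
  need_mw <- function() {
    if (!is_scalar_number(MW) || MW <= 0)
      abort(sprintf("conversion from '%s' requires a positive molecular weight (MW)", unit),
            class = "pbtksim_unit_error")
  }
  switch(unit,
    "mg" = { need_mw(); value * 1000 / MW },
    "umol" = value,
    "mg/L" = , "mg/L/day" = { need_mw(); value * 1000 / MW },
    "uM" = , "uM/day" = value,
    # 1 ppmv = 1e-6 atm partial pressure; molar density P/(RT) mol/L.
    "ppmv" = value / (R_ATM * temperature),
    value
  )
}

.from_canonical <- function(value, unit, MW, temperature, state) {
  if (unit == "ppmv" && !identical(state, "gas"))
    abort("ppmv conversion requires a gas-phase compartment (state = 'gas')",
          class = "pbtksim_unit_error")
  need_mw <- function() {
    if (!is_scalar_number(MW) || MW <= 0)
      abort(sprintf("conversion to '%s' requires a positive molecular weight (MW)", unit),
            class = "pbtksim_unit_error")
  }
  switch(unit,
    "mg" = { need_mw(); value * MW / 1000 },
    "umol" = value,
    "mg/L" = , "mg/L/day" = { need_mw(); value * MW / 1000 },
    "uM" = , "uM/day" = value,
    "ppmv" = value * R_ATM * temperature,
    value
  )
}

#' Convert a value between toxicokinetic units
#'
#' Exact dimensional conversion within the controlled vocabulary
#' (see [unit_vocabulary()]). `mg/L <-> uM` multiplies by `1000/MW`;
#' `ppmv <-> uM` uses the ideal-gas molar density at `temperature`;
#' amount <-> concentration requires a compartment `volume`.
#'
#' @param value Numeric value(s) to convert.
#' @param from,to Unit strings from the vocabulary.
#' @param MW Molecular weight in g/mol (required for mg-based conversions).
#' @param volume Compartment volume in L (required for amount <-> concentration).
#' @param temperature Temperature in K used for ppmv conversions
#'   (default 298.15 K ambient; alveolar air conversions use body temperature).
#' @param state `"liquid"` or `"gas"`; ppmv is only valid for `"gas"`.
#' @return Converted numeric value(s).
#' @examples
#' convert_units(1, "mg/L", "uM", MW = 100)   # 10 uM
#' convert_units(1, "ppmv", "uM", state = "gas")
#' @export
convert_units <- function(value, from, to, MW = NULL, volume = NULL,
                          temperature = 298.15, state = "liquid") {
  stopifnot(is.numeric(value))
  from <- match.arg(from, .unit_vocab)
  to <- match.arg(to, .unit_vocab)
  if (from == to) return(value)
  cf <- .unit_class(from); ct <- .unit_class(to)
  if (cf %in% c("dose_per_kg", "volume", "mass") ||
      ct %in% c("dose_per_kg", "volume", "mass"))
    abort(sprintf(
      "no conversion path from '%s' to '%s' (body-weight doses go through scale_dosing())",
      from, to), class = "pbtksim_unit_error")
  canon <- .to_canonical(value, from, MW, temperature, state)
  if (cf == ct) {
    # same dimension, straight through the canonical hub
  } else if (cf == "amount" && ct == "conc") {
    if (!is_scalar_number(volume) || volume <= 0)
      abort(sprintf("conversion from '%s' to '%s' requires a compartment volume (L)",
                    from, to), class = "pbtksim_unit_error")
    canon <- canon / volume
  } else if (cf == "conc" && ct == "amount") {
    if (!is_scalar_number(volume) || volume <= 0)
      abort(sprintf("conversion from '%s' to '%s' requires a compartment volume (L)",
                    from, to), class = "pbtksim_unit_error")
    canon <- canon * volume
  } else {
    abort(sprintf("no conversion path from '%s' to '%s'", from, to),
          class = "pbtksim_unit_error")
  }
  .from_canonical(canon, to, MW, temperature, state)
}

#' Scale a per-body-weight dose to an absolute dose
#'
#' Multiplies by body weight and strips the `"/kg"` token from the unit,
#' e.g. `1 mg/kg/day` at 70 kg becomes `70 mg/day`.  A unit without `"/kg"`
#' is returned unchanged with a warning.
#'
#' @param value Dose value.
#' @param units Unit string containing `"/kg"`.
#' @param BW Body weight in kg.
#' @return List with elements `value` and `units`.
#' @export
scale_dosing <- function(value, units, BW) {
  stopifnot(is.numeric(value), is_scalar_number(BW), BW > 0)
  if (!grepl("/kg", units, fixed = TRUE)) {
    warning(sprintf("unit '%s' has no '/kg' component; dose left unscaled", units))
    return(list(value = value, units = units))
  }
  list(value = value * BW, units = sub("/kg", "", units, fixed = TRUE))
}

#' Audit table of supported conversions
#'
#' One row per implemented conversion path with the factor evaluated at a
#' reference context (MW 100 g/mol, 1 L, 298.15 K).  Intended for CLI audit.
#'
#' @return A data.frame with columns `from`, `to`, `factor_at_reference`.
#' @export
units_table <- function() {
  pairs <- list(
    c("mg", "umol"), c("umol", "mg"), c("mg/L", "uM"), c("uM", "mg/L"),
    c("ppmv", "uM"), c("uM", "ppmv"), c("mg/L/day", "uM/day"),
    c("uM/day", "mg/L/day"), c("mg", "uM"), c("uM", "mg"),
    c("umol", "uM"), c("uM", "umol")
  )
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(from = p[1], to = p[2],
               factor_at_reference = convert_units(
                 1, p[1], p[2], MW = 100, volume = 1, state = "gas"))
  }))
}
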