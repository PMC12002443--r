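# Tissue:plasma partition coefficient prediction.
#
# A Schmitt-type component model: each tissue's affinity for a chemical is
# the sum of contributions from tissue water, neutral lipid, phospholipid
# membranes and tissue protein, weighted by the tissue's composition and
# corrected for ionization at the tissue's pH.  All coefficients are
# referenced to the unbound plasma concentration (Kp = tissue : unbound
# plasma).  The documented component formula, with C_up the unbound plasma
# concentration, f_n(pH) the neutral fraction and Kow = 10^logP:
#
#   Kp = f_water * f_n(pH_plasma) / f_n(pH_tissue)
#      + f_neutral_lipid * Kow * f_n(pH_plasma)
#      + f_phospholipid  * Kow * (f_n(pH_plasma) + alpha_ion * (1 - f_n(pH_plasma)))
#      + f_protein / f_protein_plasma * (1/fup - 1)
#
# The water term reflects pH-partitioning of the neutral species; the
# neutral-lipid term admits only the neutral species; membranes bind ions
# with an attenuation factor alpha_ion; tissue protein binding is scaled
# from the plasma bound:unbound ratio by relative protein content.  An
# optional per-tissue affine calibration in log10 space (slope/intercept)
# can be applied on top; the default is the identity (uncalibrated).

.PLASMA_PROTEIN_FRAC <- 0.075
.PLASMA_LIPID_FRAC <- 0.0199

#' Predict tissue:unbound-plasma partition coefficients
#'
#' @param chem A chemical record (list with `logP`, `pKa_donor`,
#'   `pKa_accept`), e.g. from an eligible library row; alternatively supply
#'   `logP`/`pKa_donor`/`pKa_accept` directly.
#' @param fup Fraction unbound in plasma, in (0, 1]. A recorded 0 is an
#'   error here: apply the default-substitution path first.
#' @param tissues Tissue composition table from [load_tissue_data()].
#' @param calibration Optional data.frame `tissue`, `slope`, `intercept`
#'   applied as `log10 Kp' = intercept + slope * log10 Kp` per tissue
#'   (default: identity, i.e. uncalibrated).
#' @param logP,pKa_donor,pKa_accept Direct chemistry inputs overriding `chem`.
#' @param alpha_ion Membrane affinity attenuation for ionized species.
#' @param plasma_pH Reference plasma pH.
#' @return Named numeric vector of Kp (> 0), one per tissue row.
#' @export
predict_partitioning_schmitt <- function(chem = NULL, fup,
                                         tissues = load_tissue_data(),
                                         calibration = NULL,
                                         logP = NULL, pKa_donor = NULL,
                                         pKa_accept = NULL,
                                         alpha_ion = 0.05, plasma_pH = 7.4) {
  logP <- logP %||% chem$logP
  pKa_donor <- pKa_donor %||% chem$pKa_donor %||% numeric(0)
  pKa_accept <- pKa_accept %||% chem$pKa_accept %||% numeric(0)
  if (!is_scalar_number(logP))
    abort("logP is required for partition coefficient prediction",
          class = "pbtksim_missing_data_error")
  if (!is_scalar_number(fup) || fup > 1 || fup < 0)
    abort("fup must lie in (0, 1]", class = "pbtksim_argument_error")
  if (fup == 0)
    abort(paste("fup = 0 means the binding assay failed;",
                "apply the default substitution (0.5%) before predicting partitioning"),
          class = "pbtksim_argument_error")
  pKa_donor <- parse_num_list(pKa_donor)
  pKa_accept <- parse_num_list(pKa_accept)
  Kow <- 10^logP
  ion_p <- ionization_fractions(plasma_pH, pKa_donor, pKa_accept)
  fn_p <- ion_p[["neutral"]]
  kp <- vapply(seq_len(nrow(tissues)), function(i) {
    t <- tissues[i, ]
    fn_t <- ionization_fractions(t$pH, pKa_donor, pKa_accept)[["neutral"]]
    term_water <- t$f_water * fn_p / fn_t
    term_nl <- t$f_neutral_lipid * Kow * fn_p
    term_pl <- t$f_phospholipid * Kow * (fn_p + alpha_ion * (1 - fn_p))
    term_prot <- t$f_protein / .PLASMA_PROTEIN_FRAC * (1 / fup - 1)
    term_water + term_nl + term_pl + term_prot
  }, numeric(1))
  names(kp) <- tissues$tissue
  if (!is.null(calibration)) {
    stopifnot(all(c("tissue", "slope", "intercept") %in% names(calibration)))
    j <- match(names(kp), calibration$tissue)
    adj <- !is.na(j)
    kp[adj] <- 10^(calibration$intercept[j[adj]] +
                   calibration$slope[j[adj]] * log10(kp[adj]))
  }
  structure(kp, class = c("partition_set", "numeric"))
}

#' Correct an in vitro fraction unbound for in vivo lipid binding
#'
#' In vitro binding assays under-represent plasma lipid, biasing the
#' measured fraction unbound upward for lipophilic chemicals.  The
#' correction adds a lipid-binding term driven by the distribution ratio at
#' plasma pH: `fup' = 1 / (Dow * f_lipid_plasma + 1/fup)` with
#' `Dow = Kow * (f_neutral + alpha_ion * (1 - f_neutral))`.  The correction
#' ratio approaches 1 for hydrophilic chemicals and strictly reduces fup for
#' lipophilic ones; `enabled = FALSE` is the identity.
#'
#' @param fup_measured Measured fraction unbound, in (0, 1].
#' @param chem Chemical record (needs `logP` and pKa lists), or pass `logP`.
#' @param logP,pKa_donor,pKa_accept Direct chemistry inputs.
#' @param f_lipid_plasma Plasma lipid volume fraction (default 0.0199).
#' @param alpha_ion Ion attenuation as in [predict_partitioning_schmitt()].
#' @param enabled Apply the correction (default) or return `fup_measured`.
#' @return Corrected fraction unbound in (0, 1].
#' @export
calc_fup_correction <- function(fup_measured, chem = NULL, logP = NULL,
                                pKa_donor = NULL, pKa_accept = NULL,
                                f_lipid_plasma = .PLASMA_LIPID_FRAC,
                                alpha_ion = 0.05, enabled = TRUE) {
  stopifnot(is_scalar_number(fup_measured), fup_measured > 0, fup_measured <= 1)
  if (!enabled) return(fup_measured)
  logP <- logP %||% chem$logP
  if (!is_scalar_number(logP)) return(fup_measured)
  fn <- ionization_fractions(7.4,
                             parse_num_list(pKa_donor %||% chem$pKa_donor %||% numeric(0)),
                             parse_num_list(pKa_accept %||% chem$pKa_accept %||% numeric(0)))[["neutral"]]
  Dow <- 10^logP * (fn + alpha_ion * (1 - fn))
  1 / (Dow * f_lipid_plasma + 1 / fup_measured)
}

#' Resolve the blood:plasma concentration ratio
#'
#' Works through a fixed cascade to obtain the most accurate ratio:
#' (1) a measured species-specific value from the library; (2) a measured
#' human value; (3) a computed value
#' `Rb2p = (1 - hct) + hct * Krbc2pu * fup` with the red-blood-cell
#' partition coefficient from the Schmitt predictor; (4) the mean of all
#' measured values across the library.
#'
#' @param chem Chemical record (from [chem_record()] or a compatible list).
#' @param species Species name.
#' @param lib Optional [chem_library()] for measured values and the
#'   library-average fallback.
#' @param fup Fraction unbound in plasma (for the computed path).
#' @param hct Hematocrit fraction in (0, 1).
#' @param tissues Tissue table containing a `"red blood cells"` row.
#' @return List with `Rb2p` and `provenance` (one of `"measured_species"`,
#'   `"measured_human"`, `"schmitt_computed"`, `"library_average"`).
#' @export
resolve_rblood2plasma <- function(chem, species = "Human", lib = NULL,
                                  fup = NULL, hct = 0.44,
                                  tissues = load_tissue_data()) {
  stopifnot(hct >= 0, hct < 1)
  val <- chem[[paste0("Rblood2plasma.", species)]]
  if (!is.null(val) && !is.na(val))
    return(list(Rb2p = as.numeric(val), provenance = "measured_species"))
  val <- chem[["Rblood2plasma.Human"]]
  if (!is.null(val) && !is.na(val))
    return(list(Rb2p = as.numeric(val), provenance = "measured_human"))
  logP <- chem$logP
  if (is_scalar_number(logP) && is_scalar_number(fup) && fup > 0) {
    kp <- predict_partitioning_schmitt(chem, fup = fup, tissues = tissues)
    if ("red blood cells" %in% names(kp)) {
      krbc <- kp[["red blood cells"]]
      return(list(Rb2p = (1 - hct) + hct * krbc * fup,
                  provenance = "schmitt_computed"))
    }
  }
  if (!is.null(lib)) {
    cols <- grep("^Rblood2plasma\\.", names(lib$records), value = TRUE)
    vals <- unlist(lib$records[cols])
    vals <- vals[!is.na(vals)]
    if (length(vals))
      return(list(Rb2p = mean(as.numeric(vals)), provenance = "library_average"))
  }
  abort("no measured, computable, or library-average blood:plasma ratio available",
        class = "pbtksim_missing_data_error")
}

#' Lump tissues into model compartments
#'
#' Aggregates tissue rows into the compartments of a lumping scheme:
#' lumped volume and flow are sums of the members', and the lumped partition
#' coefficient is the volume-weighted mean, so that total volume, total
#' flow, and total partitioning capacity (sum of V*Kp) are conserved
#' exactly.  Tissues not named in the scheme are pooled into the remainder
#' compartment.
#'
#' @param kp Named Kp vector from [predict_partitioning_schmitt()].
#' @param tissues Tissue composition table (volumes/flows).
#' @param scheme Named list: compartment name -> character vector of member
#'   tissues.
#' @param rest_name Name of the remainder compartment (default `"rest"`).
#' @param exclude Tissue rows ignored by lumping (default red blood cells,
#'   which travel with the blood).
#' @return List of named vectors `Kp`, `vol_frac_BW` (L/kg), `flow_frac_QC`.
#' @export
lump_tissues <- function(kp, tissues = load_tissue_data(), scheme,
                         rest_name = "rest", exclude = "red blood cells") {
  members <- unlist(scheme, use.names = FALSE)
  if (anyDuplicated(members))
    abort(sprintf("tissue(s) assigned to more than one lump: %s",
                  paste(unique(members[duplicated(members)]), collapse = ", ")),
          class = "pbtksim_scheme_error")
  missing <- setdiff(members, tissues$tissue)
  if (length(missing))
    abort(sprintf("scheme names unknown tissue(s): %s",
                  paste(missing, collapse = ", ")),
          class = "pbtksim_scheme_error")
  pool <- setdiff(tissues$tissue, c(members, exclude))
  full <- scheme
  if (length(pool)) full[[rest_name]] <- c(full[[rest_name]], pool)
  out_kp <- out_v <- out_q <- stats::setNames(numeric(length(full)), names(full))
  for (nm in names(full)) {
    idx <- match(full[[nm]], tissues$tissue)
    v <- tissues$vol_frac_BW[idx]
    q <- tissues$flow_frac_QC[idx]
    k <- kp[tissues$tissue[idx]]
    out_v[nm] <- sum(v)
    out_q[nm] <- sum(q)
    out_kp[nm] <- sum(v * k) / sum(v)
  }
  list(Kp = out_kp, vol_frac_BW = out_v, flow_frac_QC = out_q)
}
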