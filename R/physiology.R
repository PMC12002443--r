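# Species physiology and tissue-composition reference tables.
#
# Both tables ship as editable plain CSVs under inst/extdata.  Flows and
# glomerular filtration are stored as allometrically scaled reference values
# (L/h/kg^0.75); absolute per-individual values are derived at
# parameterization time as ref * BW^0.75.

#' Load the species physiology table
#'
#' Columns: `species`, `BW` (kg), `QC` (cardiac output, L/h/kg^0.75), `Qalv`
#' (alveolar ventilation, L/h/kg^0.75), `hct` (hematocrit fraction), `GFR`
#' (glomerular filtration, L/h/kg^0.75), `liver_mass_frac` (g liver/kg BW),
#' `hepatocellularity` (10^6 cells/g liver), `blood_vol_frac` (L/kg BW),
#' `plasma_pH`, `body_temperature` (K), `source`.
#'
#' @param path CSV path; defaults to the packaged table (Human, Rat).
#' @return A data.frame, one row per species.
#' @export
load_physiology <- function(path = NULL) {
  path <- path %||% system.file("extdata", "physiology.csv",
                                package = "pbtksim", mustWork = TRUE)
  phys <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(phys), c("species", "source"))
  for (col in num) phys[[col]] <- as.numeric(phys[[col]])
  stopifnot(all(phys$hct > 0 & phys$hct < 1),
            all(phys[num] > 0, na.rm = TRUE))
  phys
}

#' Look up one species' physiology
#'
#' @param species Species name (matched case-insensitively).
#' @param physiology Optional table from [load_physiology()].
#' @return A one-row list of physiological constants.
#' @export
get_physiology <- function(species = "Human", physiology = NULL) {
  phys <- physiology %||% load_physiology()
  i <- match(tolower(species), tolower(phys$species))
  if (is.na(i))
    abort(sprintf("species '%s' not in physiology table (%s)", species,
                  paste(phys$species, collapse = ", ")),
          class = "pbtksim_missing_data_error")
  as.list(phys[i, ])
}

#' Load the tissue composition table
#'
#' Columns: `tissue`, component fractions `f_water`, `f_neutral_lipid`,
#' `f_phospholipid`, `f_protein` (each in \\[0, 1\\]), `pH`, `vol_frac_BW`
#' (L tissue per kg body weight), `flow_frac_QC` (fraction of cardiac
#' output).  The packaged table holds an 11-tissue set plus red blood
#' cells (used for the blood:plasma partitioning cascade; its flow share
#' is 0 because it travels with the blood).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A data.frame, one row per tissue.
#' @export
load_tissue_data <- function(path = NULL) {
  path <- path %||% system.file("extdata", "tissue_composition.csv",
                                package = "pbtksim", mustWork = TRUE)
  td <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(td), "tissue")
  for (col in num) td[[col]] <- as.numeric(td[[col]])
  comp <- td$f_water + td$f_neutral_lipid + td$f_phospholipid + td$f_protein
  if (any(comp > 1 + 1e-9))
    abort("tissue component fractions exceed 1", class = "pbtksim_validation_error")
  if (any(td$vol_frac_BW <= 0))
    abort("tissue volume fractions must be positive", class = "pbtksim_validation_error")
  td
}
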