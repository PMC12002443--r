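# Shared fixtures: small reproducible libraries and reference chemicals.

fixture_library <- function(n = 20, seed = 1, volatile_fraction = 0.2) {
  generate_synthetic_library(n, seed = seed,
                             volatile_fraction = volatile_fraction)
}

# A fully specified neutral reference chemical (non-volatile).
fixture_chem <- function(logP = 2, fup = "0.1", clint = "10",
                         logHenry = -8, MW = 200, ...) {
  utils::modifyList(
    list(dtxsid = "FIX-0001", casrn = "0-00-0", name = "fixture",
         MW = MW, logP = logP, pKa_donor = numeric(0),
         pKa_accept = numeric(0), logHenry = logHenry, caco2_papp = NA_real_,
         Fabs_measured = NA, chem_class = character(0),
         Clint.Human = clint, fup.Human = fup,
         Rblood2plasma.Human = NA_real_),
    list(...))
}

fixture_records <- function() {
  data.frame(
    dtxsid = c("DTX001", "DTX002", "DTX003"),
    casrn = c("50-00-0", "64-17-5", "71-43-2"),
    name = c("alpha", "beta", "gamma"),
    MW = c(100, 200, 300),
    logP = c(1, 2, 3),
    pKa_donor = c(NA, "4.5", NA),
    pKa_accept = c(NA, NA, "9.0"),
    logHenry = c(-8, -7, -6),
    caco2_papp = c(10, NA, 1),
    chem_class = c(NA, NA, "PFAS"),
    Clint.Human = c("13,9.2,16.2,0.0012", "5", "0"),
    fup.Human = c("0.02,0.01,0.05", "0.2", "0"),
    Rblood2plasma.Human = c(0.8, NA, NA),
    stringsAsFactors = FALSE)
}
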