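# Synthetic chemical library generation.
#
# The generator emulates the marginal distributions seen in curated HTTK
# chemical tables: lognormal molecular weights, a broad normal logP,
# logit-normally distributed plasma binding with a small rate of failed
# (recorded-zero) assays, zero-inflated lognormal intrinsic clearance with a
# share of Bayesian 4-tuples, and a bimodal Henry's-law constant separating
# volatile from non-volatile chemicals.

#' Generate a synthetic chemical library
#'
#' Reproducible per `seed`.  Distributions: MW lognormal (median 250 g/mol,
#' geometric SD 1.6); logP Normal(2, 1.5); fup logit-normal with 10% of
#' records stored as 3-tuples and 5% recorded as 0 (failed assay); Clint
#' zero-inflated lognormal (10% structural zeros; median 10 uL/min/10^6
#' cells, geometric SD 3) with 20% stored as 4-tuples; `volatile_fraction`
#' of records draw log10 Henry's-law constants from Uniform(-4, -1)
#' (volatile) and the rest from Uniform(-10, -6); 5% of chemicals are tagged
#' `"PFAS"`.  About 30% of chemicals are monoprotic acids and 30% monobasic;
#' 80% carry a Caco-2 permeability; 20% carry a measured blood:plasma ratio;
#' 30% carry rat-specific in vitro values.
#'
#' @param n Number of chemicals (>= 1).
#' @param seed Integer RNG seed.
#' @param volatile_fraction Fraction of chemicals drawn from the volatile
#'   Henry's-law stratum.
#' @return A [chem_library()].
#' @export
generate_synthetic_library <- function(n, seed = 1, volatile_fraction = 0.2) {
  if (!is_scalar_number(n) || n < 1)
    abort("n must be an integer >= 1", class = "pbtksim_argument_error")
  if (volatile_fraction < 0 || volatile_fraction > 1)
    abort("volatile_fraction must lie in [0, 1]", class = "pbtksim_argument_error")
  n <- as.integer(n)
  with_seed(seed, {
    id <- sprintf("SYN%05d", seq_len(n))
    MW <- stats::rlnorm(n, log(250), log(1.6))
    logP <- stats::rnorm(n, 2, 1.5)
    acid <- stats::runif(n) < 0.3
    base <- !acid & stats::runif(n) < 3 / 7   # ~30% of all chemicals
    pKa_donor <- ifelse(acid, sprintf("%.17g", stats::runif(n, 3, 10)), "")
    pKa_accept <- ifelse(base, sprintf("%.17g", stats::runif(n, 2, 10)), "")
    volatile <- stats::runif(n) < volatile_fraction
    logHenry <- ifelse(volatile, stats::runif(n, -4, -1),
                       stats::runif(n, -10, -6))

    fup_val <- stats::plogis(stats::rnorm(n, stats::qlogis(0.1), 1.5))
    fup_zero <- stats::runif(n) < 0.05
    fup_tuple <- !fup_zero & stats::runif(n) < 0.10
    fup <- character(n)
    for (i in seq_len(n)) {
      fup[i] <- if (fup_zero[i]) "0"
      else if (fup_tuple[i]) {
        l <- stats::plogis(stats::qlogis(fup_val[i]) - 0.6)
        u <- stats::plogis(stats::qlogis(fup_val[i]) + 0.6)
        sprintf("%.6g,%.6g,%.6g", fup_val[i], l, u)
      } else sprintf("%.6g", fup_val[i])
    }

    cl_zero <- stats::runif(n) < 0.10
    cl_val <- ifelse(cl_zero, 0, stats::rlnorm(n, log(10), log(3)))
    cl_tuple <- !cl_zero & stats::runif(n) < 0.20
    clint <- character(n)
    for (i in seq_len(n)) {
      clint[i] <- if (cl_tuple[i]) {
        sprintf("%.6g,%.6g,%.6g,%.4g", cl_val[i], cl_val[i] / 1.5,
                cl_val[i] * 1.5, stats::runif(1, 0, 0.1))
      } else sprintf("%.6g", cl_val[i])
    }

    caco2 <- ifelse(stats::runif(n) < 0.8,
                    10^stats::rnorm(n, 0.5, 0.7), NA_real_)
    rb2p <- ifelse(stats::runif(n) < 0.2, stats::runif(n, 0.7, 1.5), NA_real_)
    has_rat <- stats::runif(n) < 0.3
    pfas <- stats::runif(n) < 0.05

    records <- data.frame(
      dtxsid = id,
      casrn = sprintf("%d-%02d-%d", 100000 + seq_len(n), seq_len(n) %% 100,
                      seq_len(n) %% 10),
      name = paste0("synthchem-", seq_len(n)),
      MW = MW, logP = logP,
      pKa_donor = pKa_donor, pKa_accept = pKa_accept,
      logHenry = logHenry, caco2_papp = caco2,
      Fabs_measured = NA_real_,
      chem_class = ifelse(pfas, "PFAS", ""),
      Clint.Human = clint,
      Clint.Rat = ifelse(has_rat, clint, ""),
      fup.Human = fup,
      fup.Rat = ifelse(has_rat, fup, ""),
      Rblood2plasma.Human = rb2p,
      Rblood2plasma.Rat = NA_real_,
      stringsAsFactors = FALSE
    )
    for (col in c("pKa_donor", "pKa_accept", "chem_class", "Clint.Rat", "fup.Rat"))
      records[[col]][!nzchar(records[[col]])] <- NA
    chem_library(records, sources = sprintf("synthetic(seed=%d)", seed))
  })
}
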