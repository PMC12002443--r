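# Ionization, Schmitt-type partitioning, fup correction, blood:plasma
# cascade, and tissue lumping.

test_that("ionization fractions follow Henderson-Hasselbalch", {
  f <- ionization_fractions(7.4)
  expect_equal(unname(f), c(1, 0, 0, 0))
  # single acid with pKa = pH splits 50/50
  f2 <- ionization_fractions(7.0, pKa_donor = 7.0)
  expect_equal(f2[["neutral"]], 0.5)
  expect_equal(f2[["anion"]], 0.5)
  # acid pKa 4.4 at pH 7.4: anion fraction 1/(1 + 10^(4.4-7.4))
  f3 <- ionization_fractions(7.4, pKa_donor = 4.4)
  expect_equal(f3[["anion"]], 1 / (1 + 10^(4.4 - 7.4)), tolerance = 1e-12)
  expect_gt(f3[["anion"]], 0.999)
})

test_that("ionization fractions sum to 1 and mirror under donor/acceptor swap", {
  set.seed(42)
  for (i in 1:20) {
    pd <- runif(sample(0:2, 1), 2, 12)
    pa <- runif(sample(0:2, 1), 2, 12)
    pH <- runif(1, 1, 13)
    f <- ionization_fractions(pH, pd, pa)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    # swapping donors/acceptors and reflecting pKa about pH mirrors charges
    g <- ionization_fractions(pH, pKa_donor = 2 * pH - pa,
                              pKa_accept = 2 * pH - pd)
    expect_equal(f[["anion"]], g[["cation"]], tolerance = 1e-9)
    expect_equal(f[["cation"]], g[["anion"]], tolerance = 1e-9)
  }
})

test_that("partitioning: water-only tissue gives Kp ~ 1 for a neutral chemical", {
  watery <- data.frame(tissue = "allwater", f_water = 1, f_neutral_lipid = 0,
                       f_phospholipid = 0, f_protein = 0, pH = 7.4,
                       vol_frac_BW = 0.1, flow_frac_QC = 0.1)
  kp <- predict_partitioning_schmitt(logP = 0, fup = 0.5, tissues = watery)
  expect_equal(unname(kp[["allwater"]]), 1, tolerance = 1e-12)
})

test_that("partitioning increases with logP in lipid-rich tissue", {
  td <- load_tissue_data()
  k1 <- predict_partitioning_schmitt(logP = 1, fup = 0.1, tissues = td)
  k3 <- predict_partitioning_schmitt(logP = 3, fup = 0.1, tissues = td)
  expect_gt(k3[["adipose"]], k1[["adipose"]])
  expect_true(all(k1 > 0) && all(k3 > 0))
})

test_that("partitioning matches an independent re-derivation of the component sum", {
  # straight-line re-implementation of the documented formula
  td <- load_tissue_data()
  fup <- 0.1; logP <- 2
  kp <- predict_partitioning_schmitt(logP = 2, fup = fup, tissues = td)
  for (i in seq_len(nrow(td))) {
    t <- td[i, ]
    expected <- t$f_water * 1 +                       # neutral: fn_p = fn_t = 1
      t$f_neutral_lipid * 10^logP +
      t$f_phospholipid * 10^logP * 1 +
      t$f_protein / 0.075 * (1 / fup - 1)
    expect_equal(unname(kp[[t$tissue]]), expected, tolerance = 1e-10)
  }
  # ionized acid: re-derive for one tissue with the ionization terms
  pd <- 5
  liver <- td[td$tissue == "liver", ]
  kpa <- predict_partitioning_schmitt(logP = 2, fup = fup, tissues = liver,
                                      pKa_donor = pd)
  fn_p <- 1 / (1 + 10^(7.4 - pd)); fn_t <- 1 / (1 + 10^(liver$pH - pd))
  expected <- liver$f_water * fn_p / fn_t +
    liver$f_neutral_lipid * 100 * fn_p +
    liver$f_phospholipid * 100 * (fn_p + 0.05 * (1 - fn_p)) +
    liver$f_protein / 0.075 * (1 / fup - 1)
  expect_equal(unname(kpa[["liver"]]), expected, tolerance = 1e-10)
  # calibration applies an affine log10 adjustment per tissue
  cal <- data.frame(tissue = "liver", slope = 0.8, intercept = 0.2)
  kpc <- predict_partitioning_schmitt(logP = 2, fup = fup, tissues = liver,
                                      pKa_donor = pd, calibration = cal)
  expect_equal(log10(unname(kpc[["liver"]])),
               0.2 + 0.8 * log10(expected), tolerance = 1e-10)
  expect_error(predict_partitioning_schmitt(logP = 2, fup = 0,
                                            tissues = liver),
               "default substitution", class = "pbtksim_argument_error")
})

test_that("fup correction shrinks lipophilic binding, is near-identity for hydrophilic", {
  expect_equal(calc_fup_correction(0.3, logP = 2, enabled = FALSE), 0.3)
  expect_equal(calc_fup_correction(0.3, logP = -2), 0.3, tolerance = 1e-3)
  corrected <- calc_fup_correction(0.01, logP = 4)
  expect_lt(corrected, 0.01)
  # oracle: 1 / (Dow * flipid + 1/fup), neutral chemical
  expect_equal(corrected, 1 / (1e4 * 0.0199 + 1 / 0.01), tolerance = 1e-12)
  expect_gt(corrected, 0)
})

test_that("blood:plasma cascade takes the documented branches in order", {
  lib <- chem_library(fixture_records())
  # measured species value wins
  r <- resolve_rblood2plasma(chem_record(lib, "DTX001"), "Human", lib,
                             fup = 0.02, hct = 0.44)
  expect_equal(r$Rb2p, 0.8)
  expect_equal(r$provenance, "measured_species")
  # no measurement: computed from the red-blood-cell Schmitt entry
  ch <- fixture_chem()
  r2 <- resolve_rblood2plasma(ch, "Human", NULL, fup = 0.1, hct = 0.44)
  expect_equal(r2$provenance, "schmitt_computed")
  kp <- predict_partitioning_schmitt(ch, fup = 0.1)
  expect_equal(r2$Rb2p, (1 - 0.44) + 0.44 * kp[["red blood cells"]] * 0.1)
  # hct = 0 collapses to plasma: Rb2p = 1 exactly
  r3 <- resolve_rblood2plasma(ch, "Human", NULL, fup = 0.1, hct = 0)
  expect_equal(r3$Rb2p, 1)
  # no chemistry at all: arithmetic mean of the library's measured values
  bare <- list(dtxsid = "X", MW = 100)
  rec <- fixture_records()
  rec$Rblood2plasma.Human <- c(1.0, 1.5, 2.0)
  lib2 <- chem_library(rec)
  r4 <- resolve_rblood2plasma(bare, "Human", lib2, fup = NULL, hct = 0.44)
  expect_equal(r4$Rb2p, 1.5)
  expect_equal(r4$provenance, "library_average")
  expect_error(resolve_rblood2plasma(bare, "Human", NULL, fup = NULL,
                                     hct = 0.44),
               class = "pbtksim_missing_data_error")
})

test_that("lumping conserves volume, flow and partitioning capacity", {
  td <- load_tissue_data()
  kp <- predict_partitioning_schmitt(logP = 2, fup = 0.1, tissues = td)
  scheme <- list(gut = "gut", liver = "liver", kidney = "kidney",
                 lung = "lung", rest = character(0))
  lump <- lump_tissues(kp, td, scheme)
  keep <- td$tissue != "red blood cells"
  expect_equal(sum(lump$vol_frac_BW), sum(td$vol_frac_BW[keep]))
  expect_equal(sum(lump$flow_frac_QC), sum(td$flow_frac_QC[keep]))
  expect_equal(sum(lump$vol_frac_BW * lump$Kp),
               sum(td$vol_frac_BW[keep] * kp[td$tissue[keep]]))
  # singleton lumps are the identity
  single <- lump_tissues(kp, td, as.list(setNames(td$tissue[keep],
                                                  td$tissue[keep])))
  expect_equal(unname(single$Kp[td$tissue[keep]]),
               unname(kp[td$tissue[keep]]))
  # two-tissue weighted-mean oracle: V = {1, 3}, Kp = {2, 6} -> 5
  toy <- data.frame(tissue = c("a", "b"), f_water = 1, f_neutral_lipid = 0,
                    f_phospholipid = 0, f_protein = 0, pH = 7.4,
                    vol_frac_BW = c(1, 3), flow_frac_QC = c(0.5, 0.5))
  lw <- lump_tissues(c(a = 2, b = 6), toy, list(both = c("a", "b")),
                     exclude = character(0))
  expect_equal(unname(lw$Kp[["both"]]), 5)
  expect_error(lump_tissues(kp, td, list(x = "liver", y = "liver")),
               class = "pbtksim_scheme_error")
})
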