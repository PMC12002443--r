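# Hepatic clearance scaling, oral bioavailability, and full model
# parameterization.

test_that("hepatocyte-assay binding decreases with logP and matches its formula", {
  expect_equal(calc_hep_fu(-3), 1, tolerance = 1e-2)
  expect_lt(calc_hep_fu(4), calc_hep_fu(2))
  # formula oracle at logP = 2, density = 1
  expect_equal(calc_hep_fu(2, assay_density = 1),
               1 / (1 + 10^(0.56 * 2 - 1.41)), tolerance = 1e-12)
  expect_equal(calc_hep_fu(2, assay_density = 0), 1)
})

test_that("well-stirred hepatic clearance saturates at liver blood flow", {
  expect_equal(calc_hep_clearance(0, 0.1, Q_liver = 90)$CLh, 0)
  # flow limit: fup * Clint_w = 100 * Q -> CLh within 1% of Q
  big <- calc_hep_clearance(1e9, 1, Q_liver = 90)
  expect_lt(abs(big$CLh - 90) / 90, 0.01)
  expect_lt(big$CLh, 90)
  # hand computation of the two-stage chain
  h <- calc_hep_clearance(10, 0.1, Q_liver = 90, BW = 70,
                          hepatocellularity = 110, liver_mass_frac = 24.1,
                          fu_hep = 1)
  clint_w <- 10 * 110 * 24.1 * 70 * 60 / 1e6
  expect_equal(h$Clint_whole, clint_w, tolerance = 1e-12)
  expect_equal(h$CLh, 90 * 0.1 * clint_w / (90 + 0.1 * clint_w),
               tolerance = 1e-12)
  expect_error(calc_hep_clearance(10, 0.1, Q_liver = 90, model = "magic"),
               class = "pbtksim_argument_error")
})

test_that("oral bioavailability uses the 1% gut-clearance rule", {
  # Clint = 0 leaves all fractions at 1
  o0 <- calc_oral_bioavailability(fup = 0.1, Clint_w = 0, Q_liver = 90,
                                  Q_gut = 50)
  expect_equal(o0$Fgut, 1)
  expect_equal(o0$Fhep, 1)
  o <- calc_oral_bioavailability(fup = 0.1, Clint_w = 300, Q_liver = 90,
                                 Q_gut = 50, Rb2p = 0.8)
  # gut clearance used is exactly 1% of the scaled hepatic clearance
  expect_equal(o$gut_clint, 0.01 * 300)
  expect_equal(o$Fgut, 50 / (50 + 0.1 * 3))
  expect_equal(o$Fhep, 90 / (90 + 0.1 * 300 / 0.8))
  expect_true(all(c(o$Fabs, o$Fgut, o$Fhep) > 0 &
                  c(o$Fabs, o$Fgut, o$Fhep) <= 1))
  # Caco-2 curve oracle
  ch <- fixture_chem(); ch$caco2_papp <- 5
  oc <- calc_oral_bioavailability(ch, fup = 0.1, Clint_w = 10, Q_liver = 90,
                                  Q_gut = 50)
  expect_equal(oc$Fabs, 1 / (1 + 10^(-(log10(5) - 0.2))), tolerance = 1e-12)
  expect_equal(oc$provenance, "caco2_curve")
  # absent Caco-2: default complete absorption, logged
  od <- calc_oral_bioavailability(fixture_chem(), fup = 0.1, Clint_w = 10,
                                  Q_liver = 90, Q_gut = 50)
  expect_equal(od$Fabs, 1)
  expect_equal(od$provenance, "default_complete_absorption")
})

test_that("parameterization is deterministic and honours the registry contract", {
  ch <- fixture_chem()
  for (m in list_models()) {
    p1 <- parameterize_model(m, ch)
    p2 <- parameterize_model(m, ch)
    expect_identical(unclass(p1)[order(names(p1))],
                     unclass(p2)[order(names(p2))])
    expect_setequal(names(p1), get_model_info(m)$param_names)
    expect_true(all(vapply(p1, is.finite, logical(1))))
  }
})

test_that("a failed binding assay parameterizes with the 0.5% default", {
  ch <- fixture_chem(fup = "0")
  ps <- parameterize_model("pbtk", ch)
  expect_equal(ps[["fup"]], 0.005)
  expect_true(attr(ps, "provenance")$fup_defaulted)
  expect_error(parameterize_model("pbtk", ch, substitute_fup_zero = FALSE),
               class = "pbtksim_eligibility_error")
})

test_that("flows and filtration scale allometrically with BW^0.75", {
  ch <- fixture_chem()
  phys <- load_physiology()
  ps1 <- parameterize_model("pbtk", ch, physiology = phys)
  phys2 <- phys
  s <- 2
  phys2$BW[phys2$species == "Human"] <- phys$BW[phys$species == "Human"] * s
  ps2 <- parameterize_model("pbtk", ch, physiology = phys2)
  for (q in c("Qcardiac", "Qgut", "Qliver", "Qkidney", "Qgfr"))
    expect_equal(ps2[[q]] / ps1[[q]], s^0.75, tolerance = 1e-12)
  for (v in c("Vgut", "Vliver", "Vrest", "Vven"))
    expect_equal(ps2[[v]] / ps1[[v]], s, tolerance = 1e-12)
})

test_that("gas parameterization derives blood:air partitioning from Henry's law", {
  # arithmetic oracle: HLC = 1e-2 atm m^3/mol at 310 K
  ch <- fixture_chem(logHenry = -2)
  phys <- load_physiology()
  phys$body_temperature[phys$species == "Human"] <- 310
  ps <- parameterize_model("gas_pbtk", ch, physiology = phys)
  expect_equal(ps[["Kwater2air"]], 1e-2 / (8.2057e-5 * 310),
               tolerance = 1e-4)
  expect_equal(round(ps[["Kwater2air"]], 3), 0.393)
  # doubling the Henry's law constant halves Kblood2air
  ch2 <- fixture_chem(logHenry = -2 + log10(2))
  ps2 <- parameterize_model("gas_pbtk", ch2, physiology = phys)
  expect_equal(ps2[["Kblood2air"]] / ps[["Kblood2air"]], 0.5,
               tolerance = 1e-9)
  # missing Henry's law constant is an eligibility error
  chx <- fixture_chem(); chx$logHenry <- NA
  expect_error(parameterize_model("gas_pbtk", chx),
               class = "pbtksim_eligibility_error")
  # non-volatile limit flagged as out of domain
  expect_warning(parameterize_model("gas_pbtk", fixture_chem(logHenry = -9)),
                 "out of the gas model's domain")
})

test_that("CLh stays below liver flow and bioavailability stays in (0, 1]", {
  lib <- fixture_library(15, seed = 3)
  elig <- get_cheminfo(lib, model = "3compartmentss")
  for (id in head(elig$dtxsid, 8)) {
    ps <- parameterize_model("3compartmentss", id, lib = lib)
    expect_lt(ps[["CLh"]], ps[["Qliver_total"]])
    F <- ps[["Fabs"]] * ps[["Fgut"]] * ps[["Fhep"]]
    expect_true(F > 0 && F <= 1)
  }
})
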