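# Chemical library: tuple parsing, loading, merging, eligibility filtering,
# and the synthetic generator.

test_that("uncertainty tuples parse with median-first ordering", {
  uv <- parse_uncertainty_tuple("13,9.2,16.2,0.0012", "clint")
  expect_equal(uv$point, 13)
  expect_equal(uv$l95, 9.2)
  expect_equal(uv$u95, 16.2)
  expect_equal(uv$p_no_effect, 0.0012)
  f <- parse_uncertainty_tuple("0.02,0.01,0.05", "fup")
  expect_equal(f$point, 0.02)
  expect_equal(f$l95, 0.01)
  expect_equal(f$u95, 0.05)
  p <- parse_uncertainty_tuple("0.02", "fup")
  expect_equal(p$point, 0.02)
  expect_true(is.na(p$l95))
  expect_error(parse_uncertainty_tuple("1,2,0.5,0.1", "clint"),
               class = "pbtksim_validation_error")
  expect_error(parse_uncertainty_tuple("1,2", "fup"),
               class = "pbtksim_parse_error")
  expect_error(parse_uncertainty_tuple("1,2,3", "clint"),
               class = "pbtksim_parse_error")
})

test_that("format/parse round-trips every valid uncertain value", {
  cases <- list(uncertain_value(13, 9.2, 16.2, 0.0012),
                uncertain_value(0.5),
                uncertain_value(0.02, 0.011, 0.047),
                uncertain_value(1e-7, 1e-8, 1e-6, 0.99))
  for (uv in cases) {
    kind <- if (!is.na(uv$p_no_effect) || uv$point > 1) "clint" else "fup"
    back <- parse_uncertainty_tuple(format_uncertainty_tuple(uv), kind)
    expect_equal(back, uv)
  }
})

test_that("load/write round trip preserves every field bit-for-bit", {
  lib <- chem_library(fixture_records(), sources = "unit-test")
  path <- withr::local_tempfile(fileext = ".csv")
  write_chem_library(lib, path)
  lib2 <- load_chem_library(path)
  expect_identical(lib$records, lib2$records)
})

test_that("loading validates schema and row-level numerics", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- fixture_records()
  write.csv(rec[, setdiff(names(rec), "MW")], path, row.names = FALSE)
  expect_error(load_chem_library(path), "MW",
               class = "pbtksim_schema_error")
  rec2 <- fixture_records()
  rec2$MW <- as.character(rec2$MW)
  rec2$MW[2] <- "abc"
  write.csv(rec2, path, row.names = FALSE)
  expect_error(load_chem_library(path), "row 2",
               class = "pbtksim_validation_error")
  # dialect maps foreign headers onto the canonical layout
  rec3 <- fixture_records()
  names(rec3)[names(rec3) == "MW"] <- "MolWeight"
  write.csv(rec3, path, row.names = FALSE)
  lib3 <- load_chem_library(path, dialect = c(MW = "MolWeight"))
  expect_equal(lib3$records$MW, fixture_records()$MW)
})

test_that("add_chemtable performs field-level merge with precedence", {
  lib <- chem_library(fixture_records()[1, ])
  newrec <- data.frame(dtxsid = c("DTX001", "DTX999"), MW = c(100, 42),
                       logP = c(1.5, 0.3), fup.Human = c(NA, "0.5"),
                       stringsAsFactors = FALSE)
  merged <- add_chemtable(lib, newrec, precedence = "overwrite",
                          source = "study-X")
  expect_equal(length(merged), 2L)
  r1 <- merged$records[merged$records$dtxsid == "DTX001", ]
  expect_equal(r1$logP, 1.5)                          # overwritten
  expect_equal(r1$fup.Human, "0.02,0.01,0.05")        # gap not clobbered
  expect_match(merged$records$ref.logP[1], "study-X")
  # keep_existing logs a warning on conflict and keeps the old value
  expect_warning(
    kept <- add_chemtable(lib, data.frame(dtxsid = "DTX001", MW = 101),
                          precedence = "keep_existing"),
    "keep_existing")
  expect_equal(kept$records$MW[1], 100)
  # disjoint ids union cleanly
  disjoint <- add_chemtable(lib, data.frame(dtxsid = "DTX777", MW = 50))
  expect_equal(length(disjoint), 2L)
})

test_that("get_param falls back to human values with provenance", {
  lib <- chem_library(fixture_records())
  r <- get_param(lib, "DTX002", "Clint", species = "Rat",
                 default_to_human = TRUE)
  expect_equal(r$value$point, 5)
  expect_equal(r$provenance, "human-default")
  expect_error(get_param(lib, "DTX002", "Clint", species = "Rat",
                         default_to_human = FALSE),
               class = "pbtksim_missing_data_error")
  expect_error(get_param(lib, "DTX002", "Rblood2plasma"),
               class = "pbtksim_missing_data_error")
  # id aliases resolve through casrn and name
  expect_equal(get_chem_id(lib, "64-17-5")$dtxsid, "DTX002")
  expect_equal(get_chem_id(lib, "gamma")$dtxsid, "DTX003")
})

test_that("get_cheminfo applies data requirements and exclusion filters", {
  rec <- fixture_records()
  rec$logHenry <- c(-8, -7, -6)      # all below the volatility threshold
  lib <- chem_library(rec)
  # missing Clint drops a chemical
  rec2 <- rec; rec2$Clint.Human[2] <- NA
  lib2 <- chem_library(rec2)
  expect_equal(nrow(get_cheminfo(lib2, model = "3compartmentss")), 2L)
  # fup == 0 retained but flagged when exclude_fup_zero = FALSE
  out <- get_cheminfo(lib, model = "3compartmentss",
                      exclude_fup_zero = FALSE)
  expect_true("DTX003" %in% out$dtxsid)
  expect_true(out$fup_defaulted[out$dtxsid == "DTX003"])
  out2 <- get_cheminfo(lib, model = "3compartmentss",
                       exclude_fup_zero = TRUE)
  expect_false("DTX003" %in% out2$dtxsid)
  # PFAS-tagged chemical excluded from the gas model's domain
  rec3 <- rec; rec3$logHenry <- c(-3, -2, -2.5)
  lib3 <- chem_library(rec3)
  gas <- get_cheminfo(lib3, model = "gas_pbtk")
  expect_false("DTX003" %in% gas$dtxsid)   # PFAS filtered
  # volatile chemicals excluded from liquid-only models
  liq <- get_cheminfo(lib3, model = "pbtk")
  expect_equal(nrow(liq), 0L)
  expect_error(get_cheminfo(lib, model = "no-such-model"),
               class = "pbtksim_registry_error")
  expect_error(get_cheminfo(lib, info = "not_a_field"),
               class = "pbtksim_validation_error")
})

test_that("eligibility is monotone: more requirements never enlarge the set", {
  lib <- fixture_library(40, seed = 5)
  n_ss <- nrow(get_cheminfo(lib, model = "3compartmentss"))
  n_gas <- nrow(get_cheminfo(lib, model = "gas_pbtk"))
  # gas adds logHenry requirement + PFAS filter on top of the same base
  expect_lte(nrow(get_cheminfo(lib, model = "pbtk")), n_ss)
  expect_lte(n_gas, length(lib))
  expect_lte(n_ss, length(lib))
})

test_that("synthetic library is reproducible and respects volatile_fraction", {
  a <- generate_synthetic_library(10, seed = 1)
  b <- generate_synthetic_library(10, seed = 1)
  expect_identical(a$records, b$records)
  big <- generate_synthetic_library(1000, seed = 2, volatile_fraction = 0.1)
  frac <- mean(big$records$logHenry > -4.5)
  # binomial oracle: 0.1 +/- 3 * sqrt(0.1*0.9/1000)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
  expect_error(generate_synthetic_library(0),
               class = "pbtksim_argument_error")
  # ~5% recorded-zero fup
  zeros <- mean(big$records$fup.Human == "0")
  expect_lt(abs(zeros - 0.05), 0.03)
})
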