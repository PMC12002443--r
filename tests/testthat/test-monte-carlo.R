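# Four-step Monte Carlo sampling and its endpoints.

test_that("truncated/censored sampling has the right moments and censoring", {
  x <- sample_censored_truncated(10, cv = 1e-9, n = 50, seed = 1)
  expect_equal(x, rep(10, 50))
  # mean recovery within 3 SE at n = 1e4 (truncation negligible at cv 0.2)
  x2 <- sample_censored_truncated(10, cv = 0.2, n = 1e4, seed = 2)
  expect_lt(abs(mean(x2) - 10), 3 * 2 / sqrt(1e4))
  expect_true(all(x2 > 0))
  # saturating LOD: every draw censored into [0, lod)
  x3 <- sample_censored_truncated(1, cv = 0.1, lod = 10, n = 500, seed = 3)
  expect_true(all(x3 >= 0 & x3 < 10))
  expect_error(sample_censored_truncated(1, cv = 0, n = 10),
               class = "pbtksim_argument_error")
})

test_that("population sampler hits its medians and is human-only", {
  spec <- population_spec("Human")
  d <- sample_population_physiology("Human", spec, n = 1e4, seed = 4)
  expect_lt(abs(median(d$BW) / spec$median[["BW"]] - 1), 0.02)
  expect_lt(abs(median(d$QC) / spec$median[["QC"]] - 1), 0.02)
  # zero variance returns the reference individual
  spec0 <- spec
  spec0$cv[] <- 1e-12
  d0 <- sample_population_physiology("Human", spec0, n = 5, seed = 5)
  expect_equal(d0$BW, rep(spec$reference$BW, 5), tolerance = 1e-9)
  expect_error(sample_population_physiology("Rat", n = 10),
               "non-human", class = "pbtksim_argument_error")
  # correlated draws: BW and QC share the copula correlation sign
  expect_gt(cor(log(d$BW), log(d$QC), method = "spearman"), 0.2)
})

test_that("in vitro sampling honours tuples, zero-inflation and bounds", {
  cfg <- mc_config(n = 10)
  # p_no_effect = 1: all Clint draws are zero
  ch1 <- fixture_chem(clint = "10,8,12,1")
  iv1 <- sample_invitro_uv(ch1, cfg, n = 200, seed = 6)
  expect_true(all(iv1$Clint == 0))
  # quantile-matched lognormal: median and 95% bounds recovered at n = 1e5
  # (bounds geometrically symmetric about the median, as the matched
  # two-parameter lognormal assumes)
  u95 <- 13^2 / 9.2
  ch2 <- fixture_chem(clint = sprintf("13,9.2,%.6f,0", u95))
  iv2 <- sample_invitro_uv(ch2, cfg, n = 1e5, seed = 7)
  expect_lt(abs(median(iv2$Clint) / 13 - 1), 0.02)
  expect_lt(abs(quantile(iv2$Clint, 0.025) / 9.2 - 1), 0.05)
  expect_lt(abs(quantile(iv2$Clint, 0.975) / u95 - 1), 0.05)
  # fup tuple: median recovered, all draws in (0, 1]
  ch3 <- fixture_chem(fup = "0.02,0.01,0.05")
  iv3 <- sample_invitro_uv(ch3, cfg, n = 1e5, seed = 8)
  expect_true(all(iv3$fup > 0 & iv3$fup <= 1))
  expect_lt(abs(median(iv3$fup) / 0.02 - 1), 0.03)
})

test_that("sample table is degenerate without variance and reproducible with it", {
  ch <- fixture_chem(clint = "10,7,14,0.02", fup = "0.1,0.06,0.17")
  cfg0 <- mc_config(n = 6, seed = 9, invitrouv = FALSE)
  tab <- create_mc_samples("pbtk", ch, config = cfg0)
  bl <- attr(tab, "baseline")
  for (nm in names(bl)) expect_equal(tab[[nm]], rep(bl[[nm]], 6))
  cfg <- mc_config(n = 40, seed = 10, httkpop = TRUE, invitrouv = TRUE)
  t1 <- create_mc_samples("pbtk", ch, config = cfg)
  t2 <- create_mc_samples("pbtk", ch, config = cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # provenance tags record the step that last touched each parameter
  prov <- attr(t1, "provenance")
  expect_equal(unname(prov[["fup"]]), "invitro")
  expect_equal(unname(prov[["BW"]]), "pop")
  expect_equal(unname(prov[["Clint_whole"]]), "recalc")
  # a step-1 parameter overwritten later triggers the warning
  expect_warning(create_mc_samples("pbtk", ch,
                                   config = mc_config(n = 4, seed = 1,
                                                      vary_params = c(fup = 0.2),
                                                      invitrouv = TRUE)),
                 "overwritten")
})

test_that("calcpc recalculates partition coefficients from each individual's fup", {
  ch <- fixture_chem(fup = "0.1,0.06,0.17")
  cfg <- mc_config(n = 10, seed = 11, invitrouv = TRUE)
  tab <- create_mc_samples("pbtk", ch, config = cfg)
  td <- load_tissue_data()
  scheme <- list(gut = "gut", liver = "liver", kidney = "kidney",
                 lung = "lung", rest = character(0))
  for (i in seq_len(nrow(tab))) {
    kp <- predict_partitioning_schmitt(ch, fup = tab$fup[i], tissues = td)
    lump <- lump_tissues(kp, td, scheme)
    expect_equal(tab$Kp.liver[i], unname(lump$Kp[["liver"]]),
                 tolerance = 1e-12)
    expect_equal(tab$Kp.rest[i], unname(lump$Kp[["rest"]]),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance MC endpoints equal their deterministic counterparts exactly", {
  ch <- fixture_chem()
  cfg0 <- mc_config(n = 7, seed = 12, invitrouv = FALSE)
  for (m in c("1compartment", "3compartmentss", "pbtk")) {
    a <- calc_analytic_css(m, ch)
    mc <- calc_mc_css(m, ch, config = cfg0)
    expect_identical(unname(mc[[1]]), a)
    expect_identical(attr(mc, "median"), a)
  }
})

test_that("Css quantiles are monotone and the 95th bounds the median", {
  ch <- fixture_chem(clint = "10,5,20,0.05", fup = "0.1,0.05,0.2")
  cfg <- mc_config(n = 300, seed = 13, quantiles = c(0.25, 0.5, 0.75, 0.95),
                   httkpop = TRUE)
  mc <- calc_mc_css("3compartmentss", ch, config = cfg)
  expect_true(all(diff(mc) >= 0))
  expect_gte(mc[["q95"]], mc[["q50"]])
})

test_that("reverse dosimetry inverts the dose-Css relationship", {
  ch <- fixture_chem()
  cfg0 <- mc_config(n = 5, seed = 14, invitrouv = FALSE, quantiles = 0.5)
  a <- calc_analytic_css("3compartmentss", ch)
  oe <- calc_mc_oral_equiv(a, "3compartmentss", ch, config = cfg0)
  expect_equal(unname(oe[[1]]), 1, tolerance = 1e-12)
  oe2 <- calc_mc_oral_equiv(2 * a, "3compartmentss", ch, config = cfg0)
  expect_equal(unname(oe2[[1]]), 2, tolerance = 1e-12)
  # higher Css quantile -> lower equivalent dose
  cfg <- mc_config(n = 300, seed = 15, quantiles = c(0.5, 0.95))
  oeq <- calc_mc_oral_equiv(1, "3compartmentss", ch, config = cfg)
  expect_lte(oeq[["q95"]], oeq[["q50"]])
  expect_error(calc_mc_oral_equiv(0, "3compartmentss", ch),
               class = "pbtksim_argument_error")
})

test_that("calc_mc_tk reports per-time means and degenerates correctly", {
  ch <- fixture_chem()
  tt <- seq(0, 1, 0.25)
  reg <- dose_regimen(initial_dose = 1)
  cfg0 <- mc_config(n = 3, seed = 16, invitrouv = FALSE)
  mt <- calc_mc_tk("pbtk", ch, config = cfg0, times = tt, regimen = reg)
  single <- solve_model("pbtk",
                        params = attr(create_mc_samples("pbtk", ch,
                                                        config = cfg0),
                                      "baseline"),
                        times = tt, regimen = reg, monitor_vars = "Cplasma")
  expect_equal(unname(mt$mean[, "Cplasma"]), single$Cplasma,
               tolerance = 1e-12)
  expect_true(all(mt$sd == 0))
  # n = 1: mean is that solve, sd reported as 0 with the flag set
  m1 <- calc_mc_tk("pbtk", ch, config = mc_config(n = 1, seed = 17,
                                                  invitrouv = FALSE),
                   times = tt, regimen = reg)
  expect_true(m1$single_draw)
  expect_true(all(m1$sd == 0))
  # with variance the spread is nonzero
  mv <- calc_mc_tk("pbtk", ch,
                   config = mc_config(n = 10, seed = 18, httkpop = TRUE),
                   times = tt, regimen = reg)
  expect_gt(max(mv$sd), 0)
  expect_equal(mv$n_ok, 10)
})
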