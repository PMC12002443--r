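# Model registry, contract validation, derivatives, solving, events and
# mass balance.

test_that("registry lists the built-in suite and rejects duplicates", {
  expect_setequal(list_models(),
                  c("1compartment", "3compartmentss", "pbtk", "gas_pbtk"))
  info <- get_model_info("pbtk")
  expect_s3_class(info, "model_info")
  expect_error(register_model(info), class = "pbtksim_registry_error")
})

test_that("validation passes all built-ins and catches output permutations", {
  for (m in list_models()) {
    v <- validate_model(m)
    expect_true(v$ok, info = m)
  }
  # permute two derivative output names -> ordering failure detected
  for (m in c("1compartment", "pbtk", "gas_pbtk")) {
    info <- get_model_info(m)
    k <- length(info$derivative_output_names)
    set.seed(7)
    perms <- list(c(2, 1, 3:k), c(1:(k - 2), k, k - 1),
                  sample(seq_len(k)))
    for (pm in perms) {
      if (identical(pm, seq_len(k))) next
      bad <- info
      bad$derivative_output_names <- info$derivative_output_names[pm]
      register_model(bad, overwrite = TRUE)
      v <- validate_model(m)
      expect_false(v$ok, info = m)
      expect_match(paste(v$failures, collapse = " "), "ordering")
      register_model(info, overwrite = TRUE)
    }
  }
  # output missing from the unit declaration -> unit-audit failure
  info <- get_model_info("pbtk")
  bad <- info
  bad$compartment_units <- info$compartment_units[-1]
  register_model(bad, overwrite = TRUE)
  v <- validate_model("pbtk")
  expect_false(v$ok)
  expect_match(paste(v$failures, collapse = " "), "unit")
  register_model(info, overwrite = TRUE)
})

test_that("derivatives vanish at the origin and conserve a closed system", {
  ps <- parameterize_model("pbtk", fixture_chem())
  info <- get_model_info("pbtk")
  z <- setNames(rep(0, length(info$state_vars)), info$state_vars)
  d0 <- evaluate_derivative("pbtk", 0, z, ps)
  expect_true(all(d0$dstate == 0))
  # closed system: no elimination, full absorption -> total amount conserved
  closed <- ps
  closed[["Clint_whole"]] <- 0
  closed[["Qgfr"]] <- 0
  closed[["Fabs"]] <- 1; closed[["Fgut"]] <- 1
  set.seed(1)
  y <- setNames(runif(length(info$state_vars), 0, 5), info$state_vars)
  d <- evaluate_derivative("pbtk", 0, y, closed)
  body <- setdiff(info$state_vars, c("AUC"))
  expect_equal(sum(d$dstate[body]), 0, tolerance = 1e-10)
  expect_error(evaluate_derivative("pbtk", 0, y[-1], ps))
  expect_error(evaluate_derivative("pbtk", 0, replace(y, 1, NaN), ps))
})

test_that("pbtk derivative matches an independently coded perfusion-limited RHS", {
  ps <- parameterize_model("pbtk", fixture_chem(logP = 1.5, fup = "0.2"))
  info <- get_model_info("pbtk")
  set.seed(99)
  y <- setNames(runif(length(info$state_vars), 0.1, 10), info$state_vars)
  d <- evaluate_derivative("pbtk", 0, y, ps)
  p <- as.list(ps); names(p) <- names(ps)
  # textbook re-derivation, written independently of the model code
  conc <- function(a, v) a / v
  vout <- function(ct, kp) ct * p$Rblood2plasma / (kp * p$fup)
  Cart <- conc(y[["Aart"]], p$Vart); Cven <- conc(y[["Aven"]], p$Vven)
  cv <- c(gut = vout(conc(y[["Agut"]], p$Vgut), p$Kp.gut),
          liver = vout(conc(y[["Aliver"]], p$Vliver), p$Kp.liver),
          kidney = vout(conc(y[["Akidney"]], p$Vkidney), p$Kp.kidney),
          lung = vout(conc(y[["Alung"]], p$Vlung), p$Kp.lung),
          rest = vout(conc(y[["Arest"]], p$Vrest), p$Kp.rest))
  abs_in <- p$kgutabs * y[["Agutlumen"]]
  expected <- c(
    -abs_in,
    abs_in * p$Fabs * p$Fgut + p$Qgut * (Cart - cv[["gut"]]),
    p$Qliver * Cart + p$Qgut * cv[["gut"]] -
      (p$Qliver + p$Qgut) * cv[["liver"]] -
      p$Clint_whole * conc(y[["Aliver"]], p$Vliver) / p$Kp.liver,
    p$Qkidney * (Cart - cv[["kidney"]]) -
      p$Qgfr * p$fup * Cart / p$Rblood2plasma,
    p$Qcardiac * (Cven - cv[["lung"]]),
    p$Qrest * (Cart - cv[["rest"]]),
    p$Qcardiac * cv[["lung"]] - p$Qcardiac * Cart,
    (p$Qliver + p$Qgut) * cv[["liver"]] + p$Qkidney * cv[["kidney"]] +
      p$Qrest * cv[["rest"]] - p$Qcardiac * Cven,
    p$Qgfr * p$fup * Cart / p$Rblood2plasma,
    p$Clint_whole * conc(y[["Aliver"]], p$Vliver) / p$Kp.liver,
    abs_in * (1 - p$Fabs * p$Fgut),
    Cven / p$Rblood2plasma)
  expect_equal(unname(d$dstate), unname(expected), tolerance = 1e-10)
})

test_that("1-compartment iv bolus matches the closed form to 0.1%", {
  ps <- parameterize_model("1compartment", fixture_chem())
  tt <- seq(0, 2, 0.05)
  r <- solve_model("1compartment", params = ps, times = tt,
                   regimen = dose_regimen(route = "iv", initial_dose = 1),
                   rtol = 1e-8)
  dose_umol <- 1 * ps[["BW"]] * 1000 / ps[["MW"]]
  cf <- dose_umol / (ps[["Vdist"]] * ps[["BW"]]) * exp(-ps[["kelim"]] * tt)
  expect_lt(max(abs(r$Ccompartment / cf - 1)), 1e-3)
})

test_that("zero dose gives zero everywhere; linear kinetics double with dose", {
  ps <- parameterize_model("pbtk", fixture_chem())
  tt <- seq(0, 1, 0.1)
  r0 <- solve_model("pbtk", params = ps, times = tt,
                    regimen = dose_regimen(initial_dose = 0))
  expect_true(all(as.matrix(r0[-1]) == 0))
  r1 <- solve_model("pbtk", params = ps, times = tt,
                    regimen = dose_regimen(initial_dose = 1))
  r2 <- solve_model("pbtk", params = ps, times = tt,
                    regimen = dose_regimen(initial_dose = 2))
  nz <- r1$Cplasma > 0
  expect_lt(max(abs(r2$Cplasma[nz] / r1$Cplasma[nz] - 2)), 1e-6)
})

test_that("dosing times are integrated over but only requested times returned", {
  ps <- parameterize_model("pbtk", fixture_chem())
  reg <- dose_regimen(dosing_matrix = data.frame(time = c(0, 0.33),
                                                 dose = c(1, 1)))
  tt <- c(0, 0.5, 1)
  r <- solve_model("pbtk", params = ps, times = tt, regimen = reg)
  expect_equal(r$time, tt)          # 0.33 integrated, not reported
  # the dose at 0.33 is visible in the 0.5 sample
  r_single <- solve_model("pbtk", params = ps, times = tt,
                          regimen = dose_regimen(initial_dose = 1))
  expect_gt(r$Cplasma[2], r_single$Cplasma[2])
  # unsupported route errors with the model's routes named
  expect_error(solve_model("pbtk", params = ps, times = tt,
                           regimen = dose_regimen(route = "inhalation",
                                                  forcing_series = data.frame(
                                                    time = 0, value = 1))),
               "oral", class = "pbtksim_argument_error")
})

test_that("mass balance holds to 1e-6 across randomized regimens for all built-ins", {
  lib <- fixture_library(10, seed = 21)
  set.seed(77)
  for (m in c("1compartment", "pbtk", "gas_pbtk")) {
    elig <- get_cheminfo(lib, model = m)
    skip_if(nrow(elig) == 0)
    id <- elig$dtxsid[1]
    params <- suppressWarnings(parameterize_model(m, id, lib = lib))
    for (k in 1:3) {
      route <- sample(c("oral", "iv"), 1)
      reg <- if (k == 1)
        dose_regimen(route = route, initial_dose = runif(1, 0.5, 5))
      else if (k == 2)
        dose_regimen(route = route, daily_dose = runif(1, 0.5, 3),
                     doses_per_day = sample(1:4, 1),
                     input_units = "mg/kg/day")
      else
        dose_regimen(route = route,
                     dosing_matrix = data.frame(time = sort(runif(3, 0, 2)),
                                                dose = runif(3, 0.1, 2)))
      r <- solve_model(m, params = params, times = seq(0, 3, 0.25),
                       regimen = reg, rtol = 1e-10, atol = 1e-12)
      mb <- check_mass_balance(r)
      expect_lt(mb$max_defect, 1e-6)
    }
  }
})

test_that("corrupting a compartment column is flagged by the mass balance check", {
  ps <- parameterize_model("pbtk", fixture_chem())
  r <- solve_model("pbtk", params = ps, times = seq(0, 1, 0.25),
                   regimen = dose_regimen(initial_dose = 1),
                   rtol = 1e-10, atol = 1e-12)
  expect_true(check_mass_balance(r)$pass)
  bad <- r
  bad$Aliver <- bad$Aliver + 1
  mb <- check_mass_balance(bad)
  expect_false(mb$pass)
  expect_equal(mb$max_defect, 1 / attr(r, "administered"), tolerance = 1e-6)
  # refusing to check when accumulators are not monitored
  partial <- solve_model("pbtk", params = ps, times = seq(0, 1, 0.5),
                         regimen = dose_regimen(initial_dose = 1),
                         monitor_vars = "Cplasma")
  expect_error(check_mass_balance(partial), "accumulator")
})

test_that("solver tolerance refinement converges", {
  ps <- parameterize_model("pbtk", fixture_chem())
  tt <- seq(0, 2, 0.25)
  reg <- dose_regimen(initial_dose = 1)
  coarse <- solve_model("pbtk", params = ps, times = tt, regimen = reg,
                        rtol = 1e-6, atol = 1e-12)
  fine <- solve_model("pbtk", params = ps, times = tt, regimen = reg,
                      rtol = 1e-7, atol = 1e-13)
  nz <- fine$Cplasma > 0
  expect_lt(max(abs(coarse$Cplasma[nz] / fine$Cplasma[nz] - 1)), 1e-6)
})

test_that("gas model with zero exposure reproduces pbtk oral kinetics", {
  ch <- fixture_chem(logHenry = -8)   # effectively non-volatile
  pp <- parameterize_model("pbtk", ch)
  gp <- suppressWarnings(parameterize_model("gas_pbtk", ch))
  tt <- seq(0, 3, 0.1)
  reg <- dose_regimen(route = "oral", initial_dose = 1)
  r1 <- solve_model("pbtk", params = pp, times = tt, regimen = reg)
  r2 <- solve_model("gas_pbtk", params = gp, times = tt, regimen = reg)
  expect_lt(max(abs(r2$Cplasma[-1] / r1$Cplasma[-1] - 1)), 0.02)
})

test_that("gas model inhalation run conserves mass and reports exhaled air in both units", {
  ch <- fixture_chem(logHenry = -2)
  gp <- parameterize_model("gas_pbtk", ch)
  reg <- dose_regimen(route = "inhalation",
                      forcing_series = data.frame(time = c(0, 0.25),
                                                  value = c(10, 0)),
                      forcing_units = "ppmv")
  r <- solve_model("gas_pbtk", params = gp, times = seq(0, 1, 0.05),
                   regimen = reg, rtol = 1e-10, atol = 1e-12)
  expect_lt(check_mass_balance(r)$max_defect, 1e-6)
  expect_gt(max(r$Cplasma), 0)
  # exhaled breath is reported in both ppmv and uM, consistently
  nz <- r$Cexh > 0
  expect_equal(r$Cexh_ppmv[nz] / r$Cexh[nz],
               rep(0.0820573 * gp[["body_temperature"]], sum(nz)),
               tolerance = 1e-9)
})
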