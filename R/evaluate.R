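# Model-evaluation statistics and the benchmark suite.
#
# The headline concordance statistic is the root mean squared error on the
# log10 scale (RMSLE) between predicted and observed concentrations.  When
# chemicals contribute very different numbers of observations, the squared
# log-errors are first averaged within each chemical and then across
# chemicals, so data-rich chemicals do not dominate.

#' Root mean squared log10 error
#'
#' `sqrt(mean((log10(pred) - log10(obs))^2))`.  With
#' `per_chemical_first = TRUE` the mean squared log-error is computed within
#' each chemical first, then averaged across chemicals before the root.
#'
#' @param pred,obs Positive numeric vectors of equal length.
#' @param per_chemical_first Average within chemicals before across.
#' @param chem_ids Chemical id per observation (required for
#'   `per_chemical_first`).
#' @param floor Optional positive floor applied to both vectors before the
#'   log transform (e.g. LOQ/2); without it a nonpositive value is an error.
#' @return RMSLE in log10 units (>= 0; 1 means a typical 10-fold error).
#' @export
rmsle <- function(pred, obs, per_chemical_first = FALSE, chem_ids = NULL,
                  floor = NULL) {
  stopifnot(length(pred) == length(obs))
  if (!is.null(floor)) {
    pred <- pmax(pred, floor); obs <- pmax(obs, floor)
  }
  if (any(pred <= 0) || any(obs <= 0))
    abort("nonpositive concentration without a floor; supply `floor` (e.g. LOQ/2)",
          class = "pbtksim_argument_error")
  sq <- (log10(pred) - log10(obs))^2
  if (!per_chemical_first) return(sqrt(mean(sq)))
  if (is.null(chem_ids) || length(chem_ids) != length(pred))
    abort("per_chemical_first requires chem_ids of matching length",
          class = "pbtksim_argument_error")
  sqrt(mean(tapply(sq, chem_ids, mean)))
}

#' Total explained variance (predicted vs observed)
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`, optionally on the
#' log10 scale.  Unlike the R^2 of a regression of observations on
#' predictions, this is negative when the model predicts worse than the
#' observed mean.
#'
#' @param pred,obs Numeric vectors (positive when `log_scale`).
#' @param log_scale Compute on log10-transformed values.
#' @return Explained variance (<= 1, possibly negative).
#' @export
r2_explained_variance <- function(pred, obs, log_scale = FALSE) {
  stopifnot(length(pred) == length(obs))
  if (length(obs) < 2L)
    abort("at least 2 observations required", class = "pbtksim_argument_error")
  if (log_scale) {
    if (any(pred <= 0) || any(obs <= 0))
      abort("log-scale explained variance requires positive values",
            class = "pbtksim_argument_error")
    pred <- log10(pred); obs <- log10(obs)
  }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    abort("observations have zero variance; explained variance undefined",
          class = "pbtksim_argument_error")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Generate synthetic concentration-vs-time observations
#'
#' Simulates randomized exposure conditions (chemical, route, dose, and
#' observation times) with the model itself and perturbs the predictions
#' with multiplicative lognormal noise of the requested log10 standard
#' deviation, emulating the schema of an in vivo concentration-vs-time
#' database.  Reproducible per seed.
#'
#' @param lib A [chem_library()].
#' @param model Solve-capable registered model.
#' @param n_conditions Number of experimental conditions.
#' @param noise_sd_log10 SD of the multiplicative noise in log10 units.
#' @param seed RNG seed.
#' @param species Species simulated.
#' @param obs_per_condition Observations per condition.
#' @return Data.frame with columns `dtxsid`, `species`, `route`, `dose`
#'   (mg/kg), `dose_units`, `time_h`, `conc` (uM), `conc_units`, `medium`,
#'   `study_id`.
#' @export
generate_synthetic_observations <- function(lib, model = "pbtk",
                                            n_conditions = 50,
                                            noise_sd_log10 = 0.3, seed = 1,
                                            species = "Human",
                                            obs_per_condition = 4) {
  eligible <- get_cheminfo(lib, model = model, species = species)
  if (!nrow(eligible))
    abort("no chemical in the library is eligible for this model",
          class = "pbtksim_eligibility_error")
  info <- get_model_info(model)
  routes <- intersect(names(info$routes), c("oral", "iv"))
  with_seed(seed, {
    rows <- vector("list", n_conditions)
    for (k in seq_len(n_conditions)) {
      id <- sample(eligible$dtxsid, 1)
      route <- sample(routes, 1)
      dose <- stats::runif(1, 0.1, 10)
      obs_t <- sort(stats::runif(obs_per_condition, 0.02, 2))
      params <- parameterize_model(model, id, species = species, lib = lib)
      res <- solve_model(model, params = params,
                         times = c(0, obs_t),
                         regimen = dose_regimen(route = route,
                                                initial_dose = dose,
                                                input_units = "mg/kg"),
                         monitor_vars = "Cplasma")
      pred <- res$Cplasma[match(obs_t, res$time)]
      conc <- pred * 10^stats::rnorm(length(pred), 0, noise_sd_log10)
      rows[[k]] <- data.frame(
        dtxsid = id, species = species, route = route, dose = dose,
        dose_units = "mg/kg", time_h = obs_t * 24, conc = conc,
        conc_units = "uM", medium = "plasma",
        study_id = sprintf("synthetic-%04d", k), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Compare model predictions against concentration-vs-time observations
#'
#' Simulates every experimental condition in the table (one solve per study:
#' chemical, route, dose), extracts the predicted concentration at each
#' observation time in matching units, and summarizes concordance: overall
#' and per-species RMSLE, explained variance on the log scale, fold-error
#' categories (fraction within 10-fold, fraction beyond 100-fold), and a
#' per-species regression of observed on predicted on log10 axes.
#'
#' @param records Observation table in the schema of
#'   [generate_synthetic_observations()].
#' @param model Registered model name.
#' @param lib A [chem_library()].
#' @param per_chemical_first Passed to [rmsle()].
#' @param floor Concentration floor (LOQ/2) for the log transform.
#' @return List: `per_record` (data.frame with `pred` column and
#'   `excluded` flag), `summary` (rmsle, r2, fold fractions, n, n_excluded,
#'   per-species statistics and regressions).
#' @export
compare_to_observations <- function(records, model = "pbtk", lib,
                                    per_chemical_first = FALSE,
                                    floor = 1e-9) {
  if (!nrow(records))
    return(list(per_record = records,
                summary = list(rmsle = NA_real_, n = 0L, n_excluded = 0L)))
  records$pred <- NA_real_
  records$excluded <- FALSE
  key <- interaction(records$dtxsid, records$species, records$route,
                     records$dose, records$study_id, drop = TRUE)
  for (grp in levels(key)) {
    idx <- which(key == grp)
    r1 <- records[idx[1], ]
    params <- tryCatch(
      parameterize_model(model, r1$dtxsid, species = r1$species, lib = lib),
      error = function(e) NULL)
    if (is.null(params)) { records$excluded[idx] <- TRUE; next }
    obs_t <- records$time_h[idx] / 24
    res <- tryCatch(solve_model(model, params = params,
                                times = sort(unique(c(0, obs_t))),
                                regimen = dose_regimen(route = r1$route,
                                                       initial_dose = r1$dose,
                                                       input_units = "mg/kg"),
                                monitor_vars = "Cplasma"),
                    error = function(e) NULL)
    if (is.null(res)) { records$excluded[idx] <- TRUE; next }
    records$pred[idx] <- res$Cplasma[match(obs_t, res$time)]
  }
  ok <- !records$excluded & !is.na(records$pred)
  pr <- pmax(records$pred[ok], floor); ob <- pmax(records$conc[ok], floor)
  fold <- abs(log10(pr) - log10(ob))
  by_species <- lapply(split(seq_along(pr), records$species[ok]), function(i) {
    fit <- if (length(i) >= 2L)
      stats::coef(stats::lm(log10(ob[i]) ~ log10(pr[i]))) else c(NA, NA)
    list(n = length(i), rmsle = sqrt(mean((log10(pr[i]) - log10(ob[i]))^2)),
         intercept = unname(fit[1]), slope = unname(fit[2]))
  })
  list(per_record = records,
       summary = list(
         rmsle = rmsle(pr, ob, per_chemical_first = per_chemical_first,
                       chem_ids = records$dtxsid[ok]),
         r2 = if (sum(ok) >= 2L)
           tryCatch(r2_explained_variance(pr, ob, log_scale = TRUE),
                    error = function(e) NA_real_) else NA_real_,
         frac_within_10fold = mean(fold <= 1),
         frac_beyond_100fold = mean(fold > 2),
         n = sum(ok), n_excluded = sum(records$excluded),
         by_species = by_species))
}

#' Run the benchmark suite
#'
#' Performs the standing series of package-health checks on a chemical
#' library: the count of chemicals with sufficient data for steady-state
#' IVIVE; the unit-conversion identity `(Css in mg/L / Css in uM) * 1000/MW
#' = 1` for the analytic steady state, the Monte Carlo steady state, and a
#' full solve; the "noMC" RMSLE comparing Monte Carlo median Css against
#' the non-varied analytic value; and, when reference tables are supplied,
#' RMSLE against in vivo steady-state estimates and against user-supplied
#' literature Css values.
#'
#' @param lib A [chem_library()].
#' @param species Species name.
#' @param model Steady-state model benchmarked (default `"3compartmentss"`).
#' @param n_mc Monte Carlo draws for the noMC check.
#' @param n_chems_nomc Number of eligible chemicals entering the noMC RMSLE.
#' @param mc_seed Seed for the Monte Carlo checks.
#' @param invivo_css Optional data.frame `dtxsid`, `css` (uM observed).
#' @param reference_css Optional data.frame `dtxsid`, `css95` (uM) of
#'   literature 95th-percentile values for the reference comparison.
#' @return A `benchmark_report` list of named statistics.
#' @export
benchmark_suite <- function(lib, species = "Human", model = "3compartmentss",
                            n_mc = 200, n_chems_nomc = 20, mc_seed = 42,
                            invivo_css = NULL, reference_css = NULL) {
  eligible <- get_cheminfo(lib, model = model, species = species)
  report <- list(N_steady_state = nrow(eligible))
  if (!nrow(eligible))
    return(structure(report, class = "benchmark_report"))
  id1 <- eligible$dtxsid[1]
  params1 <- parameterize_model(model, id1, species = species, lib = lib)
  mw <- params1[["MW"]]
  css_um <- calc_analytic_css(model, params = params1, output_units = "uM")
  css_mgl <- calc_analytic_css(model, params = params1, output_units = "mg/L")
  report$unit_ratio_analytic <- (css_mgl / css_um) * 1000 / mw
  cfg0 <- mc_config(n = 5, seed = mc_seed, invitrouv = FALSE)
  mc_um <- calc_mc_css(model, chem_record(lib, id1), species = species,
                       config = cfg0, output_units = "uM", lib = lib)
  mc_mgl <- calc_mc_css(model, chem_record(lib, id1), species = species,
                        config = cfg0, output_units = "mg/L", lib = lib)
  report$unit_ratio_mc <- (mc_mgl[[1]] / mc_um[[1]]) * 1000 / mw
  solve_elig <- get_cheminfo(lib, model = "pbtk", species = species)
  if (nrow(solve_elig)) {
    ps <- parameterize_model("pbtk", solve_elig$dtxsid[1], species = species,
                             lib = lib)
    tt <- seq(0, 1, 0.25)
    reg <- dose_regimen(initial_dose = 1)
    r_um <- solve_model("pbtk", params = ps, times = tt, regimen = reg,
                        monitor_vars = "Cplasma")
    r_mgl <- solve_model("pbtk", params = ps, times = tt, regimen = reg,
                         monitor_vars = "Cplasma",
                         output_units = c(Cplasma = "mg/L"))
    i <- which(r_um$Cplasma > 0)
    report$unit_ratio_solve <-
      mean(r_mgl$Cplasma[i] / r_um$Cplasma[i]) * 1000 / ps[["MW"]]
  }
  ids <- utils::head(eligible$dtxsid, n_chems_nomc)
  med <- ana <- rep(NA_real_, length(ids))
  for (j in seq_along(ids)) {
    ana[j] <- tryCatch(calc_analytic_css(model, chem_record(lib, ids[j]),
                                         species = species, lib = lib),
                       error = function(e) NA_real_)
    if (is.na(ana[j]) || !is.finite(ana[j])) next
    mc <- tryCatch(calc_mc_css(model, chem_record(lib, ids[j]),
                               species = species,
                               config = mc_config(n = n_mc, seed = mc_seed + j),
                               lib = lib),
                   error = function(e) NULL)
    if (!is.null(mc)) med[j] <- attr(mc, "median")
  }
  ok <- is.finite(med) & is.finite(ana) & med > 0 & ana > 0
  report$RMSLE_noMC <- if (any(ok)) rmsle(med[ok], ana[ok]) else NA_real_
  report$N_noMC <- sum(ok)
  if (!is.null(invivo_css)) {
    j <- match(invivo_css$dtxsid, eligible$dtxsid)
    use <- which(!is.na(j))
    if (length(use)) {
      pred <- vapply(invivo_css$dtxsid[use], function(id)
        calc_analytic_css(model, chem_record(lib, id), species = species,
                          lib = lib), numeric(1))
      report$RMSLE_invivo_css <- rmsle(pred, invivo_css$css[use])
      report$N_invivo_css <- length(use)
    }
  }
  if (!is.null(reference_css)) {
    j <- match(reference_css$dtxsid, eligible$dtxsid)
    use <- which(!is.na(j))
    if (length(use)) {
      pred <- vapply(reference_css$dtxsid[use], function(id) {
        mc <- calc_mc_css(model, chem_record(lib, id), species = species,
                          config = mc_config(n = n_mc, seed = mc_seed),
                          lib = lib)
        mc[[1]]
      }, numeric(1))
      report$RMSLE_wetmore <- rmsle(pred, reference_css$css95[use])
      report$N_wetmore <- length(use)
    }
  }
  structure(report, class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) cat(sprintf("  %-22s %.6g\n", nm, v))
  }
  invisible(x)
}

#' Append a benchmark report to a performance ledger
#'
#' Longitudinal record of benchmark statistics keyed by package version, so
#' drifts across releases are visible.
#'
#' @param report A `benchmark_report`.
#' @param path CSV ledger path (created if absent).
#' @param version Version string (default: the installed package version).
#' @return `path`, invisibly.
#' @export
write_performance_ledger <- function(report, path,
                                     version = as.character(utils::packageVersion("pbtksim"))) {
  row <- data.frame(version = version, date = format(Sys.Date()),
                    stat = names(report),
                    value = vapply(report, function(v)
                      if (is.numeric(v)) v else NA_real_, numeric(1)),
                    stringsAsFactors = FALSE)
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
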