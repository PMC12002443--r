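# Four-step Monte Carlo propagation of uncertainty and variability.
#
# Step 1 draws user-nominated parameters from truncated (and optionally
# censored) normal distributions.  Step 2 samples population physiology from
# a parametric correlated-lognormal stand-in for a survey-based population
# simulator (same interface: it overwrites only the model's declared
# population parameters, and refuses non-human populations).  Step 3 samples
# the chemical-specific in vitro parameters (Clint, fup, Caco-2) from
# distributions matched to their Bayesian uncertainty tuples.  Step 4
# recalculates every parameter that depends on the sampled ones: partition
# coefficients per-individual fup ("calcpc"), scaled clearance, and
# first-pass bioavailability ("firstpass"), plus an optional model-specific
# propagation hook.

#' Monte Carlo configuration
#'
#' @param n Number of draws.
#' @param seed Integer seed; every stochastic path in the sampler derives
#'   from it.
#' @param vary_params Named numeric vector of coefficients of variation for
#'   parameters sampled in Step 1 (truncated normal at 0).
#' @param censored_params Named numeric vector of limits of detection;
#'   draws below the LOD are replaced uniformly on `[0, LOD)`.
#' @param censored_cv CV used for censored parameters absent from
#'   `vary_params`.
#' @param httkpop Enable Step 2 population physiology sampling (human only).
#' @param pop_spec Population spec from [population_spec()].
#' @param invitrouv Enable Step 3 in vitro uncertainty sampling.
#' @param default_clint_cv,default_fup_cv,default_caco2_cv CVs used in Step
#'   3 when a measurement is a bare point value (no uncertainty tuple).
#' @param clint_pvalue_threshold In `"hard"` zero mode, Clint is zeroed for
#'   all draws iff its p-value for no clearance exceeds this threshold.
#' @param clint_zero_mode `"bernoulli"` (each draw is zero with probability
#'   `p_no_effect`) or `"hard"` (all-or-nothing at the p-value threshold).
#' @param quantiles Probabilities reported by [calc_mc_css()].
#' @return An `mc_config` list.
#' @export
mc_config <- function(n = 1000, seed = NULL, vary_params = numeric(0),
                      censored_params = numeric(0), censored_cv = 0.2,
                      httkpop = FALSE, pop_spec = NULL, invitrouv = TRUE,
                      default_clint_cv = 0.3, default_fup_cv = 0.3,
                      default_caco2_cv = 0.3,
                      clint_pvalue_threshold = 0.05,
                      clint_zero_mode = "bernoulli",
                      quantiles = 0.95) {
  stopifnot(n >= 1, all(quantiles > 0 & quantiles < 1),
            all(vary_params > 0))
  structure(list(n = as.integer(n), seed = seed, vary_params = vary_params,
                 censored_params = censored_params, censored_cv = censored_cv,
                 httkpop = httkpop, pop_spec = pop_spec,
                 invitrouv = invitrouv,
                 default_clint_cv = default_clint_cv,
                 default_fup_cv = default_fup_cv,
                 default_caco2_cv = default_caco2_cv,
                 clint_pvalue_threshold = clint_pvalue_threshold,
                 clint_zero_mode = clint_zero_mode,
                 quantiles = quantiles), class = "mc_config")
}

#' Draw from a truncated, optionally censored, normal distribution
#'
#' Truncated normal with mean `baseline` and sd `cv * baseline`, truncated
#' at 0 (exact, via the inverse CDF).  When an LOD is given, draws below it
#' are replaced by Uniform`[0, LOD)` (the censoring rule).
#'
#' @param baseline Central value (>= 0).
#' @param cv Coefficient of variation (> 0).
#' @param lod Optional limit of detection.
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Numeric vector of `n` non-negative draws.
#' @export
sample_censored_truncated <- function(baseline, cv, lod = NULL, n,
                                      seed = NULL) {
  if (!is_scalar_number(cv) || cv <= 0)
    abort("cv must be > 0", class = "pbtksim_argument_error")
  stopifnot(baseline >= 0)
  with_seed(seed, {
    sd <- cv * baseline
    if (sd == 0) return(rep(baseline, n))
    p0 <- stats::pnorm(0, baseline, sd)
    u <- stats::runif(n, p0, 1)
    x <- stats::qnorm(u, baseline, sd)
    if (!is.null(lod)) {
      below <- x < lod
      x[below] <- stats::runif(sum(below), 0, lod)
    }
    x
  })
}

#' Parametric population physiology specification
#'
#' A correlated-lognormal stand-in for a survey-based population simulator:
#' marginal medians come from the reference physiology, with default CVs of
#' 20% for body weight and 30% for flows, ventilation, glomerular
#' filtration and hepatocellularity, and a common rank correlation induced
#' by a Gaussian copula.
#'
#' @param species Species (population sampling is human-only).
#' @param cv Named CVs for `BW`, `QC`, `Qalv`, `GFR`, `hepatocellularity`.
#' @param correlation Pairwise copula correlation (default 0.4).
#' @param physiology Optional physiology table.
#' @return A `population_spec` list with `median`, `cv`, `correlation`,
#'   `reference` (full physiology row).
#' @export
population_spec <- function(species = "Human",
                            cv = c(BW = 0.2, QC = 0.3, Qalv = 0.3,
                                   GFR = 0.3, hepatocellularity = 0.3),
                            correlation = 0.4, physiology = NULL) {
  ref <- get_physiology(species, physiology)
  vars <- names(cv)
  structure(list(median = unlist(ref[vars]), cv = cv,
                 correlation = correlation, reference = ref,
                 species = species), class = "population_spec")
}

#' Sample population physiology
#'
#' Correlated lognormal draws of body weight, cardiac output, alveolar
#' ventilation, glomerular filtration and hepatocellularity; all other
#' physiological constants are carried at their reference values.
#'
#' @param species Species; must be `"Human"` (the population stand-in is
#'   parameterized for the human population and should not be used for
#'   non-human populations).
#' @param spec A [population_spec()].
#' @param n Number of individuals.
#' @param seed Optional seed.
#' @return Data.frame of `n` physiology rows (same columns as
#'   [load_physiology()]).
#' @export
sample_population_physiology <- function(species = "Human", spec = NULL,
                                         n, seed = NULL) {
  if (tolower(species) != "human")
    abort("population physiology sampling is human-only; it should not be used for non-human populations",
          class = "pbtksim_argument_error")
  spec <- spec %||% population_spec(species)
  vars <- names(spec$cv)
  k <- length(vars)
  R <- matrix(spec$correlation, k, k); diag(R) <- 1
  L <- chol(R)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * k), n, k) %*% L
    draws <- vapply(seq_len(k), function(j) {
      sdlog <- sqrt(log(1 + spec$cv[[j]]^2))
      spec$median[[j]] * exp(z[, j] * sdlog)
    }, numeric(n))
    colnames(draws) <- vars
    ref <- spec$reference
    out <- as.data.frame(lapply(ref, function(v) rep(v, n)))
    for (v in vars) out[[v]] <- draws[, v]
    out
  })
}

#' Sample in vitro chemical parameters (Step 3)
#'
#' Clint 4-tuples sample a zero-inflated lognormal: each draw is zero with
#' probability `p_no_effect` (the Bayesian p-value that no clearance was
#' observed), otherwise lognormal with quantiles matched to the tuple's
#' median and 95% bounds.  fup 3-tuples sample the analogous logit-normal,
#' bounded to (0, 1].  Point values use the configured default CVs
#' (lognormal for Clint/Caco-2, logit-normal for fup).
#'
#' @param chem Chemical record.
#' @param config An [mc_config()].
#' @param n Number of draws.
#' @param species Species for the in vitro columns.
#' @param seed Optional seed.
#' @return Data.frame with columns `Clint`, `fup`, `caco2_papp`.
#' @export
sample_invitro_uv <- function(chem, config, n, species = "Human",
                              seed = NULL) {
  clint_uv <- parse_uncertainty_tuple(
    chem[[paste0("Clint.", species)]] %||% chem[["Clint.Human"]], "clint")
  fup_uv <- parse_uncertainty_tuple(
    chem[[paste0("fup.", species)]] %||% chem[["fup.Human"]], "fup")
  with_seed(seed, {
    # Clint
    if (!is.na(clint_uv$l95) && clint_uv$point > 0) {
      ml <- log(clint_uv$point)
      sl <- (log(clint_uv$u95) - log(clint_uv$l95)) / (2 * stats::qnorm(0.975))
      clint <- stats::rlnorm(n, ml, max(sl, 1e-12))
    } else if (clint_uv$point > 0) {
      clint <- stats::rlnorm(n, log(clint_uv$point),
                             sqrt(log(1 + config$default_clint_cv^2)))
    } else clint <- rep(0, n)
    p0 <- clint_uv$p_no_effect
    if (!is.na(p0) && p0 > 0) {
      if (identical(config$clint_zero_mode, "hard")) {
        if (p0 > config$clint_pvalue_threshold) clint[] <- 0
      } else {
        clint[stats::runif(n) < p0] <- 0
      }
    }
    # fup (logit scale, bounded (0, 1])
    fp <- fup_uv$point
    if (fp == 0) fp <- .FUP_DEFAULT
    fp <- min(fp, 1 - 1e-9)
    if (!is.na(fup_uv$l95) && fup_uv$l95 > 0 && fup_uv$u95 < 1) {
      ml <- stats::qlogis(fp)
      sl <- (stats::qlogis(fup_uv$u95) - stats::qlogis(fup_uv$l95)) /
        (2 * stats::qnorm(0.975))
      fup <- stats::plogis(stats::rnorm(n, ml, max(sl, 1e-12)))
    } else {
      sdl <- sqrt(log(1 + config$default_fup_cv^2))
      fup <- stats::plogis(stats::rnorm(n, stats::qlogis(fp), sdl))
    }
    fup <- pmin(pmax(fup, 1e-9), 1)
    # Caco-2
    papp <- chem$caco2_papp
    caco2 <- if (is.null(papp) || is.na(papp)) rep(NA_real_, n)
    else stats::rlnorm(n, log(papp), sqrt(log(1 + config$default_caco2_cv^2)))
    data.frame(Clint = clint, fup = fup, caco2_papp = caco2)
  })
}

# Model-specific propagation for the one-compartment model: volume of
# distribution and elimination rate are derived quantities and must be
# recomputed from each individual's fup, clearance and physiology.
propagate_invitrouv_1compartment <- function(tab, chem, phys_draws, aux,
                                             tissues) {
  body <- tissues[tissues$tissue != "red blood cells", ]
  for (i in seq_len(nrow(tab))) {
    fup <- tab$fup[i]
    kp <- predict_partitioning_schmitt(chem, fup = fup, tissues = tissues)
    rb2p <- if (aux$rb2p_prov == "schmitt_computed")
      (1 - phys_draws$hct[i]) + phys_draws$hct[i] * kp[["red blood cells"]] * fup
    else tab$Rblood2plasma[i]
    vdist <- phys_draws$blood_vol_frac[i] * rb2p +
      sum(body$vol_frac_BW * kp[body$tissue] * fup)
    qgfr <- aux$Qgfr[i]
    clh <- aux$CLh[i]
    tab$Rblood2plasma[i] <- rb2p
    tab$Vdist[i] <- vdist
    tab$kelim[i] <- (fup * qgfr + clh) / (vdist * tab$BW[i])
  }
  tab
}

#' Generate a Monte Carlo parameter sample table
#'
#' Runs the four sampling steps in order on top of the baseline parameter
#' set and returns an `n`-row table of complete parameter sets with a
#' per-column provenance tag recording the last step that touched each
#' parameter (`baseline`, `step1`, `pop`, `invitro`, `recalc`).  With every
#' variance source disabled the table is the baseline replicated `n` times.
#'
#' @param model Registered model name.
#' @param chem Chemical record or identifier.
#' @param species Species name.
#' @param config An [mc_config()].
#' @param lib Optional [chem_library()].
#' @param ... Options for the parameterizer.
#' @return A data.frame of class `parameter_sample_table`, columns exactly
#'   the model's `param_names`; attributes: `provenance` (named step tags),
#'   `baseline` (the unsampled parameter set), `model`, `species`.
#' @export
create_mc_samples <- function(model, chem, species = "Human", config = mc_config(),
                              lib = NULL, ...) {
  info <- get_model_info(model)
  if (is.character(chem)) chem <- chem_record(lib, chem)
  dots <- list(...)
  tissues <- dots$tissues %||% load_tissue_data()
  baseline <- parameterize_model(model, chem, species = species, lib = lib, ...)
  n <- config$n
  tab <- as.data.frame(lapply(as.list(baseline), rep, n))
  names(tab) <- names(baseline)
  prov <- stats::setNames(rep("baseline", ncol(tab)), names(tab))
  bprov <- attr(baseline, "provenance")

  with_seed(config$seed, {
    # ---- Step 1: truncated/censored normal sampling of nominated params ----
    step1_params <- union(names(config$vary_params), names(config$censored_params))
    later <- character(0)
    if (config$httkpop) later <- union(later, info$mc$httkpop_params)
    if (config$invitrouv) later <- union(later, info$mc$invitro_params)
    clash <- intersect(step1_params, later)
    if (length(clash))
      warning(sprintf(
        "parameter(s) %s sampled in Step 1 will be overwritten by a later Monte Carlo step",
        paste(clash, collapse = ", ")))
    for (pn in step1_params) {
      if (!pn %in% names(tab))
        abort(sprintf("unknown parameter '%s' in Monte Carlo config", pn))
      cv <- if (pn %in% names(config$vary_params))
        config$vary_params[[pn]] else config$censored_cv
      lod <- if (pn %in% names(config$censored_params))
        config$censored_params[[pn]] else NULL
      tab[[pn]] <- sample_censored_truncated(baseline[[pn]], cv, lod = lod,
                                             n = n)
      prov[[pn]] <- "step1"
    }

    # ---- Step 2: population physiology ----
    phys_ref <- get_physiology(species, dots$physiology)
    phys_draws <- as.data.frame(lapply(phys_ref, rep, n))
    if (config$httkpop) {
      spec <- config$pop_spec %||% population_spec(species,
                                                   physiology = dots$physiology)
      phys_draws <- sample_population_physiology(species, spec, n)
      pop_cols <- intersect(info$mc$httkpop_params, names(tab))
      for (i in seq_len(n)) {
        phys_i <- phys_draws[i, , drop = FALSE]
        ps_i <- parameterize_model(model, chem, species = species, lib = lib,
                                   physiology = phys_i, ...)
        for (pc in pop_cols) tab[[pc]][i] <- ps_i[[pc]]
      }
      prov[pop_cols] <- "pop"
    }

    # ---- Step 3: in vitro uncertainty/variability ----
    iv <- NULL
    if (config$invitrouv) {
      iv <- sample_invitro_uv(chem, config, n, species = species)
      for (pc in intersect(c("Clint", "fup"), names(tab))) {
        tab[[pc]] <- iv[[pc]]
        prov[[pc]] <- "invitro"
      }
    }

    # ---- Step 4: recalculate dependent parameters ----
    if (config$invitrouv || config$httkpop) {
      aux <- list(rb2p_prov = bprov$rb2p, fu_hep = bprov$fu_hep %||% 1)
      clint_point <- parse_uncertainty_tuple(
        chem[[paste0("Clint.", species)]] %||% chem[["Clint.Human"]],
        "clint")$point
      clint_vec <- if (!is.null(iv)) iv$Clint else rep(clint_point, n)
      clint_whole_vec <- (clint_vec / aux$fu_hep) *
        phys_draws$hepatocellularity * phys_draws$liver_mass_frac *
        tab$BW * 60 * 24 / 1e6
      if ("Clint_whole" %in% names(tab)) {
        tab$Clint_whole <- clint_whole_vec
        prov[["Clint_whole"]] <- "recalc"
      }
      if (isTRUE(info$mc$calcpc) &&
          any(startsWith(names(tab), "Kp.")) && config$invitrouv) {
        scheme <- if (model %in% c("pbtk", "gas_pbtk")) .pbtk_scheme else NULL
        for (i in seq_len(n)) {
          kp <- predict_partitioning_schmitt(chem, fup = tab$fup[i],
                                             tissues = tissues)
          lump <- lump_tissues(kp, tissues, scheme)
          for (cm in names(lump$Kp)) tab[[paste0("Kp.", cm)]][i] <- lump$Kp[[cm]]
          if (aux$rb2p_prov == "schmitt_computed" &&
              "Rblood2plasma" %in% names(tab)) {
            tab$Rblood2plasma[i] <- (1 - phys_draws$hct[i]) +
              phys_draws$hct[i] * kp[["red blood cells"]] * tab$fup[i]
          }
        }
        prov[grep("^Kp\\.", names(tab), value = TRUE)] <- "recalc"
        if (aux$rb2p_prov == "schmitt_computed")
          prov[["Rblood2plasma"]] <- "recalc"
      }
      frac_gut <- sum(tissues$flow_frac_QC[tissues$tissue == "gut"])
      frac_liv_tot <- sum(tissues$flow_frac_QC[
        tissues$tissue %in% c("liver", "gut")])
      if (isTRUE(info$mc$firstpass)) {
        if ("Fgut" %in% names(tab)) {
          qgut <- if ("Qgut" %in% names(tab)) tab$Qgut
                  else tab$Qliver_total * frac_gut / frac_liv_tot
          tab$Fgut <- qgut / (qgut + tab$fup * .GUT_CLINT_FRACTION * clint_whole_vec)
          prov[["Fgut"]] <- "recalc"
        }
        if ("Fabs" %in% names(tab) && !is.null(iv) &&
            !all(is.na(iv$caco2_papp)) && bprov$fabs %in% "caco2_curve") {
          tab$Fabs <- 1 / (1 + 10^(-(log10(iv$caco2_papp) - 0.2)))
          prov[["Fabs"]] <- "recalc"
        }
        if ("Fhep" %in% names(tab)) {
          tab$Fhep <- tab$Qliver_total /
            (tab$Qliver_total + tab$fup * clint_whole_vec / tab$Rblood2plasma)
          prov[["Fhep"]] <- "recalc"
        }
        if ("CLh" %in% names(tab)) {
          tab$CLh <- tab$Qliver_total * tab$fup * clint_whole_vec /
            (tab$Qliver_total + tab$fup * clint_whole_vec)
          tab$CLh[!is.finite(tab$CLh)] <- 0
          prov[["CLh"]] <- "recalc"
        }
      }
      pf <- info$mc$propagateuv_func
      if (!is.null(pf)) {
        aux$Qgfr <- if ("Qgfr" %in% names(tab)) tab$Qgfr
                    else phys_draws$GFR * tab$BW^.ALLOMETRIC_EXP * 24
        aux$CLh <- if ("CLh" %in% names(tab)) tab$CLh else {
          qliv <- phys_draws$QC * tab$BW^.ALLOMETRIC_EXP * 24 * frac_liv_tot
          clh <- qliv * tab$fup * clint_whole_vec /
            (qliv + tab$fup * clint_whole_vec)
          clh[!is.finite(clh)] <- 0
          clh
        }
        fn <- get(pf, mode = "function")
        tab <- fn(tab, chem, phys_draws, aux, tissues)
        prov[intersect(c("Vdist", "kelim", "Rblood2plasma"), names(tab))] <- "recalc"
      }
    }
  })
  structure(tab, class = c("parameter_sample_table", "data.frame"),
            provenance = prov, baseline = baseline, model = model,
            species = species)
}

# Hidden in vitro-parameter presence differs per model; 1compartment carries
# fup but not Clint among its params, so step 3/4 routed through the
# propagation hook above.

#' Monte Carlo quasi-steady-state concentration quantiles
#'
#' Evaluates the model's analytic steady-state solution on every row of the
#' Monte Carlo parameter sample and returns the requested quantiles
#' (default: the 95th percentile, the convention used for conservative
#' exposure screening at 1 mg/kg/day).  With all variance sources disabled
#' every draw equals the deterministic analytic Css.
#'
#' @param model Registered model with an analytic steady state.
#' @param chem Chemical record or identifier.
#' @param species Species name.
#' @param config An [mc_config()].
#' @param dose_rate Dose rate, mg/kg/day (default 1).
#' @param output_units `"uM"` (default) or `"mg/L"`.
#' @param lib Optional library.
#' @param samples Optional pre-built [create_mc_samples()] table.
#' @param ... Parameterizer options.
#' @return Named numeric vector of Css quantiles; attributes `draws`
#'   (all Css values) and `median`.
#' @export
calc_mc_css <- function(model, chem = NULL, species = "Human",
                        config = mc_config(), dose_rate = 1,
                        output_units = "uM", lib = NULL, samples = NULL,
                        ...) {
  info <- get_model_info(model)
  if (is.null(info$steady_state))
    abort(sprintf("model '%s' has no analytic steady state for Monte Carlo Css",
                  model), class = "pbtksim_capability_error")
  if (is.null(samples))
    samples <- create_mc_samples(model, chem, species = species,
                                 config = config, lib = lib, ...)
  fn <- get(info$steady_state$analytic_css_func, mode = "function")
  draws <- vapply(seq_len(nrow(samples)), function(i) {
    row <- as.list(samples[i, , drop = FALSE])
    tryCatch(fn(row, dose_rate = dose_rate), pbtksim_nonclearing_error =
               function(e) Inf)
  }, numeric(1))
  mw <- samples$MW[1]
  draws <- convert_units(draws, info$steady_state$steady_state_units,
                         output_units, MW = mw)
  qs <- stats::quantile(draws, probs = config$quantiles, names = FALSE)
  structure(stats::setNames(qs, sprintf("q%g", config$quantiles * 100)),
            draws = draws, median = stats::median(draws),
            units = output_units)
}

#' Reverse-dosimetry oral equivalent dose
#'
#' Inverts the linear dose-to-Css relationship: the daily oral dose that
#' would produce `target_conc` at steady state is
#' `target / Css(1 mg/kg/day)`, evaluated at each requested Css quantile
#' (a higher Css quantile gives a lower, more conservative equivalent dose).
#'
#' @param target_conc Target steady-state plasma concentration in uM (> 0).
#' @param model,chem,species,config,lib,samples,... As [calc_mc_css()].
#' @return Named vector of equivalent doses (mg/kg/day) per quantile;
#'   attribute `n_excluded` counts zero-Css draws dropped.
#' @export
calc_mc_oral_equiv <- function(target_conc, model, chem = NULL,
                               species = "Human", config = mc_config(),
                               lib = NULL, samples = NULL, ...) {
  if (!is_scalar_number(target_conc) || target_conc <= 0)
    abort("target_conc must be > 0", class = "pbtksim_argument_error")
  css <- calc_mc_css(model, chem, species = species, config = config,
                     dose_rate = 1, output_units = "uM", lib = lib,
                     samples = samples, ...)
  draws <- attr(css, "draws")
  n_zero <- sum(draws == 0)
  if (n_zero) {
    warning(sprintf("%d zero-Css draw(s) excluded from oral-equivalent quantiles",
                    n_zero))
    draws <- draws[draws > 0]
  }
  qs <- stats::quantile(draws, probs = config$quantiles, names = FALSE)
  structure(stats::setNames(target_conc / qs,
                            sprintf("q%g", config$quantiles * 100)),
            n_excluded = n_zero, units = "mg/kg/day")
}

#' Monte Carlo full toxicokinetic simulation
#'
#' Runs the full ODE model for every sampled parameter set and reports the
#' mean and standard deviation of each monitored concentration at each
#' requested time (the route available to models without an analytic steady
#' state, such as the gas model).
#'
#' @param model Solve-capable registered model.
#' @param chem Chemical record or identifier.
#' @param species Species name.
#' @param config An [mc_config()].
#' @param times Output times (days).
#' @param regimen A [dose_regimen()].
#' @param monitor_vars Variables to summarize (default `"Cplasma"`).
#' @param lib Optional library.
#' @param ... Solver/parameterizer options.
#' @return List with `times`, `mean` and `sd` (matrices time x variable),
#'   `n_ok`, `n_failed`.
#' @export
calc_mc_tk <- function(model, chem = NULL, species = "Human",
                       config = mc_config(n = 100), times = seq(0, 1, 0.1),
                       regimen = dose_regimen(initial_dose = 1),
                       monitor_vars = "Cplasma", lib = NULL, ...) {
  info <- get_model_info(model)
  if (!info$solve_capable)
    abort(sprintf("model '%s' is not solve-capable", model),
          class = "pbtksim_capability_error")
  samples <- create_mc_samples(model, chem, species = species,
                               config = config, lib = lib, ...)
  acc <- array(NA_real_, dim = c(length(times), length(monitor_vars),
                                 nrow(samples)))
  n_failed <- 0L
  units <- attr(attr(samples, "baseline"), "units")
  for (i in seq_len(nrow(samples))) {
    row <- as.list(samples[i, , drop = FALSE])
    ps <- structure(row, class = "parameter_set",
                    model = model, species = species, units = units)
    res <- tryCatch(solve_model(model, params = ps, times = times,
                                regimen = regimen,
                                monitor_vars = monitor_vars, ...),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    acc[, , i] <- as.matrix(as.data.frame(res)[monitor_vars])
  }
  mean_m <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  sd_m <- apply(acc, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else stats::sd(v)
  })
  dimnames(mean_m) <- dimnames(sd_m) <- list(NULL, monitor_vars)
  list(times = times, mean = mean_m, sd = sd_m,
       n_ok = nrow(samples) - n_failed, n_failed = n_failed,
       single_draw = nrow(samples) == 1L)
}
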