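# ODE right-hand sides for the built-in model suite.
#
# All states are amounts (umol); concentrations are derived outputs.  This
# makes mass balance exact: the sum of all compartment amounts plus the
# cumulative elimination/exhalation accumulators must equal the cumulative
# administered plus inhaled amount at every instant.  Time is in days.
#
# Each routine returns list(dstate, aux) with BOTH components named; the
# names are the ground truth that validate_model() compares against the
# registry's declared derivative_output_names.

# Perfusion-limited rate law: blood leaving a tissue carries
# C_tissue * Rb2p / (Kp * fup), the blood concentration in equilibrium with
# the tissue (Kp is tissue:unbound-plasma).

deriv_1compartment <- function(t, y, p) {
  Agutlumen <- y[[1L]]; Acompartment <- y[[2L]]
  absorbed <- p$kgutabs * Agutlumen
  Ccompartment <- Acompartment / (p$Vdist * p$BW)   # plasma-referenced, uM
  dstate <- c(
    Agutlumen = -absorbed,
    Acompartment = absorbed * p$Fabsgut - p$kelim * Acompartment,
    Aeliminated = p$kelim * Acompartment,
    Aunabsorbed = absorbed * (1 - p$Fabsgut),
    AUC = Ccompartment
  )
  list(dstate = dstate, aux = c(Ccompartment = Ccompartment))
}

deriv_pbtk <- function(t, y, p) {
  Agutlumen <- y[[1L]]; Agut <- y[[2L]]; Aliver <- y[[3L]]
  Akidney <- y[[4L]]; Alung <- y[[5L]]; Arest <- y[[6L]]
  Aart <- y[[7L]]; Aven <- y[[8L]]

  Cgut <- Agut / p$Vgut; Cliver <- Aliver / p$Vliver
  Ckidney <- Akidney / p$Vkidney; Clung <- Alung / p$Vlung
  Crest <- Arest / p$Vrest
  Cart <- Aart / p$Vart; Cven <- Aven / p$Vven   # blood, uM
  rb <- p$Rblood2plasma; fup <- p$fup
  Cvgut <- Cgut * rb / (p$Kp.gut * fup)
  Cvliver <- Cliver * rb / (p$Kp.liver * fup)
  Cvkidney <- Ckidney * rb / (p$Kp.kidney * fup)
  Cvlung <- Clung * rb / (p$Kp.lung * fup)
  Cvrest <- Crest * rb / (p$Kp.rest * fup)

  absorbed <- p$kgutabs * Agutlumen
  Fabsgut <- p$Fabs * p$Fgut
  metab <- p$Clint_whole * Cliver / p$Kp.liver      # on free liver conc
  filtration <- p$Qgfr * fup * Cart / rb            # unbound arterial plasma

  dstate <- c(
    Agutlumen = -absorbed,
    Agut = absorbed * Fabsgut + p$Qgut * (Cart - Cvgut),
    Aliver = p$Qliver * Cart + p$Qgut * Cvgut -
      (p$Qliver + p$Qgut) * Cvliver - metab,
    Akidney = p$Qkidney * (Cart - Cvkidney) - filtration,
    Alung = p$Qcardiac * (Cven - Cvlung),
    Arest = p$Qrest * (Cart - Cvrest),
    Aart = p$Qcardiac * Cvlung -
      (p$Qgut + p$Qliver + p$Qkidney + p$Qrest) * Cart,
    Aven = (p$Qliver + p$Qgut) * Cvliver + p$Qkidney * Cvkidney +
      p$Qrest * Cvrest - p$Qcardiac * Cven,
    Atubules = filtration,
    Ametabolized = metab,
    Aunabsorbed = absorbed * (1 - Fabsgut),
    AUC = Cven / rb
  )
  aux <- c(Cplasma = Cven / rb, Cgut = Cgut, Cliver = Cliver,
           Ckidney = Ckidney, Clung = Clung, Crest = Crest,
           Cart = Cart, Cven = Cven)
  list(dstate = dstate, aux = aux)
}

deriv_gas_pbtk <- function(t, y, p) {
  Agutlumen <- y[[1L]]; Agut <- y[[2L]]; Aliver <- y[[3L]]
  Akidney <- y[[4L]]; Alung <- y[[5L]]; Arest <- y[[6L]]
  Aart <- y[[7L]]; Aven <- y[[8L]]; Amucus <- y[[9L]]

  Cgut <- Agut / p$Vgut; Cliver <- Aliver / p$Vliver
  Ckidney <- Akidney / p$Vkidney; Clung <- Alung / p$Vlung
  Crest <- Arest / p$Vrest
  Cart <- Aart / p$Vart; Cven <- Aven / p$Vven
  rb <- p$Rblood2plasma; fup <- p$fup
  Cvgut <- Cgut * rb / (p$Kp.gut * fup)
  Cvliver <- Cliver * rb / (p$Kp.liver * fup)
  Cvkidney <- Ckidney * rb / (p$Kp.kidney * fup)
  Cvlung <- Clung * rb / (p$Kp.lung * fup)
  Cvrest <- Crest * rb / (p$Kp.rest * fup)

  Cinh <- if (is.null(p$cinh_fun)) 0 else p$cinh_fun(t)   # inhaled air, uM
  # upper-respiratory mucus strips a fraction of the inhaled stream;
  # captured chemical desorbs into the gut lumen (swallowed)
  Cinh_alv <- Cinh * (1 - p$f_urt)
  swallowed <- p$k_mucus * Amucus
  # steady-state alveolar equilibration (mass-conserving by construction)
  Cart_eq <- (p$Qalv * Cinh_alv + p$Qcardiac * Cven) /
    (p$Qcardiac + p$Qalv / p$Kblood2air)
  Cexh <- Cart_eq / p$Kblood2air                           # end-exhaled air

  absorbed <- p$kgutabs * Agutlumen
  Fabsgut <- p$Fabs * p$Fgut
  metab <- p$Clint_whole * Cliver / p$Kp.liver
  filtration <- p$Qgfr * fup * Cart / rb

  dstate <- c(
    Agutlumen = -absorbed + swallowed,
    Agut = absorbed * Fabsgut + p$Qgut * (Cart - Cvgut),
    Aliver = p$Qliver * Cart + p$Qgut * Cvgut -
      (p$Qliver + p$Qgut) * Cvliver - metab,
    Akidney = p$Qkidney * (Cart - Cvkidney) - filtration,
    Alung = p$Qcardiac * (Cart_eq - Cvlung),
    Arest = p$Qrest * (Cart - Cvrest),
    Aart = p$Qcardiac * Cvlung -
      (p$Qgut + p$Qliver + p$Qkidney + p$Qrest) * Cart,
    Aven = (p$Qliver + p$Qgut) * Cvliver + p$Qkidney * Cvkidney +
      p$Qrest * Cvrest - p$Qcardiac * Cven,
    Amucus = p$Qalv * Cinh * p$f_urt - swallowed,
    Atubules = filtration,
    Ametabolized = metab,
    Aunabsorbed = absorbed * (1 - Fabsgut),
    Ainhaled = p$Qalv * Cinh,
    Aexhaled = p$Qalv * Cexh,
    AUC = Cven / rb
  )
  aux <- c(Cplasma = Cven / rb, Cgut = Cgut, Cliver = Cliver,
           Ckidney = Ckidney, Clung = Clung, Crest = Crest,
           Cart = Cart, Cven = Cven, Cexh = Cexh,
           Cexh_ppmv = Cexh * R_ATM * p$body_temperature,
           Cinh = Cinh)
  list(dstate = dstate, aux = aux)
}

#' Evaluate a model's derivative routine at a point
#'
#' @param model Registered, solve-capable model name.
#' @param t Time (days).
#' @param state Named amounts vector (umol) matching the model's
#'   `state_vars` in length.
#' @param params A `parameter_set` (or compatible named list).
#' @param forcings_at_t Named list of forcing values at `t` (e.g.
#'   `list(Cinh = 5)` in uM for the gas model).
#' @return List with named `dstate` (d amount/dt, umol/day) and named
#'   `aux` outputs (concentrations per the declared compartment units).
#' @export
evaluate_derivative <- function(model, t, state, params,
                                forcings_at_t = NULL) {
  info <- get_model_info(model)
  if (!info$solve_capable)
    abort(sprintf("model '%s' has no ODE system", model),
          class = "pbtksim_capability_error")
  if (length(state) != length(info$state_vars))
    abort(sprintf("state has length %d but model '%s' declares %d state variables",
                  length(state), model, length(info$state_vars)))
  if (!all(is.finite(state)) || !is.finite(t))
    abort("non-finite state or time passed to derivative")
  p <- as.list(params)
  names(p) <- names(params)
  if (!is.null(forcings_at_t) && length(info$input_var_names)) {
    v <- forcings_at_t[[info$input_var_names[1]]]
    if (!is.null(v)) p$cinh_fun <- function(t) v
  }
  fn <- get(info$derivative_func, mode = "function")
  fn(t, unname(state), p)
}
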