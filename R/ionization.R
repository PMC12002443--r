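# Henderson-Hasselbalch ionization over all protonation microstates.

#' Ionization fractions at a given pH
#'
#' Enumerates every protonation microstate implied by the acid (proton-donor)
#' and base (proton-acceptor) pKa values, weighting each state by the
#' Henderson-Hasselbalch equilibrium relative to the fully neutral species:
#' a deprotonated donor contributes a factor `10^(pH - pKa)` and a protonated
#' acceptor a factor `10^(pKa - pH)`.  States are classified by net charge;
#' a state carrying both a positive and a negative site with net charge zero
#' is a zwitterion.
#'
#' @param pH Ambient pH (0 < pH < 14).
#' @param pKa_donor Numeric vector of acid pKa values (may be empty).
#' @param pKa_accept Numeric vector of base pKa values (may be empty).
#' @return Named numeric vector `c(neutral, anion, cation, zwitter)` summing
#'   to 1.
#' @examples
#' ionization_fractions(7.4, pKa_donor = 4.4)  # weak acid, ~0.999 anion
#' @export
ionization_fractions <- function(pH, pKa_donor = numeric(0),
                                 pKa_accept = numeric(0)) {
  stopifnot(is_scalar_number(pH), pH > 0, pH < 14)
  pKa_donor <- parse_num_list(pKa_donor)
  pKa_accept <- parse_num_list(pKa_accept)
  nd <- length(pKa_donor); na <- length(pKa_accept)
  if (nd + na > 12L)
    abort("too many ionizable sites to enumerate (max 12)")
  out <- c(neutral = 0, anion = 0, cation = 0, zwitter = 0)
  # log10 weights per microstate, accumulated over independent sites
  logw <- 0; dneg <- 0L; dpos <- 0L
  # enumerate via integer bitmasks over donors and acceptors
  for (md in seq_len(2^nd) - 1L) {
    deprot <- as.logical(bitwAnd(md, 2^(seq_len(nd) - 1L)))
    lw_d <- sum((pH - pKa_donor)[deprot])
    nneg <- sum(deprot)
    for (ma in seq_len(2^na) - 1L) {
      prot <- as.logical(bitwAnd(ma, 2^(seq_len(na) - 1L)))
      lw <- lw_d + sum((pKa_accept - pH)[prot])
      npos <- sum(prot)
      charge <- npos - nneg
      kind <- if (charge < 0) "anion" else if (charge > 0) "cation"
              else if (nneg > 0L) "zwitter" else "neutral"
      out[kind] <- out[kind] + 10^lw
    }
  }
  out / sum(out)
}
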