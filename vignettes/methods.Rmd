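---
title: "Models and methods in pbtksim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pbtksim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtksim)
```

# The problem

High-throughput toxicokinetics (HTTK) characterizes a chemical by a small
set of standardized in vitro measurements — intrinsic hepatic clearance
(Clint, µL/min/10⁶ hepatocytes), fraction unbound in plasma (fup), Caco-2
membrane permeability — plus physico-chemical properties (molecular weight,
logP, pKa, Henry's law constant), and feeds them to generic toxicokinetic
models.  The central use is in vitro-to-in vivo extrapolation (IVIVE):
converting a bioactive in vitro concentration into the external daily dose
that would produce it at steady state, chemical by chemical, across
thousands of chemicals for which no in vivo kinetic data exist.

`pbtksim` implements that workflow end to end: a chemical data library, a
tissue-partitioning predictor, model parameterization, an event-driven ODE
core behind a model-registry contract, analytic and numerical steady
states, a four-step Monte Carlo sampler with reverse dosimetry, and an
evaluation/benchmark suite.  All data the package needs ship as editable
plain CSVs; a synthetic chemical-library generator lets every analysis run
with no external downloads.

# Chemical data conventions

Measurements carry their uncertainty inline: Clint may be a Bayesian
4-tuple string `"median,l95,u95,p"` (the last entry the p-value that no
clearance was observed) and fup the analogous 3-tuple.  A fup recorded as
exactly `0` means the binding assay was attempted but failed because the
chemical is highly bound; the raw zero is preserved in the library and the
default of **0.5% unbound** is substituted only at parameterization time,
keeping data and decision cascade separate.

Eligibility for a model is declared, not hard-coded: each registry entry
lists required fields, whether recorded-zero fup disqualifies, a Henry's
law threshold (default: chemicals with log10 HLC above −4.5 atm·m³/mol are
too volatile for the liquid-only models), and excluded chemical classes
(the gas model's applicability domain excludes PFAS).

# Tissue partitioning

Tissue:unbound-plasma partition coefficients come from a Schmitt-type
component model.  With $f_n(\mathrm{pH})$ the Henderson–Hasselbalch neutral
fraction (computed by enumerating all protonation microstates),
$K_{ow} = 10^{\log P}$, and tissue composition fractions from the packaged
table:

$$K_p = f_{water}\,\frac{f_n(7.4)}{f_n(\mathrm{pH}_t)}
 + f_{nl}\,K_{ow} f_n(7.4)
 + f_{pl}\,K_{ow}\left(f_n(7.4) + \alpha (1 - f_n(7.4))\right)
 + \frac{f_{prot}}{0.075}\left(\frac{1}{f_{up}} - 1\right)$$

The water term is pH partitioning of the permeant neutral species; neutral
lipid admits only the neutral species; phospholipid membranes bind ions
with attenuation $\alpha$ (default 0.05); tissue protein binding is scaled
from the plasma bound:unbound ratio by protein content relative to plasma
(7.5% v/v).  An affine per-tissue calibration in log10 space is accepted as
a configuration table; the default is the identity (uncalibrated), so the
component model is fully auditable.  Red blood cells are a row of the
tissue table, which makes the blood:plasma ratio cascade fall out of the
same predictor: measured species value, else measured human value, else
$R_{b2p} = (1-hct) + hct\,K_{rbc}\,f_{up}$, else the mean of measured
values across the library — with the branch taken always reported.

Lumping tissues into model compartments sums member volumes and flows and
volume-averages $K_p$, conserving total volume, flow and partitioning
capacity exactly.

# Parameterization

Internal units are days, µmol, L, L/day.  Flows, alveolar ventilation and
glomerular filtration scale allometrically as reference × BW^0.75.  Hepatic
clearance is scaled in two stages: per-cell Clint (divided by the
hepatocyte-assay unbound fraction, an association model
$f_{u,hep} = 1/(1 + D\cdot10^{0.56\log P - 1.41})$) to the whole liver via
hepatocellularity and liver mass, then the well-stirred model
$CL_h = Q_l f_{up} Cl_w/(Q_l + f_{up} Cl_w)$, bounded by liver blood flow.
Oral bioavailability has three factors: Fabs (measured value, else a
logistic curve in log10 Caco-2 permeability, else 1), Fgut computed with a
gut intrinsic clearance fixed at **1% of the scaled hepatic Clint**, and
first-pass Fhep.  The gas model additionally derives the dimensionless
air:water Henry ratio $K_{wa} = HLC/(R\,T_{body})$ and
$K_{blood:air} = K_{blood:water}/K_{wa}$, with blood:water built from fup,
hematocrit and the red-blood-cell partition coefficient.

# The model suite and the registry contract

Four models register at load: `1compartment`, `3compartmentss`
(steady-state only, no ODE), `pbtk`, and `gas_pbtk`.  Every registry entry
declares state variables, the full parameter-name set (parameterization
must match it exactly), the ordered names of everything the derivative
routine emits, per-output units and phase (gas vs liquid), dosing routes
and their target states, data requirements, and steady-state / Monte Carlo
descriptors.  `validate_model()` probes the derivative routine with
sentinel states and fails if the declared output ordering disagrees with
what the routine actually emits — the failure mode in which a permuted
declaration silently reports a ppmv column as µM.

State variables are amounts (µmol); concentrations are derived outputs.
This makes mass balance exact: at every time, compartment amounts plus the
cumulative urine, metabolism, unabsorbed and exhaled accumulators must
equal cumulative administered plus inhaled input, and
`check_mass_balance()` reports the worst relative defect (integration
error only; < 1e-6 at default tolerances).

The pbtk ODEs are perfusion-limited: blood leaving tissue $i$ carries
$C_i R_{b2p}/(K_{p,i} f_{up})$; liver receives the hepatic artery plus gut
outflow and clears at $Cl_w C_{liver}/K_{p,liver}$ (unbound concentration);
kidney filters $GFR \cdot f_{up} \cdot C_{art}/R_{b2p}$ into a cumulative
urine accumulator; lung sits in series between venous and arterial blood.
The gas model replaces the lung inlet with steady-state alveolar
equilibration,

$$C_{art}^{eq} = \frac{Q_{alv} C_{inh} + Q_C C_{ven}}{Q_C + Q_{alv}/K_{blood:air}},
\qquad C_{exh} = C_{art}^{eq}/K_{blood:air},$$

which is mass-conserving by construction, adds cumulative inhaled/exhaled
accumulators, reports end-exhaled air in both ppmv and µM, and includes a
first-order upper-respiratory mucus compartment that strips a small
fraction (default 2%) of the inhaled stream and desorbs it into the gut
lumen (swallowed); both mucus constants are configurable, as the available
literature formulations differ.  With zero exposure and a non-volatile
chemical the gas model reproduces pbtk oral kinetics.

Dosing is event-driven: doses are instantaneous "add" events on the target
state (gut lumen for oral, venous blood for iv), per-kg doses scale through
`scale_dosing()`, `doses_per_day` expands to equally spaced events, and
inhalation exposure is a piecewise-constant forcing series.  Event and
forcing times are inserted into the solver grid automatically; only
requested times are returned.

## Numerical strategy

The built-in systems are linear and time-invariant in the state (the
forcing enters affinely).  `solve_model()` therefore probes the registered
derivative routine once per run to assemble the system matrices, verifies
that the linearization reproduces the routine at a random probe state to
1e-9, and integrates with a matrix-vector right-hand side and an exact
constant Jacobian under `deSolve::lsoda`.  If verification fails (e.g. a
user registers a nonlinear model), the raw routine is used directly.  The
derivative routines remain the single source of truth — the same probing
strategy builds the analytic pbtk steady state by solving $J x = -b$, so
no separately transcribed steady-state formula can drift out of step with
the ODEs.

# Steady state

"Steady state" is the quasi-steady state of repeated discrete dosing.
Analytic solutions: the one-compartment and three-compartment models use
their closed forms (e.g. $C_{ss} = F\,\text{rate}/(f_{up} GFR + CL_h)$),
and pbtk solves the linear system as above.  The numerical route
(`calc_css()`) simulates repeated dosing — three doses per day by default —
and tracks the day-averaged plasma concentration computed exactly from the
AUC accumulator, declaring steady state at the first day whose average
changes by less than 1% (configurable) from the previous day.
Day-averaging makes detection independent of dosing phase.  For a linear
system the time-average of the periodic steady state equals the
constant-infusion steady state, so analytic and numerical routes agree once
accumulation is complete; slowly cleared chemicals (elimination rates below
roughly 0.03/day) genuinely do not equilibrate within a 100-day horizon,
which the non-convergence flag and the projected remaining accumulation
(geometric extrapolation of the daily averages) make explicit.  Package
checks that compare the two routes therefore restrict to chemicals whose
projected remaining accumulation at the horizon is below 1% — a
completeness guard, not a tolerance.

# Monte Carlo

`create_mc_samples()` runs four ordered steps on top of the baseline
parameter set, tagging each parameter with the last step that touched it:

1. **Truncated/censored sampling** of user-nominated parameters: normal
   with the given CV, truncated at zero via the inverse CDF; below an LOD,
   draws are replaced uniformly on [0, LOD) — the censoring rule is
   documented and configurable since conventions differ.
2. **Population physiology** (human only): a parametric stand-in for a
   survey-based population simulator — correlated lognormal marginals with
   default CVs of 20% (body weight) and 30% (flows, ventilation, GFR,
   hepatocellularity) and a Gaussian-copula correlation of 0.4.  Only the
   model's declared population parameters are overwritten.  The interface
   matches a survey-backed sampler so one can drop in later.
3. **In vitro uncertainty**: Clint 4-tuples sample a zero-inflated
   lognormal — each draw is zero with probability `p_no_effect`
   (a per-draw Bernoulli rather than an all-or-nothing p-value cutoff; a
   "hard" mode using the 0.05 threshold is retained) — otherwise
   quantile-matched to the tuple; fup uses the analogous logit-normal
   bounded to (0, 1]; point values use default CVs of 30%.
4. **Recalculation** of dependent parameters: partition coefficients from
   each individual's fup (`calcpc`), scaled whole-liver clearance, and
   first-pass bioavailability (`firstpass`), plus a model-specific hook
   (the one-compartment model recomputes volume of distribution and
   elimination rate).

With every variance source disabled the sample table is the baseline
replicated, and every Monte Carlo endpoint equals its deterministic
counterpart exactly — the degeneracy identity the test suite asserts.
`calc_mc_css()` evaluates the analytic steady state per row and reports
quantiles (default the 95th percentile at 1 mg/kg/day, the conservative
screening convention); `calc_mc_oral_equiv()` inverts the linear dose–Css
map for reverse dosimetry; `calc_mc_tk()` runs full ODE solves for models
without an analytic steady state, reporting per-time mean and SD.

# Evaluation

The headline statistic is the RMSLE,
$\sqrt{\mathrm{mean}((\log_{10}\hat c - \log_{10}c)^2)}$, optionally
averaging within chemicals before across so data-rich chemicals do not
dominate; explained variance is computed as total explained variance of
predictions (not a regression R²) and may be negative.  Observed zeros are
floored at a configurable LOQ/2 before the log transform.
`generate_synthetic_observations()` simulates randomized study conditions
and perturbs them with lognormal noise; with zero noise the comparison
recovers RMSLE ≈ 0 and with noise σ it recovers σ — the self-consistency
and noise-recovery properties the suite asserts.  `benchmark_suite()`
bundles the standing package-health checks (eligibility counts, the
(mg/L ÷ µM)·1000/MW ≡ 1 unit identities for analytic, Monte Carlo and
solved outputs, and the "noMC" RMSLE between Monte Carlo median and
analytic Css) into a report that can be appended to a version-keyed
performance ledger.

# What the synthetic generator does and does not emulate

Defaults: MW lognormal (median 250 g/mol, GSD 1.6); logP N(2, 1.5); fup
logit-normal with 10% stored as 3-tuples and 5% recorded as 0; Clint
zero-inflated lognormal (10% structural zeros, median 10, GSD 3) with 20%
stored as 4-tuples; log10 HLC uniform on (−4, −1) for the volatile stratum
(20% by default) and (−10, −6) otherwise; 5% PFAS-tagged; ~30% acids and
~30% bases with uniform pKa; 30% of chemicals carry rat-specific values.
These are one-time choices representing a plausible commercial-chemical
screening library.  The generator emulates marginal distributions and
encoding conventions, not the correlation structure of real chemistry
(logP–fup dependence, measurement error heteroscedasticity, assay-specific
biases) — so green tests demonstrate the machinery's correctness and
internal consistency, not predictive accuracy against in vivo data, which
requires external concentration-vs-time compilations out of scope here.

# Problem sizes and numerical choices

Default solver tolerances are rtol 1e-8 / atol 1e-10 (mass-balance checks
use 1e-10/1e-12).  Package checks use libraries of 10–50 synthetic
chemicals, Monte Carlo sizes of 100–1000 (moment-recovery checks use 1e4 to
1e5 draws of the cheap samplers), 200 synthetic observation conditions for
noise recovery, and 100-day horizons for steady-state comparisons; these
sizes hold the statistical assertions' Monte Carlo error well inside the
asserted tolerances.  ppmv conversions default to 298.15 K for ambient air;
the blood:air partition and exhaled-breath reporting use body temperature
from the physiology table — a convention choice documented here because
reference implementations are silent on it.  Degenerate inputs fail loudly:
fup = 0 must go through the default-substitution path, non-clearing
chemicals raise a dedicated error rather than returning infinity, and a
chemical too non-volatile for the gas model triggers an out-of-domain
warning.

# Known limitations

Partition calibration defaults to identity (published calibration constants
can be supplied but are not bundled); renal transport, enterohepatic
recirculation, saturable metabolism and delay equations are out of scope;
the population sampler is parametric, not survey-based; the gas model has
no analytic steady state (use `calc_mc_tk()`); species beyond Human and Rat
require extending the physiology CSV.
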