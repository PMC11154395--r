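---
title: "Threshold-hazard TK–TD modelling of copper in bivalves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-hazard TK-TD modelling of copper in bivalves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tktdcu)
```

## The scientific problem

Dissolved copper is taken up by filter-feeding bivalves roughly in
proportion to its waterborne concentration, and becomes lethal once the
internal burden passes a tolerance threshold. Dissolved organic carbon
(DOC, largely humic acid) binds Cu²⁺ and changes how much of the
dissolved pool is bioavailable, so the same nominal exposure produces
different uptake rates and different mortality at different DOC levels.
Tracer studies expose animals to enriched ⁶⁵Cu so that newly accumulated
metal can be separated from the (substantial) natural background.

`tktdcu` implements the full analysis chain for such a study: isotope
background correction, a one-compartment toxicokinetic (TK) model, a
threshold-hazard toxicodynamic (TD) survival model, staged nonlinear
least-squares estimation, dose metrics (Michaelis–Menten uptake
saturation, model-implied and probit LC50), and a seeded generator of
virtual experiments used to validate the estimators by parameter
recovery.

## Models and assumptions

### Toxicokinetics

$$\frac{dC_{int}}{dt} = k_u C_w(t) - k_e C_{int}(t)$$

* One well-mixed compartment; tissue concentrations on a dry-weight
  basis (µg g⁻¹).
* Uptake is linear in the dissolved concentration at fixed water
  chemistry; DOC effects enter through treatment-specific $k_u$, not as
  a modelled binding mechanism.
* Elimination is first-order and a property of the organism: one $k_e$
  is shared across all treatments.
* Growth dilution is neglected (appropriate for experiments of about a
  week with no measurable growth).
* The tracer starts at zero internal concentration — background ⁶⁵Cu is
  removed by the isotope correction, so $C_{int}(0) = 0$.

Solutions are closed-form on every interval where $C_w$ is affine in
time. Internally an exposure profile is compiled into segments; with
$\tau$ the time inside a segment and $k_e > 0$,
$C_{int}(\tau) = P + Q\tau + R e^{-k_e \tau}$ with constants propagated
across segment boundaries, so trajectories are continuous and exact. The
$k_e = 0$ limit is handled analytically (quadratic-in-time solution),
never by substituting a small $k_e$, which would cancel catastrophically
in round-trip tests.

### Toxicodynamics

$$\frac{dH}{dt} = k_k \max(C_{int}(t) - C_{IT}, 0) + h_0,
  \qquad S(t) = e^{-H(t)}$$

This is the stochastic-death member of the GUTS family: all individuals
share one threshold $C_{IT}$ and hazard accrues in proportion to the
excess burden. The individual-tolerance variant (population-distributed
thresholds) is deliberately out of scope. $h_0$ defaults to zero —
the standard reading when control mortality is absent — but can be
estimated (`estimate_h0 = TRUE`).

The hazard integral $\int \max(C_{int} - C_{IT}, 0)\,ds$ is evaluated
exactly. On each TK segment the integrand is an exponential-affine (or
polynomial) function with at most one interior stationary point; the
segment is split into monotone pieces, threshold crossings are solved in
closed form where the exposure is constant ($\log$ solution) and by
bisection to $10^{-13}$ h otherwise, and the antiderivative is applied
piecewise. Mortality fits are sensitive to integration error near the
threshold, which is why no generic quadrature is used on model
trajectories; arbitrary user-supplied $C_{int}$ functions fall back to
adaptive quadrature (absolute tolerance $10^{-8}$).

### Units

Hours are the internal time base everywhere; all rates are stored in
h⁻¹. Elimination rates are conventionally reported per day, so
`ke_per_day_to_per_hour()` / `ke_per_hour_to_per_day()` convert at I/O
boundaries and report tables show $k_e$ in d⁻¹ alongside $k_u$ in
L g⁻¹ h⁻¹. Mixing the two bases inside the computation is the single
most likely source of silent error in this kind of analysis, hence the
hard rule.

### Isotope correction

Two corrections from (total ⁶⁵Cu, ⁶³Cu) readings to newly accumulated
tracer are exposed as explicit modes of `tracer_correct()`:

* `as_printed` (default): $([^{65}Cu] - [^{63}Cu]) \cdot F_{65}$ with
  $F_{65} = 0.3085$;
* `abundance_ratio`: $[^{65}Cu] - [^{63}Cu] \cdot F_{65}/F_{63}$, the
  conventional natural-abundance subtraction in which the ⁶³Cu signal
  (entirely background) is scaled to the background ⁶⁵Cu it implies.

The two differ whenever background is present, and field usage is
inconsistent enough that silently choosing one would be wrong; the mode
is therefore a visible argument and a config field. Noise can push the
corrected value negative: such values are clipped to zero and flagged
(attribute `clipped`), never dropped, so downstream fits can decide.

## Estimation

All fits go through `lm_fit()`, a contract over Levenberg–Marquardt
damping (`minpack.lm::nls.lm`) with convergence tolerances
`ftol = gtol = ptol = 1e-10`, at most 500 iterations, box constraints
(all rate/threshold parameters bounded below by 0), and the classical
covariance estimate $\widehat{\sigma}^2 (J^\top J)^{-1}$ with
$\widehat{\sigma}^2 = \mathrm{RSS}/(n-p)$; reported SDs are the square
roots of its diagonal. Underdetermined problems ($n \le p$) and
non-finite residuals are hard errors naming the offending parameter
vector.

The staged scheme mirrors how such designs are identified:

1. **`fit_ke_shared()`** — one $k_e$ jointly across every depuration
   series, each series keeping its own initial concentration as a
   nuisance parameter. Initialisation: pooled log-linear regression
   slope. Only the lowest exposure group typically has depuration data,
   so a joint all-parameter fit would be weakly identified; the staged
   default reflects that, with `joint_tk = TRUE` available per
   treatment.
2. **`fit_ku()`** — single-parameter fit per treatment with $k_e$
   fixed, $C_{int}(0)=0$, and the treatment's exposure profile.
   Initialisation $k_{u,0} = C_{int}(t_{last}) / (\bar C_w t_{last})$.
3. **`fit_td()`** — $(C_{IT}, k_k)$ per humic-acid level against pooled
   survival fractions $n_{alive}(t)/n_0$, using that level's fitted
   $k_u$ at the toxicity-test concentration. Deaths recorded at
   6–8 h walkthroughs are assigned to the interval's right endpoint in
   the least-squares mode; the `multinomial_likelihood` mode instead
   maximises the interval-censored death-count likelihood (statistically
   exact for counts) and agrees with least squares in the small-noise
   limit. Initialisation: $C_{IT,0}$ = modelled tissue concentration at
   the first recorded death, $k_{k,0} = 0.01$.

Pooling replicates with equal initial counts is equivalent to weighting
by group size. We deliberately do **not** down-weight later observation
times by the number still alive: that would discard exactly the all-dead
observations that pin down the killing rate.

If no deaths occur, $C_{IT}$ has no point estimate — only the lower
bound $\max_t C_{int}(t)$. `fit_td()` raises a classed condition
(`tktd_unidentifiable`) carrying that bound rather than returning a
spurious fit.

### Identifiability at reference parameters

With the reference parameter magnitudes (killing rate of order
10 (µg g⁻¹)⁻¹ h⁻¹ and uptake of order 10² µg g⁻¹ h⁻¹ at the
toxicity-test concentration), model survival collapses from 1 to
essentially 0 within a fraction of one 6–8 h recording interval. Data
recorded at that cadence then contain no interior survival fractions and
$(C_{IT}, k_k)$ are jointly unidentifiable — any sufficiently steep
threshold model reproduces the observed step. This is a property of the
design–parameter combination, not of the estimator. Consequently:

* the generator's recording interval (`tox_check_interval`) is a design
  field, and TD recovery is validated on schedules dense enough to
  straddle the survival drop;
* binomial-noise TD recovery is demonstrated at gentler killing rates,
  where an 8-h cadence carries information;
* `recover_study()` reports TD parameters only when interior survival
  fractions exist.

## The synthetic-data generator

`generate_uptake_depuration()` and `generate_toxicity()` emulate the
study design the package targets: 4 nominal humic-acid levels (0/5/10/20
mg L⁻¹, measured DOC 0.58/3.05/5.61/8.98 mg L⁻¹), 3 nominal ⁶⁵Cu levels
(15/150/300 µg L⁻¹), a 12-h uptake phase sampled every 3 h with six
tissue measurements per point (2 individuals × 3 replicate tanks), a
168-h depuration phase (12/24/48/72/120/168 h, 15 µg L⁻¹ groups only),
and a 96-h toxicity test at 300 µg L⁻¹ with 3 × 20 individuals.

Statistical structure, chosen as the minimal model consistent with the
data types:

* concentrations carry multiplicative unit-mean lognormal noise,
  $\mathrm{LogNormal}(-\sigma^2/2, \sigma)$ with
  $\sigma^2 = \log(1 + CV^2)$ and default CV 0.15 (typical for ICP-MS
  tissue measurements with biological replication) — ratio-scale,
  strictly positive;
* deaths per recording interval are binomial draws from the conditional
  mortality $1 - S(t_2)/S(t_1)$ of the survivors at $t_1$, so counts
  are never negative and never resurrect;
* the recording interval defaults to 8 h (the coarse end of a 6–8 h
  walkthrough) for deterministic fixtures;
* optional first-order water loss (`cw_loss_rate`) produces a declining
  piecewise-linear exposure profile on the 3-h water-sampling grid,
  matching unreplaced test media.

Everything is reproducible from the design's integer seed, including
byte-identical CSV output.

What the generator does **not** emulate: Cu speciation and Cu–DOC
binding chemistry (treatments differ only through their parameter
values), depletion of the cohort by destructive sampling (the pooled
one-compartment model ignores it too), inter-individual tolerance
spread, and tank effects beyond replicate labels. Passing recovery
tests therefore demonstrates that the estimation machinery inverts the
stated model faithfully — not that the model captures every feature of
a live experiment.

A deliberate consequence of using published best-fit values as
simulation truth: the virtual tissue concentrations they imply do not
match empirically reported 12-h accumulations (the forward prediction
overshoots by an order of magnitude under either plausible unit reading
of $k_u$), and model-implied LC50s computed from those parameters do not
match empirically reported LC50s either. The package treats the printed
parameter set strictly as ground truth for generate-then-refit
validation and makes no claim to reproduce the underlying raw
observations, which were never published.

## Numerical choices

* **Closed forms over ODE solvers** everywhere in the fit path: the
  model admits exact piecewise solutions, so solver tolerance never
  contaminates gradients. A fourth-order Runge–Kutta oracle (restarted
  at exposure breakpoints) is used in the test suite only, with
  agreement required to $10^{-6}$ relative.
* **LC50 bisection** on $C_w \mapsto S(T \mid C_w)$ to
  $10^{-3}$ µg L⁻¹ by default (argument-adjustable); the bracket must
  straddle $S = 0.5$ and the error message reports survival at both
  ends. In the $C_{IT}=0$, $k_e=0$ limit the closed form
  $LC_{50} = 2\ln 2/(k_k k_u T^2)$ provides an independent check.
* **Probit LC50** by maximum-likelihood `glm` with a probit link on
  $\log_{10}$ dose (the convention of standard acute-toxicity tooling),
  $LC_{50} = 10^{-\beta_0/\beta_1}$, delta-method CI on the log scale.
  Complete separation (every dose at 0 % or 100 % mortality) raises a
  classed error instead of a divergent fit.
* **Michaelis–Menten fits** are initialised at
  $J_{max,0} = 1.2\max(J_{int})$, $K_{m,0} = \mathrm{median}(C_w)$;
  data with no detectable curvature trigger a warning that $K_m$ is
  unbounded rather than a confident-looking estimate.
* Singular $J^\top J$ (flat directions at the optimum) falls back to an
  SVD pseudo-inverse for the covariance, so SDs on identifiable
  parameters survive a degenerate partner.

## Validation problem sizes

The shipped test suite validates at sizes chosen to make each check
sharp but quick: oracle agreement on 100 random parameter/exposure
draws; noise-free recovery of all 12 uptake rate constants, the shared
elimination rate, TD parameters (dense schedule) and Michaelis–Menten
parameters to at least four significant figures; calibration of the
shared-$k_e$ estimator across 200 seeded noisy replicates of the
four-series design; probit CI coverage over 1000 simulated assays; and
median-of-200-replicates recovery of $k_u$ under 15 % noise. The
acceptance script (`scripts/acceptance.R`) re-runs the recovery
computations from scratch at any seed.

## Known limitations

* Single compartment, no growth dilution, no physiology — adequate for
  short tracer designs, not for field-scale bioaccumulation.
* The stochastic-death hazard form only; no individual-tolerance or
  damage-stage variants.
* DOC acts as a treatment label, not a mechanistic covariate; the
  package does not compute speciation (no biotic-ligand-model step).
* Fit SDs are curvature-based (classical Marquardt reporting), not
  profile or bootstrap intervals.
* TD parameters are unidentifiable from coarse mortality schedules when
  the killing rate is fast (see above); the package reports this
  honestly rather than fitting through it.
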