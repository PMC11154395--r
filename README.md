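# tktdcu

Toxicokinetic–toxicodynamic (TK–TD) modelling of waterborne copper
accumulation and lethality in filter-feeding bivalves, built for tracer
exposure studies in which dissolved organic carbon (humic acid) modulates
copper bioavailability.

## Who this is for

Ecotoxicologists analysing stable-isotope (⁶⁵Cu) tracer experiments on
bivalves: short uptake phases with tissue sampling, a depuration phase in
clean water, and an acute toxicity test scored as survival counts. The
package fits the mechanistic models behind such designs, simulates
virtual experiments with known ground truth, and checks that the
estimation machinery recovers what generated the data.

## The models

**Toxicokinetics** — one-compartment first-order kinetics linking the
dissolved concentration $C_w(t)$ (µg L⁻¹) to the tissue concentration
$C_{int}(t)$ (µg g⁻¹ dry weight):

$$\frac{dC_{int}}{dt} = k_u\,C_w(t) - k_e\,C_{int}(t), \qquad
  J_{int}(t) = k_u\,C_w(t)$$

with uptake rate constant $k_u$ (L g⁻¹ h⁻¹) and elimination rate
constant $k_e$ (h⁻¹). Solutions are closed-form, composed across the
affine segments of the exposure profile (constant, step, or
piecewise-linear $C_w$).

**Toxicodynamics** — threshold-hazard (stochastic-death) survival:

$$\frac{dH}{dt} = k_k\,\max(C_{int}(t) - C_{IT},\,0) + h_0, \qquad
  S(t) = e^{-H(t)}$$

Hazard accrues only while the tissue concentration exceeds the internal
threshold $C_{IT}$ (µg g⁻¹), at killing rate $k_k$ ((µg g⁻¹)⁻¹ h⁻¹);
$h_0$ is the background hazard (zero when controls show no mortality).
The hazard integral is evaluated exactly (piecewise analytic, with
threshold crossings solved per segment).

**Estimation** is staged Levenberg–Marquardt nonlinear least squares:
one shared $k_e$ from all depuration series jointly, then $k_u$ per
treatment with $k_e$ fixed, then $(C_{IT}, k_k)$ per humic-acid level
from pooled survival fractions (an interval-censored multinomial
likelihood mode is available). Dose metrics include Michaelis–Menten
saturation of $J_{int}$ versus $C_w$ ($J_{max}$, $K_m$), model-implied
LC50 by bisection on $S(96\,h\,|\,C_w) = 0.5$, and probit LC50 from
mortality counts.

## Worked example

Simulate a realistic virtual study (4 humic-acid levels × 3 Cu levels,
12-h uptake sampled every 3 h with n = 6, 168-h depuration at 15 µg L⁻¹,
15 % lognormal measurement noise) and refit it:

```r
library(tktdcu)
des   <- experiment_design(noise_cv = 0.15, seed = 1)
truth <- ground_truth()        # reference best-fit parameter set
study <- fit_study(generate_uptake_depuration(des, truth))
study
#> Toxicokinetic-toxicodynamic study fit
#>   shared ke: 0.0545 ± 0.00583 /d
#>   12 uptake fits, 0 toxicodynamic fits (least_squares objective)
#>  ha_mg_l           ku_15         ku_150          ku_300 c_it   kk
#>        0 0.304 ± 0.00697 0.615 ± 0.0154  0.46 ± 0.00919 <NA> <NA>
#>        5   0.29 ± 0.0101 0.607 ± 0.0164   0.473 ± 0.017 <NA> <NA>
#>       10 0.285 ± 0.00678 0.606 ± 0.0146 0.413 ± 0.00916 <NA> <NA>
#>       20 0.261 ± 0.00813 0.559 ± 0.0119  0.411 ± 0.0121 <NA> <NA>
```

Reading the output: the shared elimination rate (here 0.0545 d⁻¹, truth
0.0582 d⁻¹) is identified from the depuration series; each cell of the
table is an uptake rate constant (L g⁻¹ h⁻¹, estimate ± SD) for one
(humic acid, Cu) treatment, recovered within sampling error of the
generating values (e.g. 0.304 ± 0.007 vs a true 0.307 at HA = 0,
15 µg L⁻¹). `ku` declines as humic acid rises — the bioavailability
effect the design probes. The TD columns stay empty until toxicity-test
survival data are supplied (`tox_datasets =`), and
`study$kinetics_table` summarises uptake saturation, e.g. at HA = 0:
`jmax = 311`, `km = 370` (µg g⁻¹ h⁻¹ and µg L⁻¹; three exposure levels
give wide SDs on these two).

The file-based pipeline (`run_analysis()`, plus the `tktd.R` CLI in
`inst/cli/`) reads tidy tissue/water/survival CSVs, or a `simulate:`
block, and writes `params_table.csv`, `kinetics_table.csv`,
`survival_curves.csv`, `fit_diagnostics.csv` and a run log.

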