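---
title: "Methods: from A/Ci curves and leaf pigments to Vcmax25"
author: "photocap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from A/Ci curves and leaf pigments to Vcmax25}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocap)
```

## The problem

The maximum Rubisco carboxylation rate normalized to 25 °C (Vcmax25) is the
single most influential leaf parameter in process-based models of C3
photosynthesis, and it varies strongly through a crop's season. Measuring it
requires gas-exchange CO₂-response (A/Ci) curves, which do not scale to
landscapes; leaf pigments, by contrast, can be retrieved remotely. `photocap`
implements the full inference chain needed to study how well leaf nitrogen
(N_area), chlorophyll (Chl_area) and carotenoid (Car_area) content predict
Vcmax25 in a winter-wheat field campaign: A/Ci curve fitting, temperature
normalization, pigment and structural trait derivation, leaf-nitrogen
partitioning, and the statistical layer (correlations, regression battery,
random-forest importance, seasonal summaries). Because raw field campaigns of
this kind are rarely published, the package also ships a synthetic season
generator with known ground truth; every stage is validated by parameter
recovery against that truth.

## The FvCB model and the A/Ci fitter

Net assimilation of a C3 leaf is modeled as

$$A = \min(A_c, A_j) - R_d, \qquad
A_c = \frac{V_{cmax}\,(C_i - \Gamma^*)}{C_i + K_c\,(1 + O/K_o)}, \qquad
A_j = \frac{J\,(C_i - \Gamma^*)}{4\,C_i + 8\,\Gamma^*}.$$

Curves follow a saturating-light protocol (PPFD 1500 µmol m⁻² s⁻¹; Ca
stepped through 380, 300, 200, 100, 50, 380, 600, 800, 1000, 1200 µmol
mol⁻¹), so the electron-transport rate J is taken equal to Jmax; a
non-rectangular-hyperbola light response (`electron_transport()`) is provided
but unused by default. Rubisco kinetics (Kc, Ko, Γ*) default to the Bernacchi
in-vivo parameterization at the curve's leaf temperature — the de-facto
standard of A/Ci fitting tools — and are swappable through
`kinetic_constants()`. Mesophyll conductance is treated as infinite (the
model is Ci-based) and triose-phosphate limitation is not modeled; a flagged
cleaning rule (`trim_tpu`) can drop high-CO₂ points whose assimilation
declines with rising Ci.

`fit_aci()` estimates (Vcmax, Jmax, Rd) by making the limitation partition
explicit. For each candidate transition taken from the observed Ci values
(with at least 3 points below and 2 above), points below are modeled as
Rubisco-limited and points above as RuBP-limited. Conditional on the
partition the model is *linear* in the three parameters, so each candidate is
solved by ordinary least squares; the partition with the smallest SSE wins,
and ties break deterministically toward the larger Rubisco segment. Two
refinements matter in practice:

* **Bounded Rd.** Day respiration trades off against Vcmax along the lower
  curve segment; Rd is therefore constrained to [0, 5] µmol m⁻² s⁻¹ (a
  bounded refit replaces the OLS solution only when it leaves that range).
* **Min-consistency iteration.** A threshold partition cannot represent one
  property of the min rule: below Γ* the RuBP expression is again the
  smaller rate, so the Ca = 50 step (Ci = 35 µmol mol⁻¹ at the default
  Ci/Ca ratio) is not Rubisco-limited. After the threshold search the fitter
  relabels every point to the argmin of the fitted Ac/Aj and refits until the
  labels are stable. Each sweep cannot increase the SSE of the actual
  min-model; on noise-free curves the iteration recovers the generating
  parameters to machine precision, where the plain threshold fit carries a
  ~4 % bias.

The duplicated Ca = 380 step exists as a stability check of the instrument
protocol and is excluded from fitting by default (`use_duplicate_380 = TRUE`
keeps it). `a_sat_from_curve()` reads the light-saturated assimilation at
ambient CO₂ from the first (acclimated) 380 step, or the mean of both.

Whether this fitter is numerically equivalent to any particular spreadsheet
tool used in field studies cannot be asserted — those tools do not document
their algorithms — so the package's claims rest on internal round-trip
consistency: noise-free recovery is exact, and across 200 simulated curves
with Gaussian noise of sd 0.3 µmol m⁻² s⁻¹ the median absolute Vcmax error
is about 1 % with bias well under 2 % (see `tests/testthat/test-acceptance.R`).

## Temperature normalization

Capacities measured at leaf temperature Tk are normalized with the pure
Arrhenius response

$$f(T_k) = k_{25}\,\exp\!\big(c - \Delta H_a / (R\,T_k)\big),$$

with R = 0.008314 kJ mol⁻¹ K⁻¹ and the conventional constant pairs
(c = 26.355, ΔHa = 65.33 kJ mol⁻¹) for Vcmax and (c = 17.710, ΔHa = 43.90)
for Jmax. Both pairs satisfy the defining identity
exp(c − ΔHa/(R·298.15)) = 1 to better than 10⁻³, so normalization is a
near-identity for cuvette-controlled 25 °C measurements; the operation is
kept general because field leaf temperatures vary. No peaked (deactivation)
form is added: the temperature range of interest sits below the optimum and
the added entropy parameter would be unidentifiable from these data.

## Leaf biochemistry

Pigments are quantified from 95 %-ethanol extract absorbances at 665, 649 and
470 nm with the standard coefficient set for that solvent
(concentrations in µg mL⁻¹):

```
Chl a = 13.95 A665 − 6.88 A649
Chl b = 24.96 A649 − 7.32 A665
Car   = (1000 A470 − 2.05 Chl a − 114.8 Chl b) / 245
```

scaled by extract volume, dilution and leaf area to µg cm⁻². These
coefficients are the single source of truth for the pigment oracle in the
test suite; an alternative set can be supplied per call. Negative computed
concentrations are below-detection artifacts and are clipped to zero with a
counted warning.

Structural traits follow from dry mass and area: SLA = area/mass (cm² g⁻¹),
M_A = 10⁴/SLA (g m⁻²), N_area = M_A·N_mass. Leaf nitrogen is partitioned
into photosynthetic pools as

$$P_R = \frac{V_{cmax25}}{6.25\,V_{cr}\,M_A\,N_{mass}}, \quad
P_B = \frac{J_{max25}}{8.06\,J_{mc}\,M_A\,N_{mass}}, \quad
P_L = \frac{C_c}{C_B\,N_{mass}},$$

with V_cr = 20.5 µmol CO₂ (g Rubisco)⁻¹ s⁻¹, J_mc = 156 µmol electrons
(µmol cyt f)⁻¹ s⁻¹ (both 25 °C activities), C_B = 2.15 mmol g⁻¹, and the
6.25 / 8.06 factors fixed parts of the equations. Because V_cr and J_mc are
25 °C values, the fractions use temperature-normalized capacities by default;
rates at leaf temperature can be passed deliberately. C_c (mmol chlorophyll
per g dry mass) is derived from area-based chlorophyll via M_A and a mean
chlorophyll molar mass of 901 g mol⁻¹ (an a:b ≈ 3:1 average of 893.5 and
907.5) — the molar mass is not standardized in the source equations, so it is
an explicit, documented constant here. Fractions outside (0, 1) signal
implausible inputs and warn with the leaf id rather than fail.

## The synthetic season generator

The generator emulates a single-season winter-wheat campaign: 8 measurement
days (DOY 92–147) with 3–4 leaves each (29 in total) spanning elongation,
booting, flowering and filling stages. Its defaults *are* the study
conditions, chosen once:

* **Trajectories.** Every trait mean follows a single-peaked piecewise-linear
  path anchored at the first DOY, the flowering peak (DOY 126) and the last
  DOY; SLA declines monotonically. Vcmax25 anchors (82.4, 133.46, 46.0
  µmol m⁻² s⁻¹) and the other anchors reproduce the reported peak values and
  seasonal percent changes of such campaigns. Rd25 is 1.5 % of Vcmax25,
  typical of unstressed C3 leaves.
* **Chlorophyll from the N ratio.** The share of leaf N invested in
  chlorophyll rises early and stabilizes: the Chl_area/N_area ratio (both
  µg cm⁻²) follows 0.23 → 0.32 → 0.36 over DOY 92–105 and plateaus
  thereafter. By default the chlorophyll mean is generated as
  ratio(DOY) × N mean, which pins the late-season ratio at the plateau by
  construction (`chl_mode = "anchors"` reverts to independent anchors). A
  reported seasonal Chl increase of 68 % between DOY 92 and 126 is not
  simultaneously satisfiable with those ratios and a 26 % N increase (they
  imply ≈ 97 %); the generator follows the ratio trajectory, which is the
  quantity the allocation analysis depends on.
* **Noise.** Within-day trait variation is multiplicative lognormal with a
  per-trait CV (traits are positive); instrument noise on assimilation is
  additive Gaussian (default sd 0.3 µmol m⁻² s⁻¹). Leaf-level deviations are
  coupled through one shared "vigor" factor z: each trait deviates on the
  log scale by ρ·z + √(1−ρ²)·ε. Vcmax25 carries ρ = 1, so a trait's ρ is its
  within-day noise correlation with Vcmax25. The CV/coupling defaults
  (Chl 0.18/0.85, Car 0.11/0.70, N 0.23/0.22, SLA 0.10/0.05) were calibrated
  once so that season-level correlations of Vcmax25 with Chl/Car/N average
  about 0.83/0.68/0.58, the structure reported for winter wheat; within-day
  variances are otherwise unreported in the field literature and these are
  the package's standing choices.
* **Curves.** Ci is derived from each Ca setpoint with a constant Ci/Ca
  operating ratio of 0.7 (a typical C3 value). Stomatal behavior is not
  modeled: the fitter consumes Ci directly, so any fixed coupling rule
  suffices and the choice does not affect recovery. Capacities are projected
  from 25 °C to the cuvette temperature with the same Arrhenius response the
  normalization stage inverts.
* **Seeding.** One master seed; per-leaf streams derive from a stable hash
  of (seed, leaf id), so seasons are reproducible leaf-by-leaf and
  independent of the caller's RNG state.

What the generator does **not** emulate: instrument drift, leaks or humidity
excursions; TPU limitation; stomatal dynamics; multi-year or multi-site
designs; spatial correlation within the plot. Passing recovery tests on this
generator therefore demonstrates the correctness of the estimation chain
under its stated noise model, not robustness to every pathology of real
gas-exchange data.

### The coupling probe

In a seasonal configuration all traits share the phenological trend, so
season-level correlation mixes trajectory amplitude with leaf-level coupling:
nitrogen's larger seasonal amplitude can outweigh carotenoid's stronger
coupling, and an imposed coupling *ordering* is then confounded. For
experiments about ordering propagation the package provides
`coupling_probe_config()`: all trait means held flat at flowering-stage
levels, a common CV of 0.35, couplings Chl 0.95 > Car 0.80 > N 0.60 >
SLA 0.00. In this configuration each trait's correlation with Vcmax25 equals
its coupling by construction, which is what makes the ordering test
well-posed at n = 29. The validation suite runs ten such seasons through the
full simulate → fit → normalize chain and checks that the simple-regression
R² ordering (Chl > Car > N) and the %IncMSE ranking (Chl ≥ Car > N > SLA)
hold in at least 8 of the 10; at this sample size occasional rank flips of
the weaker predictors are expected behavior, not failures.

## The statistical layer

* `pearson_r()` reports the product-moment correlation with the two-sided
  t-test p-value; `correlation_matrix()` stars pairs at 0.05/0.01/0.001. No
  multiple-testing correction is applied — the battery is small and
  conventional practice in this literature reports unadjusted p-values.
* `fit_linear_model()` / `model_suite()` fit the ten-model battery (six
  simple models: Vcmax25 and Jmax25 on each of N, Chl, Car; four multiple
  models for Vcmax25) by OLS with R² and the overall ANOVA F-test.
  Nitrogen enters regressions in g m⁻² and pigments in µg cm⁻² — the units
  on which published coefficient magnitudes are comparable — and the units
  are stored in the model metadata rather than assumed silently.
* `rf_importance()` defines %IncMSE as 100 × (raw out-of-bag permutation
  importance, averaged over trees) / OOB MSE: the percent increase in OOB
  mean squared error when one predictor's values are permuted. Forest
  defaults: 500 trees, ⌈p/3⌉ predictors per split, explicit seed; results
  are deterministic given the seed. Note that a z-score variant circulates
  under the same name in some software; the definition used here is the
  percentage one.
* `seasonal_changes()` reports percent change between two days under *both*
  conventions — relative to the earlier mean and relative to the later mean —
  because field reports mix them (a decline can only exceed 100 % under the
  latter). Both columns are always present and labeled; no silent choice.

## Numerical and reproducibility choices

* Transition search is exhaustive over observed Ci values; SSE ties break
  toward the larger Rubisco segment. All optimizer fallbacks are bounded
  L-BFGS-B with fixed starts derived from the OLS solution.
* Ground-truth Jmax25/Vcmax25 ratios are clamped to [1.2, 2.2]; beyond ~2.4
  the RuBP-limited segment of the default protocol loses identifiability.
* Stage CSVs are UTF-8, comma-separated, '.' decimal, header mandatory,
  numerics at 6 significant digits; identical config + seed reproduces
  byte-identical files (asserted in the suite).
* Degenerate inputs fail loudly and early: non-positive Ci, out-of-range
  temperatures, zero-variance correlation inputs and rank-deficient designs
  are errors naming the offending record or column; implausible allocation
  fractions and below-detection pigments are warnings, since they represent
  data problems rather than usage errors.

## Validation problem sizes

The shipped suite exercises: a 3 × 2 capacity grid of noise-free round
trips; 200 noisy curves for the recovery study; 500 replicates for the
regression recovery at n = 29; 10 probe seasons (each with 29 fitted curves)
for the ordering property; 1000 random draws for forward-model oracle
equivalence and 100 for the correlation oracle; and two full pipeline runs
for bit-level reproducibility. These sizes give stable acceptance statistics
while keeping the whole suite in the tens of seconds.

## Known limitations

* Ci-based model only: no mesophyll-conductance fitting, no C4/CAM, no
  TPU parameter, no light- or temperature-response curve protocols.
* The Arrhenius form has no deactivation term; do not extrapolate
  normalization far above ~35 °C.
* The regression battery is descriptive (complete-case OLS); no
  cross-validation, model selection or mixed-effects structure for the
  repeated-measures design.
* Random-forest importance at n = 29 is noisy; rankings of weakly coupled
  predictors are unstable, which is why the ordering property is framed over
  repeated seasons.
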