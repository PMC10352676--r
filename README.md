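# photocap

Leaf photosynthetic capacity from A/Ci curves and leaf traits.

`photocap` is an R package for plant ecophysiologists working on the link
between leaf biochemistry and photosynthetic capacity in crops. It
implements the full inference chain from gas-exchange CO₂-response (A/Ci)
curves and leaf pigment/nitrogen measurements to the 25 °C-normalized
maximum carboxylation rate (Vcmax25), and the statistical analyses used to
ask how well leaf nitrogen (N_area), chlorophyll (Chl_area) and carotenoid
(Car_area) content predict it — the question that decides whether remotely
retrievable pigments can replace nitrogen as a Vcmax25 proxy in terrestrial
biosphere models.

## What it computes

Net assimilation of a C3 leaf follows the Farquhar–von Caemmerer–Berry
model

    A = min(Ac, Aj) − Rd
    Ac = Vcmax (Ci − Γ*) / (Ci + Kc (1 + O/Ko))
    Aj = J (Ci − Γ*) / (4 Ci + 8 Γ*)         (J = Jmax at saturating light)

`fit_aci()` estimates (Vcmax, Jmax, Rd) from a measured curve by an
exhaustive limitation-partition search with a min-consistency refinement
(each candidate partition is a linear least-squares problem; see the methods
vignette). `normalize_to_25()` maps rates between leaf temperature and 25 °C
with the Arrhenius response f(Tk) = k25·exp(c − ΔHa/(R·Tk)).
`pigments_from_absorbance()`, `structural_traits()` and
`allocation_fractions()` derive pigment contents (95 % ethanol, 665/649/470
nm), SLA/M_A/N_area, and the fractions of leaf N in Rubisco (P_R),
bioenergetics (P_B) and light harvesting (P_L). The statistical layer
(`correlation_matrix()`, `model_suite()`, `rf_importance()`,
`seasonal_changes()`) reproduces the standard trait-to-capacity analysis
battery. A synthetic winter-wheat season generator (`simulate_season()`,
`simulate_curves()`) provides ground truth for validating every stage, and
`run_pipeline()` drives the whole chain reproducibly.

## Worked example

Fit one noisy simulated curve and recover its generating parameters:

```r
library(photocap)

truth <- list(leaf_id = "demo", doy = 126, stage = "Flowering",
              vcmax25 = 100, jmax25 = 160, rd25 = 1.5, tleaf_k = 298.15)
curve <- simulate_aci_curve(truth, noise_sd = 0.3, seed = 42)
fit <- fit_aci(curve)
fit
#> FvCB fit for leaf 'demo' (DOY 126)
#>   Vcmax = 100.47, Jmax = 158.55, Rd = 1.41 umol m-2 s-1 at 298.15 K
#>   transition Ci = 266.0 umol mol-1 (4 Rubisco / 5 RuBP points), RMSE = 0.198
normalize_to_25(fit$vcmax, fit$tleaf_k, arrhenius_preset("vcmax"))
#> [1] 100.501
```

The fitted Vcmax25 of 100.5 µmol m⁻² s⁻¹ recovers the generating value of
100 to 0.5 % under instrument noise of sd 0.3 µmol m⁻² s⁻¹; the transition
Ci of 266 µmol mol⁻¹ separates the Rubisco-limited from the
RuBP-regeneration-limited points.

Run a whole synthetic season and ask which trait predicts Vcmax25:

```r
man <- run_pipeline(run_config("demo_run", seed = 1))
smp <- read.csv("demo_run/samples.csv")
model_suite(smp)
#> Capacity ~ trait model battery
#>  response                                      predictors  n r_squared  anova_p
#>   vcmax25                                     n_area_g_m2 29     0.279 3.25e-03
#>   vcmax25                                 chl_area_ug_cm2 29     0.614 4.96e-07
#>   vcmax25                                 car_area_ug_cm2 29     0.231 8.27e-03
#>   ...
#>   vcmax25 n_area_g_m2 + chl_area_ug_cm2 + car_area_ug_cm2 29     0.672 3.05e-06
```

On this generated season chlorophyll alone explains 61 % of the Vcmax25
variance while nitrogen explains 28 % — the generator couples the traits to
capacity with exactly that asymmetry — and the three-trait model tops the
battery at R² = 0.67, as nesting requires. The run directory contains every
stage table (`curves.csv`, `fits.csv`, `samples.csv`, `correlations.csv`,
`models.csv`, `importance.csv`, `seasonal.csv`) written deterministically:
the same config and seed reproduce byte-identical files.

A thin CLI wraps the same pipeline:

```sh
Rscript exec/photocap run-all --seed 1 --out demo_run
```

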