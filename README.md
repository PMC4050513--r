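# genokrig

Semi-ecological studies of outdoor air pollution link individually
measured health outcomes to *modelled* environmental exposure: pollutants
are monitored at a few dozen sites, an annual concentration surface is
interpolated, and the value of that surface at each participant's home
becomes their exposure. `genokrig` implements this design end to end for a
study of early genotoxic damage in children living in a wood-panel
(chipboard) manufacturing district, where formaldehyde and NO₂ measured by
passive samplers are linked to comet-assay markers of DNA strand breaks
(tail intensity, tail length, tail moment) and micronucleus-assay markers
of chromosomal damage (binucleated cells, micronuclei, nuclear buds per
2,000 buccal cells).

The package is aimed at biostatisticians and exposure scientists who want
a tested, fully reproducible reference implementation of each stage:

* **Synthetic district generator** — anisotropic Gaussian pollutant fields
  with exponential variograms, deterministic hot-spot kernels around the
  industries, seasonal monitoring campaigns with missingness, a stratified
  cohort with realistic covariates, and genotoxicity outcomes generated
  with published effect estimates as truth (no raw data from such studies
  are publicly deposited, so everything downstream is validated by
  parameter recovery).
* **Monitoring-network design** — balanced (equal-cluster-size) k-medoids
  placement of samplers at residence medoids, with the exact capacitated
  assignment solved as a min-cost assignment (C++), and a stratified
  variant putting half the sites within 3 km of the industries.
* **Temporal adjustment** — the difference method for multi-campaign
  passive-sampler data: campaign corrections Δ_c = A_c − Ā computed over
  complete sites, subtracted before averaging what each site has.
* **Geostatistics** — Matheron empirical variograms (with geometric
  anisotropy), Cressie-weighted least-squares fitting of
  exponential/spherical/gaussian models, global ordinary kriging
  (γ(h) = c₀ + c(1 − e^{−h/a}); "range" is the distance parameter *a*),
  and LOOCV-RMSE model selection.
* **Association battery** — per-1-SD effects from weighted linear models
  (comet markers, weighted by cells examined), linear models (binucleated
  cells) and NB2 negative-binomial models (overdispersed counts, reported
  as rate ratios), crude and adjusted for the full covariate set, plus the
  two sensitivity analyses (extra indoor-quality indicators among
  non-movers; restriction to within 4 km of the industries).

## Worked example

```r
library(genokrig)

# the fitted formaldehyde variogram, as a model object
m <- vgm_model("exponential", nugget = 0.01, psill = 0.12, range = 3.5,
               angle = 90, ratio = 0.5)
m
#> exponential variogram: nugget 0.01, psill 0.12, range 3.5 km, anisotropy 90 deg (ratio 0.50)
semivariance(m, c(1, 3.5, 10))
#> 0.0398 0.0859 0.1231    # gamma rises from the nugget toward the sill 0.13

# one synthetic cohort at the study size, with exposures and outcomes
cohort <- simulate_study_cohort(n = 374, seed = 2024)

# adjusted NB model: nuclear-bud rate ratio per 1-SD NO2 (truth 1.16)
fit_negative_binomial(cohort, "bud_count", "z_no2",
                      default_model_covariates())
#> estimate conf_low conf_high p_value   n
#>   1.2822   1.1643    1.4122  <0.001 374

# adjusted weighted linear model: tail-intensity slope per 1-SD
# formaldehyde on the 310-child comet subset (truth 0.13 %/SD)
fit_weighted_linear(cohort[1:310, ], "ti", "z_hcho",
                    default_model_covariates(), "cells_examined")
#> estimate conf_low conf_high p_value   n
#>   0.0715  -0.0293    0.1723  0.1636 310
```

Single replicates scatter around the truth (the bud RR above is high, the
TI slope low); the recovery studies below average 500 of them and land
within a few percent of the generative values.

The numbered drivers under `analysis/` run the full study narrative —
`01_simulate_district.R` through `07_recovery_studies.R` (district and
fields → site placement → campaigns and temporal adjustment → variogram
selection and kriging → exposure assignment → association batteries →
recovery studies) — each writing its tables under `results/`. The whole
sequence runs in a few minutes:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

`run_pipeline(default_config(seed = 1), "run1")` executes the same chain
as one call with a reproducibility manifest (per-stage seeds, file
digests, wall times) and a markdown report.

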