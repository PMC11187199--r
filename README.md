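# spmap — spatial perturbation analysis of SEEG implantation adequacy

Stereo-EEG (SEEG) guides epilepsy surgery by recording a few hundred
intracerebral channels — a sparse sample of the brain. When surgery fails,
a central and usually unanswerable question is whether the implantation
ever sampled the true seizure focus. `spmap` is for epilepsy
neurophysiologists and methods researchers who want to answer that question
from **interictal data alone**: it turns channel-level biomarker rates
(e.g. rates of gamma-preceded epileptiform discharges, in events/min) into
a spatial system, perturbs that system, and scores implantation adequacy
from the system's response.

## The model

For channels at template-space positions with Euclidean distances $d$ (mm)
to a *spatial reference* (the maximum-rate channel, optionally constrained
to the seizure-onset zone, SOZ), the rate field of a well-sampled unifocal
epilepsy is hypothesized to decay as a power law

$$f(d) = \alpha\,d^{\kappa}, \qquad \kappa < 0 ,$$

so that $y = \log f$ against $x = \log d$ is linear and the Pearson
correlation $\rho$ of $(x, y)$ measures the goodness of fit. Two
perturbations probe the system:

* **Virtual removal** — delete the measured SOZ and recompute. The
  perturbation strength
  $\hat\rho = \log(\nu + |\bar\rho_{BR}/\bar\rho_{AR}|)$ (medians over
  valid 10-min segments, $\nu = 1$) is large only when the SOZ carried the
  decay structure, i.e. when the focus was sampled. A random-removal
  control of matched size verifies the effect is not a channel-count
  artifact.
* **Reference permutation** — re-anchor the system at every channel in
  turn; $\hat P_i = 1 - (\rho_i - \rho_{\mathrm{ref}})$ ranks each
  channel's importance. Ranked strengths against distance to the
  high-perturbation centroid form the **SP map** (200 distance bins,
  grayscale-closed), whose quadrant features feed bootstrapped 2-means
  clustering and a Student-t probability model of adequate implantation.

Channel-sphere volumetrics (5 mm spheres on a 0.5 mm grid) support the
incomplete-resection correction, and a seeded synthetic SEEG cohort
generator provides well-sampled, missed-focus and propagation-island
scenarios with ground truth.

## Worked example

```r
library(spmap)

cfg <- sp_config(rng_seed = 42)
cohort <- generate_cohort(n_well = 6, n_poor = 6, cfg)

# virtual-removal analysis of one well-sampled patient
patient_perturbation(cohort[[1]], cfg)
#> <sp_perturbation> S001: rho_br -0.818, rho_ar 0.000, rho_rr -0.820, strength 13.615 (5 segments)
```

Before removal the rates couple tightly to distance from the SOZ reference
(`rho_br = -0.818`); randomly removing a matched number of non-SOZ channels
changes nothing (`rho_rr = -0.820`), but removing the SOZ leaves only
sub-threshold activity (`rho_ar = 0` by the zero-substitution rule), so the
strength sits at its capped maximum — the implantation clearly sampled the
focus.

```r
rk <- patient_ranked_map(cohort[[1]], cfg)
rk$map
#> <sp_map> 132 channels x 200 bins, max distance 73.2 mm
round(rk$centroid, 1)
#>  x_mm  y_mm  z_mm
#>  21.2 -18.9   1.9     # true generator at (10.8, -15.4, 5.2)
quadrant_features(rk$map, "S001")[c("q1", "q2", "q4")]
#> q1 = 0.69, q2 = 0.26, q4 = 0.00
plot(rk$map)            # diagonal bright band: the focal signature
```

The SP map needs no SOZ marking: its centroid lands near the true
generator and the off-diagonal quadrants (q2, q4) stay dim relative to q1.
Cohort-level classification by perturbation strength:

```r
strengths <- sapply(cohort, function(p) patient_perturbation(p, cfg)$strength)
labels <- sapply(cohort, function(p) p$outcome) == "seizure_free"
choose_threshold(setNames(strengths, sapply(cohort, `[[`, "patient_id")),
                 labels, seed = 42)
#> <sp_classification> threshold 1.798: sensitivity 1.00, specificity 1.00, AUC 1.000 [1.000, 1.000]

patient_volumes(cohort[[1]], cfg)[c("soz_cm3", "resected_soz_cm3")]
#> SOZ volume: 4.8 cm3, resected SOZ: 4.8 cm3
```

`run_pipeline(cohort, cfg, out_dir = "...")` chains all stages (virtual
removal, SP maps, quadrant features, cluster model, adequacy probabilities,
volumetrics) and writes result tables, model JSON and a run manifest. A
command-line front end with the same stages as subcommands lives at
`inst/cli/spmap-cli.R` (`simulate`, `vr`, `map`, `features`, `fit`,
`score`, `volumes`, `run-all`).

The methods vignette (`vignettes/spatial-perturbation.Rmd`) documents the
model, every tunable constant with its default and rationale, the synthetic
generator's scope, and known limitations.

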