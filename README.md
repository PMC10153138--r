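# syncap

Quantification of syncytial actin caps, F-actin binding and bundling.

In the syncytial Drosophila embryo, an F-actin **cap** forms above each
cortical nucleus and transient **pseudo-cleavage furrows** ingress between
neighbouring caps, compartmentalising the mitotic spindles. Studies of actin
regulators in this system quantify (i) cap geometry and nuclear density from
fluorescence images, (ii) binding of a candidate regulator to F-actin from
co-sedimentation densitometry, and (iii) its bundling activity from TIRF
images of labelled filaments. `syncap` packages those analyses for R users
who want them reproducible and testable:

* **Cap segmentation** (`segment_caps`) — the five-step recipe: intensity
  scaling (×1.25), multiscale Frangi ridge enhancement, Gaussian blur
  (σ 4–10 px), regional-minimum seeding, and marker-controlled watershed on
  the median-filtered (11 px) ridge response. Deterministic, fully
  parameterised (`segmentation_params`).
* **Morphometry** — per-embryo cap statistics with the <80 µm² small-cap
  fraction (`cap_statistics`), nuclear density (`nuclear_density`),
  missing-furrow ratio, centrosome distance / subtended angle / spindle
  length (`centrosome_metrics`), apical-basal furrow intensity ratio with
  min–max normalisation.
* **Co-sedimentation** — fraction bound with nonspecific-pelleting
  correction (`fraction_bound`) and a multi-start cooperative Hill fit

      f(A) = plateau · A^h / (K_d^h + A^h)

  with seeded bootstrap confidence intervals (`fit_hill`); low-speed
  pelleting summaries for bundling (`lowspeed_fraction_pelleted`).
* **TIRF bundling** — rolling-ball background subtraction (radius 5 px),
  bilinear line-profile extraction, Gaussian fits with
  FWHM = 2√(2 ln 2)·σ, filament-count-linear intensity metrics, and
  normalisation to the control-reaction mean.
* **Statistics & orchestration** — exact/corrected Mann-Whitney U
  comparisons (`mann_whitney`), per-embryo aggregation, and a deterministic
  config-driven pipeline (`run_pipeline`) with provenance.
* **Synthetic data with ground truth** — seeded generators for cap fields
  (tessellated compartments with bright furrow ridges, bimodal size
  distributions, nuclear-fallout holes), binding tables following a known
  Hill law, TIRF line profiles with known filament counts, and centrosome
  point geometries. Every stage of the pipeline is validated against these
  known answers; no microscopy download is needed.

## Worked example

```r
library(syncap)

# a 100-cap cortex at moderate noise, segmented and summarised
field  <- generate_cap_field(cap_field_spec(n_caps = 100, noise_sd = 0.05,
                                            seed = 1))
labels <- segment_caps(field$image)
cap_statistics(cap_table(labels))
#> <embryo_summary> 100 caps, mean area 117.28 um^2, small-cap fraction 0.060

# a simulated pelleting assay (Kd 0.45 uM, h 2.9, 3 replicates, noise 0.02)
ds <- generate_binding_table(binding_sim_spec(noise_sd = 0.02,
                                              n_replicates = 3, seed = 1))
fb <- fraction_bound(ds)
fit_hill(fb$actin_conc_um, fb$fraction_bound, n_boot = 200)
#> <hill_fit> Kd = 0.4388 uM, h = 2.72, plateau = 1 (fixed_1), RSS = 0.00526
#>   bootstrap 200 x, 95% CI: Kd [0.426, 0.453], h [2.5, 2.93]

# embryo-level group comparison
mann_whitney(c(118, 125, 131, 122, 128, 120),
             c(95, 88, 104, 92, 110, 85),
             group_names = c("control", "perturbed"))
#> <mann_whitney> control (n=6, median 123.5) vs perturbed (n=6, median 93.5)
#>   U = 36, p = 0.002165 (two_sided, exact)
```

The segmentation recovered all 100 caps (mean true area in this field is 115.8 µm²); the Hill fit lands within ~3% of the simulated dissociation
constant and within ~6% of the simulated cooperativity at this noise level,
with the truth inside the bootstrap intervals; and the fully separated 6 vs 6
comparison returns the exact two-sided minimum p = 2/C(12,6).

A thin command-line wrapper with subcommands (`pipeline`, `simulate`,
`segment`, `capstats`, `hillfit`, `lowspeed`, `compare`) is installed at
`inst/cli/syncap`; it only forwards to the functions above. The methods
vignette (`vignettes/syncap-methods.Rmd`) documents the models, parameter
meanings, numerical choices and limitations.

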