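# orivox

Simulation and analysis of fine-grained orientation preference patterns in
fMRI voxels.

## The scientific problem

The orientation of a visual grating can be decoded from human primary
visual cortex (V1) with conventional-resolution fMRI (2–3 mm voxels at 3T),
even though orientation columns live at a sub-millimetre scale. Two
competing accounts explain where that information comes from:

* **Global areal maps.** V1 responds slightly more to *radial* orientations
  (aligned with the line from fixation) and to *vertical* orientations.
  These coarse, area-wide biases alone could drive decoding.
* **Fine-grained patterns.** Voxel-scale irregular sampling of the columnar
  map leaves each voxel with its own small orientation preference, and the
  multivariate pattern of those preferences carries information.

The two accounts are hard to separate because voxels differ in their
sensitivity to neural activity (the **voxel gain field**, e.g. from partial
volume effects). A gain field can turn a perfectly smooth coarse bias into
apparent high-spatial-frequency structure — but, crucially, a strictly
positive gain field can never **invert the sign** of a response contrast.
The diagnostic signature of genuinely fine-grained information is therefore
the presence of *reliable opposite* orientation preferences among voxels
inside one small retinotopic patch: voxels preferring tangential over
radial (for gratings) or horizontal over vertical (for log-spiral stimuli),
whose preference is defined on training data and *replicates* in held-out
test data.

orivox implements that logic end to end, for its own synthetic datasets
(no external data are required) and for user-supplied pattern tables:

1. **Geometry** — a log-polar stimulus annulus (inner/outer radius
   1.5°/7.04°, exponentially spaced rings at 1.50°, 2.51°, 4.20°, 7.04°),
   grating and logarithmic-spiral orientation fields, and quarterfield ×
   eccentricity-band ROIs covering the central third of each quarterfield.
2. **Synthetic V1** — per-subject columnar preference maps (band-pass
   complex Gaussian fields), the cosine response model
   `R = b[1 + a_col·cos 2(θ_pref − θ_stim) + a_rad·cos 2(θ_stim − θ_radial)
   + a_vert·cos 2θ_stim]`, strictly positive log-normal voxel gains, and
   per-subrun t-patterns (2 runs × 4 subruns × 2 conditions per stimulus
   kind, 18 subjects, 2-mm voxels), either at pattern level or through a
   full block-design GLM with a gamma HRF.
3. **Analysis** — training-data-only preference labeling; four-fold
   leave-one-subrun-(of both runs)-out cross-validated decoding with a
   linear SVM under three voxel selections (all / reference-preferring /
   opposite-preferring); spatial-shift controls (0.5–3 voxels = 1–6 mm);
   the **preference replicability index**
   `⟨t_train, t_test⟩ / (‖t_train‖·‖t_test‖)` (a cosine similarity with no
   mean-centering, so sign agreement is required); participant bootstrap
   (10,000 resamples) and one-way ROI ANOVAs; Wilcoxon signed-rank and
   across-subject t tests.

## Worked example

```r
library(orivox)

ds <- generate_dataset(scenario_mixed(seed = 1, n_subjects = 6))
ds
#> <pattern_dataset>
#>   subjects: 6  kinds: grating, spiral
#>   patterns: 192  voxels: 288  (4 patches x 12 x 6 voxels)
#>   scenario: mixed  seed: 1  fidelity: pattern

dec <- train_test_decode(ds, selections = c("all", "A", "B"))
decoding_summary(dec)$group
#>     kind  set_label n_subjects mean_accuracy p_vs_chance
#>  grating     radial          6         0.958      0.0168
#>  grating        all          6         0.979      0.0131
#>  grating tangential          6         0.833      0.0175
#>   spiral   vertical          6         0.990      0.0131
#>   spiral        all          6         0.979      0.0131
#>   spiral horizontal          6         0.719      0.0178

repl <- crossval_replicability(ds)
rs <- replicability_summary(repl, n_boot = 10000, seed = 1)
rs[rs$roi == "combined", ]
#>     kind        set mean ci_lo ci_hi     p
#>  grating     radial 0.32 0.245  0.41 1e-04
#>  grating tangential 0.18 0.118  0.25 1e-04
#>   spiral horizontal 0.17 0.086  0.27 1e-04
#>   spiral   vertical 0.30 0.240  0.36 1e-04

preference_proportions(ds)$group
#>     kind label_ref pooled_pct_ref        p mean_contrast_psc
#>  grating    radial           56.2 0.000525            0.0380
#>   spiral  vertical           54.4 0.046687            0.0288
```

Reading the output: in the `mixed` world the minority voxel sets
(tangential- and horizontal-preferring) decode the stimulus well above
chance and their preferences replicate across folds (index > 0) — the
signature of fine-grained pattern information. A slight majority of voxels
prefers radial/vertical orientations, with mean response contrasts of a few
hundredths of a percent signal change on a ~2% response. Running the same
analyses on a `scenario_coarse_only()` dataset instead yields *zero*
opposite-preferring voxels when noise-free, and with noise the spurious
minority preferences do not replicate (index ≤ 0).

The whole chain — including the spatial-shift controls and tidy TSV/YAML
reports — can be run in one call:

```r
run_pipeline(pipeline_config(scenario_mixed(seed = 1)), out_dir = "results")
```

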