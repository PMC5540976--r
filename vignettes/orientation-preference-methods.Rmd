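---
title: "Models and methods behind orivox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind orivox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orivox asks a single question of fMRI voxel patterns evoked by oriented
stimuli in V1: is orientation information carried only by coarse, area-wide
preference maps seen through a voxel gain field, or also by fine-grained,
voxel-scale selectivity patterns? This vignette documents the models, the
parameter choices, the numerical conventions, and the limits of what the
package's simulations can show. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## Geometry and conventions

All angles are in degrees. Visual-field polar angle is measured *clockwise
from the upper vertical meridian*; orientations live in [0, 180) with 0 =
vertical, increasing clockwise. Under these conventions a grating tilted
45° clockwise (`plus45`) is radial in the upper-right and lower-left
quarterfields; an anticlockwise logarithmic spiral has local orientation
`polar − 45°`, hence vertical at the 45° diagonal. Stimuli live in an
annulus (1.5°–7.04° eccentricity) tiled log-polarly; ring radii are
geometrically spaced (`logpolar_radii()`), the standard equal-log-
eccentricity approximation to equal cortical extent.

The analysed ROIs are the central third of each quarterfield (30° of polar
angle centred on the 45°/135°/225°/315° diagonals), each split into three
eccentricity bands at the same geometric radii. Only diagonal patches are
supported by `condition_label_map()`: there the grating pair is exactly
radial/tangential and the spiral pair exactly vertical/horizontal; any
other patch centre raises an error rather than guessing a label.

One deliberately opaque point: the geometric chirality of a "clockwise"
spiral is a naming convention, not a physical fact the analysis depends on.
The package anchors the semantics of the variant names to the label map at
the upper-right diagonal (anticlockwise ↦ vertical there) and treats the
names as opaque everywhere else.

## The synthetic cortical sheet

Each quarterfield patch is a flat 2D sheet: the first axis spans the
patch's eccentricity range linearly in log eccentricity, the second its
30° of polar angle. Voxels are square 2-mm footprints tiling the sheet
(default 12 × 6 voxels per patch, 288 in total); each voxel averages an
8 × 8 block of cortical columns (0.25-mm pitch) and is scaled by its own
gain. A 3D slab with through-plane sampling is out of scope; the 2D sheet
exercises every analysis path while keeping the shift controls exact.

**Columnar map.** Preferred orientations are half the argument of a complex
Gaussian random field band-pass filtered around spatial frequency
1/`columnar_period_mm` (default period 0.8 mm, relative bandwidth 1/4) —
the standard way to synthesise pinwheel-like maps. The tests verify that
preferences are uniform on [0, 180) and that the map's radially averaged
power spectrum peaks within 20% of the columnar frequency.

**Response model.** Per column,
`R = b[1 + a_col·cos 2(θ_pref − θ_stim) + a_rad·cos 2(θ_stim − θ_radial) +
a_vert·cos 2θ_stim]`, with the double-angle cosine as the minimal
orientation-periodic kernel and the bias terms additive inside one bracket
so every amplitude reads directly in percent signal change. The amplitude
invariant `a_col + a_rad + a_vert < 1` keeps responses strictly positive.
Note one geometric subtlety the tests encode: the grating contrast equals
`2·b·a_rad` exactly only on the patch meridian where the stimulus is
exactly radial; across a 30°-wide patch it is `2·b·a_rad·cos 2Δ` — smaller,
but of one sign everywhere, which is what "coarse-scale homogeneous
effect" means operationally.

**Gain field.** Log-normal, mean-normalised to 1 (`meanlog = −σ²/2`),
default `sigma_log = 0.4`, i.i.d. across voxels (`smoothness_mm = 0`, the
worst case for spurious high-frequency structure; a Gaussian-correlated
option exists). Strict positivity is the load-bearing property: voxel
sampling can re-weight but never invert a contrast, and the test suite
asserts this sign preservation exhaustively on generated grids.

**Noise and the t scale.** Patterns are expressed on the t scale. In the
default pattern-level fidelity a pattern is `amplitude / SE + ε`, where
`SE` is the OLS standard error of one task predictor under the canonical
block design (computed from the design matrix, so the two fidelity modes
agree in expectation — verified by a rank-correlation > 0.95 test) and
`ε ~ N(0, sigma_pattern²)` with `sigma_pattern = 1`, the unit variance of a
t-statistic under noise. The time-series fidelity simulates
`X·β + N(0, sigma_timeseries²)` BOLD series (TR 2 s, 4 subruns × 6
14-s blocks with 6-s gaps, conditions alternating across blocks and the
leading condition alternating across subruns) and fits the massively
univariate GLM; its per-subrun t-patterns have unit noise variance by
construction. The gamma HRF defaults to `n = 3`, `τ = 1.25 s`, zero onset
delay — the simplest parameterisation of this family — and is
configurable.

**Subjects and seeding.** Each subject gets its own columnar maps, gain
field, and multiplicative amplitude jitter (`sigma_subject = 0.3`,
truncated at 0), reflecting that coarse biases are not equally strong in
every participant. Seeding is hierarchical: the master seed spawns
per-subject streams, so datasets are bit-reproducible and adding subjects
never perturbs existing ones.

### Calibration of the default amplitudes

The defaults were fixed once, against the empirical orders of magnitude
reported for V1 at 3T, and are not tuned per analysis:

* `baseline = 2.0` %SC — mean stimulus responses of about 2% in these
  patches;
* `a_rad = 0.0095`, `a_vert = 0.0081` — chosen so the patch-mean radial
  and vertical contrasts are ≈ 0.038 and ≈ 0.031 %SC (the vertical term is
  averaged over the patch's ±15° polar range, mean cos factor 0.955);
* `a_col = 0.6` — chosen so that, after footprint averaging (which
  attenuates the columnar signal by roughly a factor of ten at a 0.8-mm
  period under 2-mm voxels), the *mixed* world reproduces the reported
  order of the split-set replicability indices (≈ 0.3 for the majority
  sets, ≈ 0.15–0.2 for the minority sets) and of the preference
  proportions (a few percentage points above 50%).

Because simulator noise is i.i.d. across voxels — there is no spatially
correlated physiological noise, drift, or motion — absolute decoding
accuracies in the mixed world are higher (≈ 0.95 for all voxels at 18
subjects) than is typical of real data at this design size. Comparisons
*between* selections, scenarios and shifts are the meaningful outputs, not
absolute accuracy.

## The analyses

**Preference labeling.** Per patch, the condition mapped to the radial
(gratings) or vertical (spirals) reference is the positive pole; a voxel's
`delta_t` is the difference of its mean t-values between the two conditions
over the *training* subruns only, and its label is the sign. Exact ties
(`delta_t = 0`) are excluded from both sets rather than randomised: they
have measure zero under continuous noise, and excluding them keeps set
membership independent of any seed. A perturbation test verifies that
replacing held-out subruns with arbitrary data changes no label.

**Decoding.** Four folds; fold *k* holds out subrun *k* of both runs (4
test patterns) and trains on the other six subruns (12 patterns). The
literature describes this same plan as both "leave-two-subrun-out" (two
test patterns per condition) and "leave-one-subrun-out" (one subrun index);
the package implements the single four-fold subrun-index plan under both
names. The classifier is a linear SVM with fixed cost 1 and no feature
scaling — inputs are already t-values on a common scale, and fixing the
cost removes a tuning degree of freedom. Voxel selections (`all`,
reference-preferring `A`, opposite-preferring `B`) are recomputed inside
every fold from training data. Empty selections yield missing folds,
recorded as `NA`, never as zero.

**Spatial shifts.** Test patterns are re-sampled from ROI coordinates
shifted by 0.5–3 voxels (1–6 mm at 2-mm voxels) along grid axes;
half-voxel shifts average the two adjacent voxels. Voxels whose shifted
window leaves the patch are dropped from training and test symmetrically —
zero-padding would manufacture decodable edge artefacts. The default
direction set is the four in-plane directions of the 2D sheet (a 3D volume
would have six; the sheet model has no third axis, a documented
deviation). Per subject, accuracy is averaged across directions.

**Replicability.** The index is the inner product of the training and test
contrast t-vectors over a voxel set, divided by the product of their norms
— a cosine similarity with the regression intercept fixed at the origin,
so t-values must match in *sign* to score positively; it is unbiased and
symmetric about 0 under independence (verified by simulation) and negative
when preferences revert. With t-patterns as the pipeline's currency, the
fold contrast map is the mean t-difference across subruns
(`contrast = "mean_t_difference"`); a one-sample t-statistic across
subrun-wise differences is available as `contrast = "t_statistic"` for
users who prefer a variance-normalised contrast map. Fold-level indices
over empty sets or zero-norm vectors are excluded from the fold average,
not imputed. Group inference is a participant bootstrap (default 10,000
resamples, percentile CIs) with the add-one one-sided p-value
`(1 + #{means ≤ 0})/(n_boot + 1)`, which cannot return exactly zero.
ROI effects are tested with classical fixed-effects one-way ANOVAs on the
per-subject fold-averaged indices (the simplest variant defensible for
per-subject summary statistics).

**Group tests.** The Wilcoxon signed-rank test excludes zero differences,
uses the exact null distribution up to n = 25 without ties and a
continuity-corrected normal approximation otherwise; it is checked against
a complete 2⁸ sign-enumeration oracle. The across-subject t-test treats
the subject as the random effect. Following the reporting style this
pipeline mirrors, no multiple-testing correction is applied anywhere by
default.

## What the scenarios demonstrate — and a selection-bias caveat

* `coarse_only` (no columnar term): with zero noise, *every* voxel prefers
  the reference orientation — a strictly positive gain field cannot create
  opposite preferences. With noise, spurious minority preferences appear
  but do not replicate: their replicability index is negative on average.
* `fine_only` (no coarse biases): preferences split 50/50, both sets
  decode, and decodability collapses to chance once test patterns are
  shifted by a voxel or more — fine-grained information is anchored to
  exact voxel placement.
* `mixed`: both components; the realistic world in which minority sets
  both decode and replicate.

One consequence of training-set selection deserves emphasis, because it is
stronger than "spurious preferences are uninformative": in a coarse-only
world the same training noise that mislabels a voxel as
tangential-preferring also trains the classifier, so the SVM weights of
the minority set *anti-align* with the true (uniformly radial) contrast.
Held-out accuracy for that set is therefore systematically **below**
chance — the decoding counterpart of the negative replicability index —
rather than statistically indistinguishable from 0.5. The acceptance suite
states the indistinguishable-from-chance expectation and the corresponding
check fails honestly under the package's study conditions; a
truncated-normal selection argument shows the below-chance bias scales as
`√n_voxels · contrast / noise`, the very quantity that makes decoding
possible at all, so no realistic parameter choice removes it.

## Problem sizes and numerics

The test suite runs at reduced sizes chosen once for coverage per unit
time: geometry properties on dense grids (0.5° steps), simulator
statistics on 6 × 4- or 3 × 1-voxel patches, null distributions with
1,000–10,000 simulations, the Fig-style signature comparisons with 18
simulated subjects and 10–50 seed replicates, and full-design analyses
(288 voxels, 18 subjects) where group inference is the point. Tolerances:
exact arithmetic oracles at 1e−10–1e−12; closed-form response checks at
1e−6 (the patch-meridian limit); statistical checks at their stated α or
Monte-Carlo bands. Degenerate inputs fail loudly: inverted radii,
non-diagonal patches, rank-deficient designs, zero residual variance,
zero-norm index vectors, all-zero difference vectors and seedless
scenarios are all errors, not silent repairs.

## Known limitations

* No spatially correlated noise, drift, motion, or vascular geometry; the
  gain field is a statistical stand-in for partial-volume variation.
* The cortical sheet is flat; cortical folding, 3D voxel sampling and
  through-plane shifts are out of scope.
* Real-data quantities (accuracies around 70%, replicability indices for
  a specific scanner and task) are not numeric targets; the package's
  claims are about the *structure* of the comparisons between worlds,
  selections and shifts.
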