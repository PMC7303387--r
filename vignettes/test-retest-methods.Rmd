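---
title: "Test-retest reproducibility of task-fMRI pipelines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-retest reproducibility of task-fMRI pipelines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and limitations
behind `fmritrt`. The package measures how the reproducibility of
single-subject task-fMRI activation clusters depends on the processing
pipeline, by crossing methods at four stages (motion correction, masked
smoothing, regression, thresholding), applying every combination to two
sessions of the same subjects, matching activation clusters across
sessions, and comparing three agreement metrics across methods.

## The synthetic cohort

Real two-session data are replaced by a generator
(`simulation_config()`, `simulate_dataset()`) that emulates a ten-subject,
two-session, five-run block-design protocol:

* **Paradigms** (`build_paradigm()`): five fixed block designs — overt word
  repetition (76 volumes), covert verb generation (173), overt verb
  generation (88), interleaved finger/foot/lip motor blocks (184), and a
  visual landmark/detection design (238). The overt-speech runs were
  acquired with sparse sampling; they are modelled as ordinary block
  designs at the effective TR of 5 s (the acquisition gaps themselves are
  not simulated), the others at TR 2.5 s. Voxels are 4 mm isotropic.
* **Anatomy**: each subject has a fixed baseline volume — a smooth-edged
  ellipsoidal "head" at intensity 100 with a smooth intensity texture
  (SD 10, FWHM 3 voxels) standing in for tissue contrast. The texture is
  per-subject and identical across sessions, runs and volumes; it is what
  gives intensity-based motion estimation something to lock onto, exactly
  as anatomy does in real EPI.
* **Activation**: spherical clusters (`ground_truth_cluster()`) with a
  raised-cosine roll-off of one voxel at the rim, so cluster boundaries
  are stable but not razor-sharp. Each sphere's time course is
  `amplitude × condition_regressor`, with amplitude in percent signal
  change of the interior baseline (defaults 2–2.5%, typical of strong
  block-design effects at 1.5 T). The default truths place two spheres per
  language/visual run and one per motor condition.
* **Hemodynamics** (`canonical_hrf()`): the canonical double-gamma
  (response peak 6 s, undershoot peak 16 s, undershoot ratio 1/6), peak
  normalised. Any smooth causal HRF would do since generation and fitting
  share the shape; note the undershoot makes convolved regressors dip
  slightly below zero after blocks, which is physiological, not an error.
* **Noise**: the order of operations is fixed and documented so tests can
  build oracles — draw white Gaussian noise per volume, smooth spatially
  to `noise_fwhm_mm` (default 6 mm), filter in time with an AR(1)
  recursion (`ar1_rho`, default 0.3; 0.4 in the recovery tests), then
  rescale the whole noise array so its pooled SD equals `noise_sd`
  (default 1, i.e. 1% of baseline).
* **Between-session variability**: in session 2 each truth's center is
  jittered by an isotropic Gaussian (`session_com_jitter_sd_mm`, default
  2 mm) and its amplitude by `session_amplitude_jitter_sd` (default 0.2).
  Setting all stochastic terms to zero makes the two sessions
  bit-identical, which anchors the end-to-end ideal-case tests.
* **Motion**: an optional per-volume six-parameter schedule applied by
  trilinear resampling.
* **Reproducibility**: every (subject, session, run) derives its own
  31-bit seed from the config seed, so datasets are bit-reproducible and
  subjects have independent noise.

The default grid is 32 × 32 × 24 voxels — smaller than a real 64 × 64 × 30
acquisition — to keep the test suite fast; the grid is configurable and
all geometry flows through the voxel-to-mm affine. Physiological noise,
susceptibility distortion, slice timing and reconstruction artifacts are
deliberately out of scope, so a passing test suite shows the *pipeline
logic* is correct, not that real-data effect sizes will match.

## Preprocessing

**Rigid motion correction** (`rigid_register()`, `motion_correct_run()`):
six-parameter (three rotations in degrees about the volume center, three
translations in mm) registration to the run's first volume, minimising the
sum-of-squares intensity difference by Nelder-Mead descent from the
identity (warm-started from the previous volume's estimate along a run),
with trilinear resampling. Two numerical details matter:

* the cost is evaluated on copies pre-smoothed by an *edge-renormalised*
  Gaussian (FWHM 2 voxels). Trilinear interpolation at fractional offsets
  blurs the moving image, and on sharp data that energy loss can
  masquerade as alignment; pre-smoothing removes the bias. The
  renormalisation matters: zero-padded smoothing would create an intensity
  roll-off pinned to the grid boundary that anchors the optimum to the
  identity.
* the cost uses every second voxel per axis (stride 2); the final
  resampling always uses the full grid.

After motion correction (or `NoMoCo`, which changes nothing) the first
volume of every run is removed. **Framewise displacement** uses the
Power convention: the sum of absolute backward differences of the six
parameters with rotations converted to arc length on a 50 mm sphere —
the de facto standard matching the 0.2 mm (strict) and 0.5 mm (lenient)
censoring thresholds. Whether those thresholds were originally meant in
mm is an assumption, flagged here.

**Masked smoothing** (`smooth_in_mask()`): normalised convolution,
`smooth(data·mask) / smooth(mask)`, evaluated only inside the mask and
zero outside. This preserves constants exactly for every FWHM and keeps
intensity from bleeding across the brain edge. FWHM 0 is the identity.

## Regression

Every variant fits, per in-mask voxel, the retained volumes on a design
containing the task regressor(s) (boxcar convolved with the HRF, sampled
at the TR), a Legendre polynomial baseline, and variant-specific parts:

* polynomial order is 1 for runs shorter than 150 volumes and 2 otherwise,
  judged on the *as-acquired* volume count (the rule is stated in terms of
  run length, so the pre-removal count is used);
* `MPC` appends the six (mean-centered) motion parameters; these always
  come from the rigid estimator, also in the `NoMoCo` arm;
* `Cen2`/`Cen5` delete volumes with FD strictly above 0.2 / 0.5 mm
  (row deletion, matching the notion of censored time points);
* `REML` estimates a per-voxel lag-1 autocorrelation from OLS residuals,
  pools the estimates spatially (normalised in-mask smoothing, FWHM
  12 mm — raw lag-1 estimates at run length have an SD near 0.1, far too
  noisy to whiten with), prewhitens data and design with the exact AR(1)
  square-root transform, and refits. Voxels are processed in rho bins of
  0.01 so each whitening factorisation is done once per bin. A
  single-lag AR(1) is a simplification of the ARMA(1,1) used by some
  packages; degrees of freedom follow the design rank only.

Runs with several conditions (motor, visual) fit all condition regressors
jointly and emit one t-map per condition — eight activation-map types over
the five runs.

## Thresholding

All tests are one-sided for positive t, since the studied activations are
task-positive (an assumption, documented). Four rules
(`apply_threshold()`):

* **Bon** — voxel active iff `p × N_mask < 0.01` (strict inequality);
* **FDR** — Benjamini-Hochberg adjusted p below `1e-5`; the much more
  stringent level reflects FDR's greater sensitivity;
* **Clst** — voxelwise `p < 1e-4`, then clusters smaller than a
  Monte-Carlo calibrated minimum size are removed. The null tables
  (`cluster_size_threshold()`) simulate Gaussian fields inside the mask at
  the smoothness estimated from the regression residuals
  (`estimate_smoothness()`: variance of first spatial differences of
  variance-normalised residuals; the ACF sigma of smoothed noise is √2
  times the kernel sigma, and the *kernel* FWHM is reported so the null
  generator can consume it directly). The null uses a single isotropic
  FWHM (geometric mean) and Gaussian ACF — a simplification of mixed-ACF
  models — and the same 6-face connectivity as the data clustering, so
  null and data are treated identically. Tables are cached in 0.5 mm
  smoothness bins, and their seeds derive from the study seed and the
  smoothness bin only (never from the session), so identical sessions see
  identical thresholds.
* **AMPLE** — each voxel's t as a percentage of the maximum t in its
  region; active iff strictly above 60%. The percentage is invariant to
  rescaling the whole map, which makes the rule insensitive to global
  sensitivity differences between pipelines. For synthetic data the five
  regions (four superior quadrants standing in for frontal / occipital /
  parietal / temporal, inferior half as "other") come from
  `region_atlas()`; a region with no positive t yields no activation and
  a warning.

## Clusters, matching and metrics

`find_clusters()` takes 6-face connected components of the active voxels
and keeps those with at least 12 voxels (768 µl at 4 mm isotropic),
computing each cluster's t-weighted center of mass in mm. ROI masks are
built per activation type as ≥ 10% prevalence (inclusive) across *all*
activation maps of that type — every pipeline, subject and session on the
shared grid (the original design built these in atlas space; the synthetic
cohort is already co-registered by construction, so no warping is needed).
Clusters qualify by their center-of-mass voxel (floor of the mm-to-voxel
transform) being inside the ROI, not by overlap.

Matching is per test cluster: the nearest retest cluster with a
center-of-mass distance ≤ 10 mm (inclusive). A retest cluster may be
matched by several test clusters; exclusivity is deliberately not
enforced. Each pair yields PDAV (range 0–200%), DCM (≤ 10 mm by
construction) and DSC, computed on the shared grid.

## Statistical comparison

For one stage and one metric, `summarize_stage()` compares every method
pair within every activation-map type, pooling matched pairs across
subjects and all combinations of the other three stages (one matched pair
is one observation). Each comparison is a pooled-variance unpaired t test;
p-values are Bonferroni-multiplied by (number of method pairs) × (number
of activation maps) and capped at 1 — a deliberately conservative choice
where no specific correction was mandated. A method is *significantly
better* when the corrected p is below 0.05 and its mean is on the
favourable side (lower PDAV/DCM, higher DSC); each method's summary is the
percentage of its comparisons it won. A Kruskal-Wallis omnibus test (tie
corrected, χ² p on k−1 df) accompanies each stage × metric; identical
data across groups return H = 0, p = 1 by convention.

Cohen's d uses `(x̄₁ − x̄₂) / s_p` with
`s_p² = ((n₁−1)s₁² + (n₂−1)s₂²) / (n₁ + n₂)`. The `n₁ + n₂` divisor is
kept as the package's convention (the textbook `n₁ + n₂ − 2` is available
via an argument); a transcription with `(n₁−1)` weighting both variances
is treated as a typo and corrected to `(n₂−1)`.

Welch's test is intentionally not the default (the unpaired test is
specified as the plain two-sample t); it can be added by the user on the
exported records.

## Orchestration and problem sizes

`enumerate_pipelines()` forms the Cartesian product in deterministic
lexicographic stage order; the full menu is 4 × 5 × 5 × 4 = 400 pipelines,
and with 8 activation maps, 10 subjects and 2 sessions the planning
arithmetic gives 64,000 analysis units (8,000 per activation type) —
`planned_analyses()` exposes this bookkeeping. `run_study()` computes
shared stage prefixes once per run (motion correction once per arm,
cluster-size tables once per smoothness bin), logs and skips per-unit
failures instead of aborting, and is byte-reproducible given the dataset
and seed.

The test suite and the acceptance script run reduced problem sizes chosen
to exercise every code path while staying light: grids of 20–32 voxels per
axis, one to three subjects, one or two runs, 2 × 2 × 1 × 1 factorials for
end-to-end checks, and 1,000 Monte-Carlo iterations for the cluster-size
tables. These sizes are the package's own defaults for desk-scale
validation; cluster-scale sweeps of the full 400-pipeline menu on real
data use the same code paths unchanged.

## Known limitations

* The 2D+3D slicewise and affine motion-correction arms are interface
  stubs; only `NoMoCo` and `Rigid3D` are implemented.
* Session alignment via anatomical registration is not needed for the
  synthetic cohort (shared grid) and is not implemented; applying the
  package to real two-session data requires externally co-registered
  inputs.
* AR(1) (not ARMA(1,1)) temporal models; Gaussian (not mixed) spatial ACF
  in the cluster null; both documented above.
* The SSD registration cost is intensity-based; contrast changes between
  volumes (e.g. strong activation) can bias estimates slightly, as with
  any least-squares realignment.
* Headline real-data percentages from cluster-scale studies are not
  reproducible at desk scale and are not targets of the test suite; the
  suite validates the machinery with property-based checks instead.
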