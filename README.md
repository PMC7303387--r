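# fmritrt

How much does the choice of processing method change what a single-subject
task-fMRI map says? `fmritrt` answers that question the way a test–retest
study does: the same subjects are scanned twice, every combination of
processing methods is applied to both sessions, and the agreement between
the two sessions' activation clusters is measured per combination. It is
aimed at researchers evaluating single-subject pipelines — for example for
presurgical language and motor mapping, where the activation map of one
patient, not a group average, drives decisions.

## What it computes

Four processing stages are crossed factorially:

| stage             | methods                                             |
|-------------------|-----------------------------------------------------|
| motion correction | `NoMoCo`, `Rigid3D` (pluggable interface)           |
| spatial smoothing | in-mask Gaussian, FWHM ∈ {0, 3, 6, 9, 12} mm        |
| regression        | `Std`, `REML` (AR(1) prewhitened), `Cen2`, `Cen5` (FD-censored), `MPC` (motion covariates) |
| thresholding      | `Bon`, `FDR`, `Clst` (Monte-Carlo cluster extent), `AMPLE` (regional % of max) |

Each pipeline turns a block-design BOLD run into a binary activation map
via a voxelwise GLM t-map. Clusters (6-connected, ≥ 12 voxels = 768 µl at
4 mm isotropic) whose t-weighted center of mass falls inside a 10%
prevalence ROI mask are matched across sessions (closest center of mass
within 10 mm), and each matched pair yields three reproducibility metrics:

- **PDAV** — percent difference in activation volume:
  `|V1 − V2| / ((V1 + V2)/2) × 100%` (ideal 0%);
- **DCM** — Euclidean distance between the t-weighted centers of mass
  (ideal 0 mm);
- **DSC** — Dice similarity coefficient `2|C1 ∩ C2| / (|C1| + |C2|)`
  (ideal 1).

Metric distributions are then compared across the methods of each stage
with Kruskal–Wallis tests, pooled-variance t tests (Bonferroni-corrected
across method pairs × activation maps), and Cohen's d, and summarised as
the percent of comparisons in which each method was significantly better.

Because two real scanning sessions are not available at desk scale, the
package ships a synthetic-data generator that emulates the structure of a
two-session, five-run block-design cohort (overt word repetition, covert
and overt verb generation, finger/foot/lip motor, visual landmark /
detection; 4 mm voxels; TR 2.5 s, effective 5 s for the sparse overt runs)
with known spherical ground-truth activations, AR(1)-in-time and spatially
smooth noise, rigid head motion, and controllable between-session jitter.

## Worked example

```r
library(fmritrt)

cfg   <- simulation_config(n_subjects = 2, grid_shape = c(32, 32, 24), seed = 42)
ds    <- simulate_dataset(cfg, runs = "run1")
study <- run_study(ds,
                   motion = "NoMoCo", smoothing = c(0, 6),
                   regression = c("Std", "REML"), threshold = c("Bon", "FDR"),
                   seed = 1)
summary(study)
```

```
Test-retest pipeline study
  pipelines: 8, activation maps: 32, matched pairs: 23

Metric means over 23 matched pairs:
  PDAV 21.5%, DCM 3.06 mm, DSC 0.617

Percent of comparisons significantly better (alpha = 0.05):
      stage       metric method n_comparisons n_better percent_better
  smoothing pdav_percent Blur00             1        0              0
  smoothing pdav_percent Blur06             1        0              0
  ...
 regression pdav_percent    Std             1        1            100
```

Eight pipelines were applied to both sessions of two simulated subjects,
producing 32 activation maps and 23 matched cluster pairs. On average a
cluster's volume differed by 21.5% between sessions, its center of mass
moved 3.06 mm, and the voxel overlap (Dice) was 0.617 — the typical scale
of single-subject test–retest variability under the default noise and
between-session jitter. The percent-better table shows, per stage, how
often each method produced significantly more reproducible clusters than a
competitor under Bonferroni correction (here, standard regression beat
AR(1) prewhitening on PDAV and DSC in its single comparison per metric).

`write_study_report(study, "out/")` exports the matched-pair records, the
comparison table and box-plot-ready long-format metrics as TSV. A thin
command-line front end with `simulate` / `run` / `report` verbs lives at
`inst/cli/fmritrt.R`.

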