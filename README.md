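# respmorph

Three-dimensional geometric morphometrics of chest-wall breathing
kinematics.

Optoelectronic plethysmography (OEP) records the 3D trajectories of ~89
reflective markers on the chest wall and converts them into the volume
enclosed by the marker mesh — a precise measure of breathing **size**. It
does not, by itself, describe breathing **shape**: where the torso expands,
how posture constrains motion, how inspiration differs geometrically from
expiration. `respmorph` closes that gap for respiratory physiologists and
biomechanists by treating each marker snapshot as a landmark configuration
and analysing it with the standard geometric-morphometrics toolkit.

## What it computes

For marker trajectories of each subject recorded in two breathing
conditions (quiet breathing, QB, and recovery breathing after exercise,
REC) and grouped by posture (seated SIT vs standing STA):

* **Enclosed-volume signal** per frame, by the divergence theorem over a
  closed triangulation of the marker mesh, and **breathing endpoints**: the
  two most prominent end-inspiratory (IN, volume maxima) and end-expiratory
  (EX, volume minima) instants per condition — 8 landmark configurations
  per subject, 216 for a 27-subject study.
* **Missing-marker estimation** by interpolating thin-plate splines (TPS)
  from a complete reference configuration.
* **Generalized Procrustes analysis (GPA)**: configurations centred, scaled
  to unit centroid size CS = sqrt(sum_i ||x_i - x_bar||^2), and iteratively
  rotated to the consensus; **shape PCA** on the covariance of the
  Procrustes coordinates, jointly and per posture.
* **Functional size** FS = mean CS(IN) - mean CS(EX) and **functional
  shape** FSh = Procrustes distance between mean IN and mean EX shapes, per
  subject and condition — the net size and shape change of one breath.
* The **H1–H3 hypothesis battery** (paired two-sided Wilcoxon signed-rank
  tests): IN vs EX within conditions (H1), FS/FSh between QB and REC (H2),
  and matched instants between conditions (H3), for size and shape, per
  posture; plus **mean respiratory vectors** (mean EX-to-IN displacement in
  PC1–PC2 space) and **TPS mesh warps** of mean breathing shapes.
* A **synthetic cohort generator** with known ground truth (sinusoidal
  compartment-specific breathing, spinal-bend posture, subject shape
  variation, marker noise, occlusion-like dropout) so the entire pipeline
  is testable without human recordings.

## Worked example

```r
library(respmorph)
library(dplyr)

cfg <- run_config(out_dir = "run", seed = 1)   # synthetic 14 SIT + 13 STA design
res <- run_pipeline(cfg)

glance(res$pca_fits$joint)
#>       n n_components pc1_fraction pc2_fraction total_variance
#> 1   216          215        0.362        0.215        0.00440
```

216 configurations enter the joint GPA; the first PC (36% of shape
variance) separates the flexed SIT torsos from the extended STA torsos, the
second (22%) carries tall/narrow-vs-short/wide trunk proportions.

```r
head(res$functional, 4)
#>   subject_id posture condition    FS    FSh
#> 1 SIT01      SIT     QB         14.4 0.0105
#> 2 SIT01      SIT     REC        57.5 0.0392
#> 3 SIT02      SIT     QB         15.6 0.0115
#> 4 SIT02      SIT     REC        59.7 0.0399
```

Each breath changes centroid size by ~15 mm in quiet breathing and ~58 mm
during recovery after exercise, with a matching fourfold increase in net
shape change (FSh).

```r
res$tests %>% filter(hypothesis %in% c("H2_size", "H2_shape"))
#>   hypothesis posture contrast  variable n_pairs statistic  p_value stars
#> 1 H2_size    SIT     REC vs QB FS            14       105 0.000122 ***
#> 2 H2_shape   SIT     REC vs QB FSh           14       105 0.000122 ***
#> 3 H2_size    STA     REC vs QB FS            13        91 0.000244 ***
#> 4 H2_shape   STA     REC vs QB FSh           13        91 0.000244 ***
```

The exercise effect on both functional size and functional shape is
detected in every posture (exact Wilcoxon, all 14 resp. 13 paired
differences positive). Respiratory vectors in PC space are ~4x longer in
REC than in QB.

All artifacts (configurations, aligned coordinates, distance matrices, PC
scores, FS/FSh tables, test reports, warped PLY meshes, a JSON manifest)
are written under `out_dir`; re-running the same configuration reproduces
every CSV bit-identically.

See `vignettes/breathing-morphometrics.Rmd` for the methods account and
`inst/cli/respmorph` for a command-line front end
(`simulate` / `extract` / `analyze` / `warp` / `all`).

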