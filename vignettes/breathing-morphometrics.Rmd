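---
title: "Geometric morphometrics of chest-wall breathing kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric morphometrics of chest-wall breathing kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respmorph)
library(dplyr)
```

## The problem

Optoelectronic plethysmography (OEP) tracks reflective markers glued to the
chest wall — the external surface of thorax and abdomen — and converts their
3D trajectories into the volume enclosed by the marker mesh, a non-invasive
surrogate of lung volume change. Volumes quantify *size*; they say nothing
about the *three-dimensional shape* of breathing motion: where the chest wall
expands, how posture constrains it, how inspiration differs from expiration
geometrically.

`respmorph` treats each instantaneous marker configuration as a landmark
configuration and analyses breathing with the standard toolkit of geometric
morphometrics: centroid size for size, generalized Procrustes analysis (GPA)
plus principal component analysis (PCA) in shape space for shape, thin-plate
splines (TPS) for missing-marker recovery and surface warping. The design
contrasts two breathing conditions — quiet breathing (QB) and spontaneous
recovery breathing immediately after heavy exercise (REC) — in two posture
groups, seated on a cycle ergometer (SIT) and standing (STA).

## Pipeline overview

For every subject and condition:

1. **Volume signal.** The enclosed volume of the 89-marker mesh is computed
   per frame by the divergence theorem (sum of signed tetrahedra over a
   closed, outward-oriented triangulation). Frames with missing markers get
   `NA`, never an imputed volume.
2. **Endpoint detection.** The two most prominent local maxima (end
   inspiration, IN) and minima (end expiration, EX) of the volume signal are
   selected, subject to a minimum separation (`min_period_s`, default 1.5 s).
   This yields 2 cycles x 2 instants x 2 conditions = 8 landmark
   configurations per subject; 27 subjects give 216 configurations.
3. **Missing-marker estimation.** Markers occluded at an endpoint frame are
   reconstructed by an interpolating TPS from a complete reference
   configuration, before any superimposition.
4. **GPA.** All configurations are centered, scaled to unit centroid size
   (full Procrustes, Kendall shape) and iteratively rotated onto the running
   consensus. Original centroid sizes (CS) are kept for the size analyses.
5. **Shape PCA.** Eigendecomposition of the covariance of the Procrustes
   coordinates; one joint analysis (exploration of posture + shape + motion)
   and one per posture group (hypothesis testing, to keep posture out of the
   contrasts).
6. **Functional metrics.** Per subject and condition, functional size
   `FS = mean CS(IN) - mean CS(EX)` (mm) and functional shape `FSh` = the
   Procrustes distance between the cycle-mean IN and cycle-mean EX shapes —
   the net size and shape change of a breath.
7. **Hypothesis battery.** Paired two-sided Wilcoxon signed-rank tests of
   H1 (IN vs EX within condition), H2 (FS and FSh, QB vs REC) and H3
   (matched instants across conditions), for size (CS, FS) and shape
   (PC1/PC2 scores, FSh), separately per posture.
8. **Warping.** Mean EX/IN shapes per condition are visualized by mapping a
   torso surface mesh through the TPS from the template landmarks to the
   target configuration.

`run_pipeline()` orchestrates all stages, writes every intermediate table as
CSV (plus PLY warps and a JSON manifest), and is bit-reproducible given the
seed.

## Conventions and numerical choices

* **Coordinates** are millimetres, right-handed: +x subject's left, +y
  ventral, +z cranial.
* **Mesh topology.** The 89 markers are triangulated as 7 quad bands between
  8 circumferential rows, a fan to the cranial pole marker, and an ear-fan
  closing the caudal ring (174 triangles). The triangulation is validated as
  a closed orientable surface (every edge in exactly two triangles, Euler
  characteristic 2) with outward orientation (positive template volume).
  Commercial OEP connectivities are proprietary, so this is a documented
  stand-in; any triangle list can be injected as JSON (`read_topology()`).
* **Volume** is origin-independent for closed meshes; the test suite checks
  this directly and against an independent tetrahedron-fan decomposition.
* **Endpoint selection.** Prominence-ranked ("prominent", default) with ties
  broken by earlier time, or earliest-qualifying ("consecutive"); both are
  exposed because printed study protocols rarely say which breaths were
  picked. Detection interpolates linearly across missing frames but never
  reports volumes there. No smoothing by default; a moving-average window is
  available.
* **Procrustes.** Full Procrustes (unit-CS) superimposition; reflections
  forbidden (`det(R) = +1`) as appropriate for anatomical data; convergence
  when the total Procrustes sum of squares changes by less than `tol = 1e-8`
  (at most `max_iter = 100` iterations; non-convergence is flagged, not
  fatal). The Procrustes distance is the Euclidean distance between
  superimposed unit-CS coordinate sets — the partial/tangent convention of
  mainstream morphometric software; the geodesic variant is not used. No
  tangent-space projection is applied beyond mean-centering: breathing-scale
  shape variation is small, so curvature corrections are negligible at the
  reported precision.
* **PCA sign convention:** the largest-magnitude loading entry of each PC is
  made positive, so score medians are comparable across runs.
* **FSh definition.** With two cycles per instant, FSh is the distance
  between cycle-mean IN and cycle-mean EX aligned shapes; the mean of
  per-cycle distances from the GPA distance matrix is emitted alongside for
  audit. Cycle means are likewise used for the CS and PC-score tests.
* **Wilcoxon tests** drop zero differences, use the exact distribution
  whenever at most 25 non-zero differences have untied magnitudes, and the
  tie/continuity-corrected normal approximation otherwise. Two-sided
  p-values, no multiple-testing correction by default (Holm available),
  significance stars at 0.05 / 0.01 / 0.001.
* **Missing-landmark reference policy:** the mean of the subject's own
  complete configurations when at least two exist (same laboratory frame,
  closest shape); otherwise the GPA consensus of all complete configurations
  rescaled to their mean size — raw cross-subject means would smear over
  different lab placements. Estimation is refused above
  `max_missing_frac = 0.2`.
* **TPS:** kernel `U(r) = r` (the standard 3D choice), full affine part,
  side conditions annihilating affine components, dense direct solve of the
  (k+4) system — exact interpolation at control points, bending energy zero
  exactly for affine maps.

## The synthetic cohort generator

No raw recordings ship with the package, so `simulate_cohort()` generates
OEP-like data with known ground truth. One subject is built as:

template (89 markers on an elliptical-section torso)
-> per-subject anisotropic scaling driven by a single *trunk-aspect* factor
   (`subject_aspect_sd`, log-sd 0.033: tall/flat/narrow vs short/deep/wide)
-> unstructured per-marker perturbation (`subject_shape_sd`, 5 mm)
-> sinusoidal breathing, radial about the torso axis:
   `r(t) = r0 (1 + a sin(2 pi f t))` with separate thoracic/abdominal
   amplitudes per condition (defaults QB 0.008/0.012, REC 0.035/0.045,
   giving tidal volumes near 0.8 L and 3 L on the ~20 L torso envelope)
-> progressive spinal bend (flexion angle grows linearly with height;
   defaults +12 deg SIT-like, -3 deg STA-like, between-subject sd 4 deg)
-> random placement in the laboratory frame (rotation about the vertical,
   horizontal offset)
-> additive Gaussian marker noise (`noise_sd`, 0.5 mm)
-> contiguous dropout runs (two-state Markov chain, mean run 0.3 s,
   stationary rate `dropout_prob`, 1%).

End expiration is the sine trough (phase 3&pi;/2) and end inspiration the
crest (phase &pi;/2); the noise-free configurations at those phases are the
stored ground truth, together with the true FS, FSh and tidal volume they
imply. Bit-reproducibility comes from one integer seed with deterministic
per-subject substreams.

Three choices deserve comment. The bend is applied as a height-proportional
rotation because a *rigid* tilt would be removed entirely by the Procrustes
fit — posture must be a genuine shape change for a posture-dominant first PC
to exist, which is what two-posture chest-wall data show. The trunk-aspect
factor creates the familiar second morphospace axis (torso proportions).
Noise and dropout rates of commercial systems are not published; 0.5 mm and
1% are realistic placeholders, not estimates. With the defaults, a joint
216-configuration analysis puts roughly 35% of shape variance on the posture
PC and ~20% on the aspect PC, with breathing motion oblique to both — the
qualitative structure expected of such a design.

**What the generator does not emulate:** rib-by-rib kinematics, muscle
recruitment, asymmetry, drift or non-stationary breathing, realistic
anthropometric covariance beyond the single aspect factor, and soft-tissue
artifacts. Passing parameter-recovery tests therefore demonstrates that the
*pipeline* is correct and well-calibrated, not that it has been validated on
human recordings.

## Validation and problem sizes

The test suite validates each computational core against an independent
oracle: enclosed volume vs a tetrahedron-fan decomposition (1e-9 relative),
centroid size vs the direct formula (1e-12), shape PCA vs a dense SVD
(1e-9), exact Wilcoxon p-values vs full 2^m enumeration (m up to 12), TPS
interpolation exactness (1e-9 mm), plus closed forms (unit tetrahedron 1/6,
unit cube 1, quad centroid size sqrt(8), affine bending energy 0) and
GPA invariance properties (ordering, rigid pre-motions, monotone
convergence).

End-to-end checks run the full study design — 27 subjects (14 SIT at 60 Hz,
13 STA at 100 Hz), 16 s recordings at 0.25 Hz breathing — confirming 8
configurations per subject and 216 in the joint GPA, and recover the
generator truth: FS to 1e-6 mm on noise-free cohorts, FSh rank-identical to
truth, both strictly increasing with amplitude under noise. Statistical
calibration uses 14-subject cohorts at 0.5 Hz breathing and 6 s duration:
the QB-vs-REC FS contrast rejects at its nominal 5% rate across 400 null
cohorts (equal amplitudes) and detects the exercise effect in over 95% of
200 cohorts at the default amplitude contrast. These sizes keep the whole
suite in the minutes range while leaving the statistical conclusions
unchanged.

## A short session

```{r example, eval = FALSE}
library(respmorph)

cfg <- run_config(out_dir = "run", seed = 1) # 14 SIT + 13 STA synthetic design
res <- run_pipeline(cfg)

glance(res$pca_fits$joint)       # explained variance of the joint morphospace
res$functional                   # per subject x condition FS and FSh
res$tests                        # the H1-H3 Wilcoxon battery with stars
autoplot(res$pca_fits$SIT)       # posture-specific shape space
```

## Known limitations

* The marker template and mesh connectivity are stand-ins; for real OEP
  data, supply the system's own triangulation via `read_topology()` and
  trajectories converted to the long-CSV dialect (no binary C3D reader is
  included).
* The Procrustes distance matrix uses consensus-aligned coordinates;
  pairwise-optimal distances differ at second order for large shape
  differences (breathing-scale differences are far below that regime).
* The hypothesis battery reports nominal per-test p-values by design;
  switch on Holm adjustment for family-wise control.
* Compartmental volume partitioning (pulmonary vs abdominal rib cage vs
  abdomen) is out of scope: all volumes are whole-chest-wall.
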