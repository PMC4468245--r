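---
title: "Quantifying skeletal glucose metabolism from PET/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skeletal glucose metabolism from PET/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pibgm)
```

# The problem

Whole-body FDG-PET/CT provides co-registered anatomy (CT, in Hounsfield
units) and glucose metabolism (PET, as activity concentration in Bq/mL).
In fever of unknown origin (FUO), bone and bone-marrow glycolysis is often
diffusely elevated, which is hard to assess by visual reading.  `pibgm`
implements a fully automatic chain that (i) extracts the skeleton from the
CT, (ii) transfers the bone mask onto the PET, (iii) normalizes uptake to
standardized uptake values (SUV), and (iv) condenses the skeletal uptake
distribution into a single biomarker, the PET index of bone glucose
metabolism (PIBGM): the fraction of bone voxels whose SUV exceeds a cutoff
$t$,

$$\mathrm{PIBGM}(t) = \frac{N_t}{N_b},\qquad
  N_t = \#\{i : P_i > t,\ i \in \text{bone}\},\quad
  N_b = \#\{i : i \in \text{bone}\}.$$

The inequality is strict: a voxel exactly at $t$ counts as normal.  The
index is a non-increasing step function of $t$ with steps at observed
SUVs, bounded by 1 (cutoff below all uptake) and 0 (cutoff above all).

# Pipeline stages

## PET-to-CT grid matching

Clinical CT and PET grids differ (512×512 vs 168×168 in-plane is typical).
The default scheme replicates each PET pixel into a 3×3 block with the
same value and pads the four sides symmetrically with zeros (168×168 →
504×504 core inside a 512×512 frame with a 4-pixel border).  Replication
preserves every original value, multiplies the in-plane sum by exactly 9,
and is invertible by block subsampling on the core — properties the test
suite asserts.  A separable trilinear interpolator
(`upsample_pet_trilinear()`) is also provided for users who prefer a
smooth interpolant; it reproduces constants exactly and linear ramps at
interior voxels.  Replication is the default because it is the scheme the
rest of the pipeline is specified around, and because it keeps the PET
voxel histogram unchanged (interpolation manufactures intermediate values,
which would bias PIBGM counts).

## Bed removal

The scanner bed absorbs X-rays and appears in CT but never in PET, so the
PET is the natural mask for it.  The PET is smoothed with a separable
Gaussian (default σ = 3 voxels) and thresholded (default 1% of the
smoothed maximum, making the mask invariant to global rescaling of the
PET).  Two refinements matter in practice:

* **Support trimming.** Smoothing spreads activity ~2–3 σ beyond the true
  body outline; on a zero background the 1% level would dilate the mask by
  several voxels and can reach the bed.  The mask is therefore intersected
  with the raw-PET exceedance of the same threshold, restoring the support
  boundary; noise pinholes this opens inside the body are closed by the
  hole-filling step.
* **Fill value.** Voxels outside the body are set to −1000 HU (air), not
  multiplied by zero: 0 HU is water-equivalent and would inject a spurious
  soft-tissue population into the histogram the next stage fits.

The largest 6-connected component is kept and slice-wise holes are filled.
Bed removal is idempotent, and on noiseless phantoms the body mask equals
the ground-truth body exactly.

## Histogram auto-thresholding

Body-masked CT intensities are histogrammed (default 128 bins over −200 to
300 HU) and fitted with a two-Gaussian model

$$y(x) = A_m e^{-\left(\frac{x-B_m}{c_m}\right)^2}
       + A_f e^{-\left(\frac{x-B_f}{c_f}\right)^2},$$

where the components describe muscle and fat; bone is too small a
population to contribute a visible third mode, so it is deliberately not
modelled.  Note $c$ is the $\sqrt2$-scaled Gaussian width of this
parameterization, not a standard deviation.  The HU window excludes air
and dense cortical bone, which the soft-tissue model does not describe.
Fitting is bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm`), initialized at the two tallest histogram peaks separated
by at least 50 HU, with widths started at half the peak separation;
histograms without two such peaks are rejected as degenerate rather than
guessed at.  Components are sorted so $B_f < B_m$.

The bone pre-segmentation threshold is

$$\mathrm{threshold} = B_m + \frac{\omega}{2}\,(B_m - B_f),$$

which sits above the muscle centre by a tunable fraction of the fat–muscle
separation; it is strictly increasing in ω and tends to $B_m$ as ω → 0.
The reference centre subtracted from $B_m$ is the fat centre: the model
has only two centres, so no other reading is available.  ω defaults to
0.5, which on the default phantom places the threshold (~70 HU) between
muscle (40 HU) and marrow (150 HU) so that the whole bone — not just the
cortical shell — exceeds it.  Thresholding is followed by slice-wise hole
filling, because with larger ω (or denser marrow) the threshold captures
only the cortical ring while the enclosed marrow must still belong to the
bone; the bare threshold response is available via `fill_holes = FALSE`.

## Chan–Vese refinement

The pre-segmentation initializes a two-region active-contour refinement
that minimizes, per axial slice,

$$E(C) = \sum_{\text{inside}} (I - c_1)^2 + \varepsilon (I - Th)^2
       + \sum_{\text{outside}} (I - c_2)^2 + \varepsilon (I - Th)^2,$$

with $c_1, c_2$ the region means, $Th$ the threshold from the previous
stage and ε its weight.  Two structural observations shaped the
implementation:

* The ε-term is integrated over *both* regions, so for a fixed image it is
  a constant offset: it shifts reported energies but cannot influence
  which labelling is optimal.  The contour dynamics are therefore those of
  the classic two-phase Chan–Vese fidelity.
* Without a smoothness term the exact minimizer is a per-pixel
  nearest-of-$\{c_1, c_2\}$ classification.  A contour-length penalty
  weighted by `mu` is added for noise robustness; `mu = 0` reproduces the
  literal energy.  `mu = NULL` (default) scales the weight to
  0.1 × (dynamic range)², keeping the curvature force commensurate with
  the squared-intensity data force regardless of the HU range.

For `mu = 0` the evolution is implemented as the exact alternating
minimization (reassign each pixel to the nearer mean, update the means) —
the limit of the gradient flow in which the data force drives each pixel's
sign to its per-pixel optimum between mean updates.  This makes the energy
sequence provably non-increasing, a property the tests assert, and lets an
exhaustive search over all labellings of ≤ 4×4 images confirm that the
returned mask attains the global minimum on two-population fixtures.  For
`mu > 0` a standard level-set descent is used: signed-distance
initialization from the pre-segmentation, smoothed Heaviside/delta of
width 1 voxel, central-difference curvature, a CFL-normalized step,
re-initialization to a signed distance every 10 iterations, and
convergence when fewer than `tol` (default 1e-4) of the domain voxels
change sign.  Evolution is restricted to the body mask: the air background
(−1000 HU) would otherwise drag the outside mean far below any tissue and
absorb muscle into the bone region.

Evolution is slice-wise 2D.  Within a slice the contour refines the outer
bone boundary; the enclosed marrow — whose HU is nearer the soft-tissue
mean than the bone-region mean — is restored by a final slice-wise hole
fill.  Slices whose pre-segmentation is empty stay empty.  On noiseless
phantoms the result equals the ground-truth bone exactly (Dice 1.0); with
20 HU tissue noise Dice stays at or above 0.95.

Bone is split into cortex and marrow by an intensity rule within the bone
mask: Otsu's threshold over the bone-voxel HU by default (a fixed HU
cutoff is available), voxels at or above the cut labelled cortex.  On the
noiseless phantom (marrow 150 HU, cortex 700 HU) the split reproduces the
ground-truth labels exactly.

## SUV and PIBGM

Activity concentration is normalized three ways:

* `bw`: dose per body weight in grams — the conventional SUV;
* `bsa`: dose per body surface area, Du Bois formula
  $0.007184\,w^{0.425}h^{0.725}$ (m², w in kg, h in cm);
* `lbm`: dose per lean body mass, James formulas
  ($1.07w - 148(w/h)^2$ female, $1.1w - 120(w/h)^2$ male, kg).

All unit conversions (Bq↔MBq, kg↔g) are explicit and tested; SUV is linear
in activity and inversely linear in dose.  PET values are taken as
decay-corrected concentrations as exported by the scanner; no additional
decay correction is applied.  The lean-body-mass formula errors rather
than returning a non-positive mass for extreme weight/height ratios.

PIBGM profiles are evaluated on the cutoff grid 0.4 to 2.2 in steps of
0.2 by default, for whole bone, cortex and marrow.

## Diagnostics

Classification cutoffs are chosen by DANP (discriminative ability for the
normal person): for target fraction `danp`, the cutoff is the
⌈danp·n⌉-th order statistic of the normal subjects' biomarker values, and
a subject is abnormal iff strictly above it.  With distinct values this
meets the target exactly on the defining set — e.g. 95 of 100 normals
classified normal at danp = 0.95, at every SUV cutoff simultaneously,
which is what the acceptance script verifies.  Order statistics (no
interpolation) were chosen precisely so the guarantee is exact rather than
asymptotic.  The default decision biomarker is cortex PIBGM at $t = 1.2$;
both the region and the cutoff are configurable.

Group comparisons use Welch's unequal-variance t-test with Satterthwaite
degrees of freedom (via `stats::t.test`), two-sided.  No multiple-testing
correction is applied across the cutoff grid; p-values are reported raw.
ROC curves are built over all distinct score thresholds and the AUC is
computed by the trapezoid rule, which equals the tie-corrected
Mann–Whitney concordance probability (asserted against a brute-force
pairwise oracle and cross-checked against `pROC`).  AUC values are graded
qualitatively: ≥ 0.9 excellent, ≥ 0.8 good, ≥ 0.7 worthless, ≥ 0.6 not
good, below that fail.

# The phantom: what it emulates and what it does not

Every test input is generated by `make_phantom()` / `make_cohort()`: a
stylized torso of stacked ellipses — fat enclosing muscle enclosing a
circular cortical ring with a marrow core — plus a bed slab below the body
in CT only.  Default intensity populations are fat −100, muscle 40,
marrow 150, cortex 700, bed 300, air −1000 HU with 15 HU per-tissue noise:
a realistic HU ordering with clearly separated fat/muscle modes.  PET
uptake is expressed directly as target SUV_bw per tissue (defaults: fat
0.2, muscle 0.5, marrow 0.93, cortex 0.86 — marrow above cortex, both near
1, as in normal skeletal FDG uptake) and converted to Bq/mL through the
patient metadata, so the SUV computation is exercised end-to-end rather
than short-circuited.  Cohorts add a group-level cortex uptake uplift
(defaults 0.20 inflammatory, 0.17 infection, 0.23 neoplasm — disease
groups above normal, neoplasm and inflammation strongest) plus a
between-patient spread of 0.15 SUV.  The default grid is 16×48×48 voxels
at 5×1.5×1.5 mm: small enough that the full chain runs in about a second
per case, large enough that the bone comprises thousands of voxels and
discretization does not dominate the geometry.

The phantom is intensity-faithful, not anatomy-faithful.  It contains no
scanner physics (scatter, attenuation, reconstruction artifacts, partial
volume), no anatomical shape variation, no respiratory motion, and its
noise is independent Gaussian rather than reconstruction-correlated.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and behave as designed on data matching their intensity
assumptions — not that clinical accuracy figures transfer.  Cohort-level
quantities (AUC, sensitivity at a given DANP) depend on effect sizes and
sample sizes; the package's cohort tests assert structural properties
(specificity by construction, separation under strong uplift, chance-level
behaviour under no uplift) rather than any particular clinical value.

# Numerical choices and degenerate inputs

* All randomness flows from one integer seed per phantom/cohort; equal
  seeds give bit-identical volumes.
* Histogram fits reject flat or single-mode histograms instead of
  returning a meaningless optimum; non-convergence errors carry the
  initialization.
* The contour evolution errors when a region empties (the contour
  vanishes), naming the iteration; `segment_bone_volume()` prefixes stage
  errors with the slice index, and `run_patient()` with the stage name.
* Ties: PIBGM uses a strict `>` at the cutoff; DANP classification uses a
  strict `>` at the cutoff (a value equal to the cutoff is normal); the
  cortex/marrow split assigns HU exactly at the cut to cortex.
* Empty masks are errors where a statistic would be undefined (empty body,
  empty truth in overlap metrics, empty region in SUV stats) but benign
  where emptiness is meaningful (an empty label in mask transfer returns
  an empty vector; an empty pre-segmentation slice stays empty).
* Undefined diagnostic rates (zero denominators) are `NA`, never 0.

# Known limitations

* 2D slice-wise contour evolution; no 3D level set.
* Two-component histogram model only; no three-component or voxel-wise EM
  fitting.
* No partial-volume correction, SUL-peak or kinetic modelling.
* No DICOM ingestion; volumes are exchanged as NIfTI with JSON sidecars
  for units and patient metadata.
* The diagnostic evaluation is in-sample (no cross-validation), matching
  its intended use as a descriptive cohort analysis.
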