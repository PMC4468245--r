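# pibgm

Automatic quantification of skeletal glucose metabolism from co-registered
whole-body FDG-PET/CT, for computer-assisted workup of fever of unknown
origin (FUO) and related systemic conditions.

Clinicians reading whole-body PET struggle to grade *diffusely* elevated
bone and marrow uptake. `pibgm` replaces visual grading with a fully
automatic chain:

1. **Grid matching** — the coarse PET is brought onto the CT grid by 3×3
   block replication with symmetric zero padding (e.g. 168×168 → 504×504
   core in a 512×512 frame); trilinear interpolation is available as an
   alternative.
2. **Bed removal** — the scanner bed appears in CT but never in PET, so a
   smoothed, thresholded PET provides the body outline; CT voxels outside
   it are set to air (−1000 HU).
3. **Auto-thresholding** — the body CT histogram is fitted with a
   two-Gaussian fat + muscle model
   `y(x) = A_m exp(−((x−B_m)/c_m)²) + A_f exp(−((x−B_f)/c_f)²)`,
   and the bone threshold is placed at `B_m + (ω/2)(B_m − B_f)`.
4. **Segmentation** — a threshold-augmented Chan–Vese active contour
   refines the pre-segmentation slice by slice, minimizing
   `Σ_in (I−c1)² + ε(I−Th)² + Σ_out (I−c2)² + ε(I−Th)²`
   (optionally with a contour-length penalty), and the bone is split into
   cortex and marrow by a within-bone Otsu rule.
5. **Quantification** — SUV maps under body-weight, body-surface-area
   (Du Bois) and lean-body-mass (James) normalization, per-region
   statistics, and the **PIBGM** biomarker: the fraction of bone voxels
   with SUV strictly above a cutoff `t`, `PIBGM(t) = N_t / N_b`.
6. **Diagnostics** — classification cutoffs by DANP order statistics
   (choose the cutoff so a target fraction of normal subjects is
   classified correctly), confusion-matrix metrics, Welch t-tests, and
   ROC/AUC with qualitative grading.

A synthetic phantom generator (`make_phantom()`, `make_cohort()`) produces
co-registered CT/PET volumes with exact ground-truth masks and
group-structured cohorts, so the whole chain is testable without clinical
data. See `vignettes/bone-metabolism-pipeline.Rmd` for the model details
and design rationale.

## Worked example

```r
library(pibgm)

case   <- make_phantom(phantom_spec(seed = 42))   # noisy synthetic patient
report <- run_patient(case, pipeline_config(suv_modes = "bw"))
report
#> <patient_report> anonymous (normal): 2927 bone voxels (1455 marrow / 1472 cortex), HU threshold 74.8
```

The histogram fit found fat and muscle centres whose spread places the
bone threshold at 74.8 HU — between muscle (40 HU) and marrow (150 HU) —
and the contour refinement labelled 2927 bone voxels. Against the phantom
ground truth:

```r
seg_metrics(report$seg, case$truth_bone)
#>         tpr         fpr        dice
#> 1.000000000 0.001383004 0.991906320
```

Per-region SUV statistics and the cortex PIBGM profile:

```r
report$suv_stats
#>      region mode      mean        sd    n
#>  whole_bone   bw 0.8892370 0.1650751 2927
#>      marrow   bw 0.9244367 0.1725155 1455
#>      cortex   bw 0.8544438 0.1494946 1472
```

Marrow uptake (mean SUV_bw 0.92) exceeds cortex (0.85), as generated.
The cortex PIBGM profile steps down as the SUV cutoff `t` rises through
the cortex uptake distribution (centred at 0.86 with 0.15 SUV noise):

```r
#>  region   t       value  N_t  N_b
#>  cortex 0.4 0.997282609 1468 1472   # nearly all cortex voxels above 0.4
#>  cortex 0.8 0.638586957  940 1472
#>  cortex 1.2 0.008831522   13 1472   # only the noise tail above 1.2
```

Cohort analysis with group-level uptake differences:

```r
cases <- make_cohort(c(normal = 10, neoplasm = 8), seed = 7)
coh   <- run_cohort(cases, pipeline_config(suv_modes = "bw", danp_grid = c(1, 0.95)))
coh
#> <cohort_report> 18 patients, AUC 0.681 (Not good)
```

With the default modest uplift (+0.23 SUV for neoplasm), between-patient
spread 0.15 and only 18 patients, the cortex-PIBGM score separates the
groups only weakly (AUC 0.68); larger uplifts or cohorts drive the AUC
toward 1, and zero uplift yields chance level — both asserted in the test
suite. `coh$sweep` tabulates sensitivity/specificity per DANP level and
cutoff, `coh$ttests` the per-group Welch tests, `coh$roc$points` the ROC
curve.

A thin command-line front end is provided in `inst/cli/pibgm.R`:

```sh
Rscript inst/cli/pibgm.R phantom --seed 3 --out-dir ph/
Rscript inst/cli/pibgm.R run --case-dir ph/ --out-dir out/
Rscript inst/cli/pibgm.R cohort --seed 1 --n-normal 8 --n-fuo 6 --out-dir coh/
```

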