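# vdscore

Morphometry and cohort statistics for predicting the recurrence of
non-functioning pituitary adenomas (NFPAs) from preoperative MRI.

## The problem and the score

NFPAs lack hormonal symptoms, present late, and relapse in a substantial
fraction of patients even after apparently complete resection.  The
classical preoperative grading systems capture either horizontal
invasiveness (Knosp grade, cavernous-sinus invasion relative to the
carotid arteries) or longitudinal extension (Hardy–Wilson grade), but
neither quantifies both.  The V-D score combines four radiological
measurements taken from the preoperative segmentation:

- **V1** — suprasellar tumor volume (mm³), the part above the diaphragm
  sella (or above the "waist" of a dumbbell-shaped tumor when the
  diaphragm is not visible);
- **V2** — intrasellar tumor volume (mm³), including any infrasellar
  extension into the sphenoid sinus or clivus;
- **D1** — maximum horizontal (in-plane) tumor diameter (mm);
- **D2** — shortest intercarotid distance (mm) on the slice where D1 is
  attained;

and is defined as

```
V-D = V1/V2 + D1/D2
```

High values mean a tumor that bulges far above the sella and/or is wide
relative to the carotid corridor — both features that make total
resection difficult and predict recurrence.  Patients above a
ROC-derived cutoff (Youden index, J = sensitivity + specificity − 1)
recur earlier.

This package implements the whole analysis chain:

1. **Voxel morphometry** (`read_mask_nifti`, `split_by_plane`,
   `detect_waist`, `max_horizontal_diameter`, `intercarotid_distance`,
   `measure_morphometrics`) — V1/V2/TV/D1/D2 and the score from labeled
   NIfTI masks (1 = tumor, 2 = left carotid, 3 = right carotid).
2. **Clinical rules** (`vd_value`, `classify_size`,
   `classify_recurrence`, `flag_rater_discordance`) — the size classes
   (< 15 mm small, 15–30 mm large, ≥ 30 mm giant), the radiological
   recurrence definition (> 100 mm³ after total resection, > 25% growth
   of a residual after subtotal resection), and the 20% inter-rater
   discordance trigger.
3. **Cohort statistics** (`summarize_cohort`, `spearman_matrix`,
   `logistic_fit`, `roc_analysis`, `km_analysis`, `run_full_analysis`)
   — baseline tables, Spearman correlations, logistic regression with
   Wald tests, ROC with Youden cutoff, and Kaplan–Meier recurrence-free
   curves with log-rank tests.
4. **Validation instruments** (`make_phantom`, `simulate_cohort`,
   `default_calibration`) — digital phantoms with closed-form truth and
   a calibrated synthetic-cohort generator, so every stage is testable
   without patient data.

## Worked example

The numbered scripts under `analysis/` form the complete workflow.
`analysis/02_simulate_cohort.R` draws the default calibrated cohort of
98 patients and `analysis/03_cohort_analysis.R` runs the full pipeline
on it:

```
simulated 98 patients (seed 11): 55 recurrent (56.1%)
median V2 2738 mm^3, V1 245 mm^3, D1 26.1 mm, D2 25.6 mm, V-D 1.34
non-recurrent median V1 = 0.00 (zero-inflated suprasellar volume)

V-D recurrence analysis: n = 98 (55 recurrent)
  AUC: V-D 0.872 | Knosp 0.773 | size 0.676 | V1/V2 0.847 | D1/D2 0.766
  V-D cutoff 1.588 (sensitivity 0.727, specificity 0.953)
  KM high vs low V-D: log-rank p = 8.191e-20
```

Reading: on this synthetic cohort the integrated score discriminates
recurrence (AUC 0.87) better than the Knosp grade alone (0.77) or either
component ratio; the Youden-optimal cutoff splits the cohort into a
high-V-D group that recurs much earlier (log-rank p ≈ 10⁻¹⁹).  The
univariate logistic coefficient of the score on this cohort is 2.08
(S.E. 0.50, Wald p ≈ 3×10⁻⁵).

For a single case with segmentation masks:

```r
library(vdscore)
mask <- read_mask_nifti("patient01_labels.nii.gz")
m <- measure_morphometrics(mask, sellar_partition("waist_detected"))
print(m)          # V1, V2, TV, D1, D2, both ratios, and the V-D value
```

`analysis/01_phantom_validation.R` verifies the measurement engine
against spheres/ellipsoids with closed-form volumes (errors < 2% at
0.5 mm voxels, diameters exact to one in-plane voxel), and
`analysis/04_worked_cases.R` audits the five published example cases for
internal consistency (V1 + V2 reproduces each printed total volume
exactly).

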