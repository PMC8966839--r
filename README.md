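# ictexture

Noninvasive assessment of intracranial hypertension from bilateral CT
texture asymmetry in unilateral intracerebral hemorrhage.

## What it does

After a unilateral hypertensive intracerebral hemorrhage, the hematoma and
perilesional swelling deform the bleeding hemisphere against its mirror
image. `ictexture` quantifies that deformation on a single axial CT slice
and classifies intracranial hypertension (ICP ≥ 20 mmHg) from it:

* six symmetric 20×20-pixel ROIs (anterior horn, temporal lobe, posterior
  horn × both sides), placed about the midline column, validated against a
  0–50 HU window and the hematoma/ventricle masks;
* 40 second-order texture features per ROI, implemented from first
  principles: 24 gray-level co-occurrence (GLCM) and 16 gray-level
  run-length (GLRLM) features (symmetric, direction-averaged, distance 1,
  four directions, 5-HU bins over the [0, 50] window);
* the per-feature **variation rate** `R = |(F_hem − F_contra) / F_hem|`,
  min–max standardized within each region (fit on the training split,
  applied clipped to the test split);
* three morphological features: hematoma volume by HU thresholding,
  midline shift as septum-to-midline perpendicular distance, and the
  ventriculocranial ratio (VCR);
* four random-forest classifiers — MF (morphology) and AH/TL/PH (one per
  region's variation rates) — with recursive feature elimination under
  5-fold stratified cross-validation for the texture models, evaluated by
  accuracy, precision, recall, F1 and trapezoidal ROC AUC on one shared
  stratified held-out split.

Because no public imaging exists for this problem, the package includes a
phantom head-CT generator with ground-truth ICP, hematoma/ventricle masks,
ICP-coupled midline shift, ventricle compression, hematoma volume, and
region-specific texture asymmetry, which the test suite uses for
end-to-end signal-recovery and null-control experiments. See the methods
vignette (`vignettes/ct-texture-icp.Rmd`) for the model and every default.

## Worked example

```r
library(ictexture)

cfg <- run_config(n = 200, seed = 42, slice_heights_mm = c(50, 60))
reports <- run_cohort_models(cfg)
for (nm in names(reports)) print(reports[[nm]])
```

On this cohort (200 phantoms, 68% hypertension prevalence, posterior-horn
asymmetry gain 1.0, anterior/temporal gains 0.3) the run prints:

```
MF AUC 0.986  F1 0.967
AH AUC 0.545  F1 0.762
TL AUC 0.569  F1 0.758
PH AUC 0.861  F1 0.800
```

Reading: the posterior-horn texture model recovers the strong asymmetry
signal built into the generator (AUC 0.86) and clearly beats the two
weak-gain regions (≈0.55, near chance), reproducing the generator's gain
ordering. The morphology model is almost perfect *on phantoms* because
phantom volume and shift are measured noise-free — a deliberate difference
from clinical practice discussed in the vignette.

Single pieces work standalone, e.g.

```r
patch <- matrix(sample(0:50, 400, TRUE), 20, 20)
extract_features(patch)          # named vector of the 40 features
variation_rate(2, 1)             # 0.5
```

A thin CLI wrapper is installed at `inst/cli/ictexture.R`
(`simulate` and `run` subcommands over the same functions).

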