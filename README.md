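# echoflow

Detection of regional wall motion abnormalities (RWMA) — the early
echocardiographic signature of myocardial infarction — from multi-view
echo loops, using the dense cardiac motion field rather than a handful of
displacement-curve peaks.

`echoflow` implements a three-phase pipeline over apical two-chamber (A2C)
and four-chamber (A4C) loops:

1. **Cardiac structure segmentation** — a U-Net (23 convolutional layers at
   the default depth) labels the left-ventricular wall per frame and zeroes
   the background.
2. **Motion feature engineering** — dense optical flow
   `E_t(u, v) = F(I_t, I_t+1; θ_F)` between consecutive masked frames,
   encoded as 8-bit x/y frame pairs; a temporal ConvNet scores `k = 7`
   sparsely sampled 5-pair snippets (224×224×10 input) whose shared-weight
   outputs are combined by a segmental consensus
   `TSN(T_1,…,T_k) = H(g(F(T_1;W),…,F(T_k;W)))`, trained with the consensus
   cross-entropy `L(y, G) = −Σ_i y_i (G_i − log Σ_j exp G_j)`. The
   penultimate layer provides a 1024-element motion feature per view.
3. **RWMA detection** — A2C and A4C features concatenated to a 2048-element
   descriptor and classified by KNN, decision tree, random forest, SVM and
   MLP, each grid-searched with inner CV, under stratified 5-fold
   cross-validation (RWMA positive).

The package additionally provides contour kinematics (L/7–2L/7 segment
partition of the wall contour, per-segment displacement curves vs the first
frame) and a synthetic beating-heart phantom generator with ground-truth
wall masks and per-segment motion amplitudes, so the entire pipeline is
testable without clinical recordings. See the methods vignette
(`vignettes/echoflow-methods.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(echoflow)

# a 40-subject phantom cohort (20 RWMA at hypokinesia factor 0.3) plus a
# disjoint 10-subject training cohort for the segmenter and backbones
tpl    <- phantom_config(hypokinesia_factor = 0.3)
cohort <- generate_cohort(20, 20, tpl, seed = 101)
train  <- generate_cohort(5, 5, tpl, seed = 202)

cfg <- pipeline_config(cohort, out_dir = "run1", train_cohort = train,
                       seg = list(epochs = 6, frames_per_subject = 2),
                       seed = 17, n_folds = 5)
res <- run_pipeline(cfg)   # trains, segments, computes flow and features
print(res$report)          # roughly 15 minutes on one CPU core
```

```
<detection report>
  KNN  acc 90.00%  sens 80.00%  spec 100.00%  AUC 0.950
  DT   acc 90.00%  sens 95.00%  spec 85.00%  AUC 0.900
  RF   acc 95.00%  sens 90.00%  spec 100.00%  AUC 0.985
  SVM  acc 92.50%  sens 90.00%  spec 95.00%  AUC 0.958
  MLP  acc 97.50%  sens 95.00%  spec 100.00%  AUC 0.980
```

Each line is one classifier of the bank evaluated out-of-fold on the
cohort: accuracy, sensitivity (RWMA detection rate), specificity and the
area under the ROC curve of the out-of-fold scores. `run1/` holds the
fused features, per-subject predictions, and a JSON report with per-fold
and aggregated (max/mean/min) metrics.

Classical displacement-curve analysis on the same phantoms:

```r
out    <- generate_sequence(phantom_config(hypokinetic_segments = 3,
                                           hypokinesia_factor = 0.2,
                                           speckle_sigma = 0), "A4C")
curves <- displacement_curves(contour_sequence(out$truth$wall_masks))
round(curves$maxima, 2)
#>   l1   l2   l3   l4   r1   r2   r3   r4
#> 7.94 8.13 8.22 8.53 7.94 7.38 3.07 8.10
```

The hypokinetic segment (`r3`, simulated at 20% amplitude) shows a clearly
reduced displacement maximum.

## Command line

A thin CLI over the package functions ships in `inst/cli/echoflow.R`
(subcommands `generate`, `segment`, `flow`, `features`, `detect`,
`evaluate`, `run-all`). Echo loops are read as numbered PNG frame
directories or multi-frame TIFF.
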