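# ticcad

Semi-automatic, quantitative analysis of time–intensity curves (TICs) from
breast dynamic contrast-enhanced MRI (DCE-MRI).

In clinical practice a radiologist draws a region of interest (ROI) over a
suspicious breast mass, looks at the mean enhancement curve, and subjectively
calls it *persistent* (type I), *plateau* (type II) or *washout* (type III)
— shapes increasingly suggestive of malignancy. That workflow is slow,
operator-dependent, and notoriously unspecific. `ticcad` implements the
computer-aided alternative: the lesion is extracted semi-automatically inside
the user's ROI, the curve type is assigned by a numeric rule instead of the
naked eye, and a panel of semi-quantitative kinetic parameters is computed
both for the mean curve and pixel-by-pixel. It is aimed at imaging
researchers who want a reproducible, scriptable reference implementation of
this CAD pipeline, together with a digital phantom generator for validating
it end to end.

## What it computes

**Segmentation** (inside a user ROI, on the subtraction image
`S(post) − S(pre)`, third post-contrast phase by default):
Otsu thresholding of the ROI intensities → binary erosion with a 4×4
structuring element → largest eight-connected component → dilation with the
same element → intersection with the ROI.

**Kinetics**, from a curve `SI_0, SI_1, …, SI_{T−1}` (`SI_0` pre-contrast,
80 s phase spacing):

| parameter | definition |
|---|---|
| `SI_slope` | `100 · (SI_tail − SI_mean) / SI_mean`, with `SI_mean = (SI_1 + SI_2)/2` and `SI_tail = SI_{T−1}` |
| `MSI` | `max_i (SI_{i+1} − SI_i)`, maximum slope of increase (pre→post step included) |
| `E_initial` | `100 · (SI_1 − SI_0) / SI_0` |
| `E_peak` | `100 · (SI_peak − SI_0) / SI_0`, peak over post-contrast phases |
| `ESER` | `100 · (SI_1 − SI_0) / (SI_2 − SI_0)` |
| `SEP` | `100 · (SI_2 − SI_0) / SI_0` |

The curve type is assigned from `SI_slope`: type I when ≥ +10 %, type III
when ≤ −10 %, type II strictly in between (an alternative upper bound, e.g.
+9.7 %, can be supplied). Types II/III are called malignant in the
rule-based classifier.

**Evaluation**: ROC analysis per parameter (AUC as Mann–Whitney concordance,
DeLong SE, 95 % CI), an automatically oriented Youden-optimal cutoff with
sensitivity/specificity/accuracy, confusion metrics for the rule-based call,
and cohort composition summaries.

**Phantom**: a seeded generator of single-slice dynamic series (1 pre- +
8 post-contrast phases, 80 s apart) containing an elliptical mass-like
lesion whose sampled curve hits a prescribed `SI_slope` exactly, on a mildly
enhancing background, with Gaussian or Rician noise — so every stage of the
pipeline can be tested against known truth.

## Worked example

```r
library(ticcad)

# a synthetic washout (type III) case with 5% noise
case <- simulate_case(phantom_spec(sigma = 0.05),
                      lesion_kinetic_spec("III", late_slope_target = -30),
                      seed = 7, label = "malignant", case_id = "demo")

res <- analyze_case(case$series, case$roi)
res$params
#> # A tibble: 2 × 8
#>   pathway     si_slope   msi e_initial e_peak  eser   sep tic_type
#>   <chr>          <dbl> <dbl>     <dbl>  <dbl> <dbl> <dbl> <chr>
#> 1 mean_curve     -30.2  228.      45.4   89.5  50.7  89.5 III
#> 2 region_mean    -30.1  249.      45.8   90.1  50.7  90.0 III

dice_coefficient(res$lesion, case$truth_mask)
#> [1] 0.996
```

The generating washout slope was −30 %; the mean-curve estimate recovered
−30.2 % through segmentation and noise, the pixel-averaged pathway −30.1 %,
and both classify the curve as type III. The segmented lesion overlaps the
true ellipse with Dice 0.996.

A full simulated cohort study — 30 benign + 30 malignant cases, archetype
mixes favouring persistent curves in benign lesions and washout in
carcinomas — runs in seconds:

```r
pipe <- run_pipeline(n_benign = 30, n_malignant = 30, seed = 7, sigma = 0.05)
pipe
#> <pipeline_result> 60 cases analyzed, 0 failed
#>   mean segmentation Dice: 0.987
#>   rule-based call: sens 90.00%, spec 70.00%, acc 80.00%
#>   best ROC: si_slope (mean_curve) AUC 0.870

mc <- subset(pipe$cohort, pathway == "mean_curve")
glance(optimal_cutoff(mc$si_slope, mc$truth_label))
#> # A tibble: 1 × 11
#>     auc     se ci_lo ci_hi direction cutoff sensitivity specificity accuracy
#>   <dbl>  <dbl> <dbl> <dbl> <chr>      <dbl>       <dbl>       <dbl>    <dbl>
#> 1  0.87 0.0471 0.778 0.962 le         -1.92          90          80       85
```

`direction = "le"` means lower slopes indicate malignancy: a case is called
malignant when its mean-curve `SI_slope` ≤ −1.92 %, giving 90 % sensitivity
and 80 % specificity on this cohort. `tidy()` on the same object returns the
full operating-point table and `autoplot()` draws the ROC curve.

A thin command-line wrapper over the same functions ships in
`inst/cli/ticcad.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ticcad.R", package = "ticcad"))')" \
    run --n-benign 30 --n-malignant 30 --seed 42 --out ticcad_run
```

with subcommands `simulate`, `segment`, `quantify`, `evaluate` and `run`.

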