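---
title: "Methods: semi-automatic TIC analysis for breast DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic TIC analysis for breast DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticcad)
```

## The problem and the data model

Dynamic contrast-enhanced MRI of the breast acquires a T1-weighted image
once before and repeatedly after injection of a gadolinium contrast agent.
As contrast perfuses a lesion, the signal intensity of its pixels traces a
time–intensity curve (TIC) whose late shape carries diagnostic information:
persistent enhancement (type I) is more common in benign masses, a plateau
(type II) is indeterminate, and washout (type III) suggests malignancy.

`ticcad` operates on a single 2-D slice over time: a `dce_series` holds a
`T × H × W` array with `T ≥ 4` (one pre-contrast frame plus at least three
post-contrast phases) and strictly increasing acquisition times starting at
0 s. The default protocol emulated throughout is 1 + 8 phases at 80 s
spacing. Coordinates are 0-based `(row, col)` with pixel centers at integer
coordinates; volumetric inputs must be reduced to a slice explicitly (the
reader takes a `slice` index), because slice selection — clinically, the
slice showing the largest lesion cross-section — is a judgement the software
does not make.

## Semi-automatic segmentation

The lesion is extracted inside a user-drawn ROI polygon in five steps:

1. **Subtraction image.** The pre-contrast frame is subtracted from a chosen
   post-contrast phase (default: the third, `post_phase_index = 3`, a common
   choice for visualising lesion margins). The difference is signed; nothing
   is clamped.
2. **Otsu thresholding of the ROI pixels only.** The subtraction values
   inside the ROI are histogrammed into 256 equal-width bins over their
   observed range, and the internal bin edge maximizing the between-class
   variance `w0·w1·(μ0 − μ1)²` of the split `{≤ t}` vs `{> t}` is chosen
   (class moments from the raw values, which a bin-edge split partitions
   exactly; ties go to the smallest edge). Foreground is the *above*-threshold
   class: lesions enhance.
3. **Erosion** with a 4 × 4 all-ones structuring element.
4. **Largest eight-connected component** of the eroded foreground.
5. **Dilation** with the same element, then intersection with the ROI.

### Morphology conventions

A 4 × 4 element has no central pixel, so a convention is required. The
origin is fixed at grid position (1, 1) (0-based), giving offsets
`{−1, 0, 1, 2}` per axis. Erosion keeps a pixel iff every offset lands
in-bounds on a foreground pixel (outside the image counts as background, so
structures touching the border erode); dilation is the Minkowski sum with
the *same* offsets, clipped to the image. With this pairing
`dilate(erode(X))` is the algebraic opening of `X` — a subset of `X` and
idempotent — which is what the erode/label/dilate sequence is for: speckle
and thin bridges are removed, the selected component regains its original
extent. The test suite verifies both operators against brute-force set
definitions and checks the opening contract on random masks.

Two places where reasonable implementations could differ are fixed as
follows: equal-sized largest components are broken in favour of the one
containing the lexicographically smallest (row, col) pixel (deterministic
and independent of labelling order), and the final mask is re-intersected
with the ROI because dilation can leak a few pixels past the user's
boundary; the lesion is by definition inside the ROI.

Failure modes are explicit errors, not empty results: a constant-intensity
ROI cannot be thresholded (degenerate input), and a foreground smaller than
the structuring element erodes to nothing (the error suggests enlarging the
ROI or reducing the element).

## Kinetic parameters

With `SI_0` the pre-contrast intensity, `SI_mean = (SI_1 + SI_2)/2` the mean
of the first two post-contrast phases, `SI_tail` the last phase and
`SI_peak` the post-contrast maximum:

* `SI_slope = 100·(SI_tail − SI_mean)/SI_mean` — the late slope that defines
  the curve type. Type I iff `SI_slope ≥ +10`, type III iff `≤ −10`, type II
  strictly in between; both boundaries belong to the named types. The upper
  bound can be overridden (e.g. +9.7039) while keeping the lower at −10,
  since a slightly lower threshold has been proposed as more discriminative.
* `MSI = max(SI_{i+1} − SI_i)` over all consecutive phases *including* the
  pre-to-first-post step; it is not clamped at zero, so a monotonically
  decreasing curve yields a negative MSI. MSI is the only parameter carrying
  signal units; the five ratios are invariant under positive rescaling of
  the intensities (a property-tested invariant).
* `E_initial`, `E_peak`, `SEP` — first-phase, peak and second-phase
  enhancement as percentages of baseline; the peak is searched over
  post-contrast phases only (the baseline is a reference, not a candidate),
  first occurrence on ties.
* `ESER = 100·(SI_1 − SI_0)/(SI_2 − SI_0)` — the early enhancement ratio,
  reported ×100.

Guards return NaN rather than error: `SI_0 ≤ 0` undefines the three
baseline-relative percentages, `SI_2 = SI_0` undefines ESER, `SI_mean = 0`
undefines the slope. Such pixels cannot arise inside a properly segmented
enhancing lesion, but parametric maps are computed for arbitrary masks, so
the guards matter. Values are never rounded internally; rounding to two
decimals happens only in reports.

### Two pathways

Parameters are computed twice, deliberately: once on the **mean curve**
(average the lesion TICs, then apply the equations) and once **pixelwise**
(apply the equations per pixel, then average the defined pixels per
parameter independently, NaN excluded). The two coincide exactly on
homogeneous lesions and differ otherwise because the parameters are
nonlinear in the curve; both are clinically reported, so both are exposed,
tagged `mean_curve` and `region_mean` in every table. The region-level curve
type is classified from the mean pixel slope.

## Evaluation

ROC analysis treats each kinetic parameter as a malignancy score. The AUC is
the Mann–Whitney concordance probability (ties counted half); its standard
error uses the DeLong structural-components estimator and the 95 % CI is
`AUC ± 1.96·SE` clipped to [0, 1] (the normal-approximation interval;
MedCalc-style exact binomial intervals would differ slightly in small
samples — a known, documented choice). Computation is delegated to `pROC`;
the test suite cross-checks it against an exhaustive pair-counting oracle.

The optimal criterion maximizes Youden's J = sensitivity + specificity − 100
over all distinct observed scores, after orienting the score so the AUC is
at least 0.5: direction `gt` calls `score > c` malignant, direction `le`
calls `score ≤ c` malignant. J ties are broken by higher sensitivity, then
by smaller `|c|` — a fixed, documented chain so results are reproducible
across machines. Cases with undefined scores are dropped pairwise per
parameter with a message.

The rule-based classifier maps curve types to calls (II/III → malignant,
I → benign) and is scored with ordinary confusion-matrix percentages,
reported unrounded.

## The digital phantom

The generator exists to validate the pipeline against known truth, emulating
the acquisition protocol above.

**Kinetics.** Lesion curves are piecewise linear: baseline `s0` at `t = 0`,
linear wash-in to `s0·(1 + wash_in_fraction)` at `t_peak` (default 160 s,
the second post-contrast phase), then a linear late segment whose endpoint
is solved so that `SI_slope` of the *sampled* curve equals the prescribed
target exactly. Linear segments keep every parameter analytically invertible
— the calibration is a one-unknown linear solve even when `t_peak` falls
between sample points — so noise-free cases admit closed-form expected
values and every archetype re-classifies to itself by construction.
Pharmacokinetic models (Tofts-type) would add realism but no testability;
the classification logic only constrains the curve at the sample times.

**Geometry and noise.** The lesion is a random ellipse (semi-axes 3–12 px,
uniform orientation) fitting a 64 × 64 image with a ≥ 4 px margin; the
supplied ROI is the truth ellipse padded by 4 px. Background pixels enhance
slowly and linearly (20 % of their baseline, set to `0.8·s0`, by the last
phase). Lesion pixels get a per-pixel multiplicative jitter of ±5 % —
constant over time, so it perturbs MSI but, by scale invariance, none of the
ratio parameters of an individual pixel. Noise is Gaussian (default,
`σ = 0.05·s0`) or Rician (magnitude-MRI realism) per pixel and phase. All
randomness flows from one seed; cohorts draw per-case seeds once from the
master stream, so runs are bit-identical for a fixed seed.

**Cohorts.** Archetypes are drawn per class: benign I/II/III with
probabilities 0.75/0.20/0.05, malignant 0.15/0.35/0.50 — proportions chosen
so that the rule-based classifier's expected sensitivity and specificity
(85 %/75 %) sit near values reported for this kind of CAD on clinical
material. Within an archetype, slope targets are drawn uniformly from
class-conditional ranges (benign: I 15–40, II −5–9, III −25 to −12;
malignant: I 10–22, II −9–0, III −50 to −15), reflecting that carcinomas
tend to wash out faster than benign lesions within the same curve type.
Baselines vary per case (400–800 scanner units), wash-in fractions 0.6–1.2.

**What the phantom does not emulate** — and hence what passing tests do not
demonstrate about clinical data: partial-volume effects at lesion margins,
non-mass-like and multifocal lesions, motion and registration error, coil
bias fields, heterogeneous internal enhancement beyond static jitter, and
the full variability of a patient population. Phantom recovery shows the
pipeline is correct and stable, not that its clinical operating points
transfer.

## Problem sizes and determinism

The bundled experiments use cohorts of 30 + 30 cases on 64 × 64 images
(seconds of CPU), 20 + 20 noise-free cases for archetype self-consistency,
and 10 + 10 for byte-level determinism checks of the CSV outputs; oracle
equivalence suites run on hundreds of random 32 × 32 masks and
thousand-curve sweeps. At these sizes sampling noise on cohort-level
metrics (AUC, rule-based accuracy) is non-trivial — standard errors of a few
points — which is why the package reports them with uncertainty and why
validation emphasizes exact oracle equivalence and noise-free
self-consistency over hitting any particular cohort-level number.

## Known limitations

* Single-slice analysis only; no 3-D segmentation or slice selection.
* No image registration: phases are assumed co-registered.
* The optimal-cutoff objective is fixed to Youden's J; cost-weighted
  criteria are out of scope.
* The rule-based classifier uses the mean-curve type only, as in clinical
  reading; combining parameters into a joint model is deliberately not
  implemented.
* Parametric maps are returned as numeric matrices; colour rendering is
  left to `autoplot`/`plot_param_map` defaults.
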