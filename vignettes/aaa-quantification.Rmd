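---
title: "Quantifying abdominal aortic aneurysms from per-slice area signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying abdominal aortic aneurysms from per-slice area signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The signal abstraction

A contrast CT angiogram of the abdomen is an ordered stack of axial slices.
When a segmentation model traces the aortic lumen through that stack, the
number of segmented pixels in each slice is a unit-less proxy for the
aortic cross-sectional area at that level. `aaaquant` works entirely on
this **area signal**: an integer vector indexed from slice 0 (most cranial,
thoracic aorta) to slice `n - 1` (iliac bifurcation). A fusiform aneurysm
appears as a sustained bulge in the signal; a segmentation model that was
never trained on aneurysmal anatomy instead produces a sustained *gap*
(near-zero counts) over the diseased segment. Both signatures are
detectable with one-dimensional reasoning, which is what makes the signal
abstraction attractive: no pixel-level annotation is ever needed
downstream.

The package assumes the upstream stage has already (a) normalized the
grayscale images — `contrast_stretch()` implements the standard linear
stretch of the observed intensity range onto [10, 245] with half-up
rounding, mapping constant images to the lower bound — and (b) produced
binary masks or the count sequence itself. Masks are read from multi-page
TIFF or per-slice TIFF/PNG directories (lexicographic order), binarizing
any non-zero pixel; signals are stored as two-column CSV tables
(`slice_index,pixel_count`, consecutive from 0) that round-trip exactly.

## The synthetic cohort generator

Because clinical CTA datasets with slice-level aneurysm annotations are not
freely available, the package ships a generator whose output has the
statistical structure the detectors assume, with known ground truth. Each
patient is built as:

1. **Normal profile.** A baseline count `B` drawn uniformly from
   `base_count_range` (default 300–600 pixels, matching a 2–3 cm lumen at
   typical CTA pixel spacings) decreasing linearly by `taper_fraction`
   (default 0.15) from the thoracic end to the bifurcation — the normal
   aorta narrows distally.
2. **Bulge.** With probability `aneurysm_prob`, an interval of
   `aneurysm_len_range` slices (default 20–60, i.e. a few centimetres at
   0.5–3 mm spacing) is multiplied by an envelope rising from 1 at the
   start slice to `peak_ratio` (default 1.5–3.5, the area ratio implied by
   diameters from just-aneurysmal to severe) and returning to 1 at the end
   slice. Three shapes are provided: `plateau` (5-slice raised-cosine ramps
   into a flat top), `gaussian` (a scaled Gaussian bump renormalized to
   touch 1 at the interval ends), and `asymmetric` (5-slice ramp up,
   10-slice ramp down). The ramp lengths are chosen so that in the easy
   regime the onset rises by more than 20% within about 4 slices, which is
   the regime where a 4-slice window rule is meaningful.
3. **Noise.** Multiplicative lognormal noise with coefficient of variation
   `noise_cv` (default 0.03 — segmentation jitter of a few percent per
   slice), mean-corrected so the expected profile is unchanged, then
   rounded to non-negative integers.
4. **Dropout mode.** Optionally, all counts inside the aneurysm interval
   are replaced by 0, emulating the segmentation-failure signature of a
   model trained only on normal anatomy.

Per-patient seeds are derived from the cohort seed by a counter-based
mixing function, so patient `i` is reproducible independently of cohort
size, and the whole cohort is a pure function of its `cohort_spec()`.
`rasterize_patient()` converts a patient into a 3D mask stack of centered
discs whose rasterized pixel counts equal the signal exactly (pixels are
ranked by distance from a slightly offset center and exactly `count` are
filled), closing the loop mask → signal → mask for integration tests.

What the generator does **not** emulate: anatomical curvature and
branching, intensity textures, thrombus and wall (the signals represent
lumen only), multi-focal aneurysms, and tracker failure modes other than
complete dropout. Tests passing on synthetic cohorts therefore demonstrate
algorithmic correctness under the stated model, not clinical performance.

## Screening rule

`screen_signal()` scans cranial to caudal, comparing each count against a
**rolling baseline**: the mean of the last `window` (default 4) slices that
were themselves not flagged. A slice is flagged when it falls below
`low_frac` (default 0.50) or rises above `high_frac` (default 1.40) of the
baseline; an anomaly is declared after `persistence` (default 4)
consecutive flags, ends at the last flagged slice before `persistence`
consecutive clean slices, and the longest anomaly (ties: earliest) is
reported.

Two design points deserve note. First, flagged slices are excluded from the
baseline — equivalently the baseline freezes at its pre-anomaly value until
recovery. A naive rolling mean over all slices would be dragged to zero by
a dropout region within one window and immediately un-flag it; freezing
makes "first flagged slice = start, last flagged slice = end" well defined.
Second, against a zero baseline (e.g. before the tracker locks on) any
positive count is treated as anomalous; this degenerate case is defined
rather than an error. The first `window` slices are never flagged, as no
baseline exists yet. Because both thresholds are relative, the flag pattern
is invariant under rescaling all counts by a positive constant.

## Expert boundary rule

`detect_expert()` looks for a sustained **rise** and a later sustained
**drop**. A candidate start `i` requires all of slices `i .. i+window-1` to
exceed `start_frac` (default 1.20) times the mean of the `window` slices
preceding `i`; a candidate end `j` requires all of `j .. j+window-1` to
fall below `end_frac` (default 0.80) times its preceding-window mean. The
preceding mean is **anchored** at the candidate slice while the whole
window is tested against it: a per-slice rolling mean would absorb a
genuine rise within two or three slices and could never stay 20% above
itself for four consecutive slices, so the anchored reading is the one
under which the rule can fire at all.

Among all pairs with `j > i`, the pair maximizing `j - i` — the largest
abnormality window — is selected (ties toward the earliest start) and the
inclusive interval `[i, j-1]` is returned, so the reported aneurysm covers
the enlarged slices and stops just before the sustained drop. Because
consecutive slices near a step change can each satisfy the window
condition, candidates come in small clusters; maximizing `j - i` picks the
outermost pair, which on ramped bulges lands within a window-plus-ramp of
the true boundaries. The implementation is verified against an exhaustive
oracle that enumerates every `(i, j)` pair directly.

`grid_search_expert()` evaluates every combination of
`window ∈ {3,4,5,6}`, `start_frac ∈ {1.10..1.40}` and
`end_frac ∈ {0.60..0.90}` by mean interval Dice over an annotated cohort
(absent detections score 0), breaking ties toward the smaller window and
the canonical 1.20/0.80 thresholds.

## The bidirectional LSTM labeler

The trainable detector casts boundary finding as per-position binary
sequence labeling. Scans differ in slice count, so signals are linearly
resampled to `out_len = 200` positions (position `p` samples the block
center `(p + 0.5)·n/200 - 0.5`) and normalized by the per-sequence maximum
— the same scale invariance the expert rule has. Targets label a position 1
when its block center falls inside the truth interval; predicted runs map
back through the block edges, so encode/decode round-trips within
`ceil(n/200)` slices.

The network is two stacked bidirectional LSTM layers (default 600 hidden
units per direction; their concatenated 1200-dim states feed the next
layer) followed by a fully connected ReLU head (default widths 256, 64)
applied **per position**, ending in a single sigmoid logit. A per-position
shared head keeps the 200 outputs aligned one-to-one with resampled
positions; the alternative — flattening the whole sequence into one dense
map to 200 outputs — would tie every weight to absolute position and need
far more data. The loss is binary cross-entropy plus `jaccard_weight`
(default 1) times `1 - softJaccard`, with
`softJaccard = Σ(p·t) / Σ(p + t - p·t)` per sequence (defined as 1 when
both sums vanish); the Jaccard term directly rewards interval overlap,
which BCE alone underweights for short intervals. Optimization is Adam
(learning rate 0.0003, batch size 10) with early stopping on a patient-level
validation split (default 20%), returning the best-validation weights. The
fixed classification threshold is 0.5, and the longest positive run (ties:
earliest) becomes the predicted interval.

The implementation is batched backpropagation through time written with
RcppArmadillo; its gradients are checked against central differences to
~1e-11 in the test suite, and all randomness (initialization, split,
shuffling) derives from the configuration seed, making training runs
byte-reproducible.

`crossvalidate_lstm()` partitions patients into `k = 5` folds from the
seed, trains on `k-1` folds and reports per-fold and pooled interval Dice,
start/end R²/MAE/MSE and truth-vs-predicted volume R², with no patient in
two folds.

**Scaled profile.** The default 600-unit architecture is sized for GPU
training on clinical data. For the package's own cross-validation protocol
we use 64 hidden units, a 30-epoch budget with patience 8, and 200
synthetic patients; on the easy synthetic regime (plateau bulges, peak
ratio ≥ 2, 3% noise) this converges in a few minutes on one CPU core and
reaches pooled Dice well above the 0.6 bar the protocol requires, so the
reduced width loses nothing detectable at this problem size. The
`test-acceptance` suite and `scripts/acceptance.R` both run exactly this
profile.

## Volumetrics

With boundaries `s` and `e`, the surrogate volume is the plain sum of
counts over `[s, e]` — proportional to physical volume but deliberately
uncalibrated, since slice thickness and pixel spacing metadata are outside
the signal abstraction. The normal baseline joins the *measured* counts at
`s` and `e` linearly (no smoothing of the endpoints), and its volume is the
arithmetic-series sum `(P_s + P_e)/2 · (e - s + 1)` exactly. Enlargement is
reported as `100·(observed - baseline)/observed`: with typical
aneurysm-to-baseline volume ratios of 1.5–2, this convention yields
enlargements in the 30–60% range that clinicians recognize, whereas
normalizing by the baseline would double the scale. The degenerate cases
are defined explicitly: zero baseline gives 100%, equal volumes give 0%,
and zero observed volume is an error rather than a silent 0. Cohort
statistics use the sample (n−1) standard deviation, reported as 0 with an
`n = 1` flag for a single patient.

## Evaluation conventions

Interval Dice is computed on the inclusive slice-index sets of the 1D
intervals (`2TP/(2TP + FP + FN)`), which is the axial-overlap quantity the
boundary task needs; a 2D `mask_dice()` is provided for mask-level
comparisons but not used in boundary reports. Absent predictions score 0 in
Dice, are excluded from start/end and volume regressions, and are counted
in an explicit `n_absent` column. `r2()` refuses constant truth vectors
(TSS = 0) rather than returning a sentinel; confusion-matrix metrics with a
zero denominator are `NA`, never 0. Binary cross-entropy clips predictions
to `[1e-7, 1 - 1e-7]`.

## Problem sizes and determinism

The shipped protocol uses cohorts of 40 (screening mix), 50 (noise-free
expert evaluation), 200 (LSTM cross-validation) and 60 (enlargement
statistics) patients — sizes at which every Monte-Carlo bound in the test
suite has comfortable margin while the whole suite stays convenient to run
interactively. Every stochastic stage (generation, training, fold
assignment) is a pure function of the supplied seeds: reruns produce
byte-identical signal files and identical logged metrics, which the suite
asserts literally.

## Limitations

The detectors assume a single contiguous aneurysm per scan; multi-focal
disease would be reported as the largest lesion only. Boundaries are whole
slices — no sub-slice interpolation. Surrogate volumes are unit-less; they
support within-pipeline comparison and correlation analysis, not absolute
volumetry in mm³. The screening rule's behavior on signals whose baseline
is still rising (e.g. tracking that starts inside the aortic arch) depends
on the first `window` slices being representative. And all performance
figures computed by the package's own protocol characterize the synthetic
generative model above; transferring them to clinical data requires signals
from a real tracker and expert annotations.
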