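---
title: "Context-adaptive mammogram preprocessing: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-adaptive mammogram preprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MammoPrep)
```

# The problem

Screening mammograms carry two kinds of nuisance structure that harm
downstream segmentation and classification: impulse-like noise
(salt-and-pepper, quantum/photon, speckle, Gaussian sensor noise) and
bright non-anatomical artifacts — view labels, lead markers, opacity tags,
machine-induced spots. A fixed-size median filter either under-smooths the
artifacts or destroys fine tissue detail. MammoPrep's preprocessing stack
addresses both with a filter whose window size adapts to artifact geometry,
followed by global intensity standardization and a contrast enhancement
driven by spatial structure rather than the bare histogram.

This vignette is the package's own account of the three stages, the phantom
generator and evaluation layer around them, the tunable parameters, and the
design decisions taken where the procedure was genuinely open.

# Stage 1: the context/distance-adaptive median filter (CEAMF)

## Model

Let the image be `y` with shape `Z × M`, pixel coordinates `(j, i)`
(0-based rows/columns), and `R` gray levels. Bright artifacts ("light
spots") are detected by thresholding at `mean + kσ` of the intensities
(`kSigma = 2.5` by default) and taking 8-connected components of at least
`minArea = 16` pixels. Each spot `k` records its bounding-box height
`he_k`, width `wi_k`, centroid, and effective radius
`a_k = min(he_k, wi_k)/2`.

Every pixel is replaced by the median of an odd square window whose side
`U(j, i)` depends on the Euclidean distance `s` to the nearest spot center:

* inside the spot's influence (`s < a`): `U = 2(e^{a/s} − 1) + 3`, which
  diverges toward the center; `s = 0` maps directly to the cap (the limit
  of the expression);
* outside: `U = 2 log₁₀(s/a) + 3`, a slow growth that reaches 5 only at
  ten radii;
* the raw value is capped at `S_dis`, floored to the largest odd integer,
  and clamped to `[uMin, S_dis]`.

The cap is derived from the artifacts themselves:
`S_dis = ⌊min_k min(he_k, wi_k)/4⌋` floored to odd and never below 3, so
the window never outgrows a quarter of the smallest artifact dimension —
large enough to erase it, small enough to bound cost and collateral
smoothing. With no artifacts at all, a configurable default cap (9) applies
and every pixel sees the minimal window.

## Numerical choices

* **Windows are clipped at image borders** and the median is taken over the
  clipped set. No padding value is invented; every output value is attained
  in the input window.
* **Even-count medians take the lower median**, so the output is always an
  attained pixel value and the filter never creates new intensities.
* **The distance is plain Euclidean to the spot center** and the spot's
  scale enters through the single radius `a = min(he, wi)/2`. A printed
  form that mixes squared distances with a width-scaled second term is
  dimensionally inconsistent; the radius reading preserves the intended
  inside/outside branch semantics (`s < a` ⇔ inside the artifact).
* **The inside/outside test uses the radius, not the bounding box**, so it
  agrees exactly with the branch condition of the window law.
* The filter core is C++ (`std::nth_element` per pixel); the window map is
  computed vectorized in R.

Consequences tested as properties: `3 ≤ U ≤ S_dis` and odd everywhere;
range non-expansiveness; idempotence on constants; exact agreement with a
brute-force per-pixel median oracle on images up to 64×64; strict MAE
reduction on salt-and-pepper-corrupted phantoms for every seed tried.

# Stage 2: Z-score normalization and re-quantization

`y_Zs = (y − μ)/σ` with the **population** standard deviation (divisor N) —
the arithmetic is fixed by the definition of the image mean and SD over all
N pixels. A constant image has σ = 0; the output is defined as all zeros
and flagged `degenerate` rather than raising, because a pipeline must
survive a blank frame.

The contrast stage operates on integer gray levels, so the real-valued
z-scores are re-quantized by a min–max affine map onto `[0, R−1]` with
half-up rounding (`requantize()`); a constant input maps to level 0. The
re-quantization step is this package's own addition: z-scores standardize
*across* images while the level-domain enhancement needs integers, and
min–max is the canonical bridge. Since min–max is invariant to positive
affine transforms, the composition `requantize(zscore(x))` equals
`requantize(x)` pixel-for-pixel — the z-score's value lies in the recorded,
standardized real-valued intermediate that models consume, not in changing
the enhancement input.

# Stage 3: energy-curve contrast enhancement

## The energy curve

For each level `l`, threshold the image into `B_l` with `b_p = +1` if
`pix_p > l`, else −1. The energy is

    E(l) = − Σ_p Σ_{q ∈ N_p^d} w_pq · b_p b_q  +  Σ_p Σ_{q ∈ N_p^d} w_pq

over ordered neighbor pairs within Chebyshev distance `d` (border-clipped),
with pair weight `w_pq = (1/chebyshev(p, q))^f`. Equivalently each
*disagreeing* pair contributes `2 w_pq`, so `E ≥ 0`, `E(l) = 0` iff `B_l`
is constant, and `E(R−1) = 0` always. Unlike the histogram, `E` weights a
level by how much *spatial* transition structure it cuts through, which is
what makes the enhancement context-aware.

The implementation sweeps each neighbor offset once and accumulates each
pair's contribution over `[min(v_p, v_q), max(v_p, v_q))` with a difference
array — exact, and `O(pixels · offsets + R)` instead of a per-level sweep.

Parameters: `d` (neighborhood radius, default 1 = the 8 immediate
neighbors) and `f ∈ [1, 3]` (default 1). `f` is exposed as the exponent of
the inverse-distance pair weight; at `d = 1` all Chebyshev distances are 1,
so `f` has no effect and the classic curve is recovered. This is a design
decision: the coefficient is named but given no operational role in its
source, and an inverse-distance weight is the only reading under which a
"range 1–3" exponent meaningfully tempers longer-range pairs at `d > 1`.

## Clipping, banding, transfer function

* **Clip threshold** `C = mean(E) + median(E)`, applied literally;
  clipping bounds the slope any level can receive. An all-zero curve
  (constant image) short-circuits the whole stage unchanged, flagged.
* **Band boundaries**: with `m = Σ l·E_cl(l) / Σ E_cl(l)` and
  `StD = sqrt(Σ (l − m)² E_cl(l) / Σ E_cl(l))`, the axis splits at
  `lo_low = round(l_min + StD)` and `lo_high = round(l_max − StD)`
  (`l_min`, `l_max` = extreme levels present in the image). The upper
  boundary uses `l_max − StD` by symmetry; the alternative printed form
  `l_max + StD` would leave the intensity range outright. `StD` is read as
  an energy-weighted *spread over levels* — the only reading under which it
  can place boundaries on the level axis.
* **Fallback**: if the boundaries cross or leave `(0, R−1)` — e.g. a
  symmetric two-spike curve where `round(l_min + StD) = round(l_max − StD)`
  — the boundaries fall back to energy-mass terciles of the clipped curve
  (smallest levels at which cumulative energy crosses 1/3 and 2/3). The
  degenerate all-zero case uses terciles of a uniform pseudo-curve.
* **Per-band pdf/cdf** use the *clipped* curve (the clipping would be
  pointless otherwise); a zero-mass band gets a uniform pdf, flagged.
* **Transfer function**: band `[a, b]` maps onto itself by
  `TrF(l) = a + round((b − a)·cdf(l))`. The three maps have disjoint
  supports; their union (equivalently, the sum of zero-padded pieces) is
  the full `TrF`, clamped to `[0, R−1]`. Printed interval widths that can
  push outputs past `R−1` were replaced by these range-preserving maps.
  Rounding is half-up throughout for determinism across platforms.

`TrF` is non-decreasing within each band (cdfs are monotone), so ranks are
preserved within bands; outputs never leave `[0, R−1]`; the whole stage is
deterministic.

# The phantom generator

Real mammograms cannot ship with a package; the generator emulates the
features the three stages respond to, fully seeded:

* **background**: Gaussian noise low-pass filtered at
  `backgroundSmoothness` (default σ = 8 px, capped so the blur brush fits
  the image), rescaled to the mid-intensity range — smooth, textured,
  breast-like;
* **lesion**: an ellipse with an intensity boost (default +60 levels) whose
  pixels are the ground-truth mask; benign phantoms carry no lesion so
  classification tests have unambiguous truth;
* **artifacts**: bright rectangles (default 2 spots, 16–32 px, level 245)
  standing in for labels and markers;
* **noise**: one of five models — Gaussian (σ as a fraction of R), speckle
  (multiplicative), salt-and-pepper (rate split 50/50), quantum (Poisson at
  a photon scale; the standard radiographic reading of "quantum noise"),
  impulse (uniform random replacements);
* **perturbation scenarios** for robustness studies: Gaussian σ = 0.05 R /
  0.10 R, −15% contrast (deviations from the mean scaled by 0.85),
  resolution degradation (2×2 block mean, nearest-neighbor upsampling);
* **cohorts**: exactly `round(n · 0.60)` benign cases by default — the
  60/40 benign/malignant mix of the screening benchmarks this emulates —
  with CC/MLO views per case sharing the label and seed lineage.

What the phantom does *not* model: anatomy (pectoral muscle, skin line,
fibroglandular texture), BI-RADS density classes, scanner-specific bias
fields, lesion spiculation. Passing tests therefore demonstrate the
*algorithmic contracts* — window laws, metric identities, split exactness,
determinism, noise-removal efficacy on controlled corruption — not clinical
performance on real mammograms.

# Splitting and evaluation

* **Patient-level split**: the unit is the case id; within each label
  stratum, ids are shuffled by seed and apportioned 75/12/13 by largest
  remainder, so counts are exact to ±1 per stratum (at n = 1000 unstrat.:
  750/120/130 exactly; stratified 600/400: 450+300 in training). Strata
  under 3 cases are refused with advice rather than silently unstratified.
* **Leakage audit**: three mutually exclusive violation types — (b) views
  of one breast split apart, (c) lateralities of one case split apart,
  (a) residual same-case multi-split. The hierarchy makes one planted
  CC-train/MLO-test defect exactly one type-b finding.
* **Metrics**: prose-standard confusion forms (accuracy, sensitivity,
  specificity, precision, F1); zero denominators give `NA` plus an
  `undefined` attribute, never a silent 0. Dice and IoU on masks, with the
  both-empty pair defined as 1 (perfect agreement on absence, flagged) so
  lesion-free cases remain scoreable.
* **Aggregation**: unweighted mean over a case's views — one vote per case
  regardless of how many views were acquired.
* **Uncertainty**: percentile bootstrap over cases (default 1000 resamples,
  95%, linear-interpolation quantiles; BCa was not chosen because the
  protocol being mirrored specifies plain non-parametric bootstrapping) and
  a classic paired t-test (`t.test(..., paired = TRUE)` underneath);
  identical series return t = 0, p = 1, constant nonzero differences are an
  error naming the degeneracy.
* Probabilistic predictions harden at threshold 0.5; `thresholdSweep()`
  provides curve-style operating points without privileging any threshold.

# Pipeline orchestration

`runPipeline()` standardizes each image to a square side (padding with
level 0 — the black mammogram background — before bilinear resampling, so
aspect is preserved; 1024 px default, phantoms typically 256), then runs
the stages in the configured order. The default order is CEAMF →
normalize → enhance; the alternative CEAMF → enhance → normalize is one
config edit away, since both orderings appear in descriptions of this
family of pipelines. Failures are isolated per image and recorded in the
report (the run continues; the CLI exits nonzero if anything failed).
Identical manifest + config + seed gives bit-identical outputs.

Interpolation for the resize is bilinear — a deliberate choice (the
standardization target alone does not pin the kernel down); it is cheap,
monotone, and artifact-free on down- and up-scaling alike.

# Problem sizes used in the checks

The shipped test suite and acceptance script run: 20 phantoms at 256×256
for the window law and the denoising-efficacy check; brute-force median
oracles up to 64×64; 1000 fuzzed small images for the transfer-function
laws; a 1000-case cohort for split exactness plus hundreds of small fuzzed
cohorts for the audit; and a 4–5 case end-to-end determinism run at
128×128. These sizes exercise every code path at full fidelity — the
algorithms have no scale-dependent branches — while keeping the whole suite
in the low minutes on one core.

# Known limitations

* DICOM support is read-only and minimal: single-frame, uncompressed
  little-endian, MONOCHROME2. Compressed transfer syntaxes and sequences
  are rejected with clear errors.
* 16-bit PNG writing uses the package's own zlib-based encoder (the
  installed PNG bindings write 8-bit only); it emits a minimal valid file
  (IHDR/IDAT/IEND) without ancillary chunks.
* Spot detection is global-threshold based; artifacts dimmer than
  `mean + kσ` (e.g. low-contrast opacity) are treated as tissue.
* The energy curve at `R = 65536` is exact but the banding is coarse when
  only a few thousand distinct levels are present; 16-bit inputs are
  usually re-quantized to 256 levels by the normalize stage first.
* The phantom is a test harness, not a simulator; no claim about real-image
  performance follows from it.
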