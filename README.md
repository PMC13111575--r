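# MammoPrep

Screening mammograms reach an analysis pipeline degraded by impulse-like
sensor noise and by bright non-anatomical artifacts — view labels, lead
markers, embedded annotations, machine-induced "light spots". MammoPrep
implements a triple-way preprocessing stack for such images, together with
the evaluation and data-handling layer needed to study it without touching
patient data:

1. **CEAMF** (context/distance-adaptive median filter). Bright artifacts are
   detected as 8-connected components above `mean + k·sd` intensity. Each
   pixel is then median-filtered with an odd window of side `U(j,i)` that
   depends on the Euclidean distance `s` to the nearest artifact center with
   effective radius `a = min(he, wi)/2`:

   - inside the artifact (`s < a`): `U = 2(e^{a/s} − 1) + 3`, the cap at
     `s = 0`;
   - outside: `U = 2·log₁₀(s/a) + 3`;
   - always floored to odd and clamped to `[3, S_dis]` with
     `S_dis = min_k ⌊min(he_k, wi_k)/4⌋` — the window grows toward artifacts
     (erasing them) while ordinary tissue sees a minimal 3×3 median.

2. **Z-score normalization**: `y_Zs = (y − μ)/σ` with the population
   standard deviation, then min–max re-quantization back to `[0, R−1]`.

3. **Energy-curve contrast enhancement.** For each gray level `l` the image
   is thresholded to a ±1 field `B_l` and the spatial energy
   `E(l) = Σ_p Σ_{q∈N_p^d} w_{pq}(1 − b_p b_q)` accumulates neighbor
   disagreement (`w_{pq} = (1/chebyshev(p,q))^f`). The curve is clipped at
   `mean + median`, the level axis is split into three bands at
   `lo_low = round(l_min + StD)` and `lo_high = round(l_max − StD)` (energy-
   weighted spread `StD`), and each band is remapped onto its own output
   interval through its clipped-energy cdf — a spatially aware, rank-
   preserving alternative to histogram equalization.

Around the core sit a seeded **phantom generator** (textured background,
elliptical lesions with ground-truth masks, artifact spots, five noise
models: Gaussian, speckle, salt-and-pepper, quantum/Poisson, impulse),
**patient-level splitting** with largest-remainder exactness and a leakage
**audit**, and an **evaluation layer**: confusion metrics, Dice
`2|P∩G|/(|P|+|G|)`, IoU `|P∩G|/|P∪G|`, per-case aggregation across CC/MLO
views, percentile-bootstrap confidence intervals, paired t-tests.

## Worked example

```r
library(MammoPrep)

cfg <- phantomConfig(side = 256, seed = 42,
                     lesion = list(present = TRUE),
                     noise  = list(kind = "salt_pepper", params = list(rate = 0.05)))
pc <- generatePhantomCase(cfg)
pc$image
#> GrayImage: 256 x 256, R = 256, range [0, 255]

(spots <- detectLightSpots(pc$image))
#>   cen_y cen_x he wi radius_a area
#> 1   223    70 18 19        9  304
#> 2   156    88 20 16        8  295

den <- applyCEAMF(pc$image, spots = spots, report = TRUE)
mean(abs(pixels(pc$image) - pixels(pc$clean)))   # MAE before: 6.32
mean(abs(pixels(den$image) - pixels(pc$clean)))  # MAE after:  0.17

norm <- requantize(zscoreNormalize(den$image))
enh  <- enhanceContrast(norm, report = TRUE)
enh$bands
#> BandPartition: [0,55] | [56,200] | [201,255] (StD = 55.146)

bootstrapCI(c(0.91, 0.88, 0.95, 0.84, 0.90, 0.87), seed = 1)
#> MetricSummary: mean 0.8917, sd 0.0376, median 0.8900, 95% CI [0.8666, 0.9167] (n = 6, B = 1000)
```

The two planted label artifacts are found with their true bounding boxes;
the adaptive filter removes 5% salt-and-pepper corruption almost entirely
(mean absolute error to the clean phantom drops 6.32 → 0.17 levels) while
the window law keeps tissue at the 3×3 floor.

A shell front end covers the same operations:

```sh
mammoprep phantom --n 20 --side 256 --seed 42 --out phantoms
mammoprep split --manifest phantoms/manifest.csv --seed 1
mammoprep audit --manifest phantoms/manifest.csv
mammoprep run --manifest phantoms/manifest.csv --out processed
```

(`mammoprep` is installed under `<library>/MammoPrep/exec/`.)

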