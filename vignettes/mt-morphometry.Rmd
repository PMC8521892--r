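---
title: "Quantifying centrilobular fibrosis and sinusoidal lumens in trichrome-stained liver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centrilobular fibrosis and sinusoidal lumens in trichrome-stained liver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmorph)
```

## The measurement problem

Congestive hepatopathy — chronic liver injury under right-heart failure —
leaves two characteristic footprints in hepatic zone 3: collagen deposition
around the centrilobular vein, and dilatation of the sinusoids. On a
Masson's-trichrome (MT) section, collagen stains blue while hepatocyte
cytoplasm stains red/pink/purple, so both lesions are in principle
measurable from color alone. In practice they are usually graded
semi-quantitatively (the ordinal 0-4 Congestive Hepatic Fibrosis Score,
CHFS), which is insensitive to fine perisinusoidal collagen and blind to
partial changes within a grade.

`mtmorph` implements a semi-automatic morphometric protocol for this
problem. The unit of analysis is a square region of interest (ROI) centred
on a centrilobular vein (conventionally 1364 x 1364 px at 4.55 µm/px). Per
ROI it computes

* **CFR** (centrilobular fibrosis ratio): percent of tissue area covered by
  fibrosis-segmented pixels, and
* **SLR** (sinusoidal lumen ratio): percent of tissue area covered by
  sinusoidal-lumen pixels,

where *tissue area* is the ROI area minus the excluded vein. Per-slide
values are the arithmetic means over the slide's ROIs (conventionally five).

## The segmentation model

Segmentation is a fixed box threshold in hue-saturation-brightness (HSB)
space, each channel an integer 0-255. The conversion is the standard
hexcone model with brightness = channel maximum, saturation =
255·(max−min)/max, and hue mapped from degrees by h·255/360 with half-up
rounding; achromatic pixels get hue 0, so black and white are controlled
purely by the brightness bound. All band bounds are inclusive, and a hue
interval may wrap around the circle.

The two empirically established bands are:

| component           | hue     | saturation | brightness |
|---------------------|---------|------------|------------|
| collagen (fibrosis) | 140-190 | 0-255      | 0-248      |
| sinusoidal lumen    | 0-255   | 0-255      | 0-50       |

Two manual steps precede thresholding, both consumed by this package as
mask inputs rather than re-automated:

1. **Vein exclusion.** The centrilobular vein is outlined upstream; its
   pixels are filled pure white (255,255,255). White has brightness 255,
   which is outside both bands, so the vein can never contribute to either
   component — and it is removed from the denominator.
2. **Lumen annotation.** Sinusoidal lumens are traced upstream and filled
   black. Black fills have brightness 0 ≤ 50, so the lumen band recovers
   exactly the annotation. This step exists because unstained near-white
   space is ambiguous: fat droplets, ballooned hepatocytes and vessels all
   look like lumens.

Before the fibrosis threshold only, the RGB image is smoothed with a 3 x 3
unweighted mean filter (edge pixels use the in-image part of the window) to
suppress staining noise. Smoothing is applied once; applying it before
thresholding is a documented choice — the alternative readings (smoothing
only during threshold tuning, or iterated smoothing) change boundary pixels
only, and the flag `smoothing = FALSE` restores the unsmoothed route.

An **automated lumen candidate detector** is also provided
(`detect_lumen_candidates()`): near-white pixels (brightness ≥ 230,
saturation ≤ 40) minus the vein, with 8-connected components under 4 px
discarded. It is deliberately labelled candidate-quality: it cannot
distinguish lumens from fat droplets, so its area is an upper bound on true
lumen area whenever droplets are present. The annotated route is the
reference method; the detector is a convenience for screening.

## Numerical choices

* **Rounding.** Hue and saturation are rationals with denominator at most
  2·255·6; exact .5 ties must round up. A 1e-9 epsilon inside the rounding
  repairs floating-point representations that land a hair below a tie; it
  is far smaller than the 1/1530 gap to any legitimate non-tie value, so it
  can never move a true value. The test suite checks the conversion against
  an integer-exact oracle (quotient/remainder arithmetic, no floating
  point) on thousands of triples including every gray level.
* **Connectivity.** Particle filtering uses 8-connectivity (corner-adjacent
  pixels connect), matching common particle-analysis defaults; it is
  implemented as a compiled two-pass union-find.
* **Degenerate inputs.** A vein filling the whole ROI makes the CFR/SLR
  denominator zero; this raises an explicit error rather than returning 0.
  Groups with fewer than two observations abort the ANOVA with the
  offending CHFS levels listed.
* **Determinism.** The per-image pipeline uses no random numbers; batch
  processing is lexicographic in file name, and reruns are bit-identical.

## The ratio definitions

The upstream protocol computes "the percentage ... compared to the total
amount of tissue area within a ROI" but prints no formula, so the
denominator is fixed here as a documented decision:
CFR% = 100·fibrosis/(total − vein) and SLR% = 100·lumen/(total − vein).
The explicit vein-exclusion step makes the vein-free denominator the
natural reading; `include_vein = TRUE` is available as a sensitivity
toggle. Ratios are kept at full floating precision internally and rounded
to two decimals only in the CSV output layer.

## What the phantom generator emulates — and what it does not

Every stage is validated on synthetic MT phantoms
(`generate_phantom()`) with exact ground-truth masks:

* a centred white vein disk (default radius ≈ side/12 — at 4.55 µm/px and
  341 px this is a ~130 µm-radius vein, a realistic centrilobular calibre);
* thin near-white channels (brightness 235-255, saturation ≤ 25) radiating
  outward, standing in for dilated sinusoids;
* a pericentral collagen annulus painted with hue uniform in 150-185,
  saturation 80-200, brightness 120-220 — comfortably inside the 140-190
  band — plus, in `perisinusoidal` mode, 1-px collagen sleeves along the
  channels;
* red/pink/purple parenchyma elsewhere (hue 235-255 wrapping to 0-15,
  i.e. well outside the collagen band);
* optional near-white fat-droplet confounders and additive Gaussian RGB
  noise.

Component pixels are placed by exact count, so the realized fractions equal
the requested fractions to within one pixel of rounding — this is what
makes ±1-percentage-point recovery assertions sharp. The collagen annulus
is laid first and the sinusoid channels start 3 px beyond its outer radius,
so that outside the perisinusoidal mode no collagen pixel is within the
3 x 3 smoothing window of a near-white channel; components are
band-separated by construction, and tests isolate pipeline correctness
from stain-modelling realism. In `hard_mode` the collagen hue span widens
to 141-189 to probe behaviour near the band edges. In `perisinusoidal`
mode the sleeves deliberately touch the channels; smoothing then blends a
fringe of channel pixels into the collagen band, which mirrors the real
difficulty of fine perisinusoidal collagen and is why accuracy claims are
stated for the band-separated geometry only.

The phantoms are deliberately *not* photorealistic: no staining gradients
across the slide, no red-blood-cell congestion, no hepatocyte texture, no
chromatic aberration. Passing tests therefore demonstrate that the
pipeline measures what the thresholds define, with sub-percentage-point
geometric fidelity — not that the fixed bands are optimal for any given
scanner or staining batch.

Cohort emulation (`generate_cohort()`) reproduces a 50-animal design:
CHFS scores drawn with probabilities (0.46, 0.32, 0.22) and per-ROI
fibrosis fractions drawn per score from normal distributions with means
(1.32, 8.00, 14.55) percent and standard deviations (1.07, 4.45, 6.62),
truncated to [0, 0.9); five ROIs per slide. No published per-group lumen
values exist, so the lumen fraction defaults to a score-independent
N(0.08, 0.02) truncated to [0, 0.5) — sinusoids near 8% of tissue is a
plausible congested-liver figure, and the choice only affects SLR columns,
never CFR validation.

Default problem sizes are chosen so a full end-to-end validation (250
phantoms of 341 px plus the property suites) completes in a couple of
minutes on one core; all geometry scales with `side_px` if full-resolution
1364-px phantoms are wanted.

## The statistics layer

`score_frequencies()` tabulates CHFS counts and exact percentages.
`group_compare()` runs the fixed procedure: per-group mean ± sd *and*
median + IQR (both are emitted because summary conventions differ between
reports), a Kolmogorov-Smirnov normality check per group against a normal
with the group's estimated moments, one-way ANOVA, and all pairwise
Tukey-HSD comparisons. The procedure never silently switches to a
nonparametric test; it warns when normality is rejected and flags the
report. Note that the KS test with estimated parameters is
anti-conservative (the Lilliefors correction is not applied), which is
acceptable here because the check gates only a warning, not a change of
procedure.

```{r stats-example}
set.seed(1)
cohort <- data.frame(
  chfs = rep(0:2, c(23, 16, 11)),
  cfr_percent = c(rnorm(23, 1.32, 1.07), rnorm(16, 8.00, 4.45),
                  rnorm(11, 14.55, 6.62)),
  slr_percent = rnorm(50, 8, 2))
score_frequencies(cohort)
group_compare(cohort, "cfr")
```

## Known limitations

* The fixed bands were established for one staining/scanning setup; slides
  from other labs may need re-tuned bands (`hsb_band()` accepts any box).
* Color-management/ICC monitor calibration and color deconvolution into
  stain vectors are out of scope.
* The automated lumen detector does not separate lumens from fat droplets
  or vessels; treat its output as candidates.
* Whole-slide pyramid formats are not read; ROIs are extracted upstream.
* CHFS grading itself remains a pathologist task; the package only
  consumes the grades.
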