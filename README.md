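# mtmorph

Morphometry of centrilobular fibrosis and sinusoidal lumens in
Masson's-trichrome-stained liver sections.

## The problem

In congestive hepatopathy (chronic liver injury under right-heart failure),
collagen accumulates around the centrilobular vein and the sinusoids
dilate. Pathologists grade this with the ordinal Congestive Hepatic
Fibrosis Score (CHFS, 0–4), which is coarse and insensitive to fine
perisinusoidal collagen. On a Masson's-trichrome (MT) section, however,
collagen is blue and parenchyma red/pink/purple, so both lesions can be
*measured*. `mtmorph` is for experimental pathologists and image analysts
who want those measurements to be reproducible, batch-scale, and testable.

## The method

The unit of analysis is a square region of interest (ROI) centred on a
centrilobular vein (conventionally 1364 × 1364 px at 4.55 µm/px). The
pipeline per ROI:

1. attach the physical scale (µm/px);
2. exclude the manually outlined centrilobular vein by filling it pure
   white;
3. segment **fibrosis**: 3 × 3 mean smoothing, then an inclusive HSB box
   threshold with hue 140–190, saturation 0–255, brightness 0–248
   (0–255 integer scale per channel);
4. segment **sinusoidal lumens**: manually annotated lumens are filled
   black and recovered by the band hue 0–255, saturation 0–255, brightness
   0–50 (an automated near-white candidate detector is provided as a
   clearly flagged screening extension);
5. measure areas as pixel count × (µm/px)² and compute

   CFR% = 100 · A_fibrosis / (A_ROI − A_vein),
   SLR% = 100 · A_lumen / (A_ROI − A_vein);

6. aggregate slides as arithmetic means over their ROIs (conventionally
   five) and compare CFR/SLR across CHFS groups with one-way ANOVA plus
   Tukey HSD.

Every stage is validated on synthetic MT phantoms with exact ground-truth
masks (`generate_phantom()`, `generate_cohort()`), which ship as
first-class, tested code.

## Worked example

```r
library(mtmorph)

ph <- generate_phantom(phantom_spec(side_px = 341, fibrosis_fraction = 0.12,
                                    lumen_fraction = 0.08, seed = 7))
ph
#> Trichrome phantom 341 x 341 px (seed 7)
#>   vein 2453 px; fibrosis 13659 px (12.00% of tissue); lumen 9106 px (8.00% of tissue)

roi <- as_roi(ph, roi_id = "demo_roi1")          # scale + white vein fill
fib <- segment_fibrosis(roi)                     # smoothed HSB threshold
lum <- segment_lumen_annotated(annotate_lumens(roi, ph$truth_lumen))
m   <- measure_roi(roi, fib, lum)
round(t(m[, -1]), 2)
#> total_area_um2    2407307.40
#> vein_area_um2       50783.23
#> tissue_area_um2   2356524.17
#> fibrosis_area_um2  278469.33
#> lumen_area_um2     188516.96
#> cfr_percent            11.82
#> slr_percent             8.00
```

The phantom carries 12.00% true fibrosis; the pipeline measures a CFR of
11.82% — the 0.18-point deficit is smoothing blur at the collagen
boundary. The annotated-lumen route is exact by construction (SLR 8.00%).
Folder-scale processing works the same way through `run_batch()` /
`batch_config()`, which write per-ROI and per-slide CSVs, and
`group_compare()` runs the CHFS-group statistics.

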