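# ectopuncta

Semi-quantitative detection and counting of **ectopic mitochondrial DNA**
— mtDNA that has leaked out of mitochondria into the cytoplasm — in
triple-stained fluorescence microscopy images (anti-dsDNA, anti-histone
H2B, anti-Hsp60). Cytoplasmic mtDNA activates cytosolic DNA sensing
(cGAS–STING) and is studied in Parkinson's disease, aging, heart failure
and cancer; this package turns the microscopy readout into reproducible
per-field counts and group statistics.

## The method

Every DNA-containing structure stains for dsDNA; the markers say which
ones are *not* ectopic mtDNA. Histone H2B marks nuclear-origin DNA,
Hsp60 marks the mitochondrial matrix. The pipeline:

1. **Calibrate** scaling factors *x* (Hsp60) and *y* (H2B) on
   control-condition images, by the rule that the scaled subtraction
   drives the corresponding DNA signal to ≤ 0 in controls. Implemented
   as a high quantile (default 0.999; 1 = the literal rule) of the
   pixelwise ratio dsDNA/marker on marker-defined masks.
2. **Subtract**: `S2 = max(0, dsDNA − x·Hsp60 − y·H2B)` (or
   `S1 = max(0, dsDNA − x·Hsp60)`, with histone overlap used as the
   discriminator instead).
3. **Detect puncta**: Otsu binarization of the subtracted image;
   8-connected components; keep components with area 2–20 µm² and
   circularity `4πA/P²` in 0.1–1.0; exclude ring-shaped "donut"
   components (Euler number < 1, a signature of nuclear-origin
   cytoplasmic DNA with weak histone signal) and components overlapping
   the histone mask.
4. **Normalise and compare**: ectopic dots per cell (nuclei counted from
   the H2B channel), mean ± SEM per condition, two-sided pooled-variance
   Student's *t*-test between conditions.

A synthetic scene generator (`render_scene()`, presets `control`,
`tfam_kd`, `gba_kd`) renders fields with known ground truth — nuclei,
mitochondrial networks with nucleoids, ectopic puncta, histone-positive
dots, donut rings, PSF blur, channel bleed and noise — so every stage is
testable without microscope data.

## Worked example

```r
library(ectopuncta)

controls <- lapply(1:5, function(i)
  render_scene(scene_preset("control", seed = i))$stack)
factors <- calibrate(controls)
factors
#> <calibration_factors>
#>   x (Hsp60 multiplier): 1.86921
#>   y (H2B multiplier):   3.71568
#>   ratio quantile 0.999, otsu masks, 5 control image(s)

kd <- render_scene(scene_preset("tfam_kd", seed = 101))
detect(kd$stack, factors)
#> <detection_result> scene_seed101 (subtract2)
#>   13 component(s): ectopic_mito=10, rejected_size=3
#>   ectopic puncta 10, cells 4, dots per cell 2.5

ratios_ctl <- vapply(controls, function(s)
  detect(s, factors)$dots_per_cell, numeric(1))
ratios_kd <- vapply(1:10, function(i)
  detect(render_scene(scene_preset("tfam_kd", seed = 100 + i))$stack,
         factors)$dots_per_cell, numeric(1))
compare_groups(ratios_ctl, ratios_kd)
#> Student's (pooled) t-test: t = -8.686, df = 13, p = 8.988e-07
#>   group means: 0.04 vs 2.412
```

The estimated factors sit ~25 % above the true bleed (1.5 / 3.0) because
a 0.999 ratio quantile is deliberately conservative under gaussian noise;
over-subtraction only suppresses marker-positive signal and leaves the
marker-free puncta untouched (all 10 planted puncta are recovered). The
TFAM-knockdown-like condition shows ~2.4 ectopic dots per cell versus
~0.04 in controls.

For real images: `read_stack()` / `write_stack()` handle multi-channel
OME-TIFFs with physical pixel size (override > OME metadata > resolution
tags), and a command-line interface wraps the whole workflow:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ectopuncta.R", package="ectopuncta"))')
Rscript $CLI simulate  --preset tfam_kd --n-fields 10 --seed 7 --out-dir kd/
Rscript $CLI calibrate --controls 'ctl/*.ome.tif' --out factors.json
Rscript $CLI detect    --images '*/*.ome.tif' --factors factors.json \
                       --out puncta.csv --summary-out images.csv
Rscript $CLI report    --images images.csv --conditions conditions.csv \
                       --out summary.csv
```

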