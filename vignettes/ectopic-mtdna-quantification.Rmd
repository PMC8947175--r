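---
title: "Quantifying ectopic mitochondrial DNA puncta: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ectopic mitochondrial DNA puncta: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectopuncta)
```

## The measurement problem

Mitochondrial DNA that leaks into the cytoplasm ("ectopic" mtDNA) is an
inflammatory signal implicated in Parkinson's disease, aging and other
conditions. In a triple immunofluorescence stain, every DNA-containing
structure lights up in the dsDNA channel: nuclei, intra-mitochondrial
nucleoids, nuclear-derived cytoplasmic fragments, and the ectopic mtDNA
puncta of interest. The two marker channels disambiguate them: histone H2B
marks DNA of nuclear origin, and Hsp60 (a mitochondrial-matrix protein)
marks DNA still inside mitochondria. An ectopic mtDNA punctum is a small
dsDNA spot negative for both markers.

`ectopuncta` turns that definition into numbers in four steps:

1. **Calibration** -- estimate how much dsDNA signal a unit of Hsp60 (x)
   or H2B (y) signal accounts for, from control images.
2. **Subtraction** -- form `dsDNA - x*Hsp60 - y*H2B` (the "subtract-2"
   image) or `dsDNA - x*Hsp60` ("subtract-1"), clipped at zero.
3. **Detection** -- binarize, find connected components, filter by area
   (2--20 um^2) and circularity (0.1--1.0), exclude ring-shaped
   ("donut") and histone-overlapping components, and count the
   survivors as ectopic puncta.
4. **Normalisation and statistics** -- divide by the nucleus count of the
   field, and compare conditions by per-image ratios with a pooled-variance
   Student's t-test (two-sided), reporting means with standard errors.

## The calibration rule and its estimator

The factors are defined operationally: in control cells essentially all
dsDNA signal is nuclear or mitochondrial, so x must be large enough that
`dsDNA - x*Hsp60 <= 0` at mitochondrial pixels of the controls, and y
likewise for nuclear pixels. The minimal such factor is the maximum of the
pixelwise ratio `dsDNA/Hsp60` over the mitochondrial mask (Hsp60 above its
Otsu threshold, outside the nuclear mask), and analogously for y. We
implement the estimator as a quantile of that ratio (`stats::quantile`,
type 1, so that the fraction of pixels exceeding the estimate never
exceeds `1 - quantile`):

* `quantile = 1` is the literal rule, exact on clean data;
* the default `quantile = 0.999` ignores a 0.1 % tail of hot pixels.

Three implementation choices matter:

* **Ratios are only formed where the denominator is above its mask
  threshold** -- faint pixels would otherwise blow the ratio up.
* **Masks are eroded by 1 px (and the nuclear exclusion dilated by 1 px)
  before pooling.** At structure boundaries the point-spread function
  mixes signal from neighbouring objects, so boundary ratios estimate a
  mixture, not the factor. The erosion width is configurable
  (`boundary_erode_px`).
* **One `(x, y)` pair per batch**, pooled over all control images and
  applied unchanged to every condition, so all samples are processed
  under identical settings. A per-image estimate can be had by calling
  `calibrate()` on single images.

A quantile of a ratio is an extreme-value statistic, and that has a
consequence worth stating plainly: under noise with unbounded tails
(gaussian), the q = 0.999 quantile sits about three ratio-standard
deviations above the true factor, i.e. the estimator is biased upward by
roughly `3 * sigma_ratio` no matter how many pixels are pooled. The
defining "<= 0 in controls" property is only a sharp statement when the
noise is bounded. The estimator is therefore *validated* under a bounded
(uniform multiplicative) noise model, where the quantile converges to a
value within the noise half-width of the truth; under gaussian noise the
estimate is deliberately conservative (slightly too large), which costs
nothing downstream -- over-subtraction only suppresses marker-positive
signal further and does not touch marker-free puncta. `verify_factors()`
reports the per-image fraction of still-positive residual pixels so a
batch's calibration can be audited.

## Subtraction and contrast

`subtract()` is exact pixel arithmetic with clipping at zero (display
subtraction saturates, and thresholding assumes non-negative input);
nothing else is applied at that stage. When background from the
multiplication is high, a *batch-shared* linear contrast window can be
applied (`apply_contrast()`), defaulting to `(0, 99.9th percentile of the
pooled subtracted controls)` via `contrast_window()`; the window must be
shared so that all samples remain comparable. Detection is
threshold-based and Otsu is invariant to linear rescaling, so the window
is cosmetic unless chosen per-image -- which the API discourages by
taking the window as an explicit argument.

## Detection: threshold, shapes, donuts, histones

**Threshold.** Otsu's method on the *nonzero* pixels of the subtracted
image (the clipped zeros would otherwise dominate the background class),
selecting the 256-bin split that maximises between-class variance. When
an empty histogram gap separates the classes every split through the gap
ties exactly; the threshold is taken at the middle of the tied run rather
than its lower edge, so it does not hug the background mode. The mask
keeps pixels `>= threshold`; an all-zero image yields an empty mask with
a warning, not an error.

**Components and measurements.** Components use 8-connectivity by
default (the usual particle-counting convention; 4 is available). Area
is pixel count times the pixel area -- hence a physical pixel size is
mandatory input. Perimeter uses a weighted boundary-configuration
estimator (boundary pixels weighted by their local boundary
configuration, weights 1, sqrt(2) and (1+sqrt(2))/2), which is far less
biased on small objects than raw boundary-pixel counting; circularity is
`min(1, 4*pi*area/perimeter^2)`. Small-object circularity still differs
between perimeter estimators, so validation uses discs of radius >= 5 px
where estimators agree closely.

**Classification** applies the first failing rule in a fixed order --
size, shape, donut, histone overlap -- so each component receives exactly
one auditable class:

* `rejected_size`: outside [2, 20] um^2, bounds inclusive ("from 2 to
  20" reads as inclusive, and ties must be deterministic). The range
  suits HeLa cells and is configurable for other cell types.
* `rejected_shape`: circularity below 0.1 (the 1.0 ceiling, capped,
  never rejects).
* `nuclear_origin_donut`: the component contains a hole (Euler
  number < 1). Ring-shaped dsDNA arises around nuclear-origin cytoplasmic
  DNA when its histone co-signal is too weak to subtract; topology is the
  most direct operationalisation. A hole must span at least
  `min_hole_area_px` (default 4) pixels: single sub-threshold pixels
  inside an otherwise solid punctum are noise dropouts, not a lumen.
* `nuclear_origin_overlap`: more than `histone_overlap_max_fraction`
  (default 0.3) of the component's pixels fall inside the
  H2B-above-threshold mask. With the subtract-1 variant (H2B not
  subtracted) this rule is the mandatory discriminator; with subtract-2
  it is a safeguard.
* `ectopic_mito`: everything that survives -- the count of interest.

Manual review of original images is out of scope; instead every
component's row
carries all measurements so a human can audit the table.

## Cell counting and the summary statistic

The reported readout is *ectopic dots per cell*, per field. Cells are
counted as H2B-positive nuclei: Otsu threshold, hole filling, an area
floor of 40 um^2 (safely above the 20 um^2 punctum ceiling), and an
optional distance-transform watershed (`tolerance` 2 px) to split
touching nuclei. Border-touching nuclei are counted, because the ratio
uses whole-field counts and exclusion would bias the denominator; the
choice is a parameter. A field with no cells has an undefined ratio,
reported as `NA` and excluded (and counted) by `summarize_results()`.
Ratios are summarised per condition as mean +/- SEM over images -- the
image, not the punctum, is the statistical unit -- and compared with the
classical pooled-variance Student's t-test (`compare_groups()`); Welch's
form is a flag. Identically-constant groups are an error, not `p = 0`.

## The synthetic scene generator

Real microscope data cannot ship with a package, so validation uses
`render_scene()`, which emulates exactly the structures the method must
separate, on a unit intensity scale (a punctum has amplitude 1):

* **Nuclei**: 4--6 bright H2B ellipses (radius ~21--26 px at
  0.31 um/px, i.e. ~13--16 um across), with dsDNA equal to
  `bleed_y_true * H2B` (default 3.0) -- nuclear chromatin stains in both
  channels.
* **Mitochondrial network**: random-walk filaments dilated to ~3 px
  width with brighter nucleoid hot spots along them; dsDNA inside is
  `bleed_x_true * Hsp60` (default 1.5) -- the confound calibration must
  remove.
* **Ectopic puncta**: dsDNA-only discs, areas uniform in 3--12 um^2.
* **Nuclear-origin dots**: discs carrying a strong H2B co-signal.
* **Donuts**: bright dsDNA rings (outer radius 6--8 px, lumen half
  that) with a faint, sub-threshold H2B co-signal -- they appear in the
  subtracted image and must be removed by topology alone.

Objects are placed with exclusion margins (at least ~3 px plus twice the
PSF sigma between object boundaries, and the network is kept clear of
nuclei) so ground-truth classes are unambiguous; a field too crowded to
satisfy the margins is an explicit error. Rendering then applies a
gaussian PSF (sigma 1 px, replicated borders) and noise. Each stage --
nuclei, network, ectopic puncta, dots, donuts, noise -- draws from its
own seed derived from the scene seed, so adding objects of one type
changes nothing else, including the noise field; this is what makes
"adding N donuts leaves the ectopic count unchanged" a well-posed test.
Rendering is bit-reproducible from the spec.

Noise models: `gaussian` (additive, sd = `noise_sigma` on the unit
scale), `uniform` (multiplicative, bounded at +/- `noise_sigma` of the
local signal; the model under which the calibration rule is well-posed,
see above) and `poisson_gaussian` (shot noise with matching variance at
unit intensity plus 20 % read noise). The default `noise_sigma = 0.057`
is chosen so that the *subtracted* image has punctum SNR ~ 5: subtracting
x- and y-scaled channels multiplies the per-channel noise sd by
`sqrt(1 + x^2 + y^2) = 3.5` at the default bleed factors, and
`1 / (5 * 3.5) = 0.057`.

Presets encode the three experimental conditions: `control` (0--1
ectopic puncta), `tfam_kd` (8--15 ectopic puncta -- destabilised mtDNA
leaking into the cytoplasm), `gba_kd` (4--8 ectopic puncta plus 3--6
histone-positive nuclear-origin dots).

What the generator does *not* emulate -- spatially varying background,
optical aberrations and vignetting, spectrally structured bleed-through,
out-of-focus light, irregular nuclear morphology, touching cells at high
confluency -- bounds what passing tests show: they demonstrate that the
algorithm implements the method correctly and recovers known truth under
idealised imaging, not that the defaults are optimal on any particular
microscope's output.

## Numerical choices and degenerate inputs

* Intensities are promoted to doubles on load; original integer types
  are recorded so TIFF round trips are bit-exact (pixel data are stored
  as 32-bit floats with a common scale in the OME-XML description).
* Pixel size precedence: explicit override > OME `PhysicalSizeX` >
  TIFF resolution tags; absence everywhere is an error.
* `verify_factors()` counts a residual as positive only above
  `1e-9 * max(dsDNA)`, so exact cancellations do not register through
  floating-point round-off.
* Thresholding an all-zero image warns and returns an empty mask;
  empty marker masks during calibration are errors (a factor of 0 would
  silently disable subtraction).
* Area bounds inclusive on both ends; Euler rule strictly `< 1`;
  overlap rule strictly `> histone_overlap_max_fraction`.
* Degenerate two-pixel objects have configuration-perimeter 0; their
  circularity is defined as 1 (they are as compact as representable).

## Problem sizes used in validation

The shipped tests validate: exact calibration on noiseless fields;
calibration recovery within 15 % across 20 bounded-noise control batches
(5 fields each); exact agreement of component classification with an
independent brute-force implementation on 200 random small masks;
detection sensitivity >= 0.95 with <= 0.5 false calls per field over 20
fields of 10 puncta at SNR ~ 5, with ectopic counts invariant to added
dots and donuts; and the control < knockdown ordering with p < 0.05 in
>= 95 % of 100 replicate studies of 10 fields per condition. Fields are
256 x 256 px at 0.31 um/px -- a realistic confocal field that keeps a
full replicate study to a few seconds of compute.

## A worked example

```{r example, eval = FALSE}
library(ectopuncta)

controls <- lapply(1:5, function(i)
  render_scene(scene_preset("control", seed = i))$stack)
factors <- calibrate(controls)
factors

fields <- lapply(1:10, function(i)
  render_scene(scene_preset("tfam_kd", seed = 100 + i)))
results <- lapply(fields, function(sc) detect(sc$stack, factors))
results[[1]]

ratios_ctl <- vapply(controls, function(s)
  detect(s, factors)$dots_per_cell, numeric(1))
ratios_kd <- vapply(results, `[[`, numeric(1), "dots_per_cell")
compare_groups(ratios_ctl, ratios_kd)
```

## Known limitations

* 2-D only; z-stacks must be max-projected first (`max_project()`).
* Channels are assumed co-registered; no registration is attempted.
* Bleed correction is a global scalar per channel, not a spatially
  varying or full spectral unmixing model.
* The donut rule requires the ring to survive binarization as a closed
  component; heavily fragmented rings degrade into arcs that must be
  caught by the shape or overlap rules instead.
* Under unbounded noise the calibration quantile is conservatively
  biased upward (see above); if an unbiased bleed estimate is the goal,
  a lower quantile with `verify_factors()` auditing is the tool.
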