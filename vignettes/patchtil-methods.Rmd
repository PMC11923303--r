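---
title: "PatchTIL: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PatchTIL: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatchTIL)
```

PatchTIL scores tumor-infiltrating lymphocytes (TILs) on H&E slide images
by classifying fixed-size patches and pooling the patch classes. This
vignette explains each stage's model and assumptions, the parameters that
matter, the synthetic data that verifies the pipeline, and the design
decisions taken where the published protocol is silent.

## Tiling and the blank filter

Slides are tiled into non-overlapping `patchSize = 150` pixel squares
(0-based, row-major grid; partial edge tiles dropped), matching the patch
size used in published patch-based TIL scoring at ×20 magnification. No
magnification metadata is interpreted: the input raster is taken to be ×20
already. A patch is blank when the mean of its per-pixel gray values
exceeds 230 **and** their standard deviation is below 15, both strict
inequalities, exactly as the protocol states them.

Two readings of that filter are possible, because "standard deviation" is
not pinned down: statistics of the per-pixel gray value
$(V_R + V_G + V_B)/3$, or of the pooled per-channel values. The gray
reading matches the formula given for the mean, so it is the default
(`blankFilterParams(mode = "gray")`); the pooled-channel variant is a
switch. The standard deviation is the population form (denominator $n$):
on a half-226 / half-236 patch it gives exactly mean 231, sd 5.

## Stain model and Macenko normalization

All rendering and unmixing uses Beer–Lambert optics with background
intensity $I_0 = 240$:

$$\mathrm{OD} = -\ln\frac{I + 1}{I_0}, \qquad I = I_0 e^{-\mathrm{OD}} - 1,$$

with the $+1$ making the transform exactly invertible on the quantized
0–255 scale (intensity $I_0 - 1 = 239$ maps to OD 0; intensities above 239
are clipped to OD 0). Optical density is linear in stain concentration,
$\mathrm{OD} = S\,c$, with $S$ the 3×2 unit-column stain matrix
(hematoxylin, eosin).

Stain estimation follows the classical eigenplane/percentile construction:
discard pixels with any OD channel below $\beta = 0.15$; eigen-decompose
the covariance of the rest; project onto the top-2 eigenplane; take the
$\alpha = 1$ and $100-\alpha$ angle percentiles; back-project, take
absolute values (stain vectors live in the positive octant) and normalize.
Hematoxylin is the vector with the larger red-channel OD. Concentrations
come from unconstrained least squares with negatives clipped to zero —
exact on non-overlapping stains and far cheaper than NNLS, which is
available behind `macenkoParams(nnls = TRUE)`. Normalization rescales each
stain by the ratio of target to source 99th-percentile concentration and
re-renders with the target basis. The canonical target is the widely used
reference H&E basis with scales (1.9705, 1.0308).

Two departures from the textbook algorithm, both parameterized:

- **OD denoising for estimation** (`denoiseSigma = 1` px). The 1% angle
  percentile is an extreme-value statistic; with per-pixel intensity noise
  of sd 8 its error is dominated by angle jitter of individual pixels
  (measured ≈9° on seeded fixtures). A light Gaussian blur of the OD
  planes — used only for estimation, never for re-rendering — restores
  ≈3° recovery while leaving noiseless recovery at ≈0.4°. Setting
  `denoiseSigma = 0` recovers the unsmoothed algorithm.
- **Degeneracy detection.** Estimation fails explicitly (classed
  condition) when fewer than `minTissuePixels = 100` pixels survive the
  $\beta$ cut (blank patches) or the angle percentiles nearly coincide
  (`minAngleSpreadDeg = 1`°, single-stain patches). `normalizePatch()`
  converts that failure into a pass-through with a flag, so pipelines
  never crash on blank tiles.

Whether to normalize against a fixed target or per-slide profiles is not
specified in the protocol; the default is a fixed canonical target, with
per-patch source estimation.

## The labeling rule and the reference detector

The three patch classes use the published counting rule: TIL-positive
(code 0) needs at least 3 detected lymphocytes **and** at least 1 detected
tumor cell; TIL-negative (1) has at least 1 tumor cell and fewer than 3
lymphocytes; other/necrotic (2) has no tumor cell, regardless of
lymphocytes. The rule is total: every count pair maps to exactly one class.

The published pipeline never defines a nucleus detector — pathologists
labeled patches and a CNN learned from them. To make the rule executable
and testable, PatchTIL ships a deterministic reference backend:
hematoxylin concentration unmixing → Gaussian smoothing
(`smoothingSigma = 1` px) → thresholding → 8-connected components →
classification by area and circularity ($4\pi A / P^2$, perimeter measured
along the object contour). Components with area in
`lymphAreaRange = [40, 280]` px² and circularity ≥ 0.75 are lymphocytes;
area ≥ `tumorMinAreaPx = 320` is a tumor nucleus. These windows are
calibrated to the synthetic generator's geometry (lymphocyte radius 5–7 px,
tumor radius 12–20 px) and are fully exposed; on real slides they would
need re-calibration to the scanner's µm/px.

The threshold mode deserves a note. Otsu's method is offered, but the
default is a **fixed** concentration threshold of 0.25: Otsu maximizes
between-class variance over the whole histogram, and on patches dominated
by bright lymphocyte nuclei (concentration 0.8–1.2) it can place the cut
above faint tumor nuclei (0.4–0.8), deleting or eroding them. The fixed
value sits midway between background unmixing crosstalk (< 0.1) and the
faintest rendered nucleus (0.4), and is robust to intensity noise of sd 8
after smoothing.

Probabilistic backends plug in through a single contract: a 3-vector on
the probability simplex, label = argmax with ties broken toward the lowest
class code. The optional trainable backend (`trainPatchNet()`) resizes
patches to a fixed input size, summarizes them by stain-morphology
features (a five-bin size histogram of thresholded hematoxylin components,
total nucleus area, mean stain concentrations) and trains a
single-hidden-layer softmax network; it exists to exercise the backend
contract and the split/cross-validation machinery, not to replicate a deep
CNN.

Stromal and intratumoral TILs are not distinguished, mirroring the
published assessment.

## Scores, densities, maps

The TIL score of a unit with $m$ slides is the pooled ratio
$\sum_i N^{(i)}_{\mathrm{pos}} / \sum_i (N^{(i)}_{\mathrm{pos}} +
N^{(i)}_{\mathrm{neg}})$ — a patient with slides (3 pos, 1 neg) and
(1 pos, 3 neg) scores 4/8 = 0.5, whereas averaging per-slide scores would
give the same here but 0.2 ≠ 0.25 for slides (2, 2) and (0, 6); the pooled
form is the implemented one. Other/necrotic and blank patches never enter
the score. A zero denominator raises a classed undefined-score error —
silently scoring 0 would bias cohort statistics toward low TIL content;
cohort tables carry `NA` for such units.

Cohort summaries use a Gaussian KDE with Scott's-rule bandwidth on a fixed
512-point grid over [0, 1], without boundary correction (mass can leak
past the boundaries for wide bandwidths; the mode is unaffected for
interior concentrations). A zero-spread sample falls back to bandwidth
0.01. TIL maps place each patch's class at its grid position
(position-keyed, so prediction row order is irrelevant) with the palette
red/blue/green/white for positive/negative/other/blank — the published
figures do not define their palette, so it is configurable.

## The synthetic generator

The generator is the package's verification instrument. Lymphocytes are
disks of radius 5–7 px with hematoxylin concentration U[0.8, 1.2]; tumor
nuclei are ellipses (aspect 0.7–1) with a smooth ±25% radial perturbation,
radius 12–20 px, concentration U[0.4, 0.8], surrounded by an eosin
cytoplasm halo; tissue patches sit on a low-amplitude eosin stroma field
so they fail the blank filter, while non-tissue patches render at the
background level 239 and pass it. Rendering goes through the same
Beer–Lambert model the normalizer inverts, then optional Gaussian
intensity noise (`noiseSd`, 0–255 scale) and quantization. Placement is
rejection sampling with a guaranteed minimum gap (3 px beyond touching) so
nuclei never merge under the detector's smoothing — by design the
reference detector needs no nucleus splitting. Infeasible requests raise a
classed capacity error rather than degrading.

Two generator defaults depart from the weakest-plausible staining: nuclei
displace the stromal eosin field, and the tumor cytoplasm halo carries
eosin U[0.5, 0.9]. Both exist so that near-pure pixels of *each* stain
survive the Macenko $\beta$ cut — with the reference stain basis, eosin
below concentration ≈0.7 never clears $\beta = 0.15$ in the red channel,
and without pure-eosin pixels stain-vector recovery is biased by ≈17°.
Strong cytoplasmic eosin around tumor cells is also the visually plausible
choice. All of these values are `patchSpec()` arguments.

Slides draw each tissue patch's class from programmable probabilities
(default proportional to the 1 : 1.5 : 1.5 dataset ratio used for
classifier training in the published protocol) and then cell counts from
per-class ranges; labeled datasets apportion classes by largest-remainder
rounding of the requested ratio. Determinism is strict: one master seed,
per-patch seeds derived as `(seed * 1009 + counter) mod (2^31 - 2) + 1`,
and bit-identical rasters for identical specifications.

What passing on synthetic data does and does not show: it verifies the
*logic* of every stage — tiling arithmetic, filter thresholds, stain
algebra, the counting rule, score pooling, map placement — against ground
truth and independent oracles. It does not demonstrate performance on real
histology, which has overlapping nuclei, stain variability beyond a linear
two-stain model, scanner artifacts, and cells straddling patch borders
(the generator keeps cells fully inside patches; on real slides the
border-fraction convention would need a decision).

## Problem sizes and numerical choices

The shipped verification suites run on sizes chosen to exercise every code
path while staying quick on a laptop: 300-patch label-recovery sets per
noise level, 20-slide cohorts of 4×4-patch slides spanning programmed
TIL-positive fractions 0–0.9, six-fixture stain-recovery panels, and
1,000-case score-formula sweeps. Key tolerances: stain-vector recovery
within 2° clean and 5° at noise sd 8; normalization idempotence within 2
mean intensity units; OD round-trip within 1 intensity unit on [0, 239];
label recovery 100% clean and ≥90% at noise sd 8; end-to-end score
recovery exact clean and Spearman ≥0.9 noisy. Evaluation metrics use
micro-averaging as the default (the published report's equal
accuracy/precision/recall/F1 indicate micro-averaging), with macro
reported alongside; one-vs-rest AUC is macro-averaged over classes present
in the truth. Cross-validation identifies the best fold by held-out
accuracy with ties to the lowest fold index.

## Known limitations

- The reference detector is calibrated to the generator's geometry; real
  slides need parameter re-calibration and would stress the non-overlap
  assumption.
- Stain normalization assumes exactly two stains and linear mixing; it
  will mis-render third pigments (e.g. melanin).
- No pyramidal WSI reader is bundled; inputs are single-resolution
  PNG/TIFF rasters at the working magnification (an adapter extracting
  level 0 can be wrapped around `readSlide()`'s contract).
- The KDE is uncorrected at the boundaries, which matters for cohorts
  concentrated near 0 or 1.
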