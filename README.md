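# PatchTIL

Patch-level scoring of tumor-infiltrating lymphocytes (TILs) in
hematoxylin-and-eosin (H&E) slide images.

TIL density in routine H&E histology is a prognostic and predictive marker
across many solid tumors, but manual assessment is slow and poorly
reproducible. PatchTIL implements the automated patch-based strategy used in
computational pathology: a slide image is cut into non-overlapping
150×150-pixel patches, blank patches are removed, stain color is
standardized, every tissue patch is assigned one of three classes, and the
per-patch classes are aggregated into a slide- or patient-level TIL score
and a spatial TIL map. It is aimed at computational-pathology researchers
who need a tested, scriptable reference implementation of this pipeline —
with a fully synthetic H&E generator so every stage can be verified with
known ground truth, no whole-slide images required.

## The method

**Tiling and blank filter.** A slide raster (assumed ×20 magnification) is
segmented into non-overlapping 150×150 patches; partial edge tiles are
dropped. A patch is blank and excluded when its per-pixel gray values
g = (V_red + V_green + V_blue)/3 satisfy mean(g) > 230 and sd(g) < 15.

**Macenko stain normalization.** Pixels are mapped to optical density
OD = −ln((I+1)/I₀) (Beer–Lambert, background intensity I₀ = 240). Tissue
pixels (all OD channels > β = 0.15) are eigen-decomposed; the two stain
vectors are read off at the α = 1 and 99 angle percentiles of the projection
onto the top-2 eigenplane, and per-pixel hematoxylin/eosin concentrations
are obtained by least-squares unmixing. Each stain is rescaled to a
reference profile's 99th-percentile concentration and re-rendered with the
reference stain matrix.

**Three-class patch labeling.** With nL detected lymphocytes (small, round,
hematoxylin-dense nuclei) and nT detected tumor cells (larger, irregular
nuclei):

- `0` TIL-positive: nL ≥ 3 and nT ≥ 1
- `1` TIL-negative: nL < 3 and nT ≥ 1
- `2` other/necrotic: nT = 0, regardless of nL

The packaged reference backend makes this rule executable: it unmixes the
hematoxylin concentration map, smooths, thresholds, labels connected
components, and classifies them by area and circularity (4πA/P²). Any
classifier honoring the same prediction contract (3-vector of class
probabilities, argmax label, ties to the lowest code) can be plugged in; a
small trainable neural backend is included.

**TIL score.** For a unit with m slides,

```
TIL score = Σᵢ N⁽ⁱ⁾_TIL-positive / Σᵢ (N⁽ⁱ⁾_TIL-positive + N⁽ⁱ⁾_TIL-negative)
```

a pooled ratio over all slides, never the mean of per-slide scores.
Other/necrotic and blank patches never enter numerator or denominator; a
zero denominator is an explicit undefined-score condition, never silently 0.
Cohort score distributions are summarized by a Gaussian kernel density on
[0, 1] with its mode.

## Worked example

```r
library(PatchTIL)

# a synthetic 4x4-patch slide, 75% tissue, with ground truth
sl <- generateSlide(slideSpec(4, 4, tissueFraction = 0.75, seed = 11), "demo")
m  <- filterPatches(tileSlide(sl$pixels, "demo"), sl$pixels)
m
#> TileManifest 'demo': 600x600 px, 4x4 grid of 150-px patches
#>   16 patches, 4 flagged blank

preds <- classifyPatches(m, sl$pixels, ruleBackend())
head(preds, 3)
#>   slideId gridRow gridCol label p0 p1 p2
#> 1    demo       0       0     0  1  0  0
#> 2    demo       0       1     1  0  1  0
#> 3    demo       1       0     2  0  0  1

scoreCohort(preds)
#>   unitId level m nPositive nNegative nOther score
#> 1   demo slide 1         2         3      7   0.4

buildTILMap(m, preds)
#> TILMap 'demo': 4x4 grid
#> positive negative    other    blank
#>        2        3        7        4
```

The slide score 0.4 is 2 TIL-positive patches over 5 tumor-containing
(positive + negative) patches; the 7 other/necrotic and 4 blank patches are
excluded. `writeTILMap()` renders the colored patch map
(red = TIL-positive, blue = TIL-negative, green = other, white = blank).

A shell interface covering the same steps (`synth`, `tile`, `normalize`,
`classify`, `score`, `map`, `eval`, `run`) is in
`inst/scripts/patchtil-cli.R`.

## Scope

The package covers image-side TIL scoring only: no survival modeling, no
transcriptomic integration, and no pre-trained deep network weights. The
synthetic generator is a verification instrument — it emulates the geometry
and stain model the classifier rule needs, not photorealistic histology
(see the methods vignette for what that does and does not demonstrate).
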