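---
title: "Texture-based dose readout: model, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based dose readout: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texdose)
```

## The readout problem

Polymer gel dosimeters polymerize in proportion to absorbed ionizing dose.
At the micro scale this polymerization smooths the fibrous structure of the
freeze-dried gel, and the smoothing is visible in scanning electron
microscopy (SEM) micrographs. `texdose` turns that qualitative observation
into a quantitative dose readout:

1. compute second-order texture statistics of the micrograph from its
   gray-level co-occurrence matrix (GLCM);
2. calibrate a texture index against known doses with a straight line;
3. invert the line to estimate the dose of new micrographs.

The pipeline operates on 8-bit grayscale rasters and never branches on the
magnification: the physical scale enters only through the pixel size
attached to an image and through the texture itself.

## Co-occurrence statistics

For gray levels $i, j \in \{0, \dots, N_g-1\}$ and a displacement given by a
distance $d$ (pixels) and a direction $\theta \in \{0°, 45°, 90°, 135°\}$,
the co-occurrence count $P(i,j)$ is the number of in-bounds pixel pairs
whose intensities are $i$ and $j$ at that displacement. Normalizing by the
total pair count gives the joint probability $p(i,j)$. Four indices are
computed from $p$:

$$
\mathrm{entropy} = -\sum_{i,j} p \log p, \qquad
\mathrm{contrast} = \sum_{i,j} (i-j)^2\, p,
$$
$$
\mathrm{energy} = \sum_{i,j} p^2, \qquad
\mathrm{homogeneity} = \sum_{i,j} \frac{p}{1 + (i-j)^2}.
$$

Entropy measures the randomness of the gray-level pair distribution,
contrast the local intensity variation, energy the uniformity of pair
patterns, and homogeneity (the inverse difference moment) the spatial
similarity of neighbors. A smoother micrograph has lower entropy and
contrast and higher homogeneity, which is why homogeneity and entropy act
as dose indices for gels.

Conventions, fixed for reproducibility:

* **Symmetric counting** (both orderings of each pair) is the default, so
  every count matrix equals its transpose; the one-directional variant is
  available via `symmetric = FALSE`.
* **Direction offsets**, with $x$ = column and $y$ = row increasing
  downward: $0° \to (d, 0)$, $45° \to (d, -d)$, $90° \to (0, -d)$,
  $135° \to (-d, -d)$. Under symmetric counting the sign convention is
  observationally irrelevant.
* **Direction averaging**: gel fibers are isotropic, so the per-direction
  *normalized* matrices are averaged element-wise (the default uses all
  four directions).
* **$N_g = 256$** for 8-bit input. Optional requantization maps the fixed
  range 0..255 linearly onto $0..N_g-1$; the mapping is fixed-range rather
  than min–max so every tile of a micrograph shares one gray scale.
* **Entropy logarithm**: natural log by default; the base is configurable
  and no downstream decision depends on it.
* **Degenerate offsets** (no valid pixel pair) are an error, never a
  silently all-zero matrix; $0 \log 0 = 0$ in the entropy sum.

## Tiling and outlier exclusion

A full 1200×1600 micrograph is cut into a top-left-anchored 4×4 grid of
300×400 sub-images (configurable). Remainder pixels at the bottom/right are
cropped with a warning (`strict = TRUE` turns this into an error). Slicing
defects and impurities make individual tiles unrepresentative, so before
averaging, exactly `e` tile values are removed per image: iteratively, the
value with the greatest absolute deviation from the median of the currently
retained values. Ties on deviation remove the larger value; exact value
ties remove the later position — the rule is deterministic and
parameter-free, which is why it was preferred over threshold-based rules
whose cutoffs would themselves need tuning. A z-score variant
(`method = "zscore"`) is available. The per-image summary is the mean of
the retained tiles; its standard error uses the $n-1$ sample standard
deviation.

`e` is treated as a tuning parameter of the readout, not a fixed rule: the
calibration stage scans it jointly with $d$.

## Calibration and parameter optimization

For each dose level the per-image means are averaged into a dose point, and
an ordinary least-squares line $y = a\,x + b$ is fitted through the dose
points (at least three distinct dose levels are required). Linearity is the
coefficient of determination $R^2$; sensitivity is $|a|$. Dose points are
equally weighted by default because replicate counts are balanced by
design; weighting by $1/\mathrm{SE}^2$ is available behind a flag. For a
constant response the fit is degenerate and $R^2$ is reported as 0.

`build_parameter_maps()` scans the $(e, d)$ grid, fitting one curve per
cell, and records $R^2$, $|a|$, and $|a|$ normalized by the grid maximum.
`select_optimum()` returns the cell with the highest $R^2$ among cells
whose normalized sensitivity reaches a floor (default 0.5): a very linear
but insensitive curve amplifies index noise into dose noise, so such cells
are excluded before the linearity comparison. The 0.5 default separates
clearly sensitive from clearly insensitive combinations and is fully
configurable. Ties prefer higher sensitivity, then smaller $d$, then
smaller $e$. `distance_at_sensitivity()` reports where each $e$-row of the
normalized sensitivity map first reaches a level (e.g. 90%), linearly
interpolated between grid distances and averaged over rows.

Dose estimation inverts the line per image — $x = (y-b)/a$ — and averages
the per-image doses afterwards, so the reported spread reflects image-level
variability. Negative estimates are returned as-is with a warning, never
clamped: a silent clamp would bias verification summaries. Doses and
percentage errors are rounded to two decimals only for presentation; all
internal arithmetic is full precision.

## The synthetic generator

No public SEM data set exists for irradiated gels, so the package ships a
generator that emulates the relevant *texture* physics end to end:

1. a dense field of randomly oriented, anti-aliased bright capsule
   segments (the fibrous structure) over a mid-gray background;
2. additive white surface roughness (`roughness_sd`), the pixel-scale
   disorder of the unirradiated freeze-dried surface;
3. isotropic Gaussian smoothing of scale $\sigma(\text{dose})$ — the
   radiation effect; the default law is linear,
   $\sigma = \sigma_0 + k\,\text{dose}$, and must be strictly increasing;
4. additive dose-independent detector noise (`noise_sd`);
5. Poisson-distributed bright impurity blobs stamped after smoothing, so
   they remain sharp outliers like real inclusions;
6. clipping to the unit range and 8-bit quantization.

Every image is a pure function of `(dose, config, seed)`; per-image seeds
in a study derive from a counter hash of (master seed, dose index, sample,
replicate), so single images can be regenerated without rebuilding the
study.

Why this produces a near-linear homogeneity response: after blurring white
roughness by $\sigma$, the gray-level difference at a lag beyond the
correlation length has standard deviation $s \propto 1/\sigma$, and in the
rough regime the inverse difference moment behaves as
$E[1/(1+\Delta^2)] \approx \sqrt{\pi/2}\,/\,s$, i.e. proportionally to
$\sigma$. A linear $\sigma(\text{dose})$ therefore yields an approximately
linear homogeneity–dose response without any index-level shortcut — the
generator only renders pixels, and the response emerges through the full
GLCM pipeline.

Default constants (all overridable): $\sigma_0 = 1.6$ px, $k = 0.16$
px/Gy (so $\sigma$ spans 1.6–4.8 px over 0–20 Gy), roughness 0.3,
detector noise 0.01 (≈2.5 gray levels), impurity rate 0.3 blobs/image.
Fibers default to one per 75 px² with lengths 20–80 px and widths 4–14 px
— at the 125.94 nm pixel size of a 500× scan this corresponds to strands
of roughly 2.5–10 µm × 0.5–1.8 µm, the fine end of the fiber dimensions
seen in gel micrographs. The fine, numerous fibers were chosen
deliberately: a 300×400 tile then contains enough independent structure
that tile statistics are stable, which is what makes the 16-tile protocol
meaningful at reduced image sizes. The smoothing-law constants were chosen
once so that the homogeneity response is close to linear across the 0–20 Gy
range and the sensitivity-versus-distance profile rises to a plateau (as it
does for real gel texture) rather than peaking at the smallest offsets;
they were not revisited afterwards.

What the generator does **not** emulate: charging and topographic SEM
artifacts, anisotropic or flake-like morphology at high dose, spatially
correlated slicing damage, and any physical link between dose rate or
beam energy and texture. Passing synthetic tests therefore demonstrates
the correctness and statistical behavior of the *pipeline*, not the
dosimetric accuracy attainable on real micrographs.

## Study designs and problem sizes

Three layouts mirror how such readouts are validated experimentally:
`screening` (one image per dose), `calibration` (four samples per dose, one
image each), and `verification` (four samples per non-zero dose, three
images each, i.e. twelve images per dose). `end_to_end_recovery()` chains
them: optimize $(e, d)$ on a calibration study, then estimate the doses of
an independent verification study and report per-dose mean percentage
errors.

The package's own validation runs these studies at 300×400 (one protocol
tile) rather than full 1200×1600 frames, with the optimization grid
$d \in \{2, 6, \dots, 30\}$ and $e \in \{0, 1, 2\}$ — sizes chosen so a
complete round trip is a couple of minutes of desk-scale computation while
still exercising every stage (tiling, exclusion, map building, selection,
inversion). At these settings the synthetic calibration typically reaches
$R^2 > 0.99$ and per-dose verification errors within ±5%.

## Numerical and degenerate-input choices

* Co-occurrence counting is exact integer tabulation; no interpolation.
* An offset with no valid pairs, an intensity $\ge N_g$, excluding more
  than $n-2$ tiles, fewer than three dose levels, zero dose variance, and
  a zero calibration slope are all hard errors with specific messages.
* A parameter-map cell whose curve cannot be fitted propagates an error
  rather than being skipped, so a map is either complete or absent.
* Map cells tie-break deterministically (sensitivity, then smaller $d$,
  then smaller $e$); outlier ties remove the larger value, then the later
  position.
* CSV/JSON outputs carry full precision; calibration JSON round-trips
  bit-exactly.

## Known limitations

* The linear dose-response model is the method's core assumption;
  saturating responses (high-dose gels) are out of scope.
* Outlier exclusion is per-index: the tiles excluded for homogeneity may
  differ from those excluded for entropy.
* The verification spread reported per dose is the standard deviation of
  per-image inverted doses; designs that group images per sample first
  will report different (smaller) spreads.
* Real-data effects not represented in the generator (see above) mean
  synthetic accuracy figures should be read as pipeline validation, not
  instrument specification.
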