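---
title: "Methods: quantifying oocyte maturation endpoints with cocQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying oocyte maturation endpoints with cocQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocQuant)
```

# Scope and model

`cocQuant` quantifies the imaging and tabular endpoints of bovine in
vitro oocyte maturation (IVM) screens for reproductive toxicity. It does
not stage meiosis from images, simulate culture, or model instrument
chemistry: it consumes fluorescence scenes and outcome tables and
produces endpoint measurements and group statistics. A synthetic-scene
generator with attached ground truth stands in for microscope data so
that each measurement stage can be validated by parameter recovery.

# Mitochondrial distribution

An oocyte stained with a membrane-potential-dependent mitochondrial dye
shows a peripheral ring of signal when immature and a diffuse pattern
when mature. The package expresses this as the **relative peripheral
intensity** (RPI): the oocyte is segmented on its equatorial optical
section, the cell disc is split at `centerFraction` (default 0.8) of the
cell *radius* — so the center is the inner 80 % of the diameter and the
cortex is the outer 10 % on each side — and RPI is the ratio of the mean
intensity **per pixel** of the cortex annulus to that of the central
disc. Per-pixel means make the very different pixel areas of the two
compartments (the annulus holds 36 % of the disc) irrelevant.

Choices behind this definition:

* **Equator selection.** The equator is the z-plane with the maximal
  segmented cross-section, ties broken toward the stack middle. A
  single-plane option is the default; `mitoProfile(aggregate = "mean")`
  averages per-plane ratios instead, for users who prefer a stack
  summary.
* **Segmentation.** Otsu threshold on the mitochondrial channel, largest
  connected component, holes filled. Hole filling matters: a strongly
  peripheral cell thresholds as a ring, and filling recovers the full
  cell disc. The diameter of a non-circular mask is the equivalent
  circular diameter `2*sqrt(area/pi)`, which is stable and well defined.
* **Degenerate inputs.** A blank frame raises "no oocyte detected"; a
  zero center mean leaves the ratio `NA` (undefined), never infinite.
* **No peripheral/diffuse cut-off is imposed.** The ratio is reported
  and group comparison is left to the statistics layer, matching how the
  endpoint is analyzed in practice (ANOVA across exposure groups).

The ratio is scale invariant, stable under 90-degree rotation within
discretization, and strictly increasing in cortex intensity; these are
enforced as property tests.

# Cumulus expansion

Cumulus expansion is measured as projected surface area in pixels before
and after IVM, `fold = area_after / area_before`, reported at full
precision (reporting layers may round to one decimal). Segmentation is
Otsu plus largest-component plus hole filling, so the dark oocyte shadow
inside the cumulus mass counts toward the projected area. The method is
deliberately 2-D: projected area does not capture the third dimension of
the asymmetric COC, and oocyte area cannot be separated from cumulus
area — both are documented properties of the assay this package
reproduces, not corrected. The worked pair 13,231 → 38,061 px gives
2.877; published summaries of this quantity round (or truncate) to one
decimal, and the package keeps full precision.

# Nucleus cytometry

Cumulus-cell nuclei are counted on the Hoechst channel with the classic
particle-counting recipe:

1. **Noise suppression**: Gaussian smoothing, `smoothSigmaPx = 2` px
   (0 disables). Without it, an automatic threshold on a low-SNR field
   lands inside the noise and detection fails; with spot sigma ~3 px the
   attenuation of real spots is modest.
2. **Background subtraction**: morphological opening with a disc of
   radius `bgRadiusPx = 15` px (larger than a nucleus) estimates the
   background, including linear gradients, and is subtracted with
   clipping at zero. A pure intensity offset therefore cannot change
   counts (tested).
3. **Threshold**: Otsu on the subtracted plane. If the threshold does
   not exceed 4x the MAD of the subtracted plane it is inside the noise
   floor and the channel is declared empty (0 particles) — this is what
   makes a noisy but blank channel yield zero detections while a
   constant, saturated plane still errors with "threshold undefined".
4. **Watershed**: distance-transform watershed splits touching blobs.
5. **Size filter**: components outside
   `[0.25, 4] x median component area` are dropped (the window is
   derived from the image because pixel sizes vary between setups);
   border-touching particles are excluded and flagged.

Positivity in the TUNEL and EthD1 channels uses an area-overlap rule: a
nucleus is positive iff at least `overlapMin = 0.5` of its pixels fall
in the thresholded marker mask (a centroid-in-mask rule is available).
Overlap is robust to slight channel misregistration; the boundary case
(overlap exactly at the threshold) counts as positive. Classes follow
the staining logic: TUNEL⁺ only = apoptotic, EthD1⁺ only = necrotic,
double = secondary apoptotic/necrotic, neither = healthy. Rates pool the
selected optical planes (default 3, spaced evenly through the
informative depth of the stack) without tracking nucleus identity across
planes — at 10 µm plane spacing a cumulus-cell nucleus rarely appears
twice, which is a documented caveat, not a guarantee. Coordinates
throughout are R-native 1-based pixel indices, `(x, y)` = (column, row).

# Statistics

* **Contingency endpoints** (nuclear maturation, cleavage, blastocyst):
  Pearson chi-square without Yates correction (toggle available), df =
  (R−1)(C−1), expected counts below 5 flagged. Post hoc: pooled
  two-proportion z-tests, two-sided, Bonferroni-corrected. The default
  family is all pairwise group comparisons (matching column-proportion
  post hoc behavior in common commercial software); a vs-reference
  family is offered because screen reports typically compare exposed
  groups against the vehicle. A pooled proportion of 0 or 1 makes z
  undefined; such pairs fall back to Fisher's exact test, flagged.
* **Continuous endpoints** (steroid concentrations, expansion folds):
  one-way ANOVA + Tukey HSD. All-constant input is a 0/0 F statistic and
  is reported as no effect rather than letting floating-point fuzz
  fabricate an F value.
* **Rate-like endpoints with outliers** (apoptotic/necrotic rates):
  Kruskal–Wallis with tie correction, Dunn's pairwise z from mean ranks
  with tie-corrected variance, Bonferroni-adjusted — the pairwise
  procedure used by the screening literature this package serves. The
  omnibus p is asymptotic by default; `pMethod = "permutation"` gives a
  Monte-Carlo permutation p, which at small group sizes can differ
  noticeably from the chi-square approximation and is the right
  reference for exactness checks.
* α = 0.05 everywhere by default; two-sided tests; adjusted p-values are
  never below raw ones (class invariant, tested).
* Percentages are derived per group as `100*count/total`, kept at full
  precision and rounded half-up to integer percent for printed-table
  comparability.

# The synthetic-data generator

The generator defines the conditions under which the package validates
itself:

* **Oocyte scenes**: a centered spherical cell; each z-plane is the
  analytic cross-section disc, the annulus beyond 0.8 of the plane
  radius carries `trueRatio` times the center intensity (default
  `trueRatio = 1.4`, a typical vehicle-group value; center intensity
  1000 AU). Gaussian pixel noise, intensities quantized to the 16-bit
  integer grid (confocal convention; this also makes TIFF round-trips
  bit-identical). The polar body is not rendered — it does not enter the
  ratio metric.
* **Expansion pairs**: one blob per frame with low-order harmonic
  outline perturbation (`irregularity` in [0, 1]); the base radius is
  iteratively rescaled until the rasterized area is within 0.5 % of the
  request (contract: 1 %).
* **Nucleus fields**: 2-D Gaussian spots truncated at 3 sigma (sigma 3
  px, peak 10,000 AU over a 2,000 AU background, optional linear
  gradient) — truncation keeps area and centroid analytically known.
  Default frame 512 px and ~200–300 nuclei visually match a mid-COC
  optical section; both are user-overridable since nucleus density and
  COC diameter in pixels are setup-dependent. Rejection-sampled centers
  honor `minSepPx` (default 4 sigma); `minSepPx = 0` plus explicit
  centers builds the touching-nuclei watershed stress case. SNR is
  peak/noiseSd; recovery tests run at SNR 5.
* **Outcome tables**: one multinomial draw per group; steroid tables are
  normal truncated at zero with defaults set to the
  pregnenolone/progesterone effect sizes a positive screen must detect
  (vehicle 2.79 ± 0.28 and 6.40 ± 0.47 ng/ml vs high-dose 7.30 ± 0.89
  and 11.20 ± 0.86 ng/ml, n = 3 replicates).
* **Determinism**: every generator takes a seed and restores the
  caller's RNG state; the pipeline derives per-scene sub-seeds from one
  root seed, so reruns are bit-identical.

What the generator does **not** emulate: irregular nucleus shapes,
optical PSF and z-blur, cumulus-cell migration, autofluorescence
texture, chromatic misregistration. Passing recovery tests therefore
demonstrates correctness of the measurement logic under controlled
conditions, not performance on real micrographs; thresholds and size
windows will need adjustment per imaging setup, which is why every one
of them is exposed in the run configuration.

# Problem sizes used in validation

The test suite validates ratio recovery on 100-seed ensembles at radii
of 60 px for true ratios 1.0, 1.4 and 3.0 (noiseless tolerance 5 %,
noisy ensemble mean within 0.1); nucleus-rate recovery on a 227-nucleus
field at SNR 5 (precision/recall at least 0.95, rates within 0.01);
chi-square calibration on 2,000 null multinomial tables of 90
observations per group (rejection rate within 5 % ± 1.5 %); the
Kruskal–Wallis permutation check on 100,000 permutations; and
ANOVA+Tukey power across 500 simulated steroid tables. These sizes are
the package's validation conditions and are fixed in the tests.

# Known limitations

* Segmentation assumes one dominant cell/COC per frame; debris larger
  than the object of interest will defeat the largest-component rule.
* Low relative peripheral intensity (cortex dimmer than center) can bias
  the Otsu cell outline toward the bright center; the endpoint of
  interest (ratio ≥ 1) is unaffected, but strongly inverted patterns
  are better segmented on a counterstain.
* Pooling planes without identity tracking slightly overweights nuclei
  that span two planes.
* The chi-square and z-test asymptotics degrade with expected counts
  below 5; cells are flagged but the tests are still computed.
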