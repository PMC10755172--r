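---
title: "Methods: kernel color phenotyping and genetic analysis of pericarp pigmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kernel color phenotyping and genetic analysis of pericarp pigmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pericolor)
```

## The problem

Commercial dent maize is bred for clear pericarp, yet biparental doubled
haploid (DH) populations derived from clear-pericarp parents can throw
transgressive segregants with brown pigmented pericarp (phlobaphene
accumulation, classically governed by the *P1* R2R3-Myb locus and its
epistatic partners). `pericolor` implements the full analysis chain for
studying this phenotype: quantify pigmentation as hue from flatbed kernel
scans, test qualitative segregation models, estimate line BLUEs and a
generalized heritability, and map QTL in DH populations. Because the
original scans and genotypes are not redistributable, a first-class
synthetic-data module generates both with known ground truth; every
downstream stage is validated against that truth.

## Image phenotyping

### What the scan generator emulates, and what it does not

`generate_kernel_scan()` renders ovoid kernels (pointed tip, blunt base,
a lighter yellow "cap" band at the basal end where endosperm shows
through, and a slightly darker tip zone) on a near-black scanner
background, with optional touching pairs, small debris blobs, chipped
(notched) kernels, a linear illumination gradient, and additive pixel
noise. The recorded truth is exact: per-kernel placement, pixel masks,
and the hue of the rendered 8-bit body color (quantization moves the
achieved hue slightly off the requested target, so truth records the
achieved value).

It does **not** model specular highlights, shadows cast by kernel
relief, embryo-face/germ-face differences, within-kernel pigment
gradients, or scanner color calibration. Tests passing on these images
therefore validate the algorithmic chain (thresholding, morphology,
landmarking, QC, aggregation), not robustness to every artifact of real
scans.

Defaults are chosen to mimic the study's imaging: ~50-80 kernels per
scan, kernel bodies bright enough that mean-RGB luminance clears the 0.4
floor, per-kernel hue spread of ~2 degrees around the line's hue.

### Segmentation

The image is converted to luminance as the plain mean of R, G and B
scaled to [0, 1]; the source toolkit says only "grayscale", and the
unweighted mean matches its behavior closely enough. Thresholding fits
an illumination trend (luminance ~ x + y) on a random subsample of 3,000
pixels and then takes a global Otsu threshold on the trend-corrected
residuals; the threshold surface is the fitted plane plus that offset. A
constant image has no Otsu solution and falls back to the plane with a
degenerate flag. The subsample is seeded (default 0) so the surface is
reproducible.

The binary foreground is the **intersection** of two criteria: luminance
above the fixed 0.4 floor *and* above the trend surface. The source
procedure applies both a fixed floor and a fitted threshold without
stating their combination; the intersection is the interpretation used
here (flagged as interpretive).

Cleaning uses three morphological steps with sizes 1 / 7 / 5 — an
opening that removes speckles, a closing plus hull fill that closes
holes, and a final opening that removes debris. The magnitudes originate
as pixel arguments of a specific toolkit; here a "size k" step uses a
disc structuring element of diameter 2k + 1, which preserves the intent
(remove <= 1 px speckles, fill <= 7 px holes, drop <= 5 px debris) while
decoupling from that toolkit.

Touching kernels are split by distance-transform watershed before
labeling. Components are labeled with `EBImage::bwlabel()`, which is
4-connected; the connectivity is recorded in the `labeled_mask` object.
(8-connectivity was considered; on cleaned kernel-scale masks the two
conventions give identical counts, and the established labeller was
preferred over a hand-rolled 8-connected one.)

### Landmarks and the sampling region

The contour is traced at pixel resolution; kernels with fewer than 100
contour points are removed. The tip/base pair is the contour diameter
(maximal pairwise distance), found on the convex hull and tie-broken by
lowest contour index. Kernel length is that distance.

Which endpoint is the *base* is not derivable from distance alone. The
rule used here: the endpoint whose 15% axial band is more yellow
(higher R + G - 2B) is the base, since the base carries the yellow
endosperm cap; when color is uninformative the blunter end (larger end
band area) is the base. Both rules are interpretive and the choice is
recorded per kernel.

The width search scans all contour points, requires the angle
tip-center-point to be within 90 +/- 5 degrees, and takes the candidate
closest to exactly 90 degrees; the chord is extended through the center
to the opposite contour intersection. Kernels with no admissible
candidate are flagged "width unobtainable" and removed.

The color-sampling region keeps pixels whose normalized position along
the tip-to-base axis lies in [0.30, 0.85]: 30% is cut above the tip and
15% below the base, excluding the tip pigment concentration and the
yellow cap. One figure caption in the source describes the tip cut as
the "upper third"; the methods text's 30% governs here, and both cuts
are configurable.

### Quality control and hue

Per image, kernels outside 1.5 x IQR fences on the length:width ratio
are removed (zero IQR passes everything; fewer than 4 kernels skips the
filter with a warning). Pooled across lines, kernels outside 1.5 x IQR
fences on any of mean R, G, B are removed. The source text says a
"1.5% IQR" for the color filter; that is read as the same 1.5 x IQR
fence used for shape, treating the percent sign as typographical
(interpretive, multiplier configurable).

Hue is the standard RGB-to-HSV hue of the *mean* region RGB, scaled to
degrees (`grDevices::rgb2hsv`, the same base-R routine the original
analysis used; the test suite checks it against an independently coded
sector formula). Achromatic input returns 0 degrees with a flag.
Arithmetic (not circular) means are used throughout: pericarp hues live
in roughly 24-42 degrees, far from the 0/360 wrap, so circular
statistics would change nothing; this is a documented limitation should
the pipeline be reused for hues near the wrap. Per-image hue is the mean
over retained kernels, and the line x replicate phenotype is the mean
over the plot's images, which is what the replicate-level mixed model
below expects.

The binary pigmented/clear class is an input scored by eye in the
original study; `classify_pigment()` is a threshold-on-hue helper for
simulations and is never silently substituted.

## Qualitative inheritance

In a DH population every locus is homozygous with the two parental
alleles at 1:1, so L unlinked loci give 2^L equiprobable classes.
`dh_expected_proportion()` enumerates them exactly; the six candidate
models (1:1, 3:1, 1:3, 1:7, 5:3, 3:5) are declarative boolean pigment
logics over one to three loci. "Two additive genes 3:1" is modeled as
"A | B" — either functional locus pigments — which reproduces the 3:1 DH
ratio; the historical "additive" label is kept as an alias.

Observed counts are tested by Pearson chi-square goodness of fit with
1 df and **no** continuity correction (the one-way `chisq.test()` form
applies none, and the printed p-values of the source confirm it). The
best model is the one with the maximal p-value — the source says "best
fit" without a rule, so this is an explicit choice; all six p-values are
always reported and ties within 1e-6 are reported jointly. The source
reports 462 pigmented lines in its quantitative section while its
count table sums to 498; the discrepancy is noted and not resolved here
(the counts table is taken as the input).

## BLUEs and heritability

The replicate-level model is hue = line (fixed) + replicate (random) +
residual, fitted by REML (`lme4::lmer`). Lines harvested in only one
replicate are kept; the unbalanced fit handles them. `avsed` is computed
as the mean over all line pairs of sqrt(var(g_i - g_j)) from the
fixed-effect covariance — the all-pairs definition, since the original
tool's extractor is not further specified. The line variance needed by
the Cullis formula is not identified with lines fixed, so it comes from
the companion model with line random on the same data.

Cullis heritability is h2 = 1 - avsed^2 / (2 sigma_g2). It is 1 exactly
when avsed = 0 and undefined at sigma_g2 = 0 (an explicit error).

Tukey letter groups use `multcomp::glht`/`cld` on the studentized range
at a 5% experiment-wise rate; population x glume-class contrasts are
expressed as letters on the crossed factor rather than a separate
operation. Spearman validation against 1-5 visual ratings uses midranks
and is expected negative (darker = lower hue = higher rating).

The design-scale simulation behind the heritability check uses 1,327
lines, two replicates with 33% of lines in both, sigma_g2 = 6.5,
sigma_rep2 = 0.3, sigma_e2 = 0.8 (degrees^2). These are the package's
realistic choices for this trait: line SD ~2.5 degrees matches a BLUE
range of roughly 24-42 degrees, and the replicate/residual components
are small relative to it, as the high reported heritabilities imply.

## QTL scan

Genotype QC drops markers with > 75% missing data or MAF < 5% (and
monomorphic ones), then individuals with > 200 apparent crossovers or
> 15% missing data, in that order, with every removal logged.

Genotype probabilities come from a two-state (parental origin A/B)
forward-backward HMM per individual per chromosome: transitions from
map distances via the Haldane map function (the source maps on physical
positions without stating a map function; Haldane is the simplest
standard choice, and a configurable cM/Mbp conversion — default 1 —
covers physical maps), symmetric genotyping-error emission at rate
0.002 by default (the source is silent; 0.2% is common DH practice),
and uninformative emission at missing calls. The test suite checks the
posteriors against exact enumeration over hidden paths.

The scan regresses the phenotype on P(A) at each marker (Haley-Knott);
LOD = (n/2) log10(RSS0/RSS1). Scanning is at marker positions only (no
pseudomarker grid), matching marker-resolution peak reporting.
Numerically perfect fits are capped at LOD 50 and flagged.

Significance uses genome-wide permutations (default 1,000, seeded,
not stratified by chromosome): the threshold is the 95th percentile of
the permuted genome-wide maximum LOD. Peaks at or above the threshold
get a 95% Bayesian credible interval — the smallest contiguous region
around the peak holding 95% of the chromosome's normalized 10^LOD mass;
a LOD-drop interval (default 1.5) is also available. The source's
"drop = 5" argument conflates the two interval types; Bayes-95% is the
default here and the discrepancy is documented.

The allele effect at a peak treats the genotype-class effect as random
(REML), shrinking the A-vs-B contrast toward zero relative to OLS.
Individuals are classed by their most probable origin at the peak. Sign
convention: negative = the allele lowers hue (darker pericarp); the
donor parent is the one contributing the negative allele. LD is the
squared Pearson correlation of dosage vectors (pairwise-complete), and
variance explained by a marker is the adjusted R^2 of BLUEs on dosage.

For a binary 0/1 trait (cob-glume pigment) the same LOD machinery is
accepted, with the caveat that Gaussian-model LOD scores on a binary
trait are approximate.

## Numerical choices and degenerate inputs

- Seeds: every stochastic operation takes an explicit seed; the
  pipeline derives stage seeds from one run seed, so identical
  config + seed gives byte-identical outputs.
- Ties: contour-diameter ties break to the lowest contour index; model
  ties (p within 1e-6) are reported jointly; the width search minimizes
  |angle - 90| deterministically.
- Degenerate inputs: constant images flag a degenerate threshold;
  empty masks are valid (zero components); single-replicate data fall
  back to flagged line means; sigma_g2 = 0 or constant ratings/dosage
  are explicit errors or NA with a warning, never silent.
- LOD cap 50 for perfect fits preserves peak ranking without
  infinities.

## Problem sizes used by the checks

The validation suite sizes its simulations to the study's conditions:
100 seeded 12-kernel scans for the component count; realistic 55-kernel
scans (20% damaged, touching pairs, debris, gradient) for the 5-35%
removal band; 50-kernel scans for 0.5-degree line-hue recovery; 100
populations of n = 150 with a 2-degree QTL on a 3 x 80-marker map for
position/effect/coverage; 200 null populations with 1,000-permutation
thresholds for the 5% type-I check; and one 1,327-line trial for the
heritability band. The acceptance script recomputes the same quantities
at moderately smaller replicate counts.

## Known limitations

- No spatial field-trend correction (none used in the source design).
- No multi-QTL or epistasis scans; single-QTL Haley-Knott only.
- No linked-loci segregation models (the qualitative models assume
  independent assortment).
- Arithmetic hue means assume hues far from the 0/360 wrap.
- The synthetic scans are a geometric idealization; see above for what
  they do not model.
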