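---
title: "Models and methods behind scmeio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scmeio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`scmeio` analyzes synaptonemal complex (SC) length and crossover number in
F2 intercrosses. This vignette documents the models the package fits, the
defaults and why they were chosen, what the synthetic-data generator does
and does not emulate, and the numerical decisions a maintainer should know
about.

## Image morphometry

A spermatocyte spread stained for SYCP3 is reduced to a one-pixel-wide
wireframe whose pixel count, scaled by μm per pixel, is the total SC
length. The pipeline order is fixed:

1. **Channel isolation and balancing.** The SYCP3 channel (red, for RGB
   captures) is extracted and min–max normalized to [0, 1]. Balancing is
   per image; absolute intensity therefore carries no information, only
   contrast does.
2. **Morphological gradient** with a disk structuring element, default
   radius 3 (7×7 support). The disk radius must reach the strand
   half-width: the gradient of a blurred strand is near zero along its
   centerline, and a sub-strand disk produces two thin parallel edge
   rings instead of one solid band. During development we verified that a
   radius-1 disk makes the downstream cleanup erase the entire signal on
   every synthetic spread, at any strand thickness; radius 3 produces a
   solid band over strands up to ~6 px wide and is the package default.
3. **Otsu threshold** on the full gradient image, no pre-masking. With a
   mostly-background histogram Otsu lands between the noise-gradient and
   the edge-gradient modes.
4. **Opening then closing** with a 4×4 square element. Opening removes
   speckle smaller than the element; closing then fills the interior of
   the band (including the low-gradient centerline valley). The order is
   deliberate and not interchangeable: closing first would weld noise
   into the band before opening could remove it.
5. **Zhang–Suen skeletonization** to a single-pixel, 8-connected medial
   line, and the pixel count × scale as the length.

The pixel count is a *Chebyshev-type* length: a digital line at 45°
counts 1 px per √2 px of Euclidean length. The package replicates this
bias (it is part of the canonical measurement) and exposes a
non-canonical `corrected_geodesic` metric (diagonal steps weighted √2)
behind `morph_params(metric=)` for users who want Euclidean lengths. On
rendered spreads with the default geometry, the canonical pixel count
lands within ~3% of the true arc length: the diagonal undercount and the
small overcount from band-edge roughness and end caps largely cancel.
This cancellation is a property of the default geometry (3 px strands,
1 px blur), not a theorem; the acceptance suite pins it at 5%.

No border-object removal or size filter beyond the opening is applied,
and no masking precedes Otsu — curation of defective images is the
caller's job, as it was in the source protocol.

## Phenotype aggregation

Per individual: mean SC length over cells, mean MLH1 count over cells
with a non-missing count (the two assays can fail independently), the
SC/CO ratio defined as mean SC / mean CO (μm per focus), within-individual
CVs, and the number of cells, which becomes the regression weight.
Individuals with fewer than 5 cells are dropped (`min_cells`). The
per-cell ratio averaged over cells is *not* the default; the mean/mean
definition follows the phrase "ratio of mean SC length to mean MLH1
count" used in the field.

## QTL scans

Genotype probabilities come from a forward–backward pass over each
chromosome with Haldane transitions, `r(d) = (1 − e^(−2d/100))/2`.
Autosomal F2 transitions are the product of two independent gamete
chains; the male X is a two-state chain (the single X comes from the
heterozygous F1 dam). Pseudomarkers are inserted on a 1 cM grid by
default. Genotyping error defaults to 0 (synthetic data are error-free)
and is configurable.

Haley–Knott regression at each position: weighted least squares of the
phenotype on intercept, additive covariates, the additive dosage
`P(BB) − P(AA)` and the dominance expectation `P(AB)` (on the X, the
single contrast `P(BY) − P(AY)`, so the "additive effect" is half the
hemizygous class difference and comparable to autosomal effects).
`LOD = (n/2)·log10(RSS0/RSS1)`. Weights are the spermatocyte counts;
cross direction enters as an additive covariate.

**Permutations.** Phenotype rows travel with their weights and
covariates; shuffling them against the genotypes preserves the
phenotype–covariate association under the null of no linkage. (The
alternative — permuting the phenotype alone — breaks that pairing; both
are defensible, this package implements the paired version.) The
threshold is the `⌈(1 − α)·n_perm⌉`-th order statistic of the genome-wide
maximum LOD, a single threshold including the X. Internally the
permutation scan uses a vectorized projection identity (the null-model
projection is constant across replicates, so each position's LOD is a
rank-2 quadratic-form update); a test pins it to the reference
regression path at 10⁻⁹.

**Support intervals.** The 1.5-LOD interval spans the outermost evaluated
positions with `LOD ≥ peak − drop`. An endpoint strictly above the cut is
extended one grid point outward (the true crossing lies beyond it); an
endpoint exactly at the cut is taken as-is. Mb bounds are linear
interpolations between flanking markers.

**Multiple-QTL fits.** All detected loci enter one weighted regression;
per-QTL percent variance is `100·(RSS_without − RSS_full)/TSS` from
dropping that QTL's terms. Loci closer than 1 cM are refused as
unidentifiable. Stepwise model search and epistasis scans are
deliberately not implemented; the multi-QTL fit takes user-specified
positions.

## Mediation analysis

At a focal locus, for the direction "outcome mediated by mediator":

- Model A (unmediated): outcome ~ its multiple-QTL model → β at the locus
  (the additive contrast only; dominance terms stay in the model but are
  not tested).
- Model B (mediated): same + mediator covariate → β′ and α.
- Model C: mediator ~ the same QTL design → the QTL→mediator path and its
  variance.

Sobel: `t = αβ/√(α²σ²_β + β²σ²_α)` against the standard normal,
two-tailed. The empirical null permutes the mediator column across
individuals (weights and covariates stay put) and recomputes **both**
mediator-dependent regressions per replicate, so α and β in the numerator
are self-consistent; `p = (1 + #{|t*| ≥ |t|})/(1 + n_perm)`, which keeps
p ≥ 1/(n_perm+1).

Proportion mediated `f = (β − β′)/β`, with a first-order delta-method SE
that includes cov(β̂, β̂′): both estimators are linear functionals of the
same outcome vector, so the covariance is computed exactly from the two
design matrices and the mediated model's σ². Ignoring that covariance
(the independence shortcut) overstates SE_f; a bootstrap comparison in
the test suite keeps the delta SE within [0.7, 1.4] of a case-resampling
SE.

**Sensitivity to measurement error.** SC length is harder to measure than
focus counts. The sensitivity analysis equalizes the expected
within-individual CV of the two traits by adding cell-level Gaussian
noise to the less noisy trait (added variance per individual
`(mean·CV_target)² − s²`, floored at 0), re-aggregates, and refits; the
spread of `f` across replicates is compared with its regression SE.

## The synthetic-data generator

The generator is the package's ground-truth oracle, not a visual
simulator.

**Images.** Axes are unit-step random walks with a curvature bound
(turning radius ≥ 3× strand thickness — sharp kinks would break skeleton
topology), placed with a minimum centerline separation (default
`2·(thickness + blur) + 8` px, the extra 8 keeping the measurement
gradient bands of neighbors from fusing), drawn at the configured
thickness, Gaussian-blurred and noised. Exact per-axis arc and Chebyshev
lengths are recorded before rasterization. Defaults: 1030×1300 px frames,
20 axes of 80–165 px at 0.065 μm/px, so a default spread totals ≈160 μm —
a plausible calibration for a 100× objective; the true scale of the
source images was never published, so the scale is configurable and only
multiplies the output. Not emulated: MLH1 foci, nucleus-shaped background
gradients, touching/crossing bivalents (available via `allow_overlap`,
where pixel counting undercounts at intersections), and stage
classification. Passing tests therefore certify the geometry pipeline,
not robustness to real-world staining artifacts.

**Crosses.** Gametes recombine without interference (Haldane), matching
the scan's map function — internal consistency was preferred over
realism, since crossover interference affects gametes but not the stated
analysis. Phenotypes: individual latent values (intercept + QTL effects +
mediation chain + covariate + individual noise), then cell-level Gaussian
noise; crossover counts are rounded Gaussians rather than Poisson because
MLH1 counts are underdispersed under interference, with the SD free.
Defaults were calibrated once against published F2 summary statistics
(cell-level SD ≈18.7 μm and 3.3 foci; individual-mean SD ≈9.7 μm and 2.6
foci; median 18 cells per individual): SC intercept 159 μm, individual SD
9, cell SD 15; CO intercept 25, individual SD 2.4, cell SD 2.2. The
sources do not publish per-cell variances, so these reproduce the printed
spreads approximately, not exactly.

## Numerical choices and degenerate inputs

- Constant phenotype → RSS0 numerically zero → LOD defined as 0
  everywhere (threshold `1e-12·(Σwy² + 1)`).
- Singular genotype designs (collinear dosage/covariate) flag the
  position with `lod = NA` rather than failing the scan.
- Blank images (zero gradient) measure 0 μm with an empty skeleton, by
  contract not by error.
- Peak ties break toward the lowest cM position.
- Otsu uses 256 histogram levels on the min–max-normalized gradient.
- All generators and permutation engines take explicit integer seeds and
  are bit-reproducible; seeds are recorded in pipeline output metadata.
- Structuring elements: the gradient disk is parameterized by radius
  (`gradient_width = 3` ⇒ 7×7 support), the cleanup square by side
  (4×4, anchored at `floor(side/2)` with reflected-element dilation so
  opening/closing are proper adjunctions at even sizes).

## Problem sizes used in validation

The acceptance suite runs 50 rendered spreads (640² px, 20 axes) for
measurement recovery; 100 null genomes × 100 permutations for threshold
calibration plus 100 localization replicates; and, for mediation, 200
recovery replicates at n = 250, 300 null datasets × 200 permutations for
p-value uniformity, and a 100-replicate sensitivity run. These sizes give
Monte-Carlo error comfortably inside the asserted tolerances while
keeping the default suite fast on a single CPU.

## Known limitations

- The pixel-count metric inherits the √2 diagonal bias of the canonical
  algorithm; compare only against measurements made the same way, or use
  the corrected metric consciously.
- Total SC length only — no per-chromosome axis separation or karyotyping
  of the 20 bivalents.
- The mediation machinery handles a single mediator and reports both
  directions; it is not a causal-discovery tool, and with overlapping
  QTL of both traits the direction labels encode model choice, not proof
  of temporal order.
- The X-chromosome scan assumes all phenotyped individuals are male
  (hemizygous two-class model); no X-specific permutation threshold is
  used, matching the single genome-wide threshold convention.
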