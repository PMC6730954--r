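# scmeio

Genetic analysis of synaptonemal complex (SC) length variation in mouse
F2 intercrosses: automated SC morphometry from immunofluorescent
spermatocyte spreads, quantitative-trait-locus (QTL) mapping of SC length
and crossover number, and causal mediation analysis of pleiotropic loci.

## What the package does, and for whom

The SC is the protein scaffold that holds homologous chromosomes together
during meiotic prophase; its total axis length covaries with the
genome-wide crossover number (counted as MLH1 foci). `scmeio` is aimed at
meiosis and recombination geneticists who want to map the loci behind
natural variation in these traits. It provides the full analysis chain:

1. **Morphometry** — each SYCP3-stained spread is reduced to a
   single-pixel wireframe: min–max balancing, morphological gradient
   (disk element), Otsu threshold, opening + closing cleanup (4 px square
   element), Zhang–Suen skeletonization. Total SC length is the skeleton
   pixel count times the μm-per-pixel scale.
2. **Phenotypes** — cell-level records are aggregated per individual
   (mean SC length, mean MLH1 count, SC/CO ratio in μm per focus), with a
   minimum-cells filter (default 5) and cell counts carried as regression
   weights.
3. **QTL mapping** — weighted Haley–Knott regression on conditional
   genotype expectations from a hidden-Markov model with Haldane
   transitions (two-state chain on the male X). At each position the LOD
   score is `(n/2)·log10(RSS0/RSS1)`. Genome-wide thresholds come from
   permutations (phenotype rows, with weights and covariates attached,
   shuffled against genotypes); QTL get 1.5-LOD support intervals and
   multiple-QTL percent-variance decompositions.
4. **Mediation** — for a pleiotropic locus, paired models per direction:
   `Y = β0 + β·X_QTL + ε` (unmediated) and
   `Y = β0 + β′·X_QTL + α·X_med + ε` (mediated), fitted inside the
   trait's multiple-QTL model. The Sobel statistic `t = αβ/√(α²σ²_β +
   β²σ²_α)` is tested analytically (standard normal) and by permuting the
   mediator across individuals; the proportion mediated is
   `f = (β − β′)/β` with a delta-method SE.
5. **Synthetic data** — spread images built from curvature-bounded random
   axes with exact arc-length ground truth, and simulated crosses
   (Haldane recombination, additive/dominance QTL, a configurable
   QTL → crossover → SC-length mediation chain, two-level noise), so every
   stage is testable without any external data.

## Worked example

A fully synthetic experiment: 250 F2 males on a three-chromosome map, one
locus on chromosome 1 acting on SC length directly (effect 3 μm) and
through crossover number (effect 2.5 foci, 2 μm per focus):

```r
library(scmeio)

map <- genetic_map(c("1" = 60, "2" = 60, "X" = 50), marker_spacing_cM = 10)
synth <- sim_cross_config(map = map, n_individuals = 250,
                          mediation = list(chr = "1", pos = 30,
                                           qtl_to_mediator = 2.5,
                                           alpha = 2, direct = 3),
                          seed = 17)
cfg <- pipeline_config(synthetic = synth, n_perm = 100, step_cM = 5,
                       mediation_n_perm = 1000, seed = 17)
res <- run_pipeline(cfg)

scan_peak(res$scans$mean_sc_um)
#>   chr pos      lod
#> 7   1  30 10.07728
res$thresholds$mean_sc_um
#> genome-wide LOD threshold 3.142 (alpha = 0.05, 100 permutations)
lod_support_interval(res$scans$mean_sc_um, "1", map = map)
#>   chr peak_pos peak_lod lo hi lo_mb hi_mb peak_mb
#> 1   1       30 10.07728 20 40    40    80      60
res$mediation[["1:30@peak_mean_sc_um"]]$t1_mediated_by_t2
#> mediation at 1:30 cM (n = 248)
#>   beta = 7.077, beta' = 2.127, alpha = 2.042
#>   Sobel t = 6.224, analytic p = 4.83e-10, empirical p = 0.000999
#>   f = 0.70 +- 0.13
```

Reading the output: the scan finds the simulated locus exactly at 30 cM
(LOD 10.1 against a genome-wide 5% threshold of 3.1), with a 1.5-LOD
support interval of 20–40 cM. The mediation fit recovers the generative
coefficients — total additive effect β ≈ 7.1 μm (truth 3 + 2×2.5 = 8),
direct effect β′ ≈ 2.1 (truth 3), mediator coefficient α ≈ 2.0 μm per
focus (truth 2) — and estimates that 70% ± 13% of the locus's effect on
SC length is transmitted through crossover number (generative truth
0.625), significant by both the analytic Sobel test and 1000 mediator
permutations.

Image morphometry runs the same way from rasters or files:

```r
cfg_img <- synth_image_config(seed = 1)        # 1030x1300 px, 20 axes
spread <- render_spermatocyte_image(cfg_img)
measure_sc_length(spread$image)                # vs attr(spread$truth, "total_um")
batch_measure("path/to/tiffs", scale_um_per_px = 0.065)
```

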