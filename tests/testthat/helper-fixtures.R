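# Shared fixtures and independent oracles for the test suite.

# Small mouse-like map for fast scans.
test_map <- function(chrs = c("1" = 100, "2" = 80, "X" = 70), spacing = 10) {
  genetic_map(chrs, marker_spacing_cM = spacing)
}

# A cached simulated cross with one additive SC QTL, reused across tests.
.fixture_env <- new.env(parent = emptyenv())

qtl_fixture <- function() {
  if (is.null(.fixture_env$qtl)) {
    map <- test_map()
    qtl <- data.frame(trait = "sc", chr = "1", pos = 50, a = 6, d = 0)
    cfg <- sim_cross_config(map = map, n_individuals = 300, qtl = qtl, seed = 11)
    cross <- simulate_f2_genotypes(cfg)
    records <- simulate_phenotypes(cross, cfg)
    phenos <- aggregate_phenotypes(records, quiet = TRUE)
    ids <- rownames(cross$geno)
    m <- match(ids, phenos$individual_id)
    .fixture_env$qtl <- list(
      map = map, cfg = cfg, cross = cross, records = records,
      phenos = phenos,
      sc = phenos$mean_sc_um[m], co = phenos$mean_co[m],
      weights = phenos$n_cells[m], covar = cross$covar$cross_direction,
      probs = genotype_probabilities(cross, step_cM = 2)
    )
  }
  .fixture_env$qtl
}

# A cached mediation-chain cross (QTL -> CO -> SC).
mediation_fixture <- function() {
  if (is.null(.fixture_env$med)) {
    map <- genetic_map(c("1" = 100, "2" = 80), marker_spacing_cM = 10)
    med <- list(chr = "1", pos = 50, qtl_to_mediator = 1.0, alpha = 1.5,
                direct = 0.5)
    cfg <- sim_cross_config(map = map, n_individuals = 300, mediation = med,
                            sc_individual_sd = 2, co_individual_sd = 1,
                            sc_cell_sd = 3, co_cell_sd = 1, seed = 5)
    cross <- simulate_f2_genotypes(cfg)
    records <- simulate_phenotypes(cross, cfg)
    phenos <- aggregate_phenotypes(records, quiet = TRUE)
    ids <- rownames(cross$geno)
    m <- match(ids, phenos$individual_id)
    .fixture_env$med <- list(
      map = map, cfg = cfg, med = med, cross = cross, records = records,
      phenos = phenos,
      sc = phenos$mean_sc_um[m], co = phenos$mean_co[m],
      weights = phenos$n_cells[m],
      probs = genotype_probabilities(cross, step_cM = 0),
      locus = c(chr = "1", pos = 50),
      qtl = data.frame(chr = "1", pos = 50)
    )
  }
  .fixture_env$med
}

# Brute-force oracle: P(genotype at an interior position | flanking
# genotypes) for an F2 autosome, by exhaustive enumeration over the two
# independent gamete chains under Haldane recombination.
enum_f2_interior_prob <- function(gL, gR, d1, d2) {
  r1 <- haldane_r(d1); r2 <- haldane_r(d2)
  gam <- function(a, b, r) if (a == b) 1 - r else r
  # gamete-level allele pairs consistent with a genotype code
  alleles <- list(AA = list(c(0, 0)), BB = list(c(1, 1)),
                  AB = list(c(0, 1), c(1, 0)))
  post <- c(AA = 0, AB = 0, BB = 0)
  for (aL in alleles[[gL]]) for (aR in alleles[[gR]]) {
    for (m1 in 0:1) for (m2 in 0:1) {
      w <- gam(aL[1], m1, r1) * gam(m1, aR[1], r2) *
        gam(aL[2], m2, r1) * gam(m2, aR[2], r2)
      g <- m1 + m2 + 1
      post[g] <- post[g] + w / (length(alleles[[gL]]) * length(alleles[[gR]]))
    }
  }
  post / sum(post)
}

# Brute-force weighted least-squares LOD at one position, by explicit
# normal equations (independent of the scan implementation).
brute_force_lod <- function(X1, X0, y, w) {
  rss <- function(X) {
    b <- solve(crossprod(X * w, X), crossprod(X * w, y))
    sum(w * (y - X %*% b)^2)
  }
  (length(y) / 2) * log10(rss(X0) / rss(X1))
}
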