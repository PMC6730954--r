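# Synthetic cross generator: Haldane recombination, Mendelian ratios,
# phenotype moments, mediation-chain path coefficients, noise ops.

test_that("gamete simulation matches Haldane closed forms", {
  withr_seed <- function(s, code) scmeio:::with_seed(s, code)
  # zero distance forces co-inheritance
  g0 <- withr_seed(1, scmeio:::sim_gametes(200, c(0, 0)))
  expect_identical(g0[, 1], g0[, 2])
  # recombinant fractions at several distances within 3 binomial SE
  n <- 10000
  for (d in c(1, 10, 20, 50)) {
    g <- withr_seed(d, scmeio:::sim_gametes(n, c(0, d)))
    obs <- mean(g[, 1] != g[, 2])
    r <- haldane_r(d)
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / n) + 1e-12,
              label = sprintf("recombinant fraction at %g cM", d))
  }
})

test_that("F2 genotypes segregate 1:2:1 and male X is hemizygous", {
  map <- genetic_map(c("1" = 40, X = 40), marker_spacing_cM = 20)
  cfg <- sim_cross_config(map = map, n_individuals = 10000, seed = 7)
  cross <- simulate_f2_genotypes(cfg)
  counts <- table(factor(cross$geno[, "c1m1"], levels = c("AA", "AB", "BB")))
  p <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
  x_codes <- unique(as.vector(cross$geno[, map$marker[map$chr == "X"]]))
  expect_true(all(x_codes %in% c("AY", "BY")))
})

test_that("generators are reproducible and validate their inputs", {
  cfg <- sim_cross_config(map = test_map(), n_individuals = 40, seed = 3)
  c1 <- simulate_f2_genotypes(cfg)
  c2 <- simulate_f2_genotypes(cfg)
  expect_identical(c1$geno, c2$geno)
  r1 <- simulate_phenotypes(c1, cfg)
  r2 <- simulate_phenotypes(c2, cfg)
  expect_identical(r1, r2)
  bad_map <- test_map()
  bad_map$pos[2] <- bad_map$pos[1]  # non-increasing
  expect_error(sim_cross_config(map = bad_map), "strictly increasing")
  expect_error(sim_cross_config(map = test_map(), sc_cell_sd = -1), ">= 0")
})

test_that("phenotype generator is mean/variance faithful for QTL effects", {
  map <- genetic_map(c("1" = 60), marker_spacing_cM = 20)
  qtl <- data.frame(trait = "sc", chr = "1", pos = 20, a = 0.5, d = 0.3)
  cfg <- sim_cross_config(map = map, n_individuals = 2000, qtl = qtl,
                          sc_intercept = 0, sc_individual_sd = 1,
                          sc_cell_sd = 0.1, seed = 21)
  cross <- simulate_f2_genotypes(cfg)
  rec <- simulate_phenotypes(cross, cfg)
  lat <- attr(rec, "latent")$latent_sc
  # additive variance a^2/2 + dominance variance d^2/4 + individual noise
  expect_equal(mean(lat), 0.3 / 2, tolerance = 0.12)  # mean shifts by d/2
  v_expect <- 0.5^2 / 2 + 0.3^2 / 4 + 1
  expect_equal(stats::var(lat), v_expect, tolerance = 0.1)
})

test_that("mediation chain reproduces path-traced regression coefficients", {
  fx <- mediation_fixture()
  lat <- attr(fx$records, "latent")
  xa <- scmeio:::locus_dosage(fx$cross, "1", 50)$xa
  # independent oracle: plain least squares on the latent traits
  m1 <- stats::lm(lat$latent_sc ~ xa)
  m3 <- stats::lm(lat$latent_sc ~ xa + lat$latent_co)
  total <- fx$med$direct + fx$med$alpha * fx$med$qtl_to_mediator
  expect_lt(abs(stats::coef(m1)[["xa"]] - total),
            2 * summary(m1)$coefficients["xa", 2] + 0.15)
  expect_lt(abs(stats::coef(m3)[["xa"]] - fx$med$direct),
            2 * summary(m3)$coefficients["xa", 2] + 0.05)
})

test_that("cell counts follow the configured distribution", {
  fx <- qtl_fixture()
  lat <- attr(fx$records, "latent")
  expect_equal(stats::median(lat$n_cells), 18)
  expect_true(all(table(fx$records$individual_id) == lat$n_cells))
})

test_that("cellwise noise: identity at sd 0, determinism, CV targeting", {
  fx <- qtl_fixture()
  expect_identical(add_cellwise_gaussian_noise(fx$records, sd = 0, seed = 1),
                   fx$records)
  n1 <- add_cellwise_gaussian_noise(fx$records, sd = 2, seed = 9)
  n2 <- add_cellwise_gaussian_noise(fx$records, sd = 2, seed = 9)
  expect_identical(n1, n2)
  # variance-addition identity: mean 100, within SD 5, target CV 0.10
  # -> added variance 100^2 * 0.01 - 25 = 75
  set.seed(42)
  nrec <- 100000
  rec <- data.frame(individual_id = "a", cell_id = seq_len(nrec),
                    sc_length_um = rnorm(nrec, 100, 5))
  sds <- scmeio:::noise_sd_for_target_cv(rec$sc_length_um,
                                         rec$individual_id, 0.10)
  expect_equal(unique(round(sds^2, 4)),
               (mean(rec$sc_length_um) * 0.1)^2 - stats::var(rec$sc_length_um),
               tolerance = 1e-6)
  noised <- add_cellwise_gaussian_noise(rec, target_cv = 0.10, seed = 2)
  cv <- stats::sd(noised$sc_length_um) / mean(noised$sc_length_um)
  expect_equal(cv, 0.10, tolerance = 0.005)
  # target below the current CV: warn, return unchanged
  expect_warning(out <- add_cellwise_gaussian_noise(rec, target_cv = 0.01),
                 "unchanged")
  expect_identical(out, rec)
})
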