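# Mediation: Sobel closed forms, proportion mediated, permutation nulls,
# direction symmetry, delta-method SE, sensitivity analysis.

test_that("Sobel test closed form and boundary behavior", {
  s <- sobel_test(1, 1, 0.04, 0.09)
  expect_equal(s$se, sqrt(0.13), tolerance = 1e-10)
  expect_equal(s$t, 1 / sqrt(0.13), tolerance = 1e-10)  # 2.7735
  expect_equal(s$p, 2 * pnorm(-1 / sqrt(0.13)), tolerance = 1e-12)  # 0.00554
  z <- sobel_test(0, 2, 0.1, 0.1)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_error(sobel_test(0, 0, 0, 0), "undefined")
  expect_error(sobel_test(1, 1, -0.1, 0.1), ">= 0")
})

test_that("two-tailed normal p-values match reference Sobel statistics", {
  # printed (t, p) pairs from the reference coefficient table
  expect_equal(sobel_test(1, 3.33, 0, 1)$p, 8.7e-4, tolerance = 0.05e-4 / 8.7e-4)
  expect_equal(sobel_test(1, -4.18, 0, 1)$p, 2.9e-5, tolerance = 0.05e-5 / 2.9e-5)
  expect_equal(sobel_test(1, -4.92, 0, 1)$p, 8.7e-7, tolerance = 0.05)
  expect_equal(sobel_test(1, -4.17, 0, 1)$p, 3.1e-5, tolerance = 0.05)
})

test_that("proportion mediated: identities, signs and reference values", {
  expect_equal(proportion_mediated(3.73, 2.96)$f, 0.21, tolerance = 0.005 / 0.21)
  expect_equal(proportion_mediated(0.80, 1.17)$f, -0.46, tolerance = 0.011 / 0.46)
  expect_equal(proportion_mediated(2, 2)$f, 0)
  expect_equal(proportion_mediated(2, 0)$f, 1)
  expect_error(proportion_mediated(0, 1), "nonzero")
  # delta-method SE with independent coefficients
  pm <- proportion_mediated(2, 1, var_beta = 0.04, var_beta_prime = 0.09)
  g <- c(1 / 4, -1 / 2)
  expect_equal(pm$se, sqrt(g[1]^2 * 0.04 + g[2]^2 * 0.09), tolerance = 1e-12)
})

test_that("mediation fits recover the generative chain", {
  fx <- mediation_fixture()
  res <- fit_mediation_models(fx$probs, fx$sc, fx$co, fx$qtl, fx$locus,
                              weights = fx$weights)
  total <- fx$med$direct + fx$med$alpha * fx$med$qtl_to_mediator  # 2.0
  expect_lt(abs(res$beta - total), 3 * sqrt(res$se_pooled^2 + 0.1))
  expect_lt(abs(res$beta_prime - fx$med$direct), 0.5)
  expect_lt(res$p_analytic, 1e-4)
  expect_gt(res$f, 0.4)
  # half-the-homozygote-difference convention for beta
  eff <- effect_at(fx$probs, fx$sc, fx$weights, chr = "1", pos = 50)
  expect_equal(res$beta, (eff$mean[3] - eff$mean[1]) / 2, tolerance = 0.15)
})

test_that("an irrelevant mediator leaves the QTL effect unchanged", {
  fx <- qtl_fixture()
  set.seed(12)
  noise_med <- rnorm(300)
  res <- fit_mediation_models(fx$probs, fx$sc, noise_med,
                              data.frame(chr = "1", pos = 50),
                              c(chr = "1", pos = 50),
                              weights = fx$weights, covar = fx$covar)
  expect_lt(abs(res$beta - res$beta_prime),
            2 * sqrt(res$se_pooled^2 + 0.2))
  expect_gt(res$p_analytic, 0.01)
  expect_error(
    fit_mediation_models(fx$probs, fx$sc, rep(1, 300),
                         data.frame(chr = "1", pos = 50),
                         c(chr = "1", pos = 50)),
    "constant")
})

test_that("permutation p-values are seeded, bounded and match strong truth", {
  fx <- mediation_fixture()
  r1 <- mediation_permutation_p(fx$probs, fx$sc, fx$co, fx$qtl, fx$locus,
                                weights = fx$weights, n_perm = 500, seed = 6)
  r2 <- mediation_permutation_p(fx$probs, fx$sc, fx$co, fx$qtl, fx$locus,
                                weights = fx$weights, n_perm = 500, seed = 6)
  expect_identical(r1$p_empirical, r2$p_empirical)
  expect_identical(r1$t_perm, r2$t_perm)
  expect_gte(r1$p_empirical, 1 / (r1$n_perm + 1))
  expect_lte(r1$p_empirical, 0.01)  # strong simulated mediation
  expect_length(r1$t_perm, 500)
  expect_error(
    mediation_permutation_p(fx$probs, fx$sc, fx$co, fx$qtl, fx$locus,
                            n_perm = 50),
    ">= 100")
})

test_that("direction bookkeeping is symmetric", {
  fx <- mediation_fixture()
  both <- mediate_both(fx$probs, fx$sc, fx$co, qtl1 = fx$qtl, qtl2 = fx$qtl,
                       locus = fx$locus, weights = fx$weights)
  direct <- fit_mediation_models(fx$probs, fx$co, fx$sc, fx$qtl, fx$locus,
                                 weights = fx$weights)
  expect_equal(both$t2_mediated_by_t1$t, direct$t, tolerance = 1e-12)
  expect_equal(both$t1_mediated_by_t2$beta,
               fit_mediation_models(fx$probs, fx$sc, fx$co, fx$qtl, fx$locus,
                                    weights = fx$weights)$beta,
               tolerance = 1e-12)
})

test_that("delta-method SE of f agrees with a case bootstrap", {
  fx <- mediation_fixture()
  res <- fit_mediation_models(fx$probs, fx$sc, fx$co, fx$qtl, fx$locus,
                              weights = fx$weights)
  set.seed(14)
  n <- 300
  f_boot <- replicate(200, {
    idx <- sample.int(n, replace = TRUE)
    r <- fit_mediation_models(scmeio:::permute_genoprob(fx$probs, idx),
                              fx$sc[idx], fx$co[idx], fx$qtl, fx$locus,
                              weights = fx$weights[idx])
    r$f
  })
  ratio <- res$se_f / stats::sd(f_boot)
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.4)
})

test_that("sensitivity analysis is seeded and tracks the baseline", {
  fx <- mediation_fixture()
  s1 <- sensitivity_to_measurement_error(fx$records, fx$probs, fx$qtl,
                                         fx$locus, n_rep = 10, seed = 3)
  s2 <- sensitivity_to_measurement_error(fx$records, fx$probs, fx$qtl,
                                         fx$locus, n_rep = 10, seed = 3)
  expect_identical(s1$f_rep, s2$f_rep)
  expect_equal(mean(s1$f_rep), s1$baseline$f, tolerance = 0.2)
  expect_identical(s1$noised_trait, "sc_length_um")  # CO counts are noisier
})
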