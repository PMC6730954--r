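# HK scan: oracle equivalence, invariances, thresholds, support intervals.

test_that("constant phenotypes give LOD 0 everywhere", {
  fx <- qtl_fixture()
  s <- scan_hk(fx$probs, rep(5, 300), fx$weights, fx$covar)
  expect_true(all(s$lod == 0))
})

test_that("LOD at informative markers equals brute-force weighted LS", {
  fx <- qtl_fixture()
  s <- scan_hk(fx$probs, fx$sc, fx$weights, fx$covar)
  keep <- !is.na(fx$sc)
  y <- fx$sc[keep]; w <- fx$weights[keep]
  cm <- stats::model.matrix(~ fx$covar)[keep, , drop = FALSE]
  for (mk in c("c1m6", "c2m3")) {
    ch <- fx$map$chr[fx$map$marker == mk]
    pos <- fx$map$pos[fx$map$marker == mk]
    j <- which(fx$probs[[ch]]$pos == pos)
    G <- scmeio:::genoprob_design(fx$probs, ch, j)[keep, , drop = FALSE]
    lod_oracle <- brute_force_lod(cbind(cm, G), cm, y, w)
    got <- s$lod[s$chr == ch & s$pos == pos]
    expect_equal(got, lod_oracle, tolerance = 1e-8)
  }
})

test_that("scans are invariant to affine phenotype rescaling and row order", {
  fx <- qtl_fixture()
  s1 <- scan_hk(fx$probs, fx$sc, fx$weights, fx$covar)
  s2 <- scan_hk(fx$probs, 3 * fx$sc + 7, fx$weights, fx$covar)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
  set.seed(1)
  idx <- sample(300)
  s3 <- scan_hk(scmeio:::permute_genoprob(fx$probs, idx),
                fx$sc[idx], fx$weights[idx], fx$covar[idx])
  expect_equal(s1$lod, s3$lod, tolerance = 1e-9)
})

test_that("the scan localizes the simulated QTL and reports its effect", {
  fx <- qtl_fixture()
  s <- scan_hk(fx$probs, fx$sc, fx$weights, fx$covar)
  pk <- scan_peak(s)
  expect_equal(pk$chr, "1")
  expect_lt(abs(pk$pos - 50), 10)
  expect_equal(s$beta_a[s$chr == "1" & s$pos == 50], 6, tolerance = 1)
  # X positions use the 1-df contrast: no dominance estimate
  expect_true(all(is.na(s$beta_d[s$chr == "X"])))
  expect_true(all(!is.na(s$beta_d[s$chr == "1"])))
  expect_true(all(s$lod >= 0, na.rm = TRUE))
})

test_that("permutation thresholds are reproducible order statistics", {
  fx <- qtl_fixture()
  th1 <- permutation_threshold(fx$probs, fx$sc, fx$weights, fx$covar,
                               n_perm = 30, seed = 4)
  th2 <- permutation_threshold(fx$probs, fx$sc, fx$weights, fx$covar,
                               n_perm = 30, seed = 4)
  expect_identical(th1$threshold, th2$threshold)
  expect_identical(th1$max_lods, th2$max_lods)
  # alpha = 0: threshold is the maximum permuted maximum
  th0 <- permutation_threshold(fx$probs, fx$sc, fx$weights, fx$covar,
                               n_perm = 30, alpha = 0, seed = 4)
  expect_equal(th0$threshold, max(th1$max_lods))
  expect_error(permutation_threshold(fx$probs, fx$sc, n_perm = 10),
               ">= 20")
})

test_that("the vectorized permutation core reproduces scan_hk exactly", {
  fx <- qtl_fixture()
  prep <- scmeio:::prep_fast_scan(fx$probs, fx$sc, fx$weights, fx$covar)
  s <- scan_hk(fx$probs, fx$sc, fx$weights, fx$covar)
  lod_id <- scmeio:::fast_scan_lod(prep, seq_len(prep$n))
  expect_equal(lod_id, s$lod, tolerance = 1e-9)
  # and under a genuine permutation, against the slow reference path
  # (permuting genotype rows among the phenotyped individuals)
  set.seed(8)
  kept <- !is.na(fx$sc)
  idx <- sample.int(prep$n)
  full_idx <- seq_along(fx$sc)
  full_idx[kept] <- which(kept)[idx]
  s_perm <- scan_hk(scmeio:::permute_genoprob(fx$probs, full_idx),
                    fx$sc, fx$weights, fx$covar)
  expect_equal(scmeio:::fast_scan_lod(prep, idx), s_perm$lod,
               tolerance = 1e-9)
})

triangular_scan <- function() {
  pos <- 30:70
  lod <- pmax(0, 6 - 0.3 * abs(pos - 50))
  s <- data.frame(chr = "1", pos = pos, lod = lod,
                  beta_a = 0, beta_d = 0, stringsAsFactors = FALSE)
  class(s) <- c("scan_result", "data.frame")
  s
}

test_that("LOD support intervals: triangular, degenerate and clipped cases", {
  s <- triangular_scan()
  ci <- lod_support_interval(s, "1", drop = 1.5)
  expect_equal(c(ci$lo, ci$hi), c(45, 55))  # 1.5 / 0.3 = 5 cM each side
  # drop = 0 degenerates to the peak plateau
  ci0 <- lod_support_interval(s, "1", drop = 0)
  expect_equal(c(ci0$lo, ci0$hi), c(50, 50))
  # peak at the chromosome end: clipped one-sided interval
  s2 <- s[s$pos >= 50, , drop = FALSE]
  class(s2) <- c("scan_result", "data.frame")
  ci2 <- lod_support_interval(s2, "1", drop = 1.5)
  expect_equal(c(ci2$lo, ci2$hi), c(50, 55))
  # flat zero curve: no interval
  s3 <- s; s3$lod <- 0
  expect_error(lod_support_interval(s3, "1"), "flat zero")
  # Mb interpolation from the map
  ci_mb <- lod_support_interval(triangular_scan(), "1", map = test_map())
  expect_equal(ci_mb$lo_mb, 90)  # 45 cM * 2 Mb/cM
  expect_equal(ci_mb$hi_mb, 110)
})

test_that("interval endpoints extend past grid points strictly above cut", {
  pos <- c(30, 40, 44, 50, 56, 60, 70)
  lod <- c(0, 1, 5, 6, 5, 1, 0)
  s <- data.frame(chr = "1", pos = pos, lod = lod, beta_a = 0, beta_d = 0)
  class(s) <- c("scan_result", "data.frame")
  ci <- lod_support_interval(s, "1", drop = 1.5)
  # 44 and 56 qualify (5 > 4.5 strictly): extend to 40 and 60
  expect_equal(c(ci$lo, ci$hi), c(40, 60))
})

test_that("genotype-class means at the peak bracket the simulated effects", {
  fx <- qtl_fixture()
  eff <- effect_at(fx$probs, fx$sc, fx$weights, fx$covar, "1", 50)
  expect_identical(eff$class, c("AA", "AB", "BB"))
  # a = 6: homozygote means differ by ~12
  expect_equal(eff$mean[3] - eff$mean[1], 12, tolerance = 3)
  expect_true(all(eff$se > 0))
})
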