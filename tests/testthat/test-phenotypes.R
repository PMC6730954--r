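# Phenotype aggregation, within-individual CVs, trait correlation.

toy_records <- function() {
  data.frame(
    individual_id = rep(c("a", "b", "c"), c(5, 4, 6)),
    cell_id = c(1:5, 1:4, 1:6),
    sc_length_um = c(100, 110, 120, 130, 140,
                     90, 95, 100, 105,
                     118, 119, 120, 121, 122, 120),
    mlh1_count = c(24, 24, 24, 24, 24,
                   20, 21, 22, 23,
                   25, 25, 25, 25, 25, 25),
    stringsAsFactors = FALSE
  )
}

test_that("aggregation means, counts, ratio and the min-cells filter", {
  expect_message(ph <- aggregate_phenotypes(toy_records(), min_cells = 5),
                 "dropped 1")
  expect_setequal(ph$individual_id, c("a", "c"))  # b has 4 cells
  a <- ph[ph$individual_id == "a", ]
  expect_equal(a$mean_sc_um, 120)
  expect_equal(a$n_cells, 5L)
  expect_equal(a$mean_co, 24)
  expect_equal(a$sc_co_ratio, 5.0)  # 120 um / 24 foci
  expect_identical(attr(ph, "dropped"), "b")
  expect_error(aggregate_phenotypes(toy_records(), min_cells = 10),
               "all individuals filtered")
})

test_that("missing MLH1 counts drop from mean_co but not mean_sc", {
  rec <- toy_records()
  rec$mlh1_count[rec$individual_id == "a"][1:2] <- NA
  ph <- aggregate_phenotypes(rec, min_cells = 4, quiet = TRUE)
  a <- ph[ph$individual_id == "a", ]
  expect_equal(a$n_cells, 5L)
  expect_equal(a$n_cells_co, 3L)
  expect_equal(a$mean_co, 24)
})

test_that("aggregation is record-order invariant and per-individual local", {
  rec <- toy_records()
  ph1 <- aggregate_phenotypes(rec, min_cells = 4, quiet = TRUE)
  set.seed(2)
  ph2 <- aggregate_phenotypes(rec[sample(nrow(rec)), ], min_cells = 4,
                              quiet = TRUE)
  o <- order(ph2$individual_id)
  expect_equal(ph1[order(ph1$individual_id), ],
               ph2[o, ], ignore_attr = TRUE)
  # dropping one individual leaves the others' values unchanged
  ph3 <- aggregate_phenotypes(rec[rec$individual_id != "b", ],
                              min_cells = 4, quiet = TRUE)
  expect_equal(ph3[ph3$individual_id == "a", ],
               ph1[ph1$individual_id == "a", ], ignore_attr = TRUE)
  expect_true(all(ph1$sc_co_ratio > 0))
  expect_error(
    aggregate_phenotypes(rbind(toy_records(), toy_records())),
    "unique")
})

test_that("within-individual CV matches hand arithmetic and known moments", {
  rec <- data.frame(individual_id = rep("a", 2), cell_id = 1:2,
                    sc_length_um = c(90, 110), mlh1_count = c(20, 20))
  cv <- within_individual_cv(rec)
  expect_equal(cv$cv_sc, sqrt(2) * 10 / 100, tolerance = 1e-12)  # 0.1414
  expect_equal(cv$cv_co, 0)
  # constant cells -> CV 0
  rec2 <- data.frame(individual_id = rep("b", 4), cell_id = 1:4,
                     sc_length_um = rep(5, 4), mlh1_count = rep(3, 4))
  expect_equal(within_individual_cv(rec2)$cv_sc, 0)
  expect_error(within_individual_cv(rec2[1, , drop = FALSE]), ">= 2 cells")
  # moment oracle: simulated CV 0.08 with 1e4 cells
  set.seed(31)
  n <- 10000
  rec3 <- data.frame(individual_id = "c", cell_id = seq_len(n),
                     sc_length_um = rnorm(n, 100, 8), mlh1_count = 20)
  est <- within_individual_cv(rec3)$cv_sc
  se <- 0.08 / sqrt(2 * (n - 1))  # delta-method SE of a normal CV
  expect_lt(abs(est - 0.08), 3 * se + 1e-3)
})

test_that("trait correlation: exact line, bivariate-normal oracle, CI", {
  x <- 1:50
  tc <- trait_correlation(x, 2 * x)
  expect_equal(tc$r, 1)
  expect_equal(tc$slope, 2)
  set.seed(77)
  n <- 5000
  z <- matrix(rnorm(2 * n), ncol = 2)
  rho <- 0.38
  y <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  tc2 <- trait_correlation(z[, 1], y)
  expect_true(tc2$r > 0.35 && tc2$r < 0.41)
  expect_true(tc2$ci[1] < rho && tc2$ci[2] > rho)
  expect_error(trait_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_error(trait_correlation(1:3, 1:3), "at least 4")
})

test_that("Fisher-z confidence intervals achieve nominal null coverage", {
  set.seed(5)
  covered <- replicate(200, {
    x <- rnorm(200); y <- rnorm(200)
    ci <- trait_correlation(x, y)$ci
    ci[1] < 0 && ci[2] > 0
  })
  expect_gt(mean(covered), 0.90)  # ~95% nominal, 200 replicates
})
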