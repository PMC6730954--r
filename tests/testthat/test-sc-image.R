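# SC length measurement: channel isolation, the fixed pipeline order,
# skeleton validity, length metrics, batch behavior, validation harness.

bar_cfg <- function(...) {
  synth_image_config(image_height_px = 300, image_width_px = 300, n_axes = 1,
                     scale_um_per_px = 0.1, seed = 1, ...)
}

test_that("channel isolation picks planes and validates selectors", {
  rgb <- array(0, c(8, 10, 3))
  rgb[, , 1] <- matrix(runif(80), 8, 10)
  im <- isolate_channel(rgb, "red", scale_um_per_px = 0.1)
  expect_equal(im$px, rgb[, , 1])
  gray <- matrix(runif(40), 5, 8)
  expect_equal(isolate_channel(gray, "auto", 0.1)$px, gray)
  two <- array(runif(32), c(4, 4, 2))
  expect_error(isolate_channel(two, 3, 0.1), "out of range")
  # integer-encoded input is rescaled to [0, 1]
  im16 <- isolate_channel(matrix(c(0, 512, 1024), 3, 1), "auto", 0.1)
  expect_equal(max(im16$px), 1)
})

test_that("a blank image measures zero with an empty skeleton", {
  img <- fluor_image(matrix(0.1, 64, 64), 0.1)
  m <- measure_sc_length(img)
  expect_equal(m$sc_length_um, 0)
  expect_false(any(m$skeleton))
  expect_equal(m$n_components, 0L)
})

test_that("a rendered bar is recovered within tolerance of ground truth", {
  r <- render_axes(list(cbind(y = rep(150, 201), x = 50 + 0:200)), bar_cfg())
  m <- measure_sc_length(r$image)
  # pixel count close to the Chebyshev truth (end-effect bound from cleanup)
  expect_lt(abs(m$skeleton_px - r$truth$chebyshev_px), 2 * 4)
  # measured length within 5% of the 20 um arc truth
  expect_lt(abs(m$sc_length_um - 20) / 20, 0.05)
  expect_equal(m$n_components, 1L)
})

test_that("diagonal bars show the sqrt(2) pixel-count bias; the corrected
          metric recovers Euclidean length", {
  L <- 200
  pts <- cbind(y = 40 + (0:L) / sqrt(2), x = 40 + (0:L) / sqrt(2))
  r <- render_axes(list(pts), bar_cfg(noise_sd = 0))
  m <- measure_sc_length(r$image)
  expect_equal(m$skeleton_px / L, 1 / sqrt(2), tolerance = 0.05)
  mg <- measure_sc_length(r$image, morph_params(metric = "corrected_geodesic"))
  expect_equal(mg$sc_length_um / r$image$scale_um_per_px, L, tolerance = 0.05)
})

test_that("reported length is exactly linear in the physical scale", {
  r <- render_axes(list(cbind(y = rep(100, 121), x = 60 + 0:120)), bar_cfg())
  m1 <- measure_sc_length(r$image)
  img2 <- fluor_image(r$image$px, r$image$scale_um_per_px * 2)
  m2 <- measure_sc_length(img2)
  expect_identical(m2$skeleton_px, m1$skeleton_px)
  expect_equal(m2$sc_length_um, 2 * m1$sc_length_um)
})

test_that("adding a disjoint axis never decreases measured length", {
  cfg <- bar_cfg()
  a1 <- cbind(y = rep(80, 151), x = 50 + 0:150)
  a2 <- cbind(y = rep(220, 151), x = 50 + 0:150)
  m1 <- measure_sc_length(render_axes(list(a1), cfg)$image)
  m12 <- measure_sc_length(render_axes(list(a1, a2), cfg)$image)
  expect_gte(m12$sc_length_um, m1$sc_length_um)
  expect_equal(m12$n_components, 2L)
})

test_that("skeletons are idempotent and single-pixel wide", {
  r <- render_spermatocyte_image(
    synth_image_config(image_height_px = 400, image_width_px = 400,
                       n_axes = 5, axis_length_px_range = c(60, 120),
                       seed = 13))
  m <- measure_sc_length(r$image)
  sk <- m$skeleton
  expect_identical(skeletonize_mask(sk), sk)
  # a simple bar skeleton: every pixel has <= 2 neighbours, two endpoints
  rb <- render_axes(list(cbind(y = rep(150, 201), x = 50 + 0:200)), bar_cfg())
  skb <- measure_sc_length(rb$image)$skeleton
  nb <- scmeio:::neighbor_count(skb)[skb]
  expect_true(all(nb <= 2))
  expect_equal(sum(nb == 1), 2)
})

test_that("the shipped opening-then-closing order is not interchangeable", {
  set.seed(3)
  mask <- matrix(runif(40000) < 0.4, 200, 200)
  mask[90:110, 20:180] <- TRUE
  sq <- scmeio:::se_square(4)
  oc <- scmeio:::bin_close(scmeio:::bin_open(mask, sq), sq)
  co <- scmeio:::bin_open(scmeio:::bin_close(mask, sq), sq)
  expect_false(identical(oc, co))
})

test_that("batch measurement handles files, duplicates and empty dirs", {
  dir <- withr::local_tempdir()
  cfgs <- lapply(1:3, function(s) {
    synth_image_config(image_height_px = 320, image_width_px = 320,
                       n_axes = 4, axis_length_px_range = c(60, 100),
                       seed = s)
  })
  truths <- numeric(3)
  for (i in 1:3) {
    r <- render_spermatocyte_image(cfgs[[i]])
    truths[i] <- attr(r$truth, "total_um")
    png::writePNG(r$image$px, file.path(dir, sprintf("cell%d.png", i)))
  }
  tab <- batch_measure(dir, scale_um_per_px = 0.065)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$status == "ok"))
  expect_true(all(abs(tab$sc_length_um - truths) / truths < 0.05))
  # duplicate of the same image measures identically
  file.copy(file.path(dir, "cell1.png"), file.path(dir, "cell1copy.png"))
  tab2 <- batch_measure(dir, scale_um_per_px = 0.065)
  l <- tab2$sc_length_um[grep("cell1", tab2$image_id)]
  expect_equal(l[1], l[2])
  # unreadable file becomes a failed row, not an error
  writeLines("not an image", file.path(dir, "bad.png"))
  tab3 <- batch_measure(dir, scale_um_per_px = 0.065)
  expect_equal(sum(tab3$status == "failed"), 1)
  empty <- withr::local_tempdir()
  expect_warning(tab4 <- batch_measure(empty), "no readable images")
  expect_equal(nrow(tab4), 0)
})

test_that("validation harness computes R2 as fit of automated on reference", {
  ref <- seq(100, 200, length.out = 200)
  expect_equal(validate_against_reference(ref, ref)$r_squared, 1)
  # additive noise at sigma = 0.2 * SD(ref): R2 ~ 1 / 1.04
  set.seed(8)
  auto <- ref + rnorm(200, 0, 0.2 * stats::sd(ref))
  v <- validate_against_reference(auto, ref)
  expect_equal(v$r_squared, 1 / 1.04, tolerance = 0.02)
  expect_equal(v$slope, 1, tolerance = 0.1)
  # per-individual averaging reduces noise, raising R2
  ind <- rep(1:40, each = 5)
  v_ind <- validate_against_reference(auto, ref, individual = ind)
  expect_gt(v_ind$r_squared, v$r_squared)
  expect_error(validate_against_reference(ref, rep(1, 200)), "zero variance")
  expect_error(validate_against_reference(1:2, 1:2), "at least 3")
})
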