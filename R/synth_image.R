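# Synthetic spermatocyte-spread generator: curvature-bounded random axes
# with exact arc-length ground truth, rendered at a given strand thickness
# with Gaussian blur and additive noise.

#' Configuration for synthetic spread images
#'
#' Defaults emulate the captured spreads: a 1030 x 1300 px frame holding 20
#' curvilinear axes whose total length at the default 0.065 um/px scale is
#' around 160 um.
#'
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param n_axes Number of axes (bivalents) per image (>= 1).
#' @param axis_length_px_range Min/max arc length of one axis, px.
#' @param strand_thickness_px Drawn strand thickness, px (>= 1).
#' @param blur_sigma_px Gaussian blur sigma, px (>= 0).
#' @param background_level,signal_level Background/strand intensity in
#'   `[0, 1]`.
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param scale_um_per_px Physical scale (> 0).
#' @param allow_overlap Allow axes to intersect. When `FALSE` axes keep at
#'   least the `min_separation_px` centerline separation.
#' @param min_separation_px Minimum centerline separation between axes.
#'   Default `2 * (thickness + blur_sigma) + 8`: at least twice the drawn
#'   strand footprint, plus clearance so the gradient bands formed around
#'   neighboring strands by the default measurement element do not fuse.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   image and ground truth.
#' @return Object of class `synth_image_config`.
#' @export
synth_image_config <- function(image_height_px = 1030, image_width_px = 1300,
                               n_axes = 20,
                               axis_length_px_range = c(80, 165),
                               strand_thickness_px = 3, blur_sigma_px = 1,
                               background_level = 0.08, signal_level = 0.85,
                               noise_sd = 0.03, scale_um_per_px = 0.065,
                               allow_overlap = FALSE,
                               min_separation_px = NULL, seed = 1L) {
  stop_if_not(is_count(image_height_px, 16) && is_count(image_width_px, 16),
              "image dimensions must be integers >= 16")
  stop_if_not(is_count(n_axes), "n_axes must be >= 1")
  stop_if_not(length(axis_length_px_range) == 2 &&
                all(axis_length_px_range > 0) &&
                axis_length_px_range[1] <= axis_length_px_range[2],
              "axis_length_px_range must be an increasing positive pair")
  stop_if_not(axis_length_px_range[2] <
                max(image_height_px, image_width_px) * 4,
              "axis lengths must fit within the image")
  stop_if_not(is_count(strand_thickness_px), "strand_thickness_px must be >= 1")
  stop_if_not(is_number(blur_sigma_px, min = 0), "blur_sigma_px must be >= 0")
  stop_if_not(is_number(noise_sd, min = 0), "noise_sd must be >= 0")
  stop_if_not(is_number(background_level, 0) && background_level <= 1 &&
                is_number(signal_level, 0) && signal_level <= 1,
              "intensity levels must be in [0, 1]")
  stop_if_not(is_number(scale_um_per_px) && scale_um_per_px > 0,
              "scale_um_per_px must be positive")
  if (is.null(min_separation_px)) {
    min_separation_px <- 2 * (strand_thickness_px + blur_sigma_px) + 8
  }
  stop_if_not(is_number(min_separation_px, min = 0) &&
                min_separation_px >= 2 * (strand_thickness_px + blur_sigma_px),
              "min_separation_px must be >= 2 * (thickness + blur_sigma)")
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 n_axes = as.integer(n_axes),
                 axis_length_px_range = as.numeric(axis_length_px_range),
                 strand_thickness_px = as.integer(strand_thickness_px),
                 blur_sigma_px = blur_sigma_px,
                 background_level = background_level,
                 signal_level = signal_level,
                 noise_sd = noise_sd,
                 scale_um_per_px = scale_um_per_px,
                 allow_overlap = isTRUE(allow_overlap),
                 min_separation_px = min_separation_px,
                 seed = as.integer(seed)),
            class = "synth_image_config")
}

# One curvature-bounded random curve of given arc length: unit steps with a
# slowly drifting heading, turn rate capped so the turning radius stays
# >= 3 x strand thickness (sharp kinks would break the skeleton topology).
random_axis_polyline <- function(len_px, h, w, margin, thickness) {
  n <- max(2L, round(len_px) + 1L)
  max_turn <- 1 / (3 * thickness)
  start <- c(runif(1, margin, h - margin), runif(1, margin, w - margin))
  theta0 <- runif(1, 0, 2 * pi)
  dth <- pmin(pmax(rnorm(n - 1, 0, 0.6 * max_turn), -max_turn), max_turn)
  theta <- theta0 + cumsum(dth)
  ys <- start[1] + cumsum(c(0, sin(theta)))
  xs <- start[2] + cumsum(c(0, cos(theta)))
  if (any(ys < margin) || any(ys > h - margin) ||
      any(xs < margin) || any(xs > w - margin)) {
    return(NULL)  # ran out of frame; caller retries
  }
  cbind(y = ys, x = xs)
}

# Minimum pairwise distance check between a candidate polyline and a matrix
# of occupied points (and against its own non-adjacent points).
polyline_clear <- function(pts, occupied, min_sep) {
  if (!is.null(occupied) && nrow(occupied) > 0) {
    for (i in seq_len(nrow(pts))) {
      d2 <- (occupied[, 1] - pts[i, 1])^2 + (occupied[, 2] - pts[i, 2])^2
      if (min(d2) < min_sep^2) return(FALSE)
    }
  }
  # self-proximity (coiling) check, skipping a window of nearby path points
  win <- max(20L, ceiling(3 * min_sep))
  n <- nrow(pts)
  if (n > win + 1) {
    for (i in seq.int(win + 1L, n)) {
      j <- seq_len(i - win)
      d2 <- (pts[j, 1] - pts[i, 1])^2 + (pts[j, 2] - pts[i, 2])^2
      if (min(d2) < min_sep^2) return(FALSE)
    }
  }
  TRUE
}

# Exact per-axis lengths of a polyline: Euclidean arc (px) and Chebyshev
# (axis-aligned step) length (px).
polyline_lengths <- function(pts) {
  dy <- diff(pts[, 1]); dx <- diff(pts[, 2])
  list(arc_px = sum(sqrt(dy^2 + dx^2)),
       chebyshev_px = sum(pmax(abs(dy), abs(dx))))
}

# Stamp a polyline at the given thickness into an intensity raster.
stamp_polyline <- function(canvas, pts, thickness, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- thickness / 2
  rr <- ceiling(r)
  offs <- expand.grid(dy = -rr:rr, dx = -rr:rr)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  yi <- round(pts[, 1]); xi <- round(pts[, 2])
  for (k in seq_len(nrow(offs))) {
    yy <- yi + offs$dy[k]; xx <- xi + offs$dx[k]
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    canvas[cbind(yy[ok], xx[ok])] <- value
  }
  canvas
}

#' Render given axis centerlines into a synthetic image
#'
#' Low-level renderer behind [render_spermatocyte_image()], also useful for
#' oracle images with known geometry (e.g. a single straight bar).
#'
#' @param polylines List of 2-column matrices (y, x) of centerline points
#'   (consecutive points should be about 1 px apart for exact raster
#'   coverage).
#' @param config A [synth_image_config()] providing thickness, blur, noise,
#'   levels and scale. `config$seed` seeds the noise.
#' @return List with `image` (a [fluor_image()]), `truth` (data frame
#'   `axis_id`, `arc_length_um`, `arc_length_px`, `chebyshev_px`, plus
#'   attributes `total_um`), and `clean_mask` (pre-blur, pre-noise strand
#'   mask).
#' @export
render_axes <- function(polylines, config) {
  stopifnot(inherits(config, "synth_image_config"))
  h <- config$image_height_px; w <- config$image_width_px
  canvas <- matrix(config$background_level, h, w)
  truth <- list()
  for (i in seq_along(polylines)) {
    pts <- polylines[[i]]
    canvas <- stamp_polyline(canvas, pts, config$strand_thickness_px,
                             config$signal_level)
    ln <- polyline_lengths(pts)
    truth[[i]] <- data.frame(axis_id = i,
                             arc_length_px = ln$arc_px,
                             arc_length_um = ln$arc_px * config$scale_um_per_px,
                             chebyshev_px = ln$chebyshev_px)
  }
  truth <- do.call(rbind, truth)
  clean_mask <- canvas > config$background_level
  img <- canvas
  if (config$blur_sigma_px > 0) {
    img <- EBImage::gblur(img, sigma = config$blur_sigma_px)
  }
  img <- with_seed(config$seed, {
    if (config$noise_sd > 0) img + rnorm(length(img), 0, config$noise_sd) else img
  })
  img <- matrix(pmin(1, pmax(0, img)), h, w)
  attr(truth, "total_um") <- sum(truth$arc_length_um)
  list(image = fluor_image(img, config$scale_um_per_px,
                           id = sprintf("synthetic_seed%d", config$seed)),
       truth = truth, clean_mask = clean_mask)
}

#' Render a synthetic spermatocyte spread with known ground truth
#'
#' Places `n_axes` curvature-bounded random axes (rejection-sampled to
#' respect the minimum separation unless `allow_overlap`), draws them at
#' the configured thickness, blurs, adds noise, and returns the exact
#' per-axis arc and Chebyshev lengths as ground truth.
#'
#' @param config A [synth_image_config()].
#' @param max_tries Placement attempts per axis before giving up.
#' @return As [render_axes()]; the polylines are included as
#'   `attr(truth, "polylines")`.
#' @export
render_spermatocyte_image <- function(config = synth_image_config(),
                                      max_tries = 200) {
  stopifnot(inherits(config, "synth_image_config"))
  h <- config$image_height_px; w <- config$image_width_px
  sep <- config$min_separation_px
  margin <- config$strand_thickness_px + 2 * config$blur_sigma_px + 4
  polylines <- with_seed(config$seed, {
    out <- vector("list", config$n_axes)
    occupied <- NULL
    for (i in seq_len(config$n_axes)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        len <- runif(1, config$axis_length_px_range[1],
                     config$axis_length_px_range[2])
        pts <- random_axis_polyline(len, h, w, margin,
                                    config$strand_thickness_px)
        if (is.null(pts)) next
        if (!config$allow_overlap &&
            !polyline_clear(pts, occupied, sep)) next
        out[[i]] <- pts
        occupied <- rbind(occupied, pts)
        placed <- TRUE
        break
      }
      stop_if_not(placed,
                  "could not place axis %d without overlap after %d tries",
                  i, max_tries)
    }
    out
  })
  res <- render_axes(polylines, config)
  attr(res$truth, "polylines") <- polylines
  res
}
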