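# Automated SC-length morphometry from fluorescence images: channel
# isolation, morphological gradient, Otsu threshold, opening/closing
# cleanup, skeletonization, and pixel-count length scaled to um.

#' Construct a fluorescence image object
#'
#' @param px Numeric matrix of pixel intensities (rows x cols), any
#'   non-negative scale; normalized to `[0, 1]` by the pipeline.
#' @param scale_um_per_px Physical scale, um per pixel (> 0).
#' @param id Source identifier (e.g. file name).
#' @return Object of class `fluor_image`.
#' @export
fluor_image <- function(px, scale_um_per_px, id = "image") {
  stop_if_not(is.matrix(px) && length(px) > 0, "px must be a non-empty matrix")
  stop_if_not(is_number(scale_um_per_px, min = 0) && scale_um_per_px > 0,
              "scale_um_per_px must be positive")
  structure(list(px = px, scale_um_per_px = scale_um_per_px, id = id),
            class = "fluor_image")
}

#' Isolate one channel of a multi-channel image
#'
#' The SYCP3 signal lives in the red channel of RGB captures; this extracts
#' a single plane and rescales it to `[0, 1]`.
#'
#' @param img Numeric matrix (grayscale) or 3-d array (height x width x
#'   channels).
#' @param channel `"auto"` (grayscale passthrough / red for RGB), `"red"`,
#'   `"green"`, `"blue"`, or a channel index.
#' @param scale_um_per_px Physical scale for the resulting image.
#' @param id Source identifier.
#' @return A [fluor_image()].
#' @export
isolate_channel <- function(img, channel = "auto", scale_um_per_px = 0.065,
                            id = "image") {
  if (is.matrix(img)) {
    stop_if_not(identical(channel, "auto") || identical(channel, 1) ||
                  identical(channel, 1L),
                "grayscale image has a single channel")
    plane <- img
  } else {
    stop_if_not(is.array(img) && length(dim(img)) == 3,
                "img must be a matrix or a 3-d array")
    nc <- dim(img)[3]
    ch <- if (is.character(channel)) {
      switch(channel, auto = 1L, red = 1L, green = 2L, blue = 3L,
             stop("unknown channel name: ", channel, call. = FALSE))
    } else {
      as.integer(channel)
    }
    stop_if_not(ch >= 1 && ch <= nc,
                "channel %d out of range for %d-channel image", ch, nc)
    plane <- img[, , ch]
  }
  mx <- max(plane)
  if (mx > 1) plane <- plane / mx  # integer-encoded input
  fluor_image(plane, scale_um_per_px, id)
}

#' Morphometry parameters
#'
#' @param gradient_width Disk parameter for the morphological gradient,
#'   i.e. the disk radius in the conventional parameterization of the
#'   standard image-processing toolkits (default 3, a 7x7-support disk).
#'   The disk must span the strand half-width; a sub-strand disk yields a
#'   hollow gradient band that the cleanup opening erases.
#' @param cleanup_width Square side for opening/closing cleanup (default
#'   4 px).
#' @param threshold Thresholding method; only `"otsu"` is implemented.
#' @param metric `"pixel_count"` (the canonical length metric: skeleton
#'   pixels times scale, which carries the sqrt(2) underestimate on
#'   diagonal runs) or `"corrected_geodesic"` (diagonal steps weighted
#'   sqrt(2); non-canonical).
#' @return Object of class `morph_params`.
#' @export
morph_params <- function(gradient_width = 3, cleanup_width = 4,
                         threshold = "otsu",
                         metric = c("pixel_count", "corrected_geodesic")) {
  stop_if_not(is_count(gradient_width), "gradient_width must be >= 1")
  stop_if_not(is_count(cleanup_width), "cleanup_width must be >= 1")
  stop_if_not(identical(threshold, "otsu"), "only Otsu thresholding is implemented")
  structure(list(gradient_width = gradient_width,
                 cleanup_width = cleanup_width,
                 threshold = threshold,
                 metric = match.arg(metric)),
            class = "morph_params")
}

#' Measure total SC length in one image
#'
#' Runs the measurement pipeline in fixed order: min-max intensity
#' balancing, morphological gradient (disk element), Otsu threshold on the
#' full gradient image, morphological opening then closing (square
#' element), Zhang-Suen skeletonization, and length = skeleton pixel count
#' times the um-per-pixel scale (or the corrected-geodesic length under
#' that metric). A blank image yields length 0 with an empty skeleton.
#'
#' @param image A [fluor_image()].
#' @param params A [morph_params()].
#' @param keep_masks Retain intermediate rasters for diagnostics.
#' @return Object of class `sc_measurement`: list with `sc_length_um`,
#'   `skeleton` (logical matrix), `skeleton_px`, `n_components`, `id`,
#'   `scale_um_per_px` and optionally `masks`.
#' @export
measure_sc_length <- function(image, params = morph_params(),
                              keep_masks = FALSE) {
  stopifnot(inherits(image, "fluor_image"), inherits(params, "morph_params"))
  px <- image$px
  rng <- range(px)
  empty_result <- function() {
    structure(list(sc_length_um = 0, skeleton = matrix(FALSE, nrow(px), ncol(px)),
                   skeleton_px = 0L, n_components = 0L, id = image$id,
                   scale_um_per_px = image$scale_um_per_px),
              class = "sc_measurement")
  }
  if (diff(rng) == 0) return(empty_result())  # constant image: no signal
  bal <- (px - rng[1]) / diff(rng)
  grad <- morph_gradient(bal, params$gradient_width)
  if (max(grad) <= 0) return(empty_result())
  gn <- grad / max(grad)
  thr <- EBImage::otsu(gn, range = c(0, 1), levels = 256L)
  bw <- gn > thr
  sq <- se_square(params$cleanup_width)
  cleaned <- bin_close(bin_open(bw, sq), sq)
  sk <- skeletonize_mask(cleaned)
  npx <- sum(sk)
  ncomp <- count_components8(sk)
  len_px <- switch(params$metric,
                   pixel_count = npx,
                   corrected_geodesic = geodesic_length(sk))
  out <- list(sc_length_um = len_px * image$scale_um_per_px,
              skeleton = sk, skeleton_px = as.integer(npx),
              n_components = as.integer(ncomp), id = image$id,
              scale_um_per_px = image$scale_um_per_px)
  if (keep_masks) out$masks <- list(balanced = bal, gradient = grad,
                                    binary = bw, cleaned = cleaned)
  structure(out, class = "sc_measurement")
}

#' @export
print.sc_measurement <- function(x, ...) {
  cat(sprintf("SC length %.2f um (%d skeleton px, %d components) [%s]\n",
              x$sc_length_um, x$skeleton_px, x$n_components, x$id))
  invisible(x)
}

#' Measure a batch of images
#'
#' Applies [measure_sc_length()] to a directory or vector of image files
#' (TIFF/PNG) or a list of [fluor_image()] objects. Unreadable images are
#' recorded as failed rows, not fatal errors.
#'
#' @param images Directory path, character vector of files, or list of
#'   `fluor_image` objects.
#' @param params A [morph_params()].
#' @param scale_um_per_px Scale applied to images read from files.
#' @param channel Channel selector for files (see [isolate_channel()]).
#' @return Data frame with `image_id`, `sc_length_um`, `skeleton_px`,
#'   `n_components`, `status` (`"ok"`/`"failed"`).
#' @export
batch_measure <- function(images, params = morph_params(),
                          scale_um_per_px = 0.065, channel = "auto") {
  if (is.character(images) && length(images) == 1 && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.(tiff?|png)$", ignore.case = TRUE,
                         full.names = TRUE)
    if (length(images) == 0) {
      warning("no readable images found")
      return(data.frame(image_id = character(), sc_length_um = numeric(),
                        skeleton_px = integer(), n_components = integer(),
                        status = character(), stringsAsFactors = FALSE))
    }
  }
  rows <- lapply(seq_along(images), function(i) {
    item <- if (is.list(images) && !is.data.frame(images)) images[[i]] else images[i]
    res <- tryCatch({
      im <- if (inherits(item, "fluor_image")) {
        item
      } else {
        isolate_channel(read_image_array(item), channel = channel,
                        scale_um_per_px = scale_um_per_px,
                        id = basename(item))
      }
      m <- measure_sc_length(im, params)
      data.frame(image_id = m$id, sc_length_um = m$sc_length_um,
                 skeleton_px = m$skeleton_px, n_components = m$n_components,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      id <- if (inherits(item, "fluor_image")) item$id else as.character(item)
      data.frame(image_id = basename(id), sc_length_um = NA_real_,
                 skeleton_px = NA_integer_, n_components = NA_integer_,
                 status = "failed", stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate automated lengths against reference measurements
#'
#' Least-squares fit of the automated measurement on the reference (e.g.
#' manual tracing or synthetic ground truth); the coefficient of
#' determination is `1 - SS_res / SS_tot` for that fit. With `individual`
#' given, cells are averaged within individuals before fitting.
#'
#' @param automated,reference Paired length measurements (>= 3 finite
#'   pairs).
#' @param individual Optional grouping vector for per-individual averaging.
#' @return List with `r_squared`, `slope`, `intercept`, `n`.
#' @export
validate_against_reference <- function(automated, reference, individual = NULL) {
  keep <- is.finite(automated) & is.finite(reference)
  automated <- automated[keep]; reference <- reference[keep]
  if (!is.null(individual)) {
    individual <- individual[keep]
    automated <- tapply(automated, individual, mean)
    reference <- tapply(reference, individual, mean)
  }
  n <- length(automated)
  stop_if_not(n >= 3, "need at least 3 finite pairs")
  stop_if_not(stats::var(reference) > 0, "zero variance in reference: R2 undefined")
  fit <- stats::lm(automated ~ reference)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((automated - mean(automated))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = n)
}
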