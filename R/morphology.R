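# Raster morphology on plain matrices, implemented with vectorized shifts
# so that arbitrary structuring-element footprints (including even-sized
# squares and the radius-1 disk) are supported exactly. Erosion uses the
# footprint as given; dilation uses the reflected footprint, so
# opening/closing are proper adjunctions for any anchor.

# Offsets (dy, dx) of a disk structuring element of the given radius
# (the disk parameterization of the standard image-processing toolkits):
# all cells with dy^2 + dx^2 <= r^2.
se_disk <- function(radius_px) {
  stop_if_not(is_count(radius_px), "disk radius must be a positive integer")
  r <- radius_px
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
}

# Offsets of a width x width square, anchored at floor(width/2) (the
# convention of the standard image-processing toolkits for even sizes).
se_square <- function(width_px) {
  stop_if_not(is_count(width_px), "element width must be a positive integer")
  a <- width_px %/% 2
  expand.grid(dy = (0:(width_px - 1)) - a, dx = (0:(width_px - 1)) - a)
}

# Shift a matrix by (dy, dx), filling exposed cells with `fill`.
mat_shift <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  if (abs(dy) >= h || abs(dx) >= w) return(out)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

reduce_shifts <- function(m, se, fun, fill) {
  acc <- NULL
  for (i in seq_len(nrow(se))) {
    s <- mat_shift(m, se$dy[i], se$dx[i], fill)
    acc <- if (is.null(acc)) s else fun(acc, s)
  }
  acc
}

# Grayscale erosion/dilation (min/max filters) over a footprint.
gray_erode <- function(m, se) reduce_shifts(m, se, pmin, fill = Inf)
gray_dilate <- function(m, se) {
  ser <- se; ser$dy <- -se$dy; ser$dx <- -se$dx
  reduce_shifts(m, ser, pmax, fill = -Inf)
}

#' Morphological gradient
#'
#' Dilation minus erosion of a grayscale raster over a disk footprint;
#' enhances edges of the fluorescent strands. The disk must span the
#' strand half-width so that the gradient band over a strand is solid
#' rather than a hollow pair of edge rings (which the downstream opening
#' would erase).
#'
#' @param m Numeric matrix.
#' @param radius_px Disk radius in pixels (default 3).
#' @return Matrix of the same shape, non-negative.
#' @export
morph_gradient <- function(m, radius_px = 3) {
  se <- se_disk(radius_px)
  g <- gray_dilate(m, se) - gray_erode(m, se)
  g[!is.finite(g)] <- 0
  g
}

# Binary erosion/dilation/opening/closing over a footprint.
bin_erode <- function(m, se) reduce_shifts(m, se, `&`, fill = FALSE)
bin_dilate <- function(m, se) {
  ser <- se; ser$dy <- -se$dy; ser$dx <- -se$dx
  reduce_shifts(m, ser, `|`, fill = FALSE)
}
bin_open <- function(m, se) bin_dilate(bin_erode(m, se), se)
bin_close <- function(m, se) bin_erode(bin_dilate(m, se), se)

#' Skeletonize a binary mask
#'
#' Iterative Zhang-Suen thinning to a single-pixel-wide, 8-connected
#' medial representation. The operation is idempotent: re-skeletonizing a
#' skeleton leaves it unchanged.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @return Logical matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask & !is.na(mask)
  shift8 <- function(m) {
    # neighbours P2..P9 clockwise from north (dy = -1 is up/north)
    list(p2 = mat_shift(m, 1, 0, FALSE),   # north neighbour value at p
         p3 = mat_shift(m, 1, -1, FALSE),
         p4 = mat_shift(m, 0, -1, FALSE),
         p5 = mat_shift(m, -1, -1, FALSE),
         p6 = mat_shift(m, -1, 0, FALSE),
         p7 = mat_shift(m, -1, 1, FALSE),
         p8 = mat_shift(m, 0, 1, FALSE),
         p9 = mat_shift(m, 1, 1, FALSE))
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- shift8(m)
      B <- Reduce(`+`, nb)
      seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- 0
      for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1]])
      if (step == 1) {
        c1 <- !(nb$p2 & nb$p4 & nb$p6)
        c2 <- !(nb$p4 & nb$p6 & nb$p8)
      } else {
        c1 <- !(nb$p2 & nb$p4 & nb$p8)
        c2 <- !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- m & (B >= 2) & (B <= 6) & (A == 1) & c1 & c2
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Number of 8-connected neighbours of each foreground pixel.
neighbor_count <- function(mask) {
  nb <- 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- nb + mat_shift(mask, dy, dx, FALSE)
  }
  nb
}

# Count of 8-connected components of a sparse binary mask (union-find over
# the foreground pixels; suitable for skeletons and strand masks).
count_components8 <- function(mask) {
  idx <- which(mask)
  n <- length(idx)
  if (n == 0) return(0L)
  h <- nrow(mask)
  y <- (idx - 1L) %% h + 1L
  x <- (idx - 1L) %/% h + 1L
  key <- y + (x - 1L) * h
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- cbind(dy = c(-1, -1, -1, 0), dx = c(-1, 0, 1, -1))
  for (k in seq_len(nrow(offs))) {
    ny <- y + offs[k, 1]; nx <- x + offs[k, 2]
    ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= ncol(mask)
    nb <- match(ny[ok] + (nx[ok] - 1L) * h, key)
    src <- which(ok)[!is.na(nb)]
    dst <- nb[!is.na(nb)]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# Length of a skeleton in pixel-equivalents under the corrected-geodesic
# metric: orthogonal adjacencies count 1, diagonal adjacencies without an
# orthogonal shortcut count sqrt(2).
geodesic_length <- function(sk) {
  if (!any(sk)) return(0)
  horiz <- sum(sk & mat_shift(sk, 0, -1, FALSE))
  vert <- sum(sk & mat_shift(sk, -1, 0, FALSE))
  diag_pairs <- function(dy, dx) {
    # diagonal neighbour present, but neither of the two bridging
    # orthogonal pixels is
    sk & mat_shift(sk, dy, dx, FALSE) &
      !mat_shift(sk, dy, 0, FALSE) & !mat_shift(sk, 0, dx, FALSE)
  }
  d1 <- sum(diag_pairs(-1, -1))
  d2 <- sum(diag_pairs(-1, 1))
  horiz + vert + sqrt(2) * (d1 + d2)
}
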