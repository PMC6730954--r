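# Single-QTL genome scan by weighted Haley-Knott regression, permutation
# thresholds, and LOD support intervals.

# Weighted least-squares RSS via QR on sqrt(w)-scaled design.
wls_rss <- function(X, y, w) {
  sw <- sqrt(w)
  fit <- stats::lm.wfit(x = X, y = y, w = w)
  rss <- sum(w * fit$residuals^2)
  list(rss = rss, coef = fit$coefficients, rank = fit$rank, fit = fit)
}

# Coefficient covariance for a weighted fit: sigma2 * (X' W X)^-1.
wls_vcov <- function(X, y, w) {
  f <- stats::lm.wfit(x = X, y = y, w = w)
  p <- f$rank
  n <- length(y)
  rss <- sum(w * f$residuals^2)
  sigma2 <- rss / (n - p)
  XtWX <- crossprod(X * w, X)
  V <- tryCatch(solve(XtWX) * sigma2, error = function(e) NULL)
  list(coef = f$coefficients, vcov = V, sigma2 = sigma2, rss = rss, rank = p)
}

# Build the covariate block: intercept plus numeric-coded additive
# covariates (factors expanded via model.matrix).
covar_matrix <- function(covar, n) {
  if (is.null(covar)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  if (is.vector(covar) || is.factor(covar)) covar <- data.frame(covar = covar)
  mm <- stats::model.matrix(~ ., data = as.data.frame(covar))
  colnames(mm)[1] <- "intercept"
  mm
}

#' Genome scan by weighted Haley-Knott regression
#'
#' At every evaluation position, regresses the phenotype on the expected
#' additive dosage `P(BB) - P(AA)` and dominance probability `P(AB)`
#' (single hemizygous contrast `P(BY) - P(AY)` on the male X), with an
#' intercept and optional additive covariates, by weighted least squares.
#' The LOD score is `(n/2) * log10(RSS0 / RSS1)` against the same model
#' without the genotype terms.
#'
#' @param probs A `genoprob` object.
#' @param pheno Numeric phenotype vector, one value per individual (NAs
#'   dropped together with their weights/covariates).
#' @param weights Positive regression weights (e.g. number of spermatocytes
#'   per individual); default all 1.
#' @param covar Optional additive covariate(s): vector/factor or data frame
#'   aligned to individuals (e.g. cross direction).
#' @return A data frame of class `scan_result` with columns `chr`, `pos`,
#'   `lod`, `beta_a`, `beta_d` (`beta_d` is `NA` on the X). Positions with a
#'   singular genotype design get `lod = NA`.
#' @export
scan_hk <- function(probs, pheno, weights = NULL, covar = NULL) {
  stopifnot(inherits(probs, "genoprob"))
  n_all <- attr(probs, "n_ind")
  stop_if_not(length(pheno) == n_all, "phenotype length != number of individuals")
  if (is.null(weights)) weights <- rep(1, n_all)
  stop_if_not(length(weights) == n_all, "weights length != number of individuals")
  cm <- covar_matrix(covar, n_all)
  keep <- !is.na(pheno) & !is.na(weights) & stats::complete.cases(cm)
  stop_if_not(sum(keep) >= 10, "need >= 10 informative individuals")
  y <- pheno[keep]; w <- weights[keep]; cm <- cm[keep, , drop = FALSE]
  stop_if_not(all(w > 0), "weights must be positive")
  n <- length(y)
  rss0 <- wls_rss(cm, y, w)$rss
  rss_eps <- 1e-12 * (sum(w * y^2) + 1)  # numerically-zero residual scale
  res <- lapply(names(probs), function(ch) {
    np <- length(probs[[ch]]$pos)
    lod <- beta_a <- beta_d <- rep(NA_real_, np)
    for (j in seq_len(np)) {
      G <- genoprob_design(probs, ch, j)[keep, , drop = FALSE]
      X <- cbind(cm, G)
      f <- wls_rss(X, y, w)
      if (f$rank < ncol(X) || any(is.na(f$coef[colnames(G)]))) next
      lod[j] <- if (rss0 <= rss_eps) {
        0  # constant phenotype (perfect null fit): no linkage signal
      } else if (f$rss <= rss_eps) {
        Inf
      } else {
        (n / 2) * log10(rss0 / f$rss)
      }
      beta_a[j] <- f$coef[["a"]]
      beta_d[j] <- if ("d" %in% colnames(G)) f$coef[["d"]] else NA_real_
    }
    data.frame(chr = ch, pos = probs[[ch]]$pos, lod = pmax(lod, 0),
               beta_a = beta_a, beta_d = beta_d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n") <- n
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Peak of a genome scan
#'
#' Highest-LOD position, genome-wide or per chromosome; ties are broken by
#' the lowest cM position.
#'
#' @param scan A `scan_result`.
#' @param chr Optional chromosome to restrict to.
#' @return One-row data frame with `chr`, `pos`, `lod`.
#' @export
scan_peak <- function(scan, chr = NULL) {
  s <- if (is.null(chr)) scan else scan[scan$chr == as.character(chr), , drop = FALSE]
  s <- s[!is.na(s$lod), , drop = FALSE]
  stop_if_not(nrow(s) > 0, "no evaluated positions")
  i <- which(s$lod == max(s$lod))
  i <- i[which.min(s$pos[i])]
  s[i, c("chr", "pos", "lod")]
}

#' Genome-wide permutation threshold
#'
#' Estimates the genome-wide significance threshold for [scan_hk()] by
#' permuting phenotype rows (each carrying its weight and covariates)
#' against the genotype data, rescanning, and taking the
#' `ceiling((1 - alpha) * n_perm)`-th order statistic of the maximum LOD.
#'
#' @inheritParams scan_hk
#' @param n_perm Number of permutation replicates (>= 20).
#' @param alpha Genome-wide type-I error rate.
#' @param seed Integer seed for the permutations.
#' @return List of class `perm_threshold` with elements `threshold`,
#'   `max_lods`, `alpha`, `n_perm`, `seed`.
#' @export
permutation_threshold <- function(probs, pheno, weights = NULL, covar = NULL,
                                  n_perm = 1000, alpha = 0.05, seed = 1L) {
  stop_if_not(is_count(n_perm, min = 20), "n_perm must be an integer >= 20")
  stop_if_not(is_number(alpha, min = 0) && alpha < 1, "alpha must be in [0, 1)")
  # Permuting (pheno, weights, covar) rows jointly against genotypes is
  # implemented as permuting the genotype rows among the phenotyped
  # individuals: identical LOD values, and the covariate/weight structure
  # travels with each phenotype row.
  prep <- prep_fast_scan(probs, pheno, weights, covar)
  max_lods <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(prep$n)
      max(fast_scan_lod(prep, idx), na.rm = TRUE)
    }, numeric(1))
  })
  k <- max(1L, ceiling((1 - alpha) * n_perm))
  structure(list(threshold = sort(max_lods)[k], max_lods = max_lods,
                 alpha = alpha, n_perm = n_perm, seed = seed),
            class = "perm_threshold")
}

permute_genoprob <- function(probs, idx) {
  out <- lapply(probs, function(ch) {
    ch$prob <- ch$prob[idx, , , drop = FALSE]
    ch
  })
  attributes(out) <- attributes(probs)
  out
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("genome-wide LOD threshold %.3f (alpha = %g, %d permutations)\n",
              x$threshold, x$alpha, x$n_perm))
  invisible(x)
}

#' LOD support interval
#'
#' Computes the drop-LOD support interval for the peak on one chromosome:
#' the outermost evaluated positions with `LOD >= peak - drop`. When such an
#' endpoint lies strictly above `peak - drop` (the true crossing falls
#' between grid points), the interval is extended to the adjacent evaluated
#' position; an endpoint exactly at `peak - drop` is taken as-is. Intervals
#' are clipped at the terminal positions. Mb bounds are linearly
#' interpolated from the map when it carries `pos_mb`.
#'
#' @param scan A `scan_result`.
#' @param chr Chromosome to summarize.
#' @param drop LOD drop defining the interval (default 1.5).
#' @param map Optional `genetic_map` with `pos_mb` for Mb interpolation.
#' @return One-row data frame: `chr`, `peak_pos`, `peak_lod`, `lo`, `hi`
#'   (cM) and, if `map` given, `lo_mb`, `hi_mb`, `peak_mb`.
#' @export
lod_support_interval <- function(scan, chr, drop = 1.5, map = NULL) {
  chr <- as.character(chr)
  s <- scan[scan$chr == chr & !is.na(scan$lod), , drop = FALSE]
  stop_if_not(nrow(s) > 0, "no evaluated positions on chromosome %s", chr)
  stop_if_not(max(s$lod) > 0, "flat zero LOD curve on chromosome %s: no interval", chr)
  pk <- scan_peak(s)
  cut <- pk$lod - drop
  ok <- which(s$lod >= cut - 1e-12)
  i_lo <- min(ok); i_hi <- max(ok)
  if (s$lod[i_lo] > cut + 1e-12 && i_lo > 1) i_lo <- i_lo - 1L
  if (s$lod[i_hi] > cut + 1e-12 && i_hi < nrow(s)) i_hi <- i_hi + 1L
  out <- data.frame(chr = chr, peak_pos = pk$pos, peak_lod = pk$lod,
                    lo = s$pos[i_lo], hi = s$pos[i_hi],
                    stringsAsFactors = FALSE)
  if (!is.null(map) && "pos_mb" %in% names(map)) {
    out$lo_mb <- cm_to_mb(map, chr, out$lo)
    out$hi_mb <- cm_to_mb(map, chr, out$hi)
    out$peak_mb <- cm_to_mb(map, chr, out$peak_pos)
  }
  out
}

# Linear cM -> Mb interpolation between flanking markers with known Mb.
cm_to_mb <- function(map, chr, pos_cm) {
  m <- map[map$chr == as.character(chr) & !is.na(map$pos_mb), , drop = FALSE]
  stop_if_not(nrow(m) >= 2, "need >= 2 markers with Mb positions on chromosome %s", chr)
  stats::approx(m$pos, m$pos_mb, xout = pos_cm, rule = 2)$y
}

#' Genotype-class phenotype means at a position
#'
#' Estimated phenotype mean and SE for each genotype class at an evaluation
#' position, from a weighted regression of the phenotype on the class
#' probabilities (covariates, if any, are included mean-centered so the
#' class means stay on the phenotype scale).
#'
#' @inheritParams scan_hk
#' @param chr,pos Evaluation position (nearest grid point is used).
#' @return Data frame with `class`, `mean`, `se`.
#' @export
effect_at <- function(probs, pheno, weights = NULL, covar = NULL, chr, pos) {
  loc <- genoprob_index(probs, chr, pos)
  n_all <- attr(probs, "n_ind")
  if (is.null(weights)) weights <- rep(1, n_all)
  cm <- covar_matrix(covar, n_all)[, -1, drop = FALSE]
  if (ncol(cm) > 0) cm <- scale(cm, center = TRUE, scale = FALSE)
  keep <- !is.na(pheno) & !is.na(weights)
  P <- probs[[loc$chr]]$prob[keep, loc$j, ]
  X <- cbind(P, cm[keep, , drop = FALSE])
  v <- wls_vcov(X, pheno[keep], weights[keep])
  k <- ncol(P)
  data.frame(class = colnames(P),
             mean = unname(v$coef[seq_len(k)]),
             se = if (is.null(v$vcov)) NA_real_ else sqrt(diag(v$vcov)[seq_len(k)]),
             row.names = NULL)
}
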