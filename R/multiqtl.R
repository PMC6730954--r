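# Multiple-QTL weighted regression: joint fit of all detected loci,
# percent-variance decomposition, and the share of the parental strain
# difference explained by summed additive effects.

# Assemble the genotype design for a set of QTL: columns a_<chr>_<pos> and
# (autosomes) d_<chr>_<pos>.
multiqtl_design <- function(probs, qtl) {
  stop_if_not(all(c("chr", "pos") %in% names(qtl)), "qtl needs columns chr, pos")
  cols <- list()
  info <- list()
  for (i in seq_len(nrow(qtl))) {
    loc <- genoprob_index(probs, qtl$chr[i], qtl$pos[i])
    G <- genoprob_design(probs, loc$chr, loc$j)
    tag <- sprintf("%s_%g", loc$chr, loc$pos)
    colnames(G) <- paste0(colnames(G), "_", tag)
    cols[[i]] <- G
    info[[i]] <- data.frame(chr = loc$chr, pos = loc$pos, is_x = loc$is_x,
                            a_col = paste0("a_", tag),
                            d_col = if (loc$is_x) NA_character_ else paste0("d_", tag),
                            stringsAsFactors = FALSE)
  }
  info <- do.call(rbind, info)
  # refuse collinear loci (< 1 cM apart on the same chromosome)
  for (ch in unique(info$chr)) {
    p <- sort(info$pos[info$chr == ch])
    if (length(p) > 1 && any(diff(p) < 1)) {
      stop(sprintf("QTL on chromosome %s closer than 1 cM: model not identifiable", ch),
           call. = FALSE)
    }
  }
  list(G = do.call(cbind, cols), info = info)
}

#' Fit a multiple-QTL model
#'
#' Joint weighted regression of a phenotype on additive and dominance terms
#' for a set of QTL plus additive covariates. Reports per-QTL percent
#' variance explained (`100 * (RSS_without_QTL - RSS_full) / TSS`, from
#' dropping both terms of that QTL), the model LOD against the
#' covariate-only null, and genotype-class means at each QTL.
#'
#' @inheritParams scan_hk
#' @param qtl Data frame with columns `chr`, `pos` (one row per QTL).
#' @param extra_covar Optional additional covariate column(s) appended to
#'   the design (e.g. a mediating trait); coefficients are reported.
#' @return Object of class `qtl_model`: list with `coef`, `vcov`, `lod`,
#'   `rss`, `tss`, `qtl` (with `pct_var` and additive/dominance estimates
#'   and SEs), `effects` (class means per QTL), `n`, `sigma2`.
#' @export
fit_multi_qtl <- function(probs, pheno, weights = NULL, covar = NULL,
                          qtl, extra_covar = NULL) {
  stopifnot(inherits(probs, "genoprob"))
  n_all <- attr(probs, "n_ind")
  if (is.null(weights)) weights <- rep(1, n_all)
  cm <- covar_matrix(covar, n_all)
  des <- multiqtl_design(probs, qtl)
  X <- cbind(cm, des$G)
  if (!is.null(extra_covar)) {
    ec <- as.matrix(extra_covar)
    if (is.null(colnames(ec))) colnames(ec) <- paste0("mediator", seq_len(ncol(ec)))
    X <- cbind(X, ec)
  }
  keep <- !is.na(pheno) & !is.na(weights) & stats::complete.cases(X)
  y <- pheno[keep]; w <- weights[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  stop_if_not(n > ncol(X), "model not identifiable: more terms than individuals")
  full <- wls_vcov(X, y, w)
  stop_if_not(full$rank == ncol(X), "multiple-QTL design is singular")
  null_cols <- seq_len(ncol(cm))
  rss0 <- wls_rss(X[, null_cols, drop = FALSE], y, w)$rss
  wm <- stats::weighted.mean(y, w)
  tss <- sum(w * (y - wm)^2)
  lod <- (n / 2) * log10(rss0 / full$rss)
  info <- des$info
  info$pct_var <- NA_real_
  info$beta_a <- full$coef[info$a_col]
  info$se_a <- sqrt(diag(full$vcov))[info$a_col]
  info$beta_d <- ifelse(is.na(info$d_col), NA_real_, full$coef[info$d_col])
  for (i in seq_len(nrow(info))) {
    drop_cols <- stats::na.omit(c(info$a_col[i], info$d_col[i]))
    Xd <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
    rss_d <- wls_rss(Xd, y, w)$rss
    info$pct_var[i] <- 100 * (rss_d - full$rss) / tss
  }
  effects <- lapply(seq_len(nrow(info)), function(i) {
    effect_at(probs, pheno, weights, covar, info$chr[i], info$pos[i])
  })
  names(effects) <- sprintf("%s:%g", info$chr, info$pos)
  structure(list(coef = full$coef, vcov = full$vcov, lod = lod,
                 rss = full$rss, tss = tss, sigma2 = full$sigma2,
                 qtl = info, effects = effects, n = n,
                 pct_var_model = 100 * (rss0 - full$rss) / tss),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("multiple-QTL model: %d QTL, n = %d, LOD = %.2f, %%var = %.1f\n",
              nrow(x$qtl), x$n, x$lod, x$pct_var_model))
  print(x$qtl[, c("chr", "pos", "beta_a", "se_a", "beta_d", "pct_var")])
  invisible(x)
}

#' Percent of the parental strain difference explained by QTL
#'
#' Sums the additive allele-substitution effects of (autosomal) QTL and
#' expresses them as a percentage of the parental phenotype difference:
#' `100 * sum(2 * beta_a) / (mean_B - mean_A)`, with `beta_a` oriented as
#' the effect of the B (strain-2) allele. QTL acting against the strain
#' difference contribute negatively.
#'
#' @param model A `qtl_model`.
#' @param parental_means Length-2 numeric: mean phenotype of the A-strain
#'   and B-strain parents (in that order).
#' @param qtl_rows Optional subset of rows of `model$qtl` to sum (default:
#'   all autosomal QTL).
#' @return Percentage (may be negative or exceed 100).
#' @export
percent_strain_difference_explained <- function(model, parental_means,
                                                qtl_rows = NULL) {
  stopifnot(inherits(model, "qtl_model"), length(parental_means) == 2)
  diff <- parental_means[2] - parental_means[1]
  stop_if_not(abs(diff) > 0, "equal parental means: percentage undefined")
  rows <- qtl_rows %||% which(!model$qtl$is_x)
  stop_if_not(length(rows) > 0, "no autosomal QTL to sum")
  100 * sum(2 * model$qtl$beta_a[rows]) / diff
}
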