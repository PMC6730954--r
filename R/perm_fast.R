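# Vectorized permutation engine for genome-wide thresholds. For fixed
# phenotype, weights and covariates, the null-model projection is constant
# across permutations; per replicate only the genotype rows are permuted,
# and every position's LOD follows from a rank-1/2 update:
#   RSS1 = RSS0 - a' S^{-1} a
# with a = G~' r_y and S = G~' G~, where G~ is the (weighted) genotype
# design projected off the covariate block and r_y the projected response.
# Algebraically identical to the scan_hk regression at every position.

prep_fast_scan <- function(probs, pheno, weights, covar) {
  n_all <- attr(probs, "n_ind")
  if (is.null(weights)) weights <- rep(1, n_all)
  cm <- covar_matrix(covar, n_all)
  keep <- !is.na(pheno) & !is.na(weights) & stats::complete.cases(cm)
  y <- pheno[keep]; w <- weights[keep]
  cm <- cm[keep, , drop = FALSE]
  n <- length(y)
  sw <- sqrt(w)
  Q0 <- qr.Q(qr(cm * sw))
  yt <- y * sw
  r_y <- yt - Q0 %*% crossprod(Q0, yt)
  rss0 <- sum(r_y^2)
  # stack genotype designs: autosomal positions (2 columns each) and X
  # positions (1 column each), rows restricted to kept individuals
  G2 <- list(); G1 <- list()
  pos_tab <- list()
  for (ch in names(probs)) {
    np <- length(probs[[ch]]$pos)
    for (j in seq_len(np)) {
      G <- genoprob_design(probs, ch, j)[keep, , drop = FALSE]
      if (probs[[ch]]$is_x) G1[[length(G1) + 1L]] <- G else G2[[length(G2) + 1L]] <- G
      pos_tab[[length(pos_tab) + 1L]] <- data.frame(
        chr = ch, pos = probs[[ch]]$pos[j], is_x = probs[[ch]]$is_x)
    }
  }
  list(n = n, sw = sw, Q0 = Q0, r_y = r_y, rss0 = rss0,
       G2 = if (length(G2)) do.call(cbind, G2) else NULL,
       G1 = if (length(G1)) do.call(cbind, G1) else NULL,
       pos = do.call(rbind, pos_tab))
}

# LOD at every stacked position for one permutation of the genotype rows.
fast_scan_lod <- function(prep, idx) {
  lod_a <- lod_x <- numeric(0)
  rss_eps <- 1e-12 * (prep$rss0 + 1)
  lod_from_quad <- function(quad) {
    rss1 <- pmax(prep$rss0 - quad, 0)
    lod <- (prep$n / 2) * log10(prep$rss0 / rss1)
    lod[rss1 <= rss_eps] <- Inf
    lod[is.na(quad)] <- NA
    if (prep$rss0 <= rss_eps) lod[] <- 0
    pmax(lod, 0)
  }
  if (!is.null(prep$G2)) {
    Gp <- prep$G2[idx, , drop = FALSE] * prep$sw
    Gh <- Gp - prep$Q0 %*% crossprod(prep$Q0, Gp)
    a <- crossprod(Gh, prep$r_y)
    s <- colSums(Gh * Gh)
    o <- seq(1, ncol(Gh), by = 2)
    s12 <- colSums(Gh[, o, drop = FALSE] * Gh[, o + 1, drop = FALSE])
    a1 <- a[o]; a2 <- a[o + 1]
    s11 <- s[o]; s22 <- s[o + 1]
    det <- s11 * s22 - s12^2
    quad <- (a1^2 * s22 - 2 * a1 * a2 * s12 + a2^2 * s11) / det
    quad[!is.finite(quad) | det <= 1e-10 * (s11 * s22 + 1e-300)] <- NA
    lod_a <- lod_from_quad(quad)
  }
  if (!is.null(prep$G1)) {
    Gp <- prep$G1[idx, , drop = FALSE] * prep$sw
    Gh <- Gp - prep$Q0 %*% crossprod(prep$Q0, Gp)
    a <- as.vector(crossprod(Gh, prep$r_y))
    s <- colSums(Gh * Gh)
    quad <- a^2 / s
    quad[s <= 1e-12] <- NA
    lod_x <- lod_from_quad(quad)
  }
  out <- numeric(nrow(prep$pos))
  out[!prep$pos$is_x] <- lod_a
  out[prep$pos$is_x] <- lod_x
  out
}
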