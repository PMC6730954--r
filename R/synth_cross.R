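# Synthetic F2 intercross generator: genetic maps, genotypes under Haldane
# recombination, and cell-level bivariate phenotypes with an optional
# mediation chain between crossover count and SC length.

#' Build a genetic map
#'
#' Constructs a marker map for a set of chromosomes with evenly spaced
#' markers. The default emulates a mouse-like genome: 19 autosomes plus X.
#' Physical positions (Mb) are filled by a constant cM-to-Mb expansion so
#' that support intervals can be reported on both scales.
#'
#' @param chr_lengths_cM Named numeric vector of chromosome lengths in cM.
#'   Names are chromosome labels; a chromosome named `"X"` is treated as the
#'   X chromosome (hemizygous in F2 males).
#' @param marker_spacing_cM Spacing between adjacent markers in cM.
#' @param mb_per_cM Constant used to synthesize Mb positions from cM.
#' @return A data frame of class `genetic_map` with columns `marker`, `chr`,
#'   `pos` (cM) and `pos_mb`.
#' @examples
#' map <- genetic_map(c("1" = 80, X = 70), marker_spacing_cM = 10)
#' @export
genetic_map <- function(chr_lengths_cM = default_chr_lengths(),
                        marker_spacing_cM = 10,
                        mb_per_cM = 2) {
  stop_if_not(length(chr_lengths_cM) >= 1 && all(chr_lengths_cM > 0),
              "chromosome lengths must be positive")
  stop_if_not(is_number(marker_spacing_cM, min = 1e-8),
              "marker_spacing_cM must be a positive number")
  chrs <- names(chr_lengths_cM)
  if (is.null(chrs)) chrs <- as.character(seq_along(chr_lengths_cM))
  rows <- lapply(seq_along(chrs), function(i) {
    pos <- seq(0, chr_lengths_cM[[i]], by = marker_spacing_cM)
    if (pos[length(pos)] < chr_lengths_cM[[i]]) {
      pos <- c(pos, chr_lengths_cM[[i]])
    }
    data.frame(
      marker = sprintf("c%sm%d", chrs[i], seq_along(pos)),
      chr = chrs[i],
      pos = pos,
      pos_mb = pos * mb_per_cM,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  validate_map(map)
  map
}

default_chr_lengths <- function() {
  # Mouse-like: 19 autosomes shrinking from ~98 to ~60 cM, X ~ 72 cM.
  len <- round(seq(98, 60, length.out = 19))
  names(len) <- as.character(1:19)
  c(len, X = 72)
}

validate_map <- function(map) {
  stop_if_not(all(c("marker", "chr", "pos") %in% names(map)),
              "map must have columns marker, chr, pos")
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (any(diff(p) <= 0)) {
      stop(sprintf("marker positions must be strictly increasing on chromosome %s", ch),
           call. = FALSE)
    }
  }
  invisible(map)
}

map_is_x <- function(map) map$chr == "X"

#' Configuration for a synthetic F2 intercross
#'
#' Bundles the genetic map, sample size, QTL effects, an optional mediation
#' chain, cell-replication and noise parameters for
#' [simulate_f2_genotypes()] and [simulate_phenotypes()].
#'
#' The phenotype model at the individual level is
#' \deqn{CO_i = \mu_{CO} + \sum_q (a_q x_{a,iq} + d_q x_{d,iq}) +
#'       \gamma x_{a,i,med} + c_{CO} z_i + e_i}
#' \deqn{SC_i = \mu_{SC} + \sum_q (a_q x_{a,iq} + d_q x_{d,iq}) +
#'       \beta' x_{a,i,med} + \alpha (CO_i - \mu_{CO}) + c_{SC} z_i + u_i}
#' where \eqn{x_a \in \{-1, 0, 1\}} counts B alleles minus one (so `a` is
#' half the homozygote difference), \eqn{x_d} indicates heterozygotes,
#' \eqn{z} is the cross-direction covariate, and the mediation chain
#' (QTL -> CO -> SC) contributes \eqn{\gamma}, \eqn{\alpha} and the direct
#' effect \eqn{\beta'}. Cell-level observations add independent Gaussian
#' noise around the individual latent values; crossover counts are rounded
#' to non-negative integers.
#'
#' Default intercepts and noise levels were calibrated once to published F2
#' summary statistics for house-mouse spermatocytes (cell-level SD about
#' 18.7 um SC length and 3.3 MLH1 foci; individual-mean SD about 9.7 um and
#' 2.6 foci; a median of 18 cells per individual).
#'
#' @param map A `genetic_map`.
#' @param n_individuals Number of F2 males.
#' @param qtl Data frame with columns `trait` ("sc" or "co"), `chr`, `pos`,
#'   `a` (additive effect), `d` (dominance effect), or `NULL`.
#' @param mediation Optional list with elements `chr`, `pos`,
#'   `qtl_to_mediator` (gamma), `alpha` (CO -> SC coefficient), `direct`
#'   (beta-prime, direct QTL -> SC effect).
#' @param sc_intercept,co_intercept Trait means (um; focus count).
#' @param sc_individual_sd,co_individual_sd Individual-level residual SDs.
#' @param sc_cell_sd,co_cell_sd Within-individual (cell-level) noise SDs.
#' @param cells_median,cells_sd,cells_min Cell-count distribution per
#'   individual: `round(rnorm(n, cells_median, cells_sd))` clamped below at
#'   `cells_min`.
#' @param sc_direction_effect,co_direction_effect Additive effect of the
#'   cross-direction covariate on each trait.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `sim_cross_config`.
#' @export
sim_cross_config <- function(map = genetic_map(),
                             n_individuals = 300,
                             qtl = NULL,
                             mediation = NULL,
                             sc_intercept = 159, co_intercept = 25,
                             sc_individual_sd = 9, co_individual_sd = 2.4,
                             sc_cell_sd = 15, co_cell_sd = 2.2,
                             cells_median = 18, cells_sd = 5, cells_min = 1,
                             sc_direction_effect = 0,
                             co_direction_effect = 0,
                             seed = 1L) {
  validate_map(map)
  stop_if_not(is_count(n_individuals), "n_individuals must be a positive integer")
  for (nm in c("sc_individual_sd", "co_individual_sd", "sc_cell_sd",
               "co_cell_sd", "cells_sd")) {
    stop_if_not(is_number(get(nm), min = 0), "%s must be >= 0", nm)
  }
  if (!is.null(qtl)) {
    stop_if_not(all(c("trait", "chr", "pos", "a", "d") %in% names(qtl)),
                "qtl must have columns trait, chr, pos, a, d")
    stop_if_not(all(qtl$trait %in% c("sc", "co")),
                "qtl$trait must be 'sc' or 'co'")
    stop_if_not(all(as.character(qtl$chr) %in% unique(map$chr)),
                "qtl chromosome not in map")
  }
  if (!is.null(mediation)) {
    need <- c("chr", "pos", "qtl_to_mediator", "alpha", "direct")
    stop_if_not(all(need %in% names(mediation)),
                "mediation needs elements %s", paste(need, collapse = ", "))
  }
  structure(
    list(map = map, n_individuals = as.integer(n_individuals), qtl = qtl,
         mediation = mediation,
         sc_intercept = sc_intercept, co_intercept = co_intercept,
         sc_individual_sd = sc_individual_sd,
         co_individual_sd = co_individual_sd,
         sc_cell_sd = sc_cell_sd, co_cell_sd = co_cell_sd,
         cells_median = cells_median, cells_sd = cells_sd,
         cells_min = cells_min,
         sc_direction_effect = sc_direction_effect,
         co_direction_effect = co_direction_effect,
         seed = as.integer(seed)),
    class = "sim_cross_config"
  )
}

# Positions of loci that must be simulated on a chromosome: markers plus any
# hidden QTL/mediation loci. Returns a data.frame(pos, marker, hidden).
chr_sim_positions <- function(map, chr, hidden_pos) {
  m <- map[map$chr == chr, , drop = FALSE]
  pos <- m$pos
  lab <- m$marker
  hid <- rep(FALSE, length(pos))
  for (hp in hidden_pos) {
    if (!any(abs(pos - hp) < 1e-9)) {
      pos <- c(pos, hp)
      lab <- c(lab, sprintf("q%s@%g", chr, hp))
      hid <- c(hid, TRUE)
    }
  }
  o <- order(pos)
  data.frame(pos = pos[o], marker = lab[o], hidden = hid[o],
             stringsAsFactors = FALSE)
}

# Simulate n gamete haplotypes along positions `pos` (cM) under Haldane
# recombination. Returns an n x length(pos) 0/1 matrix.
sim_gametes <- function(n, pos) {
  m <- length(pos)
  g <- matrix(0L, n, m)
  g[, 1] <- rbinom(n, 1L, 0.5)
  if (m > 1) {
    r <- haldane_r(diff(pos))
    for (j in 2:m) {
      swap <- rbinom(n, 1L, r[j - 1L])
      g[, j] <- ifelse(swap == 1L, 1L - g[, j - 1L], g[, j - 1L])
    }
  }
  g
}

#' Simulate F2 genotypes
#'
#' Draws genotypes for all F2 males in the cross under a no-interference
#' (Haldane) crossover process: each autosome receives two independent
#' gamete haplotypes from heterozygous F1 parents; the single X of each F2
#' male is one gamete from the heterozygous F1 dam, giving hemizygous
#' genotypes `AY`/`BY`.
#'
#' If the config declares QTL or a mediation locus at positions without a
#' marker, those loci are simulated jointly with the markers and stored as
#' hidden ground-truth genotypes (`$hidden` element) for use by
#' [simulate_phenotypes()]; they are not part of the marker genotype matrix.
#'
#' @param config A [sim_cross_config()].
#' @return An object of class `f2cross`: list with elements `map`
#'   (`genetic_map`), `geno` (individuals x markers character matrix with
#'   codes `AA`/`AB`/`BB` on autosomes, `AY`/`BY` on X), `covar` (data frame
#'   with `individual_id`, `cross_direction`), and `hidden` (ground-truth
#'   genotypes at unmarked simulated loci).
#' @export
simulate_f2_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_cross_config"))
  map <- validate_map(config$map)
  n <- config$n_individuals
  hpos <- c(config$qtl$pos, config$mediation$pos)
  hchr <- c(as.character(config$qtl$chr), as.character(config$mediation$chr))
  hidden_by_chr <- if (length(hpos)) split(hpos, hchr) else list()
  with_seed(config$seed, {
    geno_cols <- list()
    hidden_cols <- list()
    for (ch in unique(map$chr)) {
      loci <- chr_sim_positions(map, ch, hidden_by_chr[[ch]] %||% numeric(0))
      if (ch == "X") {
        gam <- sim_gametes(n, loci$pos)
        codes <- matrix(c("AY", "BY")[gam + 1L], n, nrow(loci))
      } else {
        g <- sim_gametes(n, loci$pos) + sim_gametes(n, loci$pos)
        codes <- matrix(c("AA", "AB", "BB")[g + 1L], n, nrow(loci))
      }
      colnames(codes) <- loci$marker
      geno_cols[[ch]] <- codes[, !loci$hidden, drop = FALSE]
      if (any(loci$hidden)) {
        hid <- codes[, loci$hidden, drop = FALSE]
        colnames(hid) <- sprintf("%s@%g", ch, loci$pos[loci$hidden])
        hidden_cols[[ch]] <- hid
      }
      # genotypes at marker-coincident QTL are looked up from geno directly
    }
    geno <- do.call(cbind, geno_cols)
    stopifnot(identical(colnames(geno), map$marker))
    ids <- sprintf("ind%03d", seq_len(n))
    rownames(geno) <- ids
    covar <- data.frame(
      individual_id = ids,
      cross_direction = factor(rep_len(c("AxB", "BxA"), n)),
      stringsAsFactors = FALSE
    )
    hidden <- if (length(hidden_cols)) do.call(cbind, hidden_cols) else NULL
    structure(list(map = map, geno = geno, covar = covar, hidden = hidden),
              class = "f2cross")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Additive dosage (-1, 0, 1) and heterozygote indicator at a simulated locus
# (marker or hidden), from true genotype codes.
locus_dosage <- function(cross, chr, pos) {
  chr <- as.character(chr)
  m <- cross$map
  idx <- which(m$chr == chr & abs(m$pos - pos) < 1e-9)
  if (length(idx) == 1L) {
    codes <- cross$geno[, m$marker[idx]]
  } else {
    key <- sprintf("%s@%g", chr, pos)
    stop_if_not(!is.null(cross$hidden) && key %in% colnames(cross$hidden),
                "no simulated genotypes at %s:%g", chr, pos)
    codes <- cross$hidden[, key]
  }
  xa <- c(AA = -1, AB = 0, BB = 1, AY = -1, BY = 1)[codes]
  xd <- as.numeric(codes == "AB")
  list(xa = unname(xa), xd = unname(xd))
}

#' Simulate cell-level phenotypes
#'
#' Generates spermatocyte records (SC length in um and MLH1 focus count per
#' cell) for every individual in a simulated cross, under the additive +
#' dominance QTL model, optional mediation chain, cross-direction covariate
#' effects and two-level (individual + cell) Gaussian noise described in
#' [sim_cross_config()].
#'
#' @param cross An `f2cross` from [simulate_f2_genotypes()].
#' @param config The same [sim_cross_config()] used to create `cross`.
#' @return A data frame of records with columns `individual_id`, `cell_id`,
#'   `sc_length_um`, `mlh1_count`. The individual-level latent trait values
#'   and cell counts are attached as attribute `"latent"` for use as a
#'   simulation oracle.
#' @export
simulate_phenotypes <- function(cross, config) {
  stopifnot(inherits(cross, "f2cross"), inherits(config, "sim_cross_config"))
  n <- nrow(cross$geno)
  qtl_effect <- function(trait) {
    eff <- numeric(n)
    q <- config$qtl
    if (!is.null(q)) {
      q <- q[q$trait == trait, , drop = FALSE]
      for (i in seq_len(nrow(q))) {
        dz <- locus_dosage(cross, q$chr[i], q$pos[i])
        eff <- eff + q$a[i] * dz$xa + q$d[i] * dz$xd
      }
    }
    eff
  }
  z <- as.numeric(cross$covar$cross_direction) - 1.5  # centered +-0.5
  with_seed(config$seed + 1L, {
    med <- config$mediation
    med_xa <- if (!is.null(med)) locus_dosage(cross, med$chr, med$pos)$xa else 0
    latent_co <- config$co_intercept + qtl_effect("co") +
      (if (!is.null(med)) med$qtl_to_mediator * med_xa else 0) +
      config$co_direction_effect * z +
      rnorm(n, 0, config$co_individual_sd)
    latent_sc <- config$sc_intercept + qtl_effect("sc") +
      (if (!is.null(med)) med$direct * med_xa +
         med$alpha * (latent_co - config$co_intercept) else 0) +
      config$sc_direction_effect * z +
      rnorm(n, 0, config$sc_individual_sd)
    n_cells <- pmax(config$cells_min,
                    round(rnorm(n, config$cells_median, config$cells_sd)))
    ids <- rownames(cross$geno)
    rec <- data.frame(
      individual_id = rep(ids, n_cells),
      cell_id = unlist(lapply(n_cells, seq_len), use.names = FALSE),
      stringsAsFactors = FALSE
    )
    idx <- rep(seq_len(n), n_cells)
    rec$sc_length_um <- pmax(0.1, latent_sc[idx] +
                               rnorm(nrow(rec), 0, config$sc_cell_sd))
    rec$mlh1_count <- pmax(0L, as.integer(round(
      latent_co[idx] + rnorm(nrow(rec), 0, config$co_cell_sd))))
    attr(rec, "latent") <- data.frame(
      individual_id = ids, latent_sc = latent_sc, latent_co = latent_co,
      n_cells = n_cells, cross_direction = cross$covar$cross_direction,
      stringsAsFactors = FALSE
    )
    rec
  })
}

#' Add cell-level Gaussian noise to a trait
#'
#' Perturbs one trait of a record table with independent Gaussian noise per
#' cell, either with a fixed SD or with a per-individual SD chosen so that
#' the expected within-individual coefficient of variation reaches
#' `target_cv`: the added variance for individual i is
#' `(mean_i * target_cv)^2 - s2_i`, floored at zero, where `s2_i` is the
#' current within-individual variance. This is the perturbation used by the
#' mediation measurement-error sensitivity analysis.
#'
#' @param records Record data frame (see [simulate_phenotypes()]).
#' @param trait Column to perturb: `"sc_length_um"` or `"mlh1_count"`.
#' @param sd Fixed noise SD (>= 0), or `NULL` to use `target_cv`.
#' @param target_cv Target within-individual CV, or `NULL` to use `sd`.
#' @param seed Optional integer seed.
#' @return The records with the perturbed trait column (numeric; counts are
#'   not re-rounded, since the sensitivity analysis operates on the
#'   continuous scale). If `target_cv` is below the current CV for every
#'   individual the records are returned unchanged with a warning.
#' @export
add_cellwise_gaussian_noise <- function(records, trait = "sc_length_um",
                                        sd = NULL, target_cv = NULL,
                                        seed = NULL) {
  stop_if_not(trait %in% names(records), "trait column %s missing", trait)
  stop_if_not(xor(is.null(sd), is.null(target_cv)),
              "give exactly one of sd or target_cv")
  with_seed(seed, {
    x <- as.numeric(records[[trait]])
    keep <- !is.na(x)
    if (!is.null(sd)) {
      stop_if_not(is_number(sd, min = 0), "sd must be >= 0")
      if (sd > 0) x[keep] <- x[keep] + rnorm(sum(keep), 0, sd)
    } else {
      stop_if_not(is_number(target_cv, min = 0), "target_cv must be >= 0")
      sds <- noise_sd_for_target_cv(x[keep], records$individual_id[keep],
                                    target_cv)
      if (isTRUE(attr(sds, "all_below"))) {
        warning("target_cv does not exceed the current CV for any individual; records unchanged")
        return(records)
      }
      x[keep] <- x[keep] + rnorm(sum(keep), 0, sds)
    }
    records[[trait]] <- x
    records
  })
}

# Per-cell noise SD that raises each individual's expected within-individual
# CV to target_cv (0 where already at or above it). Attribute "all_below"
# flags a target strictly below every individual's current CV.
noise_sd_for_target_cv <- function(x, id, target_cv) {
  mu <- tapply(x, id, mean)
  s2 <- tapply(x, id, function(v) if (length(v) > 1) stats::var(v) else 0)
  raw <- (mu * target_cv)^2 - s2
  out <- sqrt(pmax(0, raw))[match(id, names(mu))]
  attr(out, "all_below") <- all(raw < -1e-12)
  out
}
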