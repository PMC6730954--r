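# Conditional genotype probabilities along the marker chain, the
# prerequisite of Haley-Knott regression. Forward-backward over a hidden
# Markov chain with Haldane transition probabilities: autosomal F2
# genotypes as the product of two independent gamete chains, a two-state
# chain on the male X.

# 3x3 F2 genotype transition matrix at recombination fraction r
# (states AA, AB, BB), as the product of two independent gamete chains.
f2_transition <- function(r) {
  s <- 1 - r
  matrix(c(s^2,     2 * r * s, r^2,
           r * s,   s^2 + r^2, r * s,
           r^2,     2 * r * s, s^2),
         nrow = 3, byrow = TRUE)
}

x_transition <- function(r) {
  matrix(c(1 - r, r, r, 1 - r), nrow = 2, byrow = TRUE)
}

geno_states <- function(is_x) if (is_x) c("AY", "BY") else c("AA", "AB", "BB")

# Emission matrix rows = observed code (including missing), cols = true
# state, with symmetric genotyping error.
emission_prob <- function(obs, states, error_prob) {
  k <- length(states)
  e <- matrix(1, length(obs), k)  # missing -> flat
  known <- obs %in% states
  if (any(known)) {
    match_idx <- match(obs[known], states)
    em <- matrix(error_prob / (k - 1), sum(known), k)
    em[cbind(seq_len(sum(known)), match_idx)] <- 1 - error_prob
    e[known, ] <- em
  }
  e
}

#' Conditional genotype probabilities
#'
#' Computes, for every individual and every evaluation position (markers
#' plus pseudomarkers on a regular cM grid), the probability of each
#' genotype class given all marker data on the chromosome, under Haldane
#' recombination. Autosomes use the three F2 states `AA`/`AB`/`BB` with
#' prior 1:2:1; the male X uses the two hemizygous states `AY`/`BY` with
#' prior 1:1.
#'
#' @param cross An `f2cross`.
#' @param step_cM Pseudomarker spacing in cM; `0` evaluates at markers only.
#' @param error_prob Genotyping error rate (default 0: observed genotypes
#'   are taken as true).
#' @return An object of class `genoprob`: a list with one element per
#'   chromosome, each containing `pos` (cM), `marker` (labels, `""` for
#'   pseudomarkers), `is_x`, and `prob`, an individuals x positions x
#'   states array. Probabilities are non-negative and sum to one at every
#'   position.
#' @export
genotype_probabilities <- function(cross, step_cM = 1, error_prob = 0) {
  stopifnot(inherits(cross, "f2cross"))
  stop_if_not(is_number(step_cM, min = 0), "step_cM must be >= 0")
  stop_if_not(is_number(error_prob, min = 0) && error_prob < 1,
              "error_prob must be in [0, 1)")
  map <- cross$map
  out <- list()
  for (ch in unique(map$chr)) {
    m <- map[map$chr == ch, , drop = FALSE]
    stop_if_not(nrow(m) >= 1, "chromosome %s has no typed markers", ch)
    is_x <- ch == "X"
    states <- geno_states(is_x)
    grid <- insert_pseudomarkers(m$pos, step_cM)
    obs <- cross$geno[, m$marker, drop = FALSE]
    prob <- hmm_chromosome(obs, m$pos, grid$pos, grid$marker_idx,
                           states, is_x, error_prob)
    dimnames(prob) <- list(rownames(cross$geno), NULL, states)
    lab <- rep("", length(grid$pos))
    lab[!is.na(grid$marker_idx)] <- m$marker[grid$marker_idx[!is.na(grid$marker_idx)]]
    out[[ch]] <- list(pos = grid$pos, marker = lab, is_x = is_x, prob = prob)
  }
  structure(out, class = "genoprob",
            n_ind = nrow(cross$geno), ids = rownames(cross$geno))
}

# Evaluation grid: markers plus pseudomarkers every step_cM.
# marker_idx gives, per grid point, the index of the coinciding marker (NA
# for pure pseudomarkers).
insert_pseudomarkers <- function(marker_pos, step_cM) {
  if (step_cM <= 0) {
    return(list(pos = marker_pos, marker_idx = seq_along(marker_pos)))
  }
  grid <- seq(marker_pos[1], marker_pos[length(marker_pos)], by = step_cM)
  pos <- sort(unique(round(c(grid, marker_pos), 8)))
  marker_idx <- match(round(marker_pos, 8), pos)
  idx <- rep(NA_integer_, length(pos))
  idx[marker_idx] <- seq_along(marker_pos)
  list(pos = pos, marker_idx = idx)
}

# Forward-backward over one chromosome for all individuals.
# obs: n x n_markers character; returns n x n_grid x k array.
hmm_chromosome <- function(obs, marker_pos, grid_pos, marker_idx,
                           states, is_x, error_prob) {
  n <- nrow(obs)
  k <- length(states)
  ng <- length(grid_pos)
  trans <- function(d) if (is_x) x_transition(haldane_r(d)) else f2_transition(haldane_r(d))
  prior <- if (is_x) c(0.5, 0.5) else c(0.25, 0.5, 0.25)
  # Emission at every grid point (flat at pseudomarkers).
  emis <- vector("list", ng)
  for (j in seq_len(ng)) {
    emis[[j]] <- if (is.na(marker_idx[j])) {
      matrix(1, n, k)
    } else {
      emission_prob(obs[, marker_idx[j]], states, error_prob)
    }
  }
  Tm <- lapply(seq_len(max(ng - 1, 0)),
               function(j) trans(grid_pos[j + 1] - grid_pos[j]))
  slice <- function(arr, j) matrix(arr[, j, ], nrow = n, ncol = k)
  # Forward
  fwd <- array(0, c(n, ng, k))
  a <- sweep(emis[[1]], 2, prior, `*`)
  fwd[, 1, ] <- a / rowSums(a)
  if (ng > 1) {
    for (j in 2:ng) {
      a <- (slice(fwd, j - 1) %*% Tm[[j - 1]]) * emis[[j]]
      fwd[, j, ] <- a / rowSums(a)
    }
  }
  # Backward
  bwd <- array(0, c(n, ng, k))
  bwd[, ng, ] <- 1
  if (ng > 1) {
    for (j in (ng - 1):1) {
      b <- (slice(bwd, j + 1) * emis[[j + 1]]) %*% t(Tm[[j]])
      bwd[, j, ] <- b / rowSums(b)
    }
  }
  post <- fwd * bwd
  tot <- apply(post, c(1, 2), sum)
  post / array(rep(tot, k), c(n, ng, k))
}

#' @export
print.genoprob <- function(x, ...) {
  cat(sprintf("genotype probabilities: %d individuals, %d chromosomes, %d positions\n",
              attr(x, "n_ind"), length(x), sum(vapply(x, function(ch) length(ch$pos), 1L))))
  invisible(x)
}

# Locate the grid index of a position on a chromosome (nearest grid point).
genoprob_index <- function(probs, chr, pos) {
  chr <- as.character(chr)
  stop_if_not(chr %in% names(probs), "chromosome %s not in genoprob", chr)
  j <- which.min(abs(probs[[chr]]$pos - pos))
  list(chr = chr, j = j, pos = probs[[chr]]$pos[j], is_x = probs[[chr]]$is_x)
}

# Genotype design columns at one grid point: additive dosage and (autosome)
# dominance indicator expectation.
genoprob_design <- function(probs, chr, j) {
  p <- probs[[chr]]$prob
  if (probs[[chr]]$is_x) {
    cbind(a = p[, j, "BY"] - p[, j, "AY"])
  } else {
    cbind(a = p[, j, "BB"] - p[, j, "AA"], d = p[, j, "AB"])
  }
}
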