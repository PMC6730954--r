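# Causal mediation analysis of pleiotropic QTL: paired regression models
# with and without the mediating trait, Sobel test with pooled SE,
# permutation null of the mediator, proportion mediated with delta-method
# error, and the measurement-error sensitivity analysis.

#' Sobel test of an indirect (mediated) effect
#'
#' Tests the product of the QTL-to-mediator path (`beta`) and the
#' mediator-to-outcome path (`alpha`) with the pooled standard error
#' `SE = sqrt(alpha^2 * var_beta + beta^2 * var_alpha)`; the statistic
#' `t = alpha * beta / SE` is referred to the standard normal, two-tailed.
#'
#' @param alpha Mediator coefficient in the mediated outcome model.
#' @param beta QTL additive effect on the mediator.
#' @param var_alpha,var_beta Sampling variances of the two coefficients.
#' @return List with `t`, `se`, `p` (two-tailed analytic p-value).
#' @examples
#' sobel_test(1, 1, 0.04, 0.09)  # t = 2.7735, p = 0.00554
#' @export
sobel_test <- function(alpha, beta, var_alpha, var_beta) {
  stop_if_not(is_number(var_alpha, min = 0) && is_number(var_beta, min = 0),
              "coefficient variances must be >= 0")
  se <- sqrt(alpha^2 * var_beta + beta^2 * var_alpha)
  stop_if_not(se > 0, "pooled SE is zero: Sobel statistic undefined")
  t <- alpha * beta / se
  list(t = t, se = se, p = 2 * stats::pnorm(-abs(t)))
}

#' Proportion of a QTL effect explained by a mediator
#'
#' `f = (beta - beta_prime) / beta`: the fraction of the total QTL effect
#' removed when the mediator enters the model. May be negative
#' (inconsistent mediation, opposite-sign direct effect) or exceed one. The
#' standard error is first-order delta method on `(beta, beta_prime)`
#' including their sampling covariance.
#'
#' @param beta Unmediated QTL additive effect (nonzero).
#' @param beta_prime Mediated (direct) QTL effect.
#' @param var_beta,var_beta_prime,cov_bb Sampling (co)variances; default 0
#'   gives the point estimate only.
#' @return List with `f` and `se`.
#' @examples
#' proportion_mediated(3.73, 2.96)$f  # 0.2064
#' @export
proportion_mediated <- function(beta, beta_prime, var_beta = 0,
                                var_beta_prime = 0, cov_bb = 0) {
  stop_if_not(is.numeric(beta) && beta != 0, "beta must be nonzero")
  f <- (beta - beta_prime) / beta
  g <- c(beta_prime / beta^2, -1 / beta)  # d f / d(beta, beta')
  v <- g[1]^2 * var_beta + g[2]^2 * var_beta_prime + 2 * g[1] * g[2] * cov_bb
  list(f = f, se = sqrt(max(v, 0)))
}

# Shared regression machinery for one mediation direction.
# Returns kept-row designs and index of the focal additive column.
mediation_designs <- function(probs, outcome, mediator, qtl, locus,
                              weights, covar) {
  n_all <- attr(probs, "n_ind")
  if (is.null(weights)) weights <- rep(1, n_all)
  cm <- covar_matrix(covar, n_all)
  des <- multiqtl_design(probs, qtl)
  loc <- genoprob_index(probs, locus[["chr"]], as.numeric(locus[["pos"]]))
  a_col <- sprintf("a_%s_%g", loc$chr, loc$pos)
  if (!a_col %in% colnames(des$G)) {
    # focal locus not among the model's QTL: append it
    extra <- multiqtl_design(probs, data.frame(chr = loc$chr, pos = loc$pos))
    des$G <- cbind(des$G, extra$G)
  }
  keep <- !is.na(outcome) & !is.na(mediator) & !is.na(weights) &
    stats::complete.cases(cm)
  stop_if_not(stats::sd(mediator[keep]) > 0, "mediator is constant: degenerate")
  X <- cbind(cm, des$G)[keep, , drop = FALSE]
  list(X = X, y = outcome[keep], m = mediator[keep], w = weights[keep],
       a_col = a_col, n = sum(keep))
}

#' Fit the paired mediation models at a locus
#'
#' For one direction of mediation (outcome trait possibly mediated by the
#' mediator trait), fits the outcome's multiple-QTL model without
#' (unmediated) and with (mediated) the mediator as a covariate, and the
#' regression of the mediator on the same QTL design. Reports the focal
#' locus's additive effect in each (`beta`, `beta_prime`, `beta_med`), the
#' mediator coefficient `alpha_med` with variance, the Sobel statistic and
#' analytic p-value, and the proportion mediated `f` with a delta-method
#' SE that includes the sampling covariance of `beta` and `beta_prime`
#' (both are linear functionals of the same outcome vector).
#'
#' @inheritParams scan_hk
#' @param outcome Numeric outcome trait per individual.
#' @param mediator Numeric mediating trait per individual.
#' @param qtl Data frame (`chr`, `pos`): all QTL in the outcome trait's
#'   multiple-QTL model (the focal locus is appended if absent).
#' @param locus Focal locus, e.g. `c(chr = "4", pos = 44)`.
#' @return Object of class `mediation_result`.
#' @export
fit_mediation_models <- function(probs, outcome, mediator, qtl, locus,
                                 weights = NULL, covar = NULL) {
  d <- mediation_designs(probs, outcome, mediator, qtl, locus, weights, covar)
  a_idx <- match(d$a_col, colnames(d$X))
  # Model 1: outcome ~ QTLs (unmediated)
  m1 <- wls_vcov(d$X, d$y, d$w)
  # Model 3: outcome ~ QTLs + mediator (mediated)
  X3 <- cbind(d$X, mediator = d$m)
  m3 <- wls_vcov(X3, d$y, d$w)
  # Model 2: mediator ~ QTLs
  m2 <- wls_vcov(d$X, d$m, d$w)
  stop_if_not(!is.null(m1$vcov) && !is.null(m2$vcov) && !is.null(m3$vcov),
              "singular mediation design")
  beta <- unname(m1$coef[d$a_col])
  beta_prime <- unname(m3$coef[d$a_col])
  alpha_med <- unname(m3$coef[["mediator"]])
  var_alpha <- m3$vcov["mediator", "mediator"]
  beta_med <- unname(m2$coef[d$a_col])
  var_beta_med <- m2$vcov[d$a_col, d$a_col]
  sob <- sobel_test(alpha_med, beta_med, var_alpha, var_beta_med)
  # cov(beta_hat, beta_prime_hat): both are c' y with Var(y) = sigma2 W^-1.
  u1 <- d$X %*% solve(crossprod(d$X * d$w, d$X))[, a_idx]
  u3 <- X3 %*% solve(crossprod(X3 * d$w, X3))[, a_idx]
  cov_bb <- m3$sigma2 * sum(d$w * u1 * u3)
  pm <- proportion_mediated(beta, beta_prime,
                            var_beta = m1$vcov[d$a_col, d$a_col],
                            var_beta_prime = m3$vcov[d$a_col, d$a_col],
                            cov_bb = cov_bb)
  structure(list(locus = locus, n = d$n,
                 beta = beta, beta_prime = beta_prime,
                 alpha_med = alpha_med, var_alpha = var_alpha,
                 beta_med = beta_med, var_beta_med = var_beta_med,
                 se_pooled = sob$se, t = sob$t, p_analytic = sob$p,
                 f = pm$f, se_f = pm$se),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation at %s:%s cM (n = %d)\n", x$locus[["chr"]],
              x$locus[["pos"]], x$n))
  cat(sprintf("  beta = %.3f, beta' = %.3f, alpha = %.4g\n",
              x$beta, x$beta_prime, x$alpha_med))
  cat(sprintf("  Sobel t = %.3f, analytic p = %.3g", x$t, x$p_analytic))
  if (!is.null(x$p_empirical)) cat(sprintf(", empirical p = %.3g", x$p_empirical))
  cat(sprintf("\n  f = %.2f +- %.2f\n", x$f, x$se_f))
  invisible(x)
}

#' Permutation p-value for the Sobel statistic
#'
#' Builds the null distribution of the Sobel statistic by resampling the
#' mediating trait without replacement across individuals (weights and
#' covariates stay attached to their individuals; only the mediator column
#' is shuffled) and recomputing the mediator-dependent regressions each
#' replicate. `p = (1 + #{|t*| >= |t_obs|}) / (1 + n_perm)`.
#'
#' @inheritParams fit_mediation_models
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return The `mediation_result` with `p_empirical`, `n_perm`, `seed` and
#'   the permuted statistics `t_perm` (for normality diagnostics) added.
#' @export
mediation_permutation_p <- function(probs, outcome, mediator, qtl, locus,
                                    weights = NULL, covar = NULL,
                                    n_perm = 10000, seed = 1L) {
  stop_if_not(is_count(n_perm, min = 100), "n_perm must be an integer >= 100")
  res <- fit_mediation_models(probs, outcome, mediator, qtl, locus,
                              weights, covar)
  d <- mediation_designs(probs, outcome, mediator, qtl, locus, weights, covar)
  t_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ms <- d$m[sample.int(d$n)]
      m2 <- wls_vcov(d$X, ms, d$w)
      m3 <- wls_vcov(cbind(d$X, mediator = ms), d$y, d$w)
      if (is.null(m2$vcov) || is.null(m3$vcov)) return(NA_real_)
      sobel_test(unname(m3$coef[["mediator"]]),
                 unname(m2$coef[d$a_col]),
                 m3$vcov["mediator", "mediator"],
                 m2$vcov[d$a_col, d$a_col])$t
    }, numeric(1))
  })
  t_perm <- t_perm[!is.na(t_perm)]
  res$p_empirical <- (1 + sum(abs(t_perm) >= abs(res$t))) / (1 + length(t_perm))
  res$t_perm <- t_perm
  res$n_perm <- length(t_perm)
  res$seed <- seed
  res
}

#' Mediation in both directions at a locus
#'
#' Convenience wrapper reproducing the paired bookkeeping of the two
#' mediation models at one locus: the first element treats trait 1 as
#' outcome mediated by trait 2, the second swaps them. Each direction uses
#' the multiple-QTL model of its own outcome trait.
#'
#' @inheritParams fit_mediation_models
#' @param trait1,trait2 The two phenotype vectors (e.g. mean SC length and
#'   mean MLH1 count).
#' @param qtl1,qtl2 QTL model (data frame `chr`, `pos`) for each trait.
#' @param n_perm If > 0, also computes permutation p-values.
#' @param seed Seed for the permutations.
#' @return List with elements `t1_mediated_by_t2` and `t2_mediated_by_t1`.
#' @export
mediate_both <- function(probs, trait1, trait2, qtl1, qtl2, locus,
                         weights = NULL, covar = NULL, n_perm = 0,
                         seed = 1L) {
  run <- function(outc, med, qtl, sd_off) {
    if (n_perm > 0) {
      mediation_permutation_p(probs, outc, med, qtl, locus, weights, covar,
                              n_perm = n_perm, seed = seed + sd_off)
    } else {
      fit_mediation_models(probs, outc, med, qtl, locus, weights, covar)
    }
  }
  list(t1_mediated_by_t2 = run(trait1, trait2, qtl1, 0L),
       t2_mediated_by_t1 = run(trait2, trait1, qtl2, 1L))
}

#' Sensitivity of the proportion mediated to measurement error
#'
#' Repeats the mediation fit after equalizing the expected within-individual
#' coefficient of variation of the two traits: per replicate, Gaussian noise
#' is added to the cell-level observations of the lower-CV trait (via
#' [add_cellwise_gaussian_noise()] with `target_cv` set to the mean
#' within-individual CV of the noisier trait), phenotypes are re-aggregated,
#' and `f` is recomputed. A spread of replicate `f` values much smaller than
#' the regression SE of `f` indicates the mediation inference is robust to
#' the traits' unequal measurement error.
#'
#' @inheritParams fit_mediation_models
#' @param records Cell-level records (see [simulate_phenotypes()]) for the
#'   individuals in `probs`.
#' @param outcome_trait,mediator_trait Which record column feeds the outcome
#'   and mediator: `"sc_length_um"` or `"mlh1_count"`.
#' @param min_cells Minimum cells per individual for aggregation.
#' @param n_rep Number of noise replicates.
#' @param seed Integer seed.
#' @return List with `baseline` (the unnoised `mediation_result`), `f_rep`
#'   (replicate f values), `sd_f_rep`, `noised_trait`, `target_cv`.
#' @export
sensitivity_to_measurement_error <- function(records, probs, qtl, locus,
                                             outcome_trait = "sc_length_um",
                                             mediator_trait = "mlh1_count",
                                             covar = NULL, min_cells = 5,
                                             n_rep = 1000, seed = 1L) {
  stop_if_not(is_count(n_rep), "n_rep must be a positive integer")
  base_ph <- aggregate_phenotypes(records, min_cells = min_cells, quiet = TRUE)
  ids <- attr(probs, "ids")
  trait_col <- c(sc_length_um = "mean_sc_um", mlh1_count = "mean_co")
  cv_col <- c(sc_length_um = "cv_sc", mlh1_count = "cv_co")
  cvs <- vapply(c(outcome_trait, mediator_trait), function(tr) {
    mean(base_ph[[cv_col[[tr]]]], na.rm = TRUE)
  }, numeric(1))
  low_trait <- c(outcome_trait, mediator_trait)[which.min(cvs)]
  target_cv <- max(cvs)
  fit_once <- function(ph) {
    m <- match(ids, ph$individual_id)
    fit_mediation_models(
      probs,
      outcome = ph[[trait_col[[outcome_trait]]]][m],
      mediator = ph[[trait_col[[mediator_trait]]]][m],
      qtl = qtl, locus = locus,
      weights = ph$n_cells[m], covar = covar
    )
  }
  baseline <- fit_once(base_ph)
  f_rep <- with_seed(seed, {
    vapply(seq_len(n_rep), function(b) {
      noised <- add_cellwise_gaussian_noise(records, trait = low_trait,
                                            target_cv = target_cv)
      fit_once(aggregate_phenotypes(noised, min_cells = min_cells,
                                    quiet = TRUE))$f
    }, numeric(1))
  })
  list(baseline = baseline, f_rep = f_rep, sd_f_rep = stats::sd(f_rep),
       noised_trait = low_trait, target_cv = target_cv)
}
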