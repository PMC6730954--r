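stat_first <- function(x, fid) {
  unname(unlist(lapply(split(x, fid), `[`, 1)))
}

# Aggregation of cell-level spermatocyte records into the per-individual
# traits used for mapping: mean SC length, mean MLH1 (crossover) count,
# SC/CO ratio, regression weights and within-individual CVs.

#' Aggregate spermatocyte records into individual phenotypes
#'
#' One row per individual: mean SC length, mean MLH1 count (over cells with
#' a non-missing count), their ratio (um per focus), the number of
#' contributing cells (used as the regression weight downstream) and
#' within-individual CVs. Individuals represented by fewer than `min_cells`
#' spermatocytes are dropped.
#'
#' @param records Data frame with `individual_id`, `cell_id`,
#'   `sc_length_um` and optionally `mlh1_count` and `cross_direction`.
#' @param min_cells Minimum number of cells for an individual to be kept.
#' @param quiet Suppress the message listing dropped individuals.
#' @return Data frame with columns `individual_id`, `mean_sc_um`,
#'   `mean_co`, `sc_co_ratio`, `n_cells`, `n_cells_co`, `cv_sc`, `cv_co`
#'   and, when present in the input, `cross_direction`. Dropped individuals
#'   are recorded in attribute `"dropped"`.
#' @export
aggregate_phenotypes <- function(records, min_cells = 5, quiet = FALSE) {
  stop_if_not(nrow(records) > 0, "no records to aggregate")
  stop_if_not(is_count(min_cells, min = 1), "min_cells must be a positive integer")
  stop_if_not(!anyDuplicated(records[c("individual_id", "cell_id")]),
              "(individual_id, cell_id) pairs must be unique")
  ids <- unique(records$individual_id)
  fid <- factor(records$individual_id, levels = ids)
  sc_by <- split(records$sc_length_um, fid)
  co_by <- if ("mlh1_count" %in% names(records)) {
    split(records$mlh1_count, fid)
  } else {
    rep(list(numeric(0)), length(ids))
  }
  stat <- function(xs, f) vapply(xs, f, numeric(1))
  mean_sc <- stat(sc_by, function(x) mean(x, na.rm = TRUE))
  n_sc <- stat(sc_by, function(x) sum(!is.na(x)))
  sd_sc <- stat(sc_by, function(x) stats::sd(x[!is.na(x)]))
  mean_co <- stat(co_by, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  n_co <- stat(co_by, function(x) sum(!is.na(x)))
  sd_co <- stat(co_by, function(x) stats::sd(x[!is.na(x)]))
  out <- data.frame(
    individual_id = ids,
    mean_sc_um = mean_sc,
    mean_co = mean_co,
    sc_co_ratio = ifelse(!is.na(mean_co) & mean_co > 0, mean_sc / mean_co, NA_real_),
    n_cells = as.integer(n_sc),
    n_cells_co = as.integer(n_co),
    cv_sc = ifelse(n_sc > 1 & mean_sc != 0, sd_sc / mean_sc, NA_real_),
    cv_co = ifelse(n_co > 1 & !is.na(mean_co) & mean_co != 0, sd_co / mean_co, NA_real_),
    cross_direction = if ("cross_direction" %in% names(records)) {
      stat_first(records$cross_direction, fid)
    } else NA,
    stringsAsFactors = FALSE
  )
  keep <- out$n_cells >= min_cells
  dropped <- out$individual_id[!keep]
  out <- out[keep, , drop = FALSE]
  stop_if_not(nrow(out) > 0, "all individuals filtered out (min_cells = %d)", min_cells)
  if (all(is.na(out$cross_direction))) out$cross_direction <- NULL
  rownames(out) <- NULL
  if (length(dropped) && !quiet) {
    message(sprintf("dropped %d individual(s) with fewer than %d cells: %s",
                    length(dropped), min_cells,
                    paste(utils::head(dropped, 10), collapse = ", ")))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Within-individual coefficients of variation
#'
#' Sample SD divided by mean, per individual and trait, across that
#' individual's cells. Requires at least two cells per individual.
#'
#' @inheritParams aggregate_phenotypes
#' @return Data frame with `individual_id`, `cv_sc`, `cv_co`.
#' @export
within_individual_cv <- function(records) {
  counts <- table(records$individual_id)
  stop_if_not(all(counts >= 2), "every individual needs >= 2 cells for a CV")
  cv <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    m <- mean(x)
    stop_if_not(m != 0, "zero mean: CV undefined")
    stats::sd(x) / m
  }
  ids <- unique(records$individual_id)
  data.frame(
    individual_id = ids,
    cv_sc = vapply(ids, function(i) cv(records$sc_length_um[records$individual_id == i]), numeric(1)),
    cv_co = if ("mlh1_count" %in% names(records)) {
      vapply(ids, function(i) cv(records$mlh1_count[records$individual_id == i]), numeric(1))
    } else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Correlation between SC length and crossover count
#'
#' Pearson correlation with a Fisher-z 95% confidence interval,
#' `tanh(atanh(r) +- 1.96 / sqrt(n - 3))`, plus the ordinary least-squares
#' slope (with SE) of the second trait on the first.
#'
#' @param x,y Paired trait values (cell-level or individual-level), e.g. SC
#'   length and MLH1 count. Pairs with missing values are dropped.
#' @return List with `r`, `ci` (length 2), `slope`, `slope_se`, `n`.
#' @export
trait_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  stop_if_not(n >= 4, "need at least 4 complete pairs")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0, "constant trait: correlation undefined")
  r <- stats::cor(x, y)
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  list(r = r, ci = ci, slope = unname(sm["x", "Estimate"]),
       slope_se = unname(sm["x", "Std. Error"]), n = n)
}
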