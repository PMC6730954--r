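# End-to-end driver: measure -> aggregate -> scan (SC, CO, SC/CO ratio) ->
# mediate at overlapping significant loci, with seeds and parameters
# recorded in the results bundle.

#' Pipeline configuration
#'
#' @param cross_csv Path to a cross CSV ([read_cross_csv()]), or `NULL`
#'   when `synthetic` is given.
#' @param records_tsv Path to a cell-level record TSV, or `NULL`.
#' @param image_dir Directory of spread images to measure; file names
#'   `<individual>_<cell>.(tif|png)` define the record keys. MLH1 counts
#'   for measured images are joined from `records_tsv` when present.
#' @param synthetic Optional [sim_cross_config()]: simulate the cross and
#'   records instead of reading files.
#' @param morph A [morph_params()].
#' @param scale_um_per_px Scale for measured images.
#' @param min_cells Minimum spermatocytes per individual.
#' @param step_cM Pseudomarker step for the scans.
#' @param n_perm Scan permutation replicates.
#' @param alpha Genome-wide significance level.
#' @param mediation_n_perm Mediator permutation replicates (0 = analytic
#'   p-values only).
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it and records it in the bundle.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cross_csv = NULL, records_tsv = NULL,
                            image_dir = NULL, synthetic = NULL,
                            morph = morph_params(),
                            scale_um_per_px = 0.065, min_cells = 5,
                            step_cM = 1, n_perm = 1000, alpha = 0.05,
                            mediation_n_perm = 10000, seed = 1L,
                            out_dir = NULL) {
  stop_if_not(!is.null(synthetic) || !is.null(cross_csv),
              "need either a cross_csv or a synthetic config")
  if (!is.null(image_dir)) {
    stop_if_not(dir.exists(image_dir), "image directory not found: %s", image_dir)
  }
  structure(list(cross_csv = cross_csv, records_tsv = records_tsv,
                 image_dir = image_dir, synthetic = synthetic,
                 morph = morph, scale_um_per_px = scale_um_per_px,
                 min_cells = min_cells, step_cM = step_cM,
                 n_perm = n_perm, alpha = alpha,
                 mediation_n_perm = mediation_n_perm,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments (`synthetic: true` requests the default synthetic cross).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (isTRUE(y$synthetic)) y$synthetic <- sim_cross_config(seed = y$seed %||% 1L)
  do.call(pipeline_config, y)
}

# Records from an image directory: SC lengths measured, MLH1 joined.
records_from_images <- function(config) {
  tab <- batch_measure(config$image_dir, config$morph, config$scale_um_per_px)
  ok <- tab[tab$status == "ok", , drop = FALSE]
  stem <- sub("\\.(tiff?|png)$", "", ok$image_id, ignore.case = TRUE)
  parts <- regmatches(stem, regexec("^(.*)_([^_]+)$", stem))
  rec <- data.frame(
    individual_id = vapply(parts, function(p) if (length(p) == 3) p[2] else p[1], ""),
    cell_id = vapply(parts, function(p) if (length(p) == 3) p[3] else "1", ""),
    sc_length_um = ok$sc_length_um,
    mlh1_count = NA_real_, stringsAsFactors = FALSE
  )
  if (!is.null(config$records_tsv)) {
    mlh <- read_records_tsv(config$records_tsv)
    key <- paste(rec$individual_id, rec$cell_id)
    m <- match(key, paste(mlh$individual_id, mlh$cell_id))
    rec$mlh1_count <- mlh$mlh1_count[m]
  }
  rec
}

#' Run the full analysis pipeline
#'
#' Executes measurement (or simulation), aggregation, the three genome
#' scans (mean SC length, mean MLH1 count, SC/CO ratio) with permutation
#' thresholds, and mediation at loci where the SC and CO scans are both
#' genome-wide significant on the same chromosome. Results and all seeds
#' are collected in a bundle; with `out_dir` set, TSV/JSON artifacts are
#' written and the run is bit-reproducible for a fixed config.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `records`, `phenotypes`,
#'   `scans`, `thresholds`, `qtl` (significant peaks per trait),
#'   `mediation`, `correlation`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(seed = config$seed, step_cM = config$step_cM,
              n_perm = config$n_perm, alpha = config$alpha,
              package_version = as.character(utils::packageVersion("scmeio")))
  # --- inputs
  if (!is.null(config$synthetic)) {
    cross <- simulate_f2_genotypes(config$synthetic)
    records <- simulate_phenotypes(cross, config$synthetic)
    log$input <- "synthetic"
  } else {
    cross <- read_cross_csv(config$cross_csv)
    records <- if (!is.null(config$image_dir)) {
      records_from_images(config)
    } else {
      stop_if_not(!is.null(config$records_tsv),
                  "need records_tsv or image_dir with a real cross")
      read_records_tsv(config$records_tsv)
    }
    log$input <- config$cross_csv
  }
  # --- aggregate
  phenos <- aggregate_phenotypes(records, min_cells = config$min_cells,
                                 quiet = TRUE)
  ids <- rownames(cross$geno)
  m <- match(ids, phenos$individual_id)
  traits <- list(mean_sc_um = phenos$mean_sc_um[m],
                 mean_co = phenos$mean_co[m],
                 sc_co_ratio = phenos$sc_co_ratio[m])
  weights <- phenos$n_cells[m]
  covar <- cross$covar$cross_direction
  # --- scans
  probs <- genotype_probabilities(cross, step_cM = config$step_cM)
  scans <- list(); thresholds <- list(); qtl <- list()
  for (tr in names(traits)) {
    scans[[tr]] <- scan_hk(probs, traits[[tr]], weights, covar)
    thresholds[[tr]] <- permutation_threshold(
      probs, traits[[tr]], weights, covar,
      n_perm = config$n_perm, alpha = config$alpha,
      seed = config$seed + match(tr, names(traits)))
    sig <- vapply(unique(scans[[tr]]$chr), function(ch) {
      scan_peak(scans[[tr]], ch)$lod > thresholds[[tr]]$threshold
    }, logical(1))
    qtl[[tr]] <- if (any(sig)) {
      do.call(rbind, lapply(names(sig)[sig], function(ch) {
        scan_peak(scans[[tr]], ch)
      }))
    } else {
      NULL
    }
  }
  # --- mediation at overlapping significant loci
  mediation <- list()
  shared <- intersect(qtl$mean_sc_um$chr, qtl$mean_co$chr)
  if (length(shared) == 0) {
    message("no chromosome significant for both SC length and MLH1 count; mediation skipped")
  } else {
    for (ch in shared) {
      for (tr in c("mean_sc_um", "mean_co")) {
        pk <- qtl[[tr]][qtl[[tr]]$chr == ch, ]
        loc <- c(chr = ch, pos = pk$pos)
        mediation[[sprintf("%s:%g@peak_%s", ch, pk$pos, tr)]] <- mediate_both(
          probs, traits$mean_sc_um, traits$mean_co,
          qtl1 = qtl$mean_sc_um, qtl2 = qtl$mean_co, locus = loc,
          weights = weights, covar = covar,
          n_perm = config$mediation_n_perm, seed = config$seed + 10L)
      }
    }
  }
  correlation <- tryCatch(
    trait_correlation(phenos$mean_sc_um, phenos$mean_co),
    error = function(e) NULL)
  out <- structure(list(records = records, phenotypes = phenos,
                        scans = scans, thresholds = thresholds, qtl = qtl,
                        mediation = mediation, correlation = correlation,
                        map = cross$map, log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_results(out, config$out_dir)
  out
}

# TSV/JSON artifacts for a pipeline result.
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (tr in names(result$scans)) {
    utils::write.table(result$scans[[tr]],
                       file.path(dir, sprintf("scan_%s.tsv", tr)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    log = result$log,
    thresholds = lapply(result$thresholds, function(th) {
      th[c("threshold", "alpha", "n_perm", "seed")]
    }),
    qtl = lapply(result$qtl, function(q) if (is.null(q)) list() else q),
    mediation = lapply(result$mediation, function(mb) {
      lapply(mb, function(r) {
        r[c("locus", "beta", "beta_prime", "alpha_med", "t",
            "p_analytic", "p_empirical", "f", "se_f")]
      })
    }),
    correlation = result$correlation
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' Report figures and tables for a pipeline result
#'
#' Writes per-trait LOD curves (with the genome-wide threshold as a dashed
#' line), a mediation summary TSV, and a correlation summary TSV.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return Invisible vector of written paths.
#' @export
report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(result$scans) == 0) {
    warning("empty results: nothing to report")
    return(invisible(character()))
  }
  paths <- character()
  for (tr in names(result$scans)) {
    s <- result$scans[[tr]]
    s$chr <- factor(s$chr, levels = unique(s$chr))
    p <- ggplot2::ggplot(s, ggplot2::aes(x = pos, y = lod)) +
      ggplot2::geom_line() +
      ggplot2::facet_grid(. ~ chr, scales = "free_x", space = "free_x") +
      ggplot2::geom_hline(yintercept = result$thresholds[[tr]]$threshold,
                          linetype = "dashed") +
      ggplot2::labs(x = "position (cM)", y = "LOD", title = tr) +
      ggplot2::theme_minimal()
    f <- file.path(dir, sprintf("lod_%s.png", tr))
    ggplot2::ggsave(f, p, width = 10, height = 3, dpi = 150)
    paths <- c(paths, f)
  }
  if (length(result$mediation)) {
    rows <- lapply(names(result$mediation), function(nm) {
      mb <- result$mediation[[nm]]
      do.call(rbind, lapply(names(mb), function(dir_nm) {
        r <- mb[[dir_nm]]
        data.frame(locus = nm, direction = dir_nm, beta = r$beta,
                   beta_prime = r$beta_prime, alpha = r$alpha_med,
                   t = r$t, f = r$f, se_f = r$se_f,
                   p_analytic = r$p_analytic,
                   p_empirical = r$p_empirical %||% NA_real_,
                   stringsAsFactors = FALSE)
      }))
    })
    f <- file.path(dir, "mediation.tsv")
    utils::write.table(do.call(rbind, rows), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(result$correlation)) {
    co <- result$correlation
    f <- file.path(dir, "correlation.tsv")
    utils::write.table(
      data.frame(r = co$r, ci_lo = co$ci[1], ci_hi = co$ci[2],
                 slope = co$slope, slope_se = co$slope_se, n = co$n),
      f, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
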