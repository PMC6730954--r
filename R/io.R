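# File formats: R/qtl-style cross CSV, record/phenotype TSVs, TIFF/PNG
# image reading and writing.

GENO_CODES <- c("AA", "AB", "BB", "AY", "BY", "-")

#' Write a cross to CSV
#'
#' R/qtl-style layout: row 1 column names (phenotype/covariate columns then
#' markers), row 2 chromosome (blank for phenotype columns), row 3 position
#' in cM, then one row per individual with genotype codes `AA/AB/BB/AY/BY`
#' and `-` for missing.
#'
#' @param cross An `f2cross`.
#' @param path Output file.
#' @param phenotypes Optional data frame keyed by `individual_id` whose
#'   remaining columns are written before the markers.
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(cross, path, phenotypes = NULL) {
  stopifnot(inherits(cross, "f2cross"))
  map <- cross$map
  ph <- data.frame(individual_id = rownames(cross$geno),
                   stringsAsFactors = FALSE)
  ph$cross_direction <- as.character(cross$covar$cross_direction)
  if (!is.null(phenotypes)) {
    m <- match(ph$individual_id, phenotypes$individual_id)
    for (cn in setdiff(names(phenotypes), "individual_id")) {
      v <- phenotypes[[cn]][m]
      # full-precision text so the round trip is lossless
      ph[[cn]] <- if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
    }
  }
  geno <- cross$geno
  geno[is.na(geno)] <- "-"
  header1 <- c(names(ph), map$marker)
  header2 <- c(rep("", ncol(ph)), as.character(map$chr))
  header3 <- c(rep("", ncol(ph)), as.character(map$pos))
  body <- cbind(as.matrix(ph), geno)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header1, collapse = ","), con)
  writeLines(paste(header2, collapse = ","), con)
  writeLines(paste(header3, collapse = ","), con)
  utils::write.table(body, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cross from CSV
#'
#' Parses the layout written by [write_cross_csv()], validating genotype
#' codes (hard error on heterozygous male X genotypes) and marker order.
#'
#' @param path CSV file.
#' @return An `f2cross` (phenotype columns, if any, in `$pheno`).
#' @export
read_cross_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  stop_if_not(nrow(raw) >= 4, "cross CSV needs 3 header rows plus data")
  nm <- as.character(raw[1, ])
  chr <- as.character(raw[2, ])
  pos <- as.character(raw[3, ])
  is_marker <- chr != ""
  stop_if_not(any(is_marker), "no marker columns found")
  map <- data.frame(marker = nm[is_marker], chr = chr[is_marker],
                    pos = as.numeric(pos[is_marker]),
                    stringsAsFactors = FALSE)
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    stop_if_not(all(diff(p) > 0),
                "markers on chromosome %s are not sorted by position", ch)
  }
  class(map) <- c("genetic_map", "data.frame")
  body <- raw[-(1:3), , drop = FALSE]
  ph <- body[, !is_marker, drop = FALSE]
  names(ph) <- nm[!is_marker]
  geno <- as.matrix(body[, is_marker, drop = FALSE])
  colnames(geno) <- map$marker
  bad <- matrix(!(geno %in% GENO_CODES), nrow(geno), ncol(geno))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype code '%s' at individual row %d, marker %s",
                 geno[bad][1], idx[1], colnames(geno)[idx[2]]), call. = FALSE)
  }
  x_cols <- map$marker[map$chr == "X"]
  if (length(x_cols)) {
    het <- geno[, x_cols, drop = FALSE] == "AB"
    if (any(het)) {
      i <- which(rowSums(het) > 0)[1]
      id <- if ("individual_id" %in% names(ph)) ph$individual_id[i] else paste("row", i)
      stop(sprintf("male X genotype 'AB' for individual %s", id), call. = FALSE)
    }
    auto_codes <- geno[, x_cols, drop = FALSE] %in% c("AA", "BB")
    if (any(auto_codes)) {
      stop("homozygous autosomal codes on the male X; use AY/BY", call. = FALSE)
    }
  }
  geno[geno == "-"] <- NA
  ids <- if ("individual_id" %in% names(ph)) ph$individual_id else
    sprintf("ind%03d", seq_len(nrow(geno)))
  rownames(geno) <- ids
  covar <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  if ("cross_direction" %in% names(ph)) {
    covar$cross_direction <- factor(ph$cross_direction)
  }
  pheno <- ph[setdiff(names(ph), c("individual_id", "cross_direction"))]
  for (cn in names(pheno)) pheno[[cn]] <- as.numeric(pheno[[cn]])
  if (ncol(pheno)) pheno <- cbind(individual_id = ids, pheno)
  structure(list(map = map, geno = geno, covar = covar,
                 pheno = if (ncol(pheno)) pheno else NULL, hidden = NULL),
            class = "f2cross")
}

#' Read/write spermatocyte record tables
#'
#' Plain TSV with columns `individual_id`, `cell_id`, `sc_length_um`,
#' `mlh1_count`.
#'
#' @param records Record data frame.
#' @param path File path.
#' @return `read_records_tsv`: the records; `write_records_tsv`: `path`,
#'   invisibly.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_records_tsv
#' @export
read_records_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Read a TIFF or PNG file into a numeric array in [0, 1].
read_image_array <- function(path) {
  stop_if_not(file.exists(path), "image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext, call. = FALSE))
  img
}

#' Write a synthetic image and its ground truth
#'
#' Writes the rendered image as single-channel TIFF (or PNG by extension),
#' the ground-truth axis table as TSV, and a JSON sidecar carrying the
#' generator configuration and seed.
#'
#' @param rendered Output of [render_spermatocyte_image()].
#' @param path Image path (`.tiff` or `.png`); the truth TSV and JSON
#'   sidecar take the same stem.
#' @param config The [synth_image_config()] used (stored in the sidecar).
#' @return Invisible list of the three paths written.
#' @export
write_synthetic_image <- function(rendered, path, config = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- rendered$image$px
  switch(ext,
         tif = , tiff = tiff::writeTIFF(px, path),
         png = png::writePNG(px, path),
         stop("unsupported image format: ", ext, call. = FALSE))
  stem <- sub(sprintf("\\.%s$", ext), "", path)
  truth_path <- paste0(stem, "_truth.tsv")
  utils::write.table(rendered$truth, truth_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  json_path <- paste0(stem, "_config.json")
  jsonlite::write_json(c(unclass(config) %||% list(),
                         list(total_um = attr(rendered$truth, "total_um"))),
                       json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(image = path, truth = truth_path, config = json_path))
}
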