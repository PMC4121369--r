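#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature identifiers, the header holds sample
#' identifiers. Every data cell must be numeric (or `NA`); a non-numeric
#' cell aborts with a message naming the offending row and column.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  assert_that(ncol(dt) >= 2, sprintf("matrix file %s has no sample columns", path))
  ids <- as.character(dt[[1]])
  vals <- dt[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col) && !is.logical(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      stop(sprintf("non-numeric value '%s' in row '%s', column '%s' of %s",
                   col[bad], ids[bad], names(vals)[j], path), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param mat numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_col name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a plain TSV table
#'
#' @param path path to a tab-separated file with header.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                    na.strings = c("NA", ""))
}

#' Write a plain TSV table
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read genomic segments from BED
#'
#' BED files are 0-based half-open; internal coordinates are 1-based
#' inclusive (array-manifest convention), so `start` gains 1 on read.
#' A fourth column, when present, is interpreted as integer copy number
#' (the convention used for the index case's CNV segments).
#'
#' @param path path to a BED file (no header).
#' @return data.frame with `chromosome`, `start`, `end` and optionally
#'   `copy_number`, 1-based inclusive, chromosome labels normalized.
#' @export
read_bed <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  assert_that(ncol(dt) >= 3, sprintf("BED file %s needs >= 3 columns", path))
  start0 <- suppressWarnings(as.numeric(dt[[2]]))
  end0 <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start0) | is.na(end0) | start0 >= end0)
  if (length(bad)) {
    stop(sprintf("malformed BED interval at line %d of %s", bad[1], path),
         call. = FALSE)
  }
  out <- data.frame(chromosome = norm_chrom(dt[[1]]),
                    start = as.integer(start0 + 1L),
                    end = as.integer(end0),
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 4 && all(!is.na(suppressWarnings(as.numeric(dt[[4]]))))) {
    out$copy_number <- as.integer(dt[[4]])
  }
  out
}

#' Write genomic segments to BED
#'
#' Inverse of [read_bed()]: internal 1-based inclusive intervals are
#' written 0-based half-open. Extra columns beyond
#' `chromosome`/`start`/`end` are appended in order.
#'
#' @param df data.frame with `chromosome`, `start`, `end` plus optional
#'   extra columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  assert_that(all(c("chromosome", "start", "end") %in% names(df)),
              "BED output needs chromosome/start/end columns")
  extra <- setdiff(names(df), c("chromosome", "start", "end"))
  out <- data.frame(df$chromosome, as.integer(df$start) - 1L,
                    as.integer(df$end), stringsAsFactors = FALSE)
  for (cn in extra) out[[cn]] <- df[[cn]]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' @param report a list (nested lists / data.frames are fine).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
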