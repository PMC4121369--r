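#' Locate a shipped case-study summary file
#'
#' The package ships plain-text transcriptions of the printed summary
#' statistics of the 47,XXY brain case study (differentially expressed
#' gene tables per tissue, brain-mass phenotypes, repeat-element global
#' methylation, XCI skewing) under `extdata/case_study`.
#'
#' @param name file name, e.g. `"de_genes_pfc.tsv"`.
#' @return absolute path to the installed file.
#' @export
case_study_file <- function(name) {
  p <- system.file("extdata", "case_study", name, package = "nof1omics")
  assert_that(nzchar(p), sprintf("no case-study file named '%s'", name))
  p
}

#' Read a transcribed differentially-expressed-gene table
#'
#' Parses a shipped DE-gene transcription: blank cells (gene not
#' significant, or comparison not made under the chromosome policy)
#' become `NA`; p values printed as `<2.00E-16` are loaded at the
#' printed bound with `censored = TRUE` recorded in a companion column.
#'
#' @param path path to the table (see [case_study_file()]).
#' @return data.frame with numeric `fc_all`/`fc_males`/`fc_females`,
#'   numeric `p_*` columns and logical `p_*_censored` columns, plus
#'   `chromosome` parsed from the printed position.
#' @export
read_case_de_table <- function(path) {
  df <- read_tsv_table(path)
  for (fam in c("all", "males", "females")) {
    pcol <- paste0("p_", fam)
    raw <- as.character(df[[pcol]])
    df[[paste0(pcol, "_censored")]] <- !is.na(raw) & startsWith(raw, "<")
    df[[pcol]] <- suppressWarnings(as.numeric(sub("^<", "", raw)))
    df[[paste0("fc_", fam)]] <- suppressWarnings(as.numeric(df[[paste0("fc_", fam)]]))
  }
  df$chromosome <- norm_chrom(sub(":.*$", "", df$position))
  df
}

#' Count up/down-regulated transcripts in a comparison column
#'
#' @param de a table from [read_case_de_table()].
#' @param comparison `"all"`, `"males"` or `"females"`.
#' @return list with `up`, `down`, `total` counts of transcripts with a
#'   reported fold change in that comparison.
#' @export
count_de_directions <- function(de, comparison = c("all", "males", "females")) {
  comparison <- match.arg(comparison)
  fc <- de[[paste0("fc_", comparison)]]
  fc <- fc[!is.na(fc)]
  list(up = sum(fc > 0), down = sum(fc < 0), total = length(fc))
}
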