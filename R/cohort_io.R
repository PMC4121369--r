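# serialize a sim_config to plain lists for YAML and back
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  df_to_records <- function(df) {
    if (is.null(df) || !nrow(df)) return(list())
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  out$spikes <- df_to_records(cfg$spikes)
  out$global_shift <- df_to_records(cfg$global_shift)
  out$xci_ratio_by_tissue <- as.list(cfg$xci_ratio_by_tissue)
  out
}

list_to_config <- function(lst) {
  records_to_df <- function(recs) {
    if (is.null(recs) || !length(recs)) return(NULL)
    do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  spikes <- records_to_df(lst$spikes)
  gs <- records_to_df(lst$global_shift)
  xci <- unlist(lst$xci_ratio_by_tissue)
  cohort_config(
    n_individuals = lst$n_individuals,
    n_probes_autosomal = lst$n_probes_autosomal,
    n_probes_x = lst$n_probes_x,
    n_probes_y = lst$n_probes_y,
    n_expression_probes = lst$n_expression_probes,
    n_snps_x = lst$n_snps_x,
    xtr_fraction = lst$xtr_fraction,
    tissues = lst$tissues,
    index_karyotype = lst$index_karyotype,
    spikes = spikes,
    global_shift = gs,
    meth_precision = lst$meth_precision,
    expression_sd = lst$expression_sd,
    baf_sd = lst$baf_sd,
    detection_failure_rate = lst$detection_failure_rate,
    beadcount_lambda = lst$beadcount_lambda,
    xci_ratio_by_tissue = xci,
    seed = lst$seed)
}

#' Read a simulation configuration from YAML
#'
#' @param path path to a YAML file written by [write_cohort()] (or hand
#'   written with the same keys).
#' @return a [cohort_config()] object (re-validated on read).
#' @export
read_config_yaml <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  lst <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(lst), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  list_to_config(lst)
}

#' Write a synthetic cohort to a directory of interchange files
#'
#' Emits TSV matrices (one per tissue for methylation/expression
#' channels), SNP tables, BED CNV segments, repeat-assay and XCI peak
#' tables, metadata, the YAML config, and a JSON manifest listing every
#' file written. Round-trips through [read_cohort()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest (named list of relative file paths).
#' @export
write_cohort <- function(cohort, directory) {
  assert_that(inherits(cohort, "synthetic_cohort"), "not a synthetic_cohort")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(directory), sprintf("cannot create directory %s", directory))
  files <- list()
  put <- function(key, rel, writer) {
    path <- file.path(directory, rel)
    ok <- tryCatch({ writer(path); TRUE },
                   error = function(e) stop(sprintf("failed writing %s: %s", rel,
                                                    conditionMessage(e)), call. = FALSE))
    files[[key]] <<- rel
  }
  md <- cohort$metadata
  put("manifest", "manifest.tsv", function(p) write_tsv_table(cohort$manifest, p))
  put("expr_manifest", "expression_manifest.tsv",
      function(p) write_tsv_table(cohort$expr_manifest, p))
  for (t in cohort$config$tissues) {
    cols <- md$sample_id[md$tissue == t]
    for (ch in c("betas", "beadcount", "detection_p", "expression", "expr_detection_p")) {
      rel <- sprintf("%s_%s.tsv", ch, t)
      local({
        ch0 <- ch; cols0 <- cols
        put(sprintf("%s_%s", ch0, t), rel,
            function(p) write_matrix_tsv(cohort[[ch0]][, cols0, drop = FALSE], p,
                                         id_col = "probe_id"))
      })
    }
  }
  put("snp_probe_betas", "snp_probe_betas.tsv",
      function(p) write_matrix_tsv(cohort$snp_probe_betas, p, id_col = "probe_id"))
  put("snp_info", "snp_info.tsv", function(p) write_tsv_table(cohort$snps$info, p))
  put("snp_genotype", "snp_genotype.tsv", function(p) {
    df <- data.frame(snp_id = rownames(cohort$snps$genotype),
                     cohort$snps$genotype, check.names = FALSE)
    write_tsv_table(df, p)
  })
  put("snp_baf", "snp_baf.tsv",
      function(p) write_matrix_tsv(cohort$snps$baf, p, id_col = "snp_id"))
  if (!is.null(cohort$cnv)) {
    put("cnv", "cnv_index.bed", function(p) write_bed(cohort$cnv, p))
  }
  put("repeats", "repeat_assay.tsv", function(p) write_tsv_table(cohort$repeats, p))
  if (!is.null(cohort$xci)) {
    put("xci", "xci_peaks.tsv", function(p) write_tsv_table(cohort$xci, p))
  }
  put("metadata", "metadata.tsv", function(p) write_tsv_table(md, p))
  put("gene_sets", "gene_sets.json", function(p)
    jsonlite::write_json(cohort$gene_sets, p, auto_unbox = FALSE, pretty = TRUE))
  put("config", "config.yaml", function(p)
    yaml::write_yaml(config_to_list(cohort$config), p, precision = 15))
  manifest <- c(files, list(index_individual = cohort$index_individual))
  jsonlite::write_json(manifest, file.path(directory, "cohort_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(files)
}

#' Read a synthetic cohort back from a directory
#'
#' @param directory a directory produced by [write_cohort()].
#' @return a `synthetic_cohort` object equal (to numerical write
#'   precision) to the one written.
#' @export
read_cohort <- function(directory) {
  mf_path <- file.path(directory, "cohort_manifest.json")
  assert_that(file.exists(mf_path),
              sprintf("no cohort_manifest.json under %s", directory))
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  rd <- function(rel) file.path(directory, rel)
  cfg <- read_config_yaml(rd(mf$config))
  md <- read_tsv_table(rd(mf$metadata))
  bind_tissues <- function(prefix, id_col = "probe_id") {
    mats <- lapply(cfg$tissues, function(t) read_matrix_tsv(rd(sprintf("%s_%s.tsv", prefix, t))))
    do.call(cbind, mats)[, md$sample_id, drop = FALSE]
  }
  geno_df <- read_tsv_table(rd(mf$snp_genotype))
  geno <- as.matrix(geno_df[, -1, drop = FALSE])
  rownames(geno) <- geno_df[[1]]
  xci <- if (!is.null(mf$xci)) read_tsv_table(rd(mf$xci)) else NULL
  cnv <- if (!is.null(mf$cnv)) read_bed(rd(mf$cnv)) else NULL
  gene_sets <- lapply(jsonlite::read_json(rd(mf$gene_sets), simplifyVector = TRUE),
                      as.character)
  beadcount <- bind_tissues("beadcount")
  storage.mode(beadcount) <- "integer"
  structure(list(
    config = cfg,
    manifest = read_tsv_table(rd(mf$manifest)),
    betas = bind_tissues("betas"),
    beadcount = beadcount,
    detection_p = bind_tissues("detection_p"),
    expression = bind_tissues("expression"),
    expr_manifest = read_tsv_table(rd(mf$expr_manifest)),
    expr_detection_p = bind_tissues("expr_detection_p"),
    snp_probe_betas = read_matrix_tsv(rd(mf$snp_probe_betas)),
    snps = list(info = read_tsv_table(rd(mf$snp_info)),
                genotype = geno,
                baf = read_matrix_tsv(rd(mf$snp_baf))),
    cnv = cnv,
    repeats = read_tsv_table(rd(mf$repeats)),
    xci = xci,
    metadata = md,
    gene_sets = gene_sets,
    index_individual = if (is.null(mf$index_individual) ||
                           is.na(mf$index_individual)) NA_character_
                       else mf$index_individual
  ), class = "synthetic_cohort")
}
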