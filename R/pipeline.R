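#' Run the full single-subject analysis pipeline
#'
#' Orchestrates, in order: probe/sample QC, cross-tissue identity
#' checking, karyotype inference, per-tissue singleton screens
#' (methylation and expression), adjacent-probe region calling with
#' CNV overlap screening, repeat-element global-methylation assessment,
#' phenotype outlier checks, XCI skewing, and gene-set bookkeeping.
#' Any stage failure aborts with the stage name and cause. The pipeline
#' is deterministic: it draws no random numbers.
#'
#' @param cohort a `synthetic_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param alpha family-wise significance level for the screens.
#' @param dmr_window,dmr_min_probes region-calling parameters.
#' @param tail singleton test tail (see [singleton_z_test()]).
#' @param out_dir when non-`NULL`, result tables (TSV/BED) and the JSON
#'   report are written there.
#' @return a run-report list with per-stage results and counts.
#' @export
run_pipeline <- function(cohort, alpha = 0.05, dmr_window = 500L,
                         dmr_min_probes = 2L, tail = "normal",
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  md <- cohort$metadata
  tissues <- cohort$config$tissues
  index_ind <- cohort$index_individual
  has_index <- !is.na(index_ind)
  report <- list(tool_version = as.character(packageVersion("nof1omics")),
                 alpha = alpha, dmr_window = dmr_window,
                 dmr_min_probes = dmr_min_probes, tail = tail,
                 index_individual = if (has_index) index_ind else NULL)

  ## QC ------------------------------------------------------------------
  qc <- stage("qc", {
    blacklist <- cohort$manifest$probe_id[cohort$manifest$cross_reactive]
    meth <- filter_methylation_probes(cohort$manifest, cohort$betas,
                                      cohort$beadcount, cohort$detection_p,
                                      blacklist = blacklist)
    expr <- filter_expression_probes(cohort$expression, cohort$expr_detection_p)
    list(meth = meth, expr = expr)
  })
  report$qc <- list(methylation = qc$meth$report, expression = qc$expr$report,
                    meth_probes_surviving = length(qc$meth$surviving),
                    expr_probes_surviving = length(qc$expr$surviving))

  ## identity ------------------------------------------------------------
  if (length(tissues) >= 2) {
    report$identity <- stage("identity", {
      inds <- unique(md$individual_id)
      pairs <- do.call(rbind, lapply(inds, function(i) {
        s <- md$sample_id[md$individual_id == i]
        if (length(s) < 2) return(NULL)
        data.frame(a = s[1], b = s[2], stringsAsFactors = FALSE)
      }))
      sample_identity_check(cohort$snp_probe_betas, pairs)
    })
  }

  ## karyotype ------------------------------------------------------------
  karyo <- stage("karyotype", infer_karyotypes(cohort))
  report$karyotype <- karyo

  ## singleton screens ----------------------------------------------------
  screens <- NULL
  dmrs <- NULL
  if (has_index) {
    sexes <- setNames(md$reported_sex[!duplicated(md$individual_id)],
                      md$individual_id[!duplicated(md$individual_id)])
    meth_chrom <- setNames(cohort$manifest$chromosome, cohort$manifest$probe_id)
    expr_chrom <- setNames(cohort$expr_manifest$chromosome,
                           cohort$expr_manifest$probe_id)
    screens <- stage("screen", {
      out <- list()
      for (t in tissues) {
        cols <- md$sample_id[md$tissue == t]
        idx <- paste(index_ind, t, sep = "_")
        sex_t <- setNames(sexes[md$individual_id[match(cols, md$sample_id)]], cols)
        mb <- qc$meth$betas[, cols, drop = FALSE]
        sm <- run_singleton_screen(mb, idx, sex_t,
                                   meth_chrom[rownames(mb)], alpha = alpha,
                                   tail = tail)
        sm$tissue <- t
        sm$assay <- "methylation"
        me <- qc$expr$intensities[, cols, drop = FALSE]
        se <- run_singleton_screen(me, idx, sex_t,
                                   expr_chrom[rownames(me)], alpha = alpha,
                                   tail = tail)
        se$tissue <- t
        se$assay <- "expression"
        out[[t]] <- rbind(sm, se)
      }
      do.call(rbind, out)
    })
    rownames(screens) <- NULL
    sig <- screens[screens$significant, , drop = FALSE]
    count_dir <- function(sub) list(up = sum(sub$effect > 0),
                                    down = sum(sub$effect < 0),
                                    zero = sum(sub$effect == 0),
                                    total = nrow(sub))
    counts <- list()
    for (t in tissues) for (a in c("methylation", "expression"))
      for (fam in c("all", "males", "females")) {
        counts[[t]][[a]][[fam]] <-
          count_dir(sig[sig$tissue == t & sig$assay == a & sig$comparison == fam, ])
      }
    report$screen_counts <- counts

    ## DMRs + CNV overlap -------------------------------------------------
    dmrs <- stage("dmr", {
      meth_res <- screens[screens$assay == "methylation", , drop = FALSE]
      d <- call_dmrs(meth_res, cohort$manifest, window = dmr_window,
                     min_probes = dmr_min_probes)
      overlap_cnv(d, cohort$cnv)
    })
    report$dmrs <- dmrs

    ## phenotype outliers --------------------------------------------------
    report$phenotypes <- stage("phenotype", {
      one_per_ind <- md[!duplicated(md$individual_id), ]
      ref <- one_per_ind[one_per_ind$individual_id != index_ind, ]
      idx <- one_per_ind[one_per_ind$individual_id == index_ind, ]
      list(cerebellum_mass = phenotype_outlier(idx$cerebellum_mass,
                                               ref$cerebellum_mass),
           total_brain_mass = phenotype_outlier(idx$total_brain_mass,
                                                ref$total_brain_mass))
    })

    ## gene sets -----------------------------------------------------------
    sets <- Filter(length, cohort$gene_sets)
    if (length(sets)) {
      report$gene_sets <- stage("gene_sets",
        gene_set_outlier_report(screens[screens$assay == "expression", ], sets))
    }
  } else {
    report$screen_skipped <- "no index case configured; singleton screens not run"
  }

  ## global methylation ----------------------------------------------------
  report$global_methylation <- stage("globalmeth", {
    recs <- summarize_assay(cohort$repeats)
    if (has_index) global_outlier_assessment(recs, index_ind)
    else list(note = "no index case; summary only",
              n_records = nrow(recs))
  })

  ## XCI -------------------------------------------------------------------
  if (!is.null(cohort$xci)) {
    report$xci <- stage("xci", xci_from_peaks(cohort$xci))
  }

  ## outputs ---------------------------------------------------------------
  if (!is.null(out_dir)) {
    stage("report", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_table(karyo, file.path(out_dir, "karyotype_calls.tsv"))
      if (!is.null(screens)) {
        write_tsv_table(screens, file.path(out_dir, "singleton_screen.tsv"))
      }
      if (!is.null(dmrs) && nrow(dmrs)) {
        write_tsv_table(dmrs, file.path(out_dir, "dmrs.tsv"))
        write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
      }
      write_report(report, file.path(out_dir, "run_report.json"))
    })
  }
  report
}
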