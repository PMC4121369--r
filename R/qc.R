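#' Filter methylation probes
#'
#' Applies, in a fixed documented order, the probe-level quality filters
#' used before any single-subject methylation analysis:
#'
#' 1. `snp_proximity` — probes with a common SNP (MAF > `maf_threshold`)
#'    within `snp_window` bp of the CG target site;
#' 2. `non_cg` — probes whose sequence context is not CG;
#' 3. `blacklist` — supplied probe ids (e.g. probes cross-hybridizing to
#'    the sex chromosomes);
#' 4. `pfilter` — probes with beadcount < `min_beadcount` in more than
#'    `beadcount_sample_frac` of samples, or detection
#'    p > `detection_p_threshold` in more than `detection_sample_frac`
#'    of samples.
#'
#' A probe failing several rules is attributed to the first rule it
#' fails (first-rule-wins), so per-rule counts sum to the total removed.
#' Retained values are never altered, only membership changes.
#'
#' @param manifest probe annotation with `probe_id`, `context`,
#'   `nearest_snp_distance`, `nearest_snp_maf`.
#' @param betas,beadcounts,detection_p probes-by-samples matrices sharing
#'   rownames with `manifest$probe_id` (beadcounts/detection_p may be
#'   `NULL` to skip rule 4).
#' @param blacklist character vector of probe ids to drop (rule 3).
#' @param maf_threshold,snp_window rule-1 thresholds.
#' @param min_beadcount,beadcount_sample_frac,detection_p_threshold,detection_sample_frac
#'   rule-4 thresholds (defaults follow the conventional pfilter
#'   settings: beadcount < 3 in > 5% of samples; detection p > 0.05 in
#'   > 1% of samples).
#' @return list with `betas` (filtered matrix), `report` (data.frame of
#'   per-rule removal counts), `surviving` and `removed` probe-id
#'   vectors.
#' @export
filter_methylation_probes <- function(manifest, betas, beadcounts = NULL,
                                      detection_p = NULL,
                                      blacklist = character(0),
                                      maf_threshold = 0.05, snp_window = 10,
                                      min_beadcount = 3,
                                      beadcount_sample_frac = 0.05,
                                      detection_p_threshold = 0.05,
                                      detection_sample_frac = 0.01) {
  ids <- manifest$probe_id
  check_axes <- function(m, what) {
    if (is.null(m)) return(invisible())
    assert_that(!is.null(rownames(m)) && identical(rownames(m), ids),
                sprintf("probe index of %s does not match the manifest", what))
    assert_that(identical(colnames(m), colnames(betas)),
                sprintf("sample index of %s does not match betas", what))
  }
  assert_that(!is.null(rownames(betas)) && identical(rownames(betas), ids),
              "probe index of betas does not match the manifest")
  check_axes(beadcounts, "beadcounts")
  check_axes(detection_p, "detection_p")

  fail1 <- manifest$nearest_snp_maf > maf_threshold &
    manifest$nearest_snp_distance <= snp_window
  fail2 <- manifest$context != "CG"
  fail3 <- ids %in% blacklist
  fail4 <- rep(FALSE, length(ids))
  if (!is.null(beadcounts)) {
    fail4 <- fail4 | rowMeans(beadcounts < min_beadcount) > beadcount_sample_frac
  }
  if (!is.null(detection_p)) {
    fail4 <- fail4 | rowMeans(detection_p > detection_p_threshold) > detection_sample_frac
  }
  # first-rule-wins attribution
  r1 <- fail1
  r2 <- fail2 & !r1
  r3 <- fail3 & !r1 & !r2
  r4 <- fail4 & !r1 & !r2 & !r3
  removed <- r1 | r2 | r3 | r4
  report <- data.frame(
    rule = c("snp_proximity", "non_cg", "blacklist", "pfilter"),
    n_removed = c(sum(r1), sum(r2), sum(r3), sum(r4)),
    stringsAsFactors = FALSE)
  list(betas = betas[!removed, , drop = FALSE],
       report = report,
       surviving = ids[!removed],
       removed = ids[removed])
}

#' Filter expression probes on detection
#'
#' Drops probes considered non-detectable: detection p above
#' `threshold` in every sample. A probe detected in even one sample is
#' retained.
#'
#' @param intensities probes-by-samples log2 intensity matrix.
#' @param detection_p matching detection p-value matrix.
#' @param threshold detection p-value cutoff (default 0.01).
#' @return list with `intensities` (filtered), `report`, `surviving`,
#'   `removed`.
#' @export
filter_expression_probes <- function(intensities, detection_p, threshold = 0.01) {
  assert_that(identical(dim(intensities), dim(detection_p)) &&
                identical(rownames(intensities), rownames(detection_p)),
              "probe index of detection_p does not match intensities")
  assert_that(identical(colnames(intensities), colnames(detection_p)),
              "sample index of detection_p does not match intensities")
  removed <- rowSums(detection_p <= threshold) == 0
  report <- data.frame(rule = "non_detectable", n_removed = sum(removed),
                       stringsAsFactors = FALSE)
  list(intensities = intensities[!removed, , drop = FALSE],
       report = report,
       surviving = rownames(intensities)[!removed],
       removed = rownames(intensities)[removed])
}

#' Cross-tissue sample identity check
#'
#' Correlates SNP-type probe betas (trimodal genotype fingerprints)
#' between paired samples; pairs from the same individual correlate
#' near 1, unrelated pairs near 0.
#'
#' @param snp_probe_betas SNP-probe-by-sample beta matrix (>= 10 probes).
#' @param pairs data.frame (or 2-column matrix) of sample-id pairs.
#' @param min_r Pearson correlation at or above which a pair is called
#'   the same individual.
#' @return data.frame with `sample_a`, `sample_b`, `r`, `same_individual`.
#' @export
sample_identity_check <- function(snp_probe_betas, pairs, min_r = 0.9) {
  assert_that(nrow(snp_probe_betas) >= 10,
              "need at least 10 SNP-type probes for an identity check")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  assert_that(ncol(pairs) >= 2, "pairs needs two columns of sample ids")
  unknown <- setdiff(unique(c(pairs[[1]], pairs[[2]])), colnames(snp_probe_betas))
  assert_that(length(unknown) == 0,
              paste("unknown sample id(s):", paste(unknown, collapse = ", ")))
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    stats::cor(snp_probe_betas[, pairs[[1]][i]], snp_probe_betas[, pairs[[2]][i]])
  }, numeric(1))
  data.frame(sample_a = pairs[[1]], sample_b = pairs[[2]], r = r,
             same_individual = r >= min_r, stringsAsFactors = FALSE)
}
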