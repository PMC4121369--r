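#' Summarize repeat-element pyrosequencing assays
#'
#' Each LINE-1 / Alu assay interrogates three CpG sites; the per-sample
#' methylation estimate is their arithmetic mean. Rows with a missing
#' CpG value are dropped with a warning. When control rows are present
#' (`role` of `methylated_control` / `unmethylated_control`) they are
#' validated to be > 90% and < 10% methylated respectively.
#'
#' @param raw data.frame with `individual_id`, `tissue`, `assay`,
#'   `cpg1`, `cpg2`, `cpg3` and optionally `role`.
#' @param control_bounds numeric length-2: minimum mean for methylated
#'   controls, maximum for unmethylated controls.
#' @return data.frame of records with `mean_methylation` added and a
#'   logical attribute `"controls_pass"` (`NA` when no controls).
#' @export
summarize_assay <- function(raw, control_bounds = c(90, 10)) {
  need <- c("individual_id", "tissue", "assay", "cpg1", "cpg2", "cpg3")
  assert_that(all(need %in% names(raw)),
              paste("repeat-assay table needs columns:", paste(need, collapse = ", ")))
  cpg <- as.matrix(raw[c("cpg1", "cpg2", "cpg3")])
  assert_that(all(cpg >= 0 & cpg <= 100, na.rm = TRUE),
              "CpG methylation values must be percentages in [0, 100]")
  incomplete <- rowSums(is.na(cpg)) > 0
  if (any(incomplete)) {
    warning(sprintf("%d record(s) dropped for missing CpG values", sum(incomplete)))
    raw <- raw[!incomplete, , drop = FALSE]
    cpg <- cpg[!incomplete, , drop = FALSE]
  }
  out <- raw
  out$mean_methylation <- rowMeans(cpg)
  if (is.null(out$role)) out$role <- "sample"
  pass <- NA
  meth_ctrl <- out$mean_methylation[out$role == "methylated_control"]
  unmeth_ctrl <- out$mean_methylation[out$role == "unmethylated_control"]
  if (length(meth_ctrl) || length(unmeth_ctrl)) {
    pass <- all(meth_ctrl > control_bounds[1]) && all(unmeth_ctrl < control_bounds[2])
    if (!pass) warning("assay control samples out of bounds")
  }
  attr(out, "controls_pass") <- pass
  rownames(out) <- NULL
  out
}

#' Classify a global-methylation deviation
#'
#' Direction of an index value against a reference mean/SD:
#' `hypo` when `z <= -threshold`, `hyper` when `z >= threshold`,
#' otherwise `none`.
#'
#' @param value index percent methylation.
#' @param ref_mean,ref_sd reference cohort statistics.
#' @param threshold absolute z cutoff (default two standard
#'   deviations).
#' @return list with `z` and `direction`.
#' @export
methylation_direction <- function(value, ref_mean, ref_sd, threshold = 2) {
  po <- phenotype_outlier(value, ref_mean = ref_mean, ref_sd = ref_sd,
                          threshold = threshold)
  dir <- if (isTRUE(po$untestable)) NA_character_
    else if (po$z <= -threshold) "hypo"
    else if (po$z >= threshold) "hyper"
    else "none"
  list(z = po$z, direction = dir)
}

#' Assess the index sample as a global-methylation outlier
#'
#' For every tissue x assay combination, the index individual's mean
#' repeat methylation is z-scored against the other individuals
#' (reference SD excludes the index) and classified with
#' [methylation_direction()].
#'
#' @param records summarized assay table from [summarize_assay()]
#'   (control rows are ignored).
#' @param index_individual individual id of the index case.
#' @param threshold absolute z cutoff for calling a direction.
#' @return data.frame with `tissue`, `assay`, `index_value`,
#'   `ref_mean`, `ref_sd`, `n_ref`, `z`, `direction` (`NA` z /
#'   direction when fewer than 3 references or the index is missing).
#' @export
global_outlier_assessment <- function(records, index_individual, threshold = 2) {
  recs <- records[(records$role %||% "sample") == "sample", , drop = FALSE]
  combos <- unique(recs[c("tissue", "assay")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- recs[recs$tissue == combos$tissue[i] & recs$assay == combos$assay[i], ]
    idx <- sub$mean_methylation[sub$individual_id == index_individual]
    ref <- sub$mean_methylation[sub$individual_id != index_individual]
    row <- data.frame(tissue = combos$tissue[i], assay = combos$assay[i],
                      index_value = if (length(idx)) idx[1] else NA_real_,
                      ref_mean = mean(ref), ref_sd = sd(ref),
                      n_ref = length(ref), z = NA_real_,
                      direction = NA_character_, stringsAsFactors = FALSE)
    if (length(idx) && length(ref) >= 3) {
      md <- methylation_direction(idx[1], mean(ref), sd(ref), threshold)
      row$z <- md$z
      row$direction <- md$direction
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
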