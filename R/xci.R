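#' X-inactivation ratio from allelic peak heights
#'
#' Computes the corrected allelic XCI ratio from capillary peak heights
#' of a two-allele (CAG)n repeat assay: each allele's
#' methylation-sensitive (HpaII) digested peak is normalized by its
#' undigested peak to correct for allele-specific amplification
#' (`R1 = h1d/h1u`, `R2 = h2d/h2u`), and the corrected allele-1 share is
#' `R1 / (R1 + R2)`. Skewing is `|ratio - 0.5| * 100` percent, so it
#' lies in \[0, 50\]. MspI (methylation-insensitive) digests, when
#' supplied, act as digestion controls: both MspI peaks must fall below
#' `control_fraction` of the undigested heights.
#'
#' Setting `normalize = FALSE` uses the raw digested peaks
#' (`ratio = h1d / (h1d + h2d)`) without amplification correction.
#'
#' @param h1u,h2u undigested peak heights of alleles 1 and 2 (> 0).
#' @param h1d,h2d HpaII-digested peak heights.
#' @param h1m,h2m optional MspI-digested peak heights.
#' @param normalize normalize digested by undigested peaks (default).
#' @param control_fraction MspI-control pass threshold.
#' @return list with `ratio` (corrected allele-1 share, `NA` when
#'   uninformative), `skewing_percent`, `mspI_control_pass`
#'   (`NA` without MspI data), `informative`.
#' @export
xci_ratio <- function(h1u, h2u, h1d, h2d, h1m = NULL, h2m = NULL,
                      normalize = TRUE, control_fraction = 0.05) {
  assert_that(all(c(h1u, h2u, h1d, h2d, h1m, h2m) >= 0),
              "peak heights must be non-negative")
  assert_that(h1u > 0 && h2u > 0,
              "undigested peak heights must be positive")
  r1 <- if (normalize) h1d / h1u else h1d
  r2 <- if (normalize) h2d / h2u else h2d
  ctrl <- if (is.null(h1m) || is.null(h2m)) NA else
    (h1m < control_fraction * h1u) && (h2m < control_fraction * h2u)
  if (r1 + r2 == 0) {
    return(list(ratio = NA_real_, skewing_percent = NA_real_,
                mspI_control_pass = ctrl, informative = FALSE))
  }
  ratio <- r1 / (r1 + r2)
  list(ratio = ratio, skewing_percent = abs(ratio - 0.5) * 100,
       mspI_control_pass = ctrl, informative = TRUE)
}

#' XCI skewing from a replicate peak-height table
#'
#' Averages replicate digests per individual x tissue (arithmetic mean
#' of each peak height) and computes [xci_ratio()]. Homozygous assays
#' (equal allele repeat lengths) are uninformative and rejected.
#'
#' @param peaks data.frame with `individual_id`, `tissue`, `replicate`,
#'   `allele1`, `allele2`, `h1u`, `h2u`, `h1d`, `h2d` and optionally
#'   `h1m`, `h2m`.
#' @param ... passed to [xci_ratio()].
#' @return data.frame with one row per individual x tissue: `ratio`,
#'   `skewing_percent`, `mspI_control_pass`, `informative`.
#' @export
xci_from_peaks <- function(peaks, ...) {
  need <- c("individual_id", "tissue", "h1u", "h2u", "h1d", "h2d")
  assert_that(all(need %in% names(peaks)),
              paste("peak table needs columns:", paste(need, collapse = ", ")))
  if (all(c("allele1", "allele2") %in% names(peaks)) &&
      any(peaks$allele1 == peaks$allele2)) {
    stop("uninformative locus: homozygous alleles", call. = FALSE)
  }
  combos <- unique(peaks[c("individual_id", "tissue")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- peaks[peaks$individual_id == combos$individual_id[i] &
                   peaks$tissue == combos$tissue[i], , drop = FALSE]
    has_m <- all(c("h1m", "h2m") %in% names(sub))
    r <- xci_ratio(mean(sub$h1u), mean(sub$h2u), mean(sub$h1d), mean(sub$h2d),
                   h1m = if (has_m) mean(sub$h1m) else NULL,
                   h2m = if (has_m) mean(sub$h2m) else NULL, ...)
    out[[i]] <- data.frame(individual_id = combos$individual_id[i],
                           tissue = combos$tissue[i],
                           ratio = r$ratio,
                           skewing_percent = r$skewing_percent,
                           mspI_control_pass = r$mspI_control_pass,
                           informative = r$informative,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
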