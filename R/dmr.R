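#' Call differentially methylated regions from adjacent probes
#'
#' Aggregates individually significant probes into regions: within each
#' comparison family (and tissue, when present) and chromosome, tested
#' probes are sorted by position; consecutive significant probes are
#' linked when no tested-but-nonsignificant probe intervenes and the
#' inter-probe gap is at most `max_gap` bp. Maximal runs of at least
#' `min_probes` whose span fits in `max_span` are emitted; over-long
#' runs are split greedily left-to-right into maximal chunks of span
#' at most `max_span` (a terminal chunk smaller than `min_probes` is
#' dropped). The region statistic is Stouffer's combination of the
#' member z scores with equal weights,
#' `Z = sum(z_i) / sqrt(k)`, reported as the upper-tail
#' `p = 1 - Phi(|Z|)` (one-sided in the region's own direction); the
#' region effect is the mean member effect. Regions mixing effect signs
#' are kept but flagged `sign_mixed`.
#'
#' @param results a singleton screen result table with `feature_id`,
#'   `comparison`, `z`, `p`, `effect`, `significant`, `untestable`, and
#'   optionally `tissue`.
#' @param manifest probe annotation supplying `probe_id`, `chromosome`,
#'   `position` for every tested probe.
#' @param window region extent in bp; sets both defaults below.
#' @param min_probes minimum member probes per region (>= 2).
#' @param max_gap largest allowed gap between consecutive member
#'   probes (bp; defaults to `window`).
#' @param max_span largest allowed region span `end - start` (bp;
#'   defaults to `window`).
#' @return data.frame of regions: `chromosome`, `start`, `end`
#'   (1-based inclusive span of member probes), `n_probes`,
#'   `probe_ids` (comma-joined, position-sorted), `mean_effect`,
#'   `combined_z`, `combined_p`, `comparison` (+ `tissue` if supplied),
#'   `sign_mixed`.
#' @export
call_dmrs <- function(results, manifest, window = 500L, min_probes = 2L,
                      max_gap = window, max_span = window) {
  assert_that(min_probes >= 2, "min_probes must be at least 2")
  pos <- setNames(manifest$position, manifest$probe_id)
  chrom <- setNames(norm_chrom(manifest$chromosome), manifest$probe_id)
  missing <- setdiff(unique(results$feature_id), manifest$probe_id)
  assert_that(length(missing) == 0,
              paste("probes missing from manifest:", paste(utils::head(missing, 3), collapse = ", ")))
  res <- results[!results$untestable, , drop = FALSE]
  res$chromosome <- chrom[res$feature_id]
  res$position <- pos[res$feature_id]
  has_tissue <- "tissue" %in% names(res)
  key <- paste(res$comparison, if (has_tissue) res$tissue else "", res$chromosome)
  out <- list()
  for (k in unique(key)) {
    sub <- res[key == k, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    assert_that(!anyDuplicated(sub$position),
                sprintf("duplicated probe positions on chromosome %s", sub$chromosome[1]))
    n <- nrow(sub)
    if (n < 2) next
    # adjacency on the tested-probe grid: consecutive, both significant,
    # gap within max_gap
    linked <- sub$significant[-n] & sub$significant[-1] &
      diff(sub$position) <= max_gap
    run_id <- cumsum(c(TRUE, !linked))
    for (r in split(seq_len(n), run_id)) {
      if (length(r) < min_probes || !all(sub$significant[r])) next
      i <- 1L
      while (i <= length(r)) {
        j <- i
        while (j < length(r) &&
               sub$position[r[j + 1]] - sub$position[r[i]] <= max_span) j <- j + 1L
        if (j - i + 1L >= min_probes) {
          mem <- r[i:j]
          zc <- sum(sub$z[mem]) / sqrt(length(mem))
          row <- data.frame(
            chromosome = sub$chromosome[1],
            start = sub$position[mem[1]],
            end = sub$position[mem[length(mem)]],
            n_probes = length(mem),
            probe_ids = paste(sub$feature_id[mem], collapse = ","),
            mean_effect = mean(sub$effect[mem]),
            combined_z = zc,
            combined_p = pnorm(abs(zc), lower.tail = FALSE),
            comparison = sub$comparison[1],
            sign_mixed = length(unique(sign(sub$effect[mem]))) > 1,
            stringsAsFactors = FALSE)
          if (has_tissue) row$tissue <- sub$tissue[1]
          out[[length(out) + 1L]] <- row
        }
        i <- j + 1L
      }
    }
  }
  if (!length(out)) {
    cols <- c(chromosome = "character", start = "integer", end = "integer",
              n_probes = "integer", probe_ids = "character",
              mean_effect = "numeric", combined_z = "numeric",
              combined_p = "numeric", comparison = "character",
              sign_mixed = "logical")
    empty <- as.data.frame(lapply(cols, function(tp) vector(tp, 0)),
                           stringsAsFactors = FALSE)
    if (has_tissue) empty$tissue <- character(0)
    return(empty)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$comparison, res$chromosome, res$start), , drop = FALSE]
}

#' Annotate regions with overlapping copy-number segments
#'
#' Screens regions against CNV segments; any 1-bp overlap counts
#' (boundary touching included). Chromosome naming conventions
#' (`chr1` vs `1`) are normalized before matching; a message is logged
#' when normalization changed labels.
#'
#' @param dmrs region table from [call_dmrs()] (needs `chromosome`,
#'   `start`, `end`).
#' @param segments CNV table with `chromosome`, `start`, `end`,
#'   `copy_number` (1-based inclusive; use [read_bed()] for BED input).
#' @return `dmrs` with added `cnv_copy_numbers` (comma-joined copy
#'   numbers of all overlapping segments, `""` when none) and
#'   `n_cnv_overlaps`.
#' @export
overlap_cnv <- function(dmrs, segments) {
  dmr_chr <- norm_chrom(dmrs$chromosome)
  seg_chr <- norm_chrom(segments$chromosome)
  if (!identical(dmr_chr, as.character(dmrs$chromosome)) ||
      !identical(seg_chr, as.character(segments$chromosome))) {
    message("overlap_cnv: chromosome labels normalized to unprefixed convention")
  }
  dmrs$cnv_copy_numbers <- rep("", nrow(dmrs))
  dmrs$n_cnv_overlaps <- rep(0L, nrow(dmrs))
  if (!nrow(dmrs) || is.null(segments) || !nrow(segments)) return(dmrs)
  gr_d <- GenomicRanges::GRanges(dmr_chr,
                                 IRanges::IRanges(dmrs$start, dmrs$end))
  gr_s <- GenomicRanges::GRanges(seg_chr,
                                 IRanges::IRanges(segments$start, segments$end))
  # differing seqlevel sets between query and subject are expected here
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_d, gr_s))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    for (i in unique(q)) {
      cn <- segments$copy_number[s[q == i]]
      dmrs$cnv_copy_numbers[i] <- paste(cn, collapse = ",")
      dmrs$n_cnv_overlaps[i] <- length(cn)
    }
  }
  dmrs
}

#' Write regions as a BED track
#'
#' Regions are written 0-based half-open with name
#' `comparison` (or `tissue:comparison`) and score
#' `-log10(combined_p)` (capped at 1000).
#'
#' @param dmrs region table from [call_dmrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  nm <- if ("tissue" %in% names(dmrs)) {
    paste(dmrs$tissue, dmrs$comparison, sep = ":")
  } else dmrs$comparison
  df <- data.frame(chromosome = dmrs$chromosome, start = dmrs$start,
                   end = dmrs$end, name = nm,
                   score = round(pmin(1000, -log10(pmax(dmrs$combined_p, 1e-300))), 3),
                   stringsAsFactors = FALSE)
  write_bed(df, path)
}
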