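#' Chromosome-aware comparison-group policy
#'
#' Autosomal features are tested against all references, males only and
#' females only; X-linked features against females only; Y-linked
#' features against males only (hemizygous references are not a valid
#' baseline for the opposite channel).
#'
#' @param chromosome character vector of chromosome labels.
#' @return list (one element per input) of allowed comparison family
#'   names among `"all"`, `"males"`, `"females"`.
#' @export
comparison_policy <- function(chromosome) {
  ch <- norm_chrom(chromosome)
  lapply(ch, function(c1) {
    if (c1 == "X") "females"
    else if (c1 == "Y") "males"
    else c("all", "males", "females")
  })
}

#' Per-feature reference statistics
#'
#' Mean and sample SD (n-1 denominator) of each feature over a
#' reference group.
#'
#' @param mat features-by-samples matrix.
#' @param group character vector of reference sample ids (>= 3; must not
#'   include the index sample downstream).
#' @return data.frame with `feature_id`, `n_ref`, `mean_ref`, `sd_ref`.
#' @export
reference_statistics <- function(mat, group) {
  assert_that(length(group) >= 3, "reference group must have at least 3 samples")
  missing <- setdiff(group, colnames(mat))
  assert_that(length(missing) == 0,
              paste("reference sample(s) not in matrix:", paste(missing, collapse = ", ")))
  sub <- mat[, group, drop = FALSE]
  data.frame(feature_id = rownames(mat),
             n_ref = length(group),
             mean_ref = row_means(sub),
             sd_ref = row_sds(sub),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Singleton z-score outlier test
#'
#' Tests one index observation against a reference mean and SD:
#' `z = (x - mean_ref) / sd_ref`, two-sided `p = 2 * Phi(-|z|)` under
#' the default `"normal"` tail. Because `sd_ref` is estimated from a
#' moderate reference group this normal tail is anti-conservative; the
#' `"t"` tail instead refers `z / sqrt(1 + 1/n_ref)` to a t distribution
#' with `n_ref - 1` degrees of freedom (the exact prediction-interval
#' law for Gaussian features), which restores finite-sample calibration.
#' Features with `sd_ref = 0` are flagged untestable (`NA` statistics)
#' and must be excluded from multiplicity counts.
#'
#' @param index_value numeric vector of index observations (recycled
#'   against `ref`).
#' @param ref data.frame from [reference_statistics()] (or any frame
#'   with `mean_ref`, `sd_ref`, `n_ref`).
#' @param tail `"normal"` (plain normal z) or `"t"` (prediction-scaled
#'   t).
#' @return data.frame with `feature_id`, `index_value`, `effect`
#'   (index minus reference mean: beta difference on the methylation
#'   scale, log2 fold change for expression), `z`, `p`, `untestable`.
#' @export
singleton_z_test <- function(index_value, ref, tail = c("normal", "t")) {
  tail <- match.arg(tail)
  sd0 <- ref$sd_ref == 0
  effect <- index_value - ref$mean_ref
  z <- ifelse(sd0, NA_real_, effect / ref$sd_ref)
  p <- if (tail == "normal") {
    2 * pnorm(-abs(z))
  } else {
    2 * pt(-abs(z) / sqrt(1 + 1 / ref$n_ref), df = ref$n_ref - 1)
  }
  data.frame(feature_id = ref$feature_id %||% seq_along(z),
             index_value = index_value,
             effect = ifelse(sd0, NA_real_, effect),
             z = z, p = p, untestable = sd0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full singleton outlier screen
#'
#' For every feature, tests the index sample against each comparison
#' family its chromosome allows (see [comparison_policy()]):
#' all references, male references, female references. Bonferroni
#' correction is applied within each family separately, with the
#' multiplicity `m` counting only testable (sd > 0, policy-allowed)
#' features of that family.
#'
#' @param mat features-by-samples matrix (index column included).
#' @param index_sample the index sample id.
#' @param sex named character vector (`"male"`/`"female"`) covering
#'   every reference sample.
#' @param feature_chrom named (by feature id) chromosome vector; when
#'   `NULL` all features are treated as autosomal.
#' @param alpha family-wise significance level (default 0.05).
#' @param tail passed to [singleton_z_test()].
#' @return data.frame, one row per feature x allowed family:
#'   `feature_id`, `comparison`, `index_value`, `effect`, `z`, `p`,
#'   `p_adj` (`min(1, p * m)`), `significant`, `untestable`. The
#'   per-family multiplicities are attached as attribute `"m"`.
#' @export
run_singleton_screen <- function(mat, index_sample, sex, feature_chrom = NULL,
                                 alpha = 0.05, tail = c("normal", "t")) {
  tail <- match.arg(tail)
  assert_that(index_sample %in% colnames(mat),
              sprintf("index sample '%s' missing from matrix", index_sample))
  ref_ids <- setdiff(colnames(mat), index_sample)
  missing_sex <- setdiff(ref_ids, names(sex))
  assert_that(length(missing_sex) == 0,
              paste("reference sample(s) without sex:", paste(missing_sex, collapse = ", ")))
  groups <- list(all = ref_ids,
                 males = ref_ids[sex[ref_ids] == "male"],
                 females = ref_ids[sex[ref_ids] == "female"])
  if (is.null(feature_chrom)) {
    feature_chrom <- setNames(rep("1", nrow(mat)), rownames(mat))
  }
  allowed <- comparison_policy(feature_chrom[rownames(mat)])
  names(allowed) <- rownames(mat)
  out <- list()
  m_per_family <- c(all = 0L, males = 0L, females = 0L)
  for (fam in names(groups)) {
    feats <- rownames(mat)[vapply(allowed, function(a) fam %in% a, logical(1))]
    if (!length(feats)) next
    assert_that(length(groups[[fam]]) >= 3,
                sprintf("comparison family '%s' has fewer than 3 reference samples", fam))
    ref <- reference_statistics(mat[feats, , drop = FALSE], groups[[fam]])
    res <- singleton_z_test(mat[feats, index_sample], ref, tail = tail)
    m <- sum(!res$untestable)
    m_per_family[fam] <- m
    res$comparison <- fam
    res$p_adj <- pmin(1, res$p * m)
    res$significant <- !res$untestable & res$p_adj < alpha
    out[[fam]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("feature_id", "comparison", "index_value", "effect", "z",
                 "p", "p_adj", "significant", "untestable")]
  attr(res, "m") <- m_per_family
  res
}

#' Scalar phenotype outlier assessment
#'
#' z-score of a single phenotype value against a reference cohort
#' (vector, or precomputed mean/SD); an absolute z at or above
#' `threshold` (default two standard deviations) is called an outlier.
#'
#' @param value index phenotype value.
#' @param ref_values reference cohort values (>= 3), or `NULL` when
#'   `ref_mean`/`ref_sd` are given directly.
#' @param ref_mean,ref_sd reference summary statistics (used when
#'   `ref_values` is `NULL`).
#' @param threshold absolute-z outlier threshold.
#' @return list with `z`, `outlier`, `direction` (`"low"`/`"high"`/
#'   `"none"`), `ref_mean`, `ref_sd`.
#' @export
phenotype_outlier <- function(value, ref_values = NULL, ref_mean = NULL,
                              ref_sd = NULL, threshold = 2) {
  if (!is.null(ref_values)) {
    assert_that(length(ref_values) >= 3, "need at least 3 reference values")
    ref_mean <- mean(ref_values)
    ref_sd <- sd(ref_values)
  }
  assert_that(!is.null(ref_mean) && !is.null(ref_sd),
              "supply ref_values or ref_mean and ref_sd")
  if (ref_sd == 0) {
    return(list(z = NA_real_, outlier = NA, direction = NA_character_,
                ref_mean = ref_mean, ref_sd = ref_sd, untestable = TRUE))
  }
  z <- (value - ref_mean) / ref_sd
  list(z = z, outlier = abs(z) >= threshold,
       direction = if (abs(z) < threshold) "none" else if (z < 0) "low" else "high",
       ref_mean = ref_mean, ref_sd = ref_sd, untestable = FALSE)
}

#' Gene-set outlier summary
#'
#' Tabulates the index sample's direction of change (`up` / `down` /
#' `none`, or `missing` when a feature is absent or untestable) per
#' gene, tissue and comparison family, for named gene sets such as
#' XCI-escape genes or the pseudoautosomal regions PAR1/PAR2. No
#' aggregate statistic is computed — the output is a bookkeeping table.
#'
#' @param results a screen result table (rows per feature x comparison)
#'   with a `tissue` column, as produced by [run_pipeline()]'s screens
#'   or by stacking [run_singleton_screen()] outputs.
#' @param gene_sets named list of feature-id vectors (no set may be
#'   empty).
#' @return data.frame with `set`, `feature_id`, `tissue`, `comparison`,
#'   `direction`, plus a per-feature `consistent` flag (same non-none
#'   direction wherever testable). Features absent from `results` are
#'   reported with direction `missing`.
#' @export
gene_set_outlier_report <- function(results, gene_sets) {
  assert_that(length(gene_sets) > 0 && !is.null(names(gene_sets)),
              "gene_sets must be a named list")
  assert_that("tissue" %in% names(results), "results needs a tissue column")
  grid <- unique(results[c("tissue", "comparison")])
  out <- list()
  for (set in names(gene_sets)) {
    feats <- gene_sets[[set]]
    assert_that(length(feats) > 0, sprintf("gene set '%s' is empty", set))
    for (f in feats) {
      rows <- results[results$feature_id == f, , drop = FALSE]
      for (g in seq_len(nrow(grid))) {
        r <- rows[rows$tissue == grid$tissue[g] &
                    rows$comparison == grid$comparison[g], , drop = FALSE]
        direction <- if (!nrow(r) || r$untestable[1]) "missing"
          else if (!r$significant[1]) "none"
          else if (r$effect[1] > 0) "up" else "down"
        out[[length(out) + 1L]] <- data.frame(
          set = set, feature_id = f, tissue = grid$tissue[g],
          comparison = grid$comparison[g], direction = direction,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  cons <- vapply(unique(res$feature_id), function(f) {
    d <- res$direction[res$feature_id == f]
    d <- d[d != "missing"]
    length(d) > 0 && length(unique(d)) == 1 && d[1] != "none"
  }, logical(1))
  res$consistent <- cons[res$feature_id]
  res
}
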