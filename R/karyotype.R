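#' Select the most variable probes
#'
#' @param betas probes-by-samples matrix.
#' @param frac fraction of probes to keep, ranked by variance (top
#'   decile by default).
#' @return matrix restricted to the selected probes.
#' @export
select_variable_probes <- function(betas, frac = 0.1) {
  v <- apply(betas, 1, var)
  k <- max(1L, ceiling(frac * nrow(betas)))
  betas[order(v, decreasing = TRUE)[seq_len(k)], , drop = FALSE]
}

# deterministic 1-D 2-means: initial centers at the observed extremes
two_means_split <- function(x, labels = c("low", "high")) {
  if (length(unique(x)) < 2) {
    return(list(cluster = rep(NA_character_, length(x)), indeterminate = TRUE))
  }
  km <- kmeans(x, centers = matrix(c(min(x), max(x)), ncol = 1))
  lab <- labels[order(km$centers)][km$cluster]
  list(cluster = lab, indeterminate = FALSE)
}

#' Cluster samples by X-chromosome methylation
#'
#' Reduces each sample to its mean beta over supplied sex-dimorphic X
#' probes and splits samples by 2-means clustering (initialized at the
#' observed extremes, hence deterministic). The cluster with the higher
#' mean beta is labeled `female-like` (X inactivation pushes island
#' probes towards intermediate betas when two X chromosomes are
#' present).
#'
#' @param betas matrix restricted to sex-dimorphic X probes (>= 5
#'   probes, >= 4 samples).
#' @return data.frame with `sample_id`, `x_meth_score` (mean beta) and
#'   `x_meth_cluster` (`female-like`/`male-like`, `NA` when the input is
#'   degenerate).
#' @export
cluster_x_methylation <- function(betas) {
  assert_that(nrow(betas) >= 5, "need at least 5 X probes")
  assert_that(ncol(betas) >= 4, "need at least 4 samples")
  score <- colMeans(betas)
  sp <- two_means_split(score, labels = c("male-like", "female-like"))
  data.frame(sample_id = colnames(betas), x_meth_score = unname(score),
             x_meth_cluster = sp$cluster, stringsAsFactors = FALSE)
}

#' Classify XIST expression
#'
#' 2-means split of per-sample XIST log2 intensity; the higher-mean
#' cluster is `high` (XIST marks the presence of an inactive X).
#'
#' @param xist named numeric vector of per-sample XIST intensity
#'   (>= 4 samples).
#' @return data.frame with `sample_id`, `xist_value`, `xist_class`
#'   (`high`/`low`, `NA` when constant).
#' @export
classify_xist <- function(xist) {
  assert_that(length(xist) >= 4, "need at least 4 samples")
  sp <- two_means_split(as.numeric(xist), labels = c("low", "high"))
  data.frame(sample_id = names(xist) %||% as.character(seq_along(xist)),
             xist_value = as.numeric(xist), xist_class = sp$cluster,
             stringsAsFactors = FALSE)
}

#' Assess Y-chromosome signal
#'
#' A sample is called Y-positive when at least half of the Y
#' methylation probes are detected (boundary inclusive) AND its mean Y
#' expression lies within 2 SD of the Y-high (male) expression cluster.
#'
#' @param y_detection_p Y-probe detection p-value matrix (methylation;
#'   >= 3 probes).
#' @param y_expression Y-transcript log2 intensity matrix over the same
#'   samples.
#' @param detection_threshold detection p cutoff defining "detected".
#' @return data.frame with per-sample `y_detected_frac`, `y_expr_mean`,
#'   `y_present`.
#' @export
assess_y_signal <- function(y_detection_p, y_expression,
                            detection_threshold = 0.05) {
  assert_that(nrow(y_detection_p) >= 3, "need at least 3 Y probes")
  assert_that(identical(colnames(y_detection_p), colnames(y_expression)),
              "sample index of y_expression does not match y_detection_p")
  det_frac <- colMeans(y_detection_p <= detection_threshold)
  expr_mean <- colMeans(y_expression)
  sp <- two_means_split(expr_mean, labels = c("low", "high"))
  if (sp$indeterminate) {
    expr_ok <- rep(TRUE, length(expr_mean))  # no contrast in expression
  } else {
    hi <- expr_mean[sp$cluster == "high"]
    sd_hi <- max(sd(hi), 1e-8)
    expr_ok <- abs(expr_mean - mean(hi)) <= 2 * sd_hi
  }
  data.frame(sample_id = colnames(y_detection_p),
             y_detected_frac = unname(det_frac),
             y_expr_mean = unname(expr_mean),
             y_present = unname(det_frac >= 0.5 & expr_ok),
             stringsAsFactors = FALSE)
}

#' X-chromosome heterozygosity rate
#'
#' Fraction of non-missing X-SNP genotype calls that are heterozygous,
#' per sample. Hemizygous 46,XY individuals score near 0; individuals
#' with two X chromosomes score high.
#'
#' @param genotypes SNP-by-sample character matrix of calls
#'   (`"AA"`/`"AB"`/`"BB"`, `NA` missing; >= 20 SNPs).
#' @return named numeric vector of het rates.
#' @export
x_heterozygosity <- function(genotypes) {
  assert_that(nrow(genotypes) >= 20, "need at least 20 X SNPs")
  apply(genotypes, 2, function(g) {
    ok <- !is.na(g)
    assert_that(any(ok), "all genotype calls missing for a sample")
    mean(g[ok] == "AB")
  })
}

#' Count B-allele-frequency bands
#'
#' Histograms BAF values into 50 fixed bins on \[0, 1\] and counts
#' local maxima carrying more than `min_mass` of the total mass. A bin
#' is a peak when its count exceeds the left neighbor and is at least
#' the right neighbor (so a two-bin plateau — e.g. a mode sitting on a
#' bin edge — counts once); bins outside the range count as zero.
#' Diploid samples show bands at \{0, 1/2, 1\}; a trisomic chromosome
#' splits heterozygotes into bands at 1/3 and 2/3, giving four bands.
#'
#' @param baf numeric vector of B-allele frequencies (>= 200 values for
#'   a stable histogram).
#' @param bins number of histogram bins (fixed-width on \[0,1\]).
#' @param min_mass minimum fraction of total mass for a peak bin.
#' @return list with `n_bands` and `centers` (peak bin midpoints).
#' @export
count_baf_bands <- function(baf, bins = 50L, min_mass = 0.05) {
  baf <- baf[!is.na(baf)]
  assert_that(length(baf) >= 200,
              "need at least 200 BAF values for stable band counting")
  assert_that(all(baf >= 0 & baf <= 1), "BAF values must lie in [0, 1]")
  idx <- pmin(pmax(findInterval(baf, seq(0, 1, length.out = bins + 1),
                                rightmost.closed = TRUE), 1L), bins)
  cnt <- tabulate(idx, nbins = bins)
  padded <- c(0, cnt, 0)
  is_peak <- vapply(seq_len(bins), function(i) {
    padded[i + 1] > padded[i] && padded[i + 1] >= padded[i + 2] &&
      cnt[i] > min_mass * length(baf)
  }, logical(1))
  mids <- (seq_len(bins) - 0.5) / bins
  list(n_bands = sum(is_peak), centers = mids[is_peak])
}

#' Call a karyotype from integrated evidence
#'
#' Decision table over the evidence channels:
#' * female-like X methylation, no Y signal: `46,XX`;
#' * male-like X methylation with Y signal: `46,XY`;
#' * female-like X methylation **and** Y signal: `47,XXY`, provided the
#'   genotype channel (when present) supports two X copies — X het rate
#'   > `het_threshold` or 4 BAF bands;
#' * anything else: `indeterminate`.
#'
#' The discordance flag is set when the call's sex-equivalent (`46,XX`
#' is female; `46,XY` and `47,XXY` are male) differs from the reported
#' sex. The call is a pure function of its inputs.
#'
#' @param evidence list or one-row data.frame with `x_meth_cluster`
#'   (`female-like`/`male-like`/`NA`), `y_present` (logical or `NA`),
#'   and optionally `x_het_rate`, `baf_band_count`, `xist_class`.
#' @param reported_sex `"male"` or `"female"` (or `NA`).
#' @param het_threshold X-het rate above which two X copies are
#'   supported.
#' @return list with `call`, `sex_equivalent`,
#'   `discordant_with_reported_sex`, and the evidence echoed back.
#' @export
call_karyotype <- function(evidence, reported_sex = NA_character_,
                           het_threshold = 0.02) {
  ev <- as.list(evidence)
  x <- ev$x_meth_cluster %||% NA_character_
  y <- ev$y_present %||% NA
  het <- ev$x_het_rate %||% NA_real_
  bands <- ev$baf_band_count %||% NA_integer_
  geno_present <- !is.na(het) || !is.na(bands)
  two_x_support <- (!is.na(het) && het > het_threshold) ||
    (!is.na(bands) && bands == 4L)
  call <- "indeterminate"
  if (!is.na(x) && !is.na(y)) {
    if (x == "female-like" && !y) {
      call <- "46,XX"
    } else if (x == "male-like" && y) {
      call <- "46,XY"
    } else if (x == "female-like" && y) {
      call <- if (!geno_present || two_x_support) "47,XXY" else "indeterminate"
    }
  }
  sex_eq <- switch(call, "46,XX" = "female", "46,XY" = "male",
                   "47,XXY" = "male", NA_character_)
  discord <- if (is.na(sex_eq) || is.na(reported_sex)) NA else sex_eq != reported_sex
  list(call = call, sex_equivalent = sex_eq,
       discordant_with_reported_sex = discord, evidence = ev)
}

#' Assemble karyotype evidence and calls for a whole cohort
#'
#' Convenience wrapper running every evidence channel on a synthetic (or
#' equivalently structured) cohort and calling [call_karyotype()] per
#' individual. Methylation and expression channels are averaged over an
#' individual's samples across tissues; the X-methylation score is
#' computed over the top-variance decile of X probes; heterozygosity
#' uses non-XTR X SNPs (XTR-homolog SNPs cross-hybridize with the Y and
#' would inflate male het rates); band counting uses all X SNPs.
#'
#' @param cohort a `synthetic_cohort` (or list with the same fields).
#' @param variable_frac variance-rank fraction of X probes used for the
#'   methylation score.
#' @return data.frame, one row per individual, with the evidence
#'   channels, `call` and `discordant_with_reported_sex`.
#' @export
infer_karyotypes <- function(cohort, variable_frac = 0.1) {
  md <- cohort$metadata
  individuals <- unique(md$individual_id)
  agg <- function(m) {
    # average a per-sample matrix into a per-individual matrix
    out <- vapply(individuals, function(i) {
      cols <- md$sample_id[md$individual_id == i]
      rowMeans(m[, cols, drop = FALSE])
    }, numeric(nrow(m)))
    matrix(out, nrow = nrow(m), dimnames = list(rownames(m), individuals))
  }
  x_probes <- cohort$manifest$probe_id[cohort$manifest$chromosome == "X"]
  xb <- select_variable_probes(agg(cohort$betas[x_probes, , drop = FALSE]),
                               frac = variable_frac)
  xcl <- cluster_x_methylation(xb)
  xist <- classify_xist(agg(cohort$expression)["expr_XIST", ])
  y_probes <- cohort$manifest$probe_id[cohort$manifest$chromosome == "Y"]
  y_expr_ids <- cohort$expr_manifest$probe_id[cohort$expr_manifest$chromosome == "Y"]
  ys <- assess_y_signal(agg(cohort$detection_p[y_probes, , drop = FALSE]),
                        agg(cohort$expression[y_expr_ids, , drop = FALSE]))
  non_xtr <- cohort$snps$info$region != "XTR"
  het <- x_heterozygosity(cohort$snps$genotype[non_xtr, individuals, drop = FALSE])
  # band counting follows the allele-frequency plot over the X/Y-homologous
  # (XTR) regions, where a supernumerary X reads as three copies (bands at
  # 1/3 and 2/3) while a 46,XY male reads diploid (band at 1/2); falls back
  # to all X SNPs, or NA, when the XTR panel is too small for a stable
  # histogram
  xtr_rows <- which(!non_xtr)
  band_rows <- if (length(xtr_rows) >= 200) xtr_rows else seq_len(nrow(cohort$snps$baf))
  bands <- vapply(individuals, function(i) {
    baf <- cohort$snps$baf[band_rows, i]
    if (sum(!is.na(baf)) < 200) return(NA_integer_)
    as.integer(count_baf_bands(baf)$n_bands)
  }, integer(1))
  reported <- md$reported_sex[match(individuals, md$individual_id)]
  calls <- lapply(seq_along(individuals), function(k) {
    call_karyotype(list(
      x_meth_cluster = xcl$x_meth_cluster[k],
      y_present = ys$y_present[k],
      x_het_rate = unname(het[k]),
      baf_band_count = bands[k],
      xist_class = xist$xist_class[k]), reported_sex = reported[k])
  })
  data.frame(
    individual_id = individuals,
    reported_sex = reported,
    x_meth_score = xcl$x_meth_score,
    x_meth_cluster = xcl$x_meth_cluster,
    xist_class = xist$xist_class,
    y_present = ys$y_present,
    x_het_rate = unname(het),
    baf_band_count = unname(bands),
    call = vapply(calls, `[[`, character(1), "call"),
    discordant_with_reported_sex =
      vapply(calls, function(cl) cl$discordant_with_reported_sex %||% NA,
             logical(1)),
    stringsAsFactors = FALSE)
}
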