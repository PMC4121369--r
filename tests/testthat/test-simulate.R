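test_that("identical seed and config reproduce the cohort exactly", {
  cfg <- small_cfg(seed = 11)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- small_cfg(seed = 12)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("cohort satisfies its structural invariants", {
  co <- simulate_cohort(small_cfg(seed = 2))
  expect_true(all(co$betas >= 0 & co$betas <= 1))
  expect_true(all(co$snps$baf >= 0 & co$snps$baf <= 1, na.rm = TRUE))
  expect_setequal(colnames(co$betas), co$metadata$sample_id)
  expect_setequal(colnames(co$expression), co$metadata$sample_id)
  # index present in both tissues
  idx_samples <- co$metadata$sample_id[co$metadata$individual_id == co$index_individual]
  expect_setequal(co$metadata$tissue[match(idx_samples, co$metadata$sample_id)],
                  co$config$tissues)
  expect_true(all(co$repeats[c("cpg1", "cpg2", "cpg3")] >= 0 &
                    co$repeats[c("cpg1", "cpg2", "cpg3")] <= 100))
})

test_that("contradictory configurations are rejected with a message", {
  bad_spike <- data.frame(type = "methylation", label = "y_spike",
                          chromosome = "Y", start = 100L, end = 200L,
                          effect = 0.3, tissue = "PFC", n_probes = 2L)
  expect_error(small_cfg(index_karyotype = "46,XX", spikes = bad_spike),
               "chromosome Y")
  expect_error(small_cfg(tissues = character(0)), "non-empty")
  expect_error(small_cfg(index_karyotype = "none"), "no index case")
  expect_error(small_cfg(n_probes_autosomal = 0L), "positive")
})

test_that("a 46,XX index sits inside the female X-heterozygosity range", {
  co <- simulate_cohort(small_cfg(seed = 5, index_karyotype = "46,XX",
                                  spikes = NULL))
  non_xtr <- co$snps$info$region != "XTR"
  het <- x_heterozygosity(co$snps$genotype[non_xtr, , drop = FALSE])
  md1 <- co$metadata[!duplicated(co$metadata$individual_id), ]
  females <- md1$individual_id[md1$karyotype == "46,XX" &
                                 md1$individual_id != co$index_individual]
  expect_gte(het[co$index_individual], min(het[females]) * 0.8)
  expect_lte(het[co$index_individual], max(het[females]) * 1.2)
})

test_that("47,XXY heterozygous BAFs form modes near 1/3 and 2/3 with four bands", {
  co <- simulate_cohort(small_cfg(seed = 4))
  xtr <- co$snps$info$region == "XTR"
  baf <- co$snps$baf[xtr, co$index_individual]
  geno <- co$snps$genotype[xtr, co$index_individual]
  hets <- baf[!is.na(geno) & geno == "AB"]
  lo <- hets[hets < 0.5]; hi <- hets[hets >= 0.5]
  expect_equal(mean(lo), 1 / 3, tolerance = 0.02)
  expect_equal(mean(hi), 2 / 3, tolerance = 0.02)
  expect_equal(count_baf_bands(baf)$n_bands, 4L)
})

test_that("spiked index shifts recover the configured effects (3 MC SE)", {
  co <- simulate_cohort(small_cfg(seed = 9))
  md <- co$metadata
  spikes <- co$config$spikes[co$config$spikes$type == "methylation", ]
  for (i in seq_len(nrow(spikes))) {
    r <- spikes[i, ]
    pr <- co$manifest$probe_id[co$manifest$chromosome == r$chromosome &
                                 co$manifest$position >= r$start &
                                 co$manifest$position <= r$end]
    expect_gte(length(pr), r$n_probes)
    idx_col <- paste(co$index_individual, r$tissue, sep = "_")
    ref_cols <- md$sample_id[md$tissue == r$tissue & md$sample_id != idx_col]
    est <- mean(co$betas[pr, idx_col] - rowMeans(co$betas[pr, ref_cols]))
    # per-probe sampling sd of (index - ref mean), averaged over k probes
    sds <- apply(co$betas[pr, ref_cols], 1, sd)
    se <- sqrt(mean(sds^2 * (1 + 1 / length(ref_cols)))) / sqrt(length(pr))
    expect_lt(abs(est - r$effect), 3 * se + 0.02)  # 0.02 absorbs beta clamping
  }
})

test_that("mean X-probe beta separates the sexes with no misassignments", {
  for (seed in 1:5) {
    co <- simulate_cohort(cohort_config(n_individuals = 21L,
                                        n_probes_autosomal = 100L,
                                        n_probes_x = 120L, n_probes_y = 30L,
                                        n_expression_probes = 80L,
                                        n_snps_x = 400L, seed = seed))
    x_probes <- co$manifest$probe_id[co$manifest$chromosome == "X"]
    score <- colMeans(co$betas[x_probes, , drop = FALSE])
    km <- kmeans(score, centers = matrix(range(score), ncol = 1))
    lab <- c("low", "high")[order(km$centers)][km$cluster]
    truth <- co$metadata$karyotype[match(names(score), co$metadata$sample_id)]
    # two X copies (46,XX and the 47,XXY index) give the high-beta cluster
    expect_identical(lab == "high", truth %in% c("46,XX", "47,XXY"))
  }
})

test_that("a cohort round-trips through write_cohort/read_cohort", {
  co <- simulate_cohort(small_cfg(seed = 3))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  # per-tissue matrix files exist for every channel
  for (t in co$config$tissues) {
    expect_true(file.exists(file.path(dir, sprintf("betas_%s.tsv", t))))
    expect_true(file.exists(file.path(dir, sprintf("expression_%s.tsv", t))))
  }
  back <- read_cohort(dir)
  expect_equal(back, co, tolerance = 1e-9)
})
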