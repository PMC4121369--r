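make_manifest <- function(n, chromosome = "1") {
  data.frame(probe_id = sprintf("p%03d", seq_len(n)), chromosome = chromosome,
             position = seq_len(n) * 1000L, strand = "+", context = "CG",
             nearest_snp_distance = 1000L, nearest_snp_maf = 0.0,
             cross_reactive = FALSE, stringsAsFactors = FALSE)
}

make_mat <- function(n, m, fill = 0.5) {
  matrix(fill, n, m, dimnames = list(sprintf("p%03d", seq_len(n)),
                                     sprintf("s%02d", seq_len(m))))
}

test_that("methylation probe filters apply the documented rules in order", {
  mf <- make_manifest(10)
  # rule 1: SNP within 10 bp at MAF > 5%
  mf$nearest_snp_maf[1] <- 0.10; mf$nearest_snp_distance[1] <- 5L
  # same MAF but outside the window: retained
  mf$nearest_snp_maf[2] <- 0.10; mf$nearest_snp_distance[2] <- 50L
  mf$context[3] <- "CH"
  # probe failing rules 1 and 2 attributed to rule 1 (first-rule-wins)
  mf$nearest_snp_maf[4] <- 0.30; mf$nearest_snp_distance[4] <- 0L
  mf$context[4] <- "CH"
  betas <- make_mat(10, 6)
  res <- filter_methylation_probes(mf, betas, blacklist = "p005")
  expect_equal(res$report$n_removed, c(2L, 1L, 1L, 0L))
  expect_setequal(res$removed, c("p001", "p003", "p004", "p005"))
  expect_true("p002" %in% res$surviving)
  expect_identical(res$betas, betas[res$surviving, ])
})

test_that("pfilter rule catches beadcount and detection failures; counts match a longhand oracle", {
  n <- 100; m <- 40
  mf <- make_manifest(n)
  betas <- make_mat(n, m)
  bead <- make_mat(n, m, fill = 10)
  detp <- make_mat(n, m, fill = 0.001)
  # 4 probes with low beads in 3/40 samples (7.5% > 5%), 3 probes with
  # high detection p in 1/40 samples (2.5% > 1%)
  bead[1:4, 1:3] <- 2
  detp[5:7, 1] <- 0.2
  # borderline cases that must NOT fail: low beads in exactly 2/40 = 5%,
  # bad detection in 0 samples
  bead[8, 1:2] <- 1
  res <- filter_methylation_probes(mf, betas, bead, detp)
  # longhand recomputation of rule 4
  fail4 <- rowSums(bead < 3) / m > 0.05 | rowSums(detp > 0.05) / m > 0.01
  expect_equal(sum(fail4), 7L)
  expect_equal(res$report$n_removed[res$report$rule == "pfilter"], 7L)
  expect_equal(length(res$surviving), 93L)
  expect_setequal(res$removed, rownames(bead)[fail4])
})

test_that("probe filters are idempotent and never alter retained values", {
  co <- simulate_cohort(small_cfg(seed = 6))
  bl <- co$manifest$probe_id[co$manifest$cross_reactive]
  r1 <- filter_methylation_probes(co$manifest, co$betas, co$beadcount,
                                  co$detection_p, blacklist = bl)
  mf2 <- co$manifest[co$manifest$probe_id %in% r1$surviving, ]
  r2 <- filter_methylation_probes(mf2, r1$betas,
                                  co$beadcount[r1$surviving, ],
                                  co$detection_p[r1$surviving, ],
                                  blacklist = bl)
  expect_identical(r2$surviving, r1$surviving)
  expect_equal(sum(r2$report$n_removed), 0L)
  expect_identical(r1$betas, co$betas[r1$surviving, ])
  # per-rule removals sum to the total removed
  expect_equal(sum(r1$report$n_removed), length(r1$removed))
  expect_equal(length(r1$surviving) + length(r1$removed), nrow(co$manifest))
})

test_that("index mismatches are reported with the offending axis", {
  mf <- make_manifest(5)
  betas <- make_mat(5, 4)
  bead <- make_mat(4, 4)
  expect_error(filter_methylation_probes(mf, betas, bead), "probe index")
  bead2 <- make_mat(5, 4)
  colnames(bead2) <- paste0("x", 1:4)
  expect_error(filter_methylation_probes(mf, betas, bead2), "sample index")
})

test_that("expression probes are removed only when undetected in every sample", {
  n <- 200; m <- 40
  x <- make_mat(n, m, fill = 8)
  detp <- make_mat(n, m, fill = 0.5)   # everything undetected by default
  detp[1:188, 1] <- 0.001              # detected in a single sample: retained
  res <- filter_expression_probes(x, detp)
  expect_equal(length(res$surviving), 188L)
  expect_equal(res$report$n_removed, 12L)
  expect_true(all(sprintf("p%03d", 189:200) %in% res$removed))
})

test_that("identity check separates same-individual pairs from unrelated ones", {
  # identical columns: r = 1
  m <- matrix(rep(c(0, 0.5, 1), length.out = 50), 50, 2,
              dimnames = list(sprintf("rs%02d", 1:50), c("a", "b")))
  res <- sample_identity_check(m, data.frame(a = "a", b = "b"))
  expect_equal(res$r, 1)
  expect_true(res$same_individual)
  # unrelated trimodal columns decorrelate: |r| < 0.5 in > 99% of draws
  withr::with_seed(42, {
    rs <- replicate(1000, {
      g <- matrix(sample(c(0, 0.5, 1), 100, replace = TRUE), 50, 2)
      cor(g[, 1], g[, 2])
    })
    expect_gt(mean(abs(rs) < 0.5), 0.99)
  })
  # the generator's two tissues of one individual match
  co <- simulate_cohort(small_cfg(seed = 8))
  md <- co$metadata
  ind <- unique(md$individual_id)[2]
  s <- md$sample_id[md$individual_id == ind]
  res <- sample_identity_check(co$snp_probe_betas, data.frame(s[1], s[2]))
  expect_true(res$same_individual)
  # cross-individual pair does not
  other <- md$sample_id[md$individual_id == unique(md$individual_id)[3]][1]
  res2 <- sample_identity_check(co$snp_probe_betas, data.frame(s[1], other))
  expect_false(res2$same_individual)
  expect_error(sample_identity_check(co$snp_probe_betas,
                                     data.frame("nope", s[1])), "unknown sample")
})
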