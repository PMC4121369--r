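test_that("reference statistics match closed forms and a longhand oracle", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  colnames(m) <- c("s1", "s2", "s3")
  rs <- reference_statistics(m, c("s1", "s2", "s3"))
  expect_equal(rs$mean_ref, c(2, 5))
  expect_equal(rs$sd_ref, c(1, 0))
  withr::with_seed(14, {
    mat <- matrix(rnorm(300), 30, 10,
                  dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:10)))
    grp <- sprintf("s%02d", 2:10)
    rs <- reference_statistics(mat, grp)
    oracle <- longhand_ref_stats(mat, grp)
    expect_equal(rs$mean_ref, unname(oracle[, "mean"]))
    expect_equal(rs$sd_ref, unname(oracle[, "sd"]))
  })
  expect_error(reference_statistics(m, c("s1", "s2")), "at least 3")
})

test_that("the singleton z-test reproduces worked values", {
  ref <- data.frame(feature_id = "cer_mass", n_ref = 48, mean_ref = 170, sd_ref = 24)
  r <- singleton_z_test(111, ref)
  expect_equal(r$z, -59 / 24)
  expect_equal(r$z, -2.458, tolerance = 1e-3)
  expect_equal(r$effect, -59)
  # index at the reference mean: z = 0, p = 1
  r0 <- singleton_z_test(170, ref)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  # z = 1.96 is the two-sided 5% point
  r196 <- singleton_z_test(170 + 1.96 * 24, ref)
  expect_equal(r196$p, 0.05, tolerance = 1e-3)
  # sd 0 flags untestable
  refc <- data.frame(feature_id = "const", n_ref = 10, mean_ref = 1, sd_ref = 0)
  expect_true(singleton_z_test(2, refc)$untestable)
  expect_true(is.na(singleton_z_test(2, refc)$z))
})

test_that("z is shift-invariant and scale costs the effect only", {
  withr::with_seed(3, {
    mat <- matrix(rnorm(200, 5, 2), 20, 10,
                  dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:10)))
    sex <- setNames(rep(c("male", "female"), 5)[-1], colnames(mat)[-1])
    base <- run_singleton_screen(mat, "s01", sex)
    shifted <- run_singleton_screen(mat + 7, "s01", sex)
    expect_equal(shifted$z, base$z)
    expect_equal(shifted$effect, base$effect)
    scaled <- run_singleton_screen(mat * 3, "s01", sex)
    expect_equal(scaled$z, base$z)
    expect_equal(scaled$effect, base$effect * 3)
  })
})

test_that("the screen honors the chromosome comparison policy", {
  withr::with_seed(8, {
    mat <- matrix(rnorm(240, 8, 1), 24, 10,
                  dimnames = list(sprintf("f%02d", 1:24), sprintf("s%02d", 1:10)))
    chrom <- setNames(rep(c("1", "X", "Y"), each = 8), rownames(mat))
    sex <- setNames(rep(c("male", "female"), length.out = 9), colnames(mat)[-10])
    res <- run_singleton_screen(mat, "s10", sex, chrom)
    xres <- res[res$feature_id %in% rownames(mat)[9:16], ]
    expect_setequal(unique(xres$comparison), "females")
    yres <- res[res$feature_id %in% rownames(mat)[17:24], ]
    expect_setequal(unique(yres$comparison), "males")
    ares <- res[res$feature_id %in% rownames(mat)[1:8], ]
    expect_setequal(unique(ares$comparison), c("all", "males", "females"))
    # Bonferroni multiplicity is family-specific and counts testable features
    m <- attr(res, "m")
    expect_equal(unname(m["all"]), 8L)
    expect_equal(unname(m["males"]), 16L)
    expect_equal(unname(m["females"]), 16L)
    expect_equal(res$p_adj, pmin(1, res$p * unname(m[res$comparison])))
  })
})

test_that("a strongly spiked feature is significant in every family", {
  withr::with_seed(5, {
    mat <- matrix(rnorm(30 * 100, 0.5, 0.03), 100, 30,
                  dimnames = list(sprintf("f%03d", 1:100), sprintf("s%02d", 1:30)))
    mat["f001", "s01"] <- mat["f001", "s01"] + 0.5
    sex <- setNames(rep(c("male", "female"), length.out = 29), colnames(mat)[-1])
    res <- run_singleton_screen(mat, "s01", sex)
    hit <- res[res$feature_id == "f001", ]
    expect_true(all(hit$significant))
    # sign bookkeeping: up + down + zero = total significant
    sig <- res[res$significant, ]
    expect_equal(sum(sig$effect > 0) + sum(sig$effect < 0) + sum(sig$effect == 0),
                 nrow(sig))
  })
})

test_that("Bonferroni controls the family-wise error for the t tail, while the plain normal tail is anti-conservative at cohort sizes", {
  n_feat <- 2000L; n_ref <- 20L; n_rep <- 50L
  hits_t <- 0L; hits_norm <- 0L
  withr::with_seed(99, {
    for (r in seq_len(n_rep)) {
      mat <- matrix(rnorm(n_feat * (n_ref + 1)), n_feat, n_ref + 1,
                    dimnames = list(sprintf("f%04d", seq_len(n_feat)),
                                    sprintf("s%02d", seq_len(n_ref + 1))))
      sex <- setNames(rep(c("male", "female"), length.out = n_ref),
                      colnames(mat)[-1])
      rt <- run_singleton_screen(mat, "s01", sex, tail = "t")
      rn <- run_singleton_screen(mat, "s01", sex, tail = "normal")
      hits_t <- hits_t + any(rt$significant[rt$comparison == "all"])
      hits_norm <- hits_norm + any(rn$significant[rn$comparison == "all"])
    }
  })
  # t tail: observed FWER not significantly above the nominal 0.05
  expect_gt(binom.test(hits_t, n_rep, 0.05, alternative = "greater")$p.value, 0.05)
  # normal tail with estimated SD at n_ref = 20: grossly inflated
  expect_gt(hits_norm / n_rep, 0.2)
})

test_that("phenotype outlier calls match the printed brain-mass examples", {
  cer <- phenotype_outlier(111, ref_mean = 170, ref_sd = 24)
  expect_true(cer$outlier)
  expect_equal(cer$direction, "low")
  expect_gt(abs(cer$z), 2)
  tot <- phenotype_outlier(1417, ref_mean = 1410, ref_sd = 182)
  expect_false(tot$outlier)
  expect_equal(tot$direction, "none")
  expect_equal(phenotype_outlier(5, ref_values = c(4, 5, 6))$z, 0)
  expect_true(phenotype_outlier(5, ref_values = c(4, 4, 4))$untestable)
  expect_error(phenotype_outlier(5, ref_values = c(1, 2)), "at least 3")
})

test_that("gene-set bookkeeping flags directions, consistency and missingness", {
  res <- expand.grid(feature_id = c("gA", "gB", "gC"),
                     tissue = c("PFC", "CER"),
                     comparison = c("males", "females"),
                     stringsAsFactors = FALSE)
  res$effect <- ifelse(res$feature_id == "gA", 1, -1)
  res$z <- res$effect * 4
  res$significant <- res$feature_id != "gB"
  res$untestable <- FALSE
  # gC untestable in CER: marked missing there, not none
  res$untestable[res$feature_id == "gC" & res$tissue == "CER"] <- TRUE
  rep <- gene_set_outlier_report(res, list(escape = c("gA", "gB", "gC", "gD")))
  a <- rep[rep$feature_id == "gA", ]
  expect_setequal(a$direction, "up")
  expect_true(all(a$consistent))
  expect_setequal(rep$direction[rep$feature_id == "gB"], "none")
  cc <- rep[rep$feature_id == "gC", ]
  expect_setequal(cc$direction[cc$tissue == "CER"], "missing")
  expect_setequal(cc$direction[cc$tissue == "PFC"], "down")
  expect_true(all(cc$consistent))  # consistent over testable cells
  # absent feature is reported missing everywhere
  expect_setequal(rep$direction[rep$feature_id == "gD"], "missing")
  expect_false(any(rep$consistent[rep$feature_id == "gD"]))
  expect_error(gene_set_outlier_report(res, list(empty = character(0))), "empty")
})
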