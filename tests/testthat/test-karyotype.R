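test_that("X-methylation clustering labels two-X samples female-like", {
  co <- simulate_cohort(small_cfg(seed = 21))
  x_probes <- co$manifest$probe_id[co$manifest$chromosome == "X"]
  xb <- select_variable_probes(co$betas[x_probes, ], frac = 0.1)
  cl <- cluster_x_methylation(xb)
  truth <- co$metadata$karyotype[match(cl$sample_id, co$metadata$sample_id)]
  expect_identical(cl$x_meth_cluster == "female-like",
                   truth %in% c("46,XX", "47,XXY"))
  # degenerate input: all-identical betas are indeterminate
  flat <- matrix(0.5, 6, 5, dimnames = list(letters[1:6], LETTERS[1:5]))
  expect_true(all(is.na(cluster_x_methylation(flat)$x_meth_cluster)))
  expect_error(cluster_x_methylation(flat[1:3, ]), "5 X probes")
})

test_that("XIST classification splits a bimodal cohort cleanly", {
  x <- c(rnorm(8, 6.5, 0.3), rnorm(8, 10.5, 0.3))
  names(x) <- sprintf("s%02d", 1:16)
  cl <- classify_xist(x)
  expect_identical(cl$xist_class, rep(c("low", "high"), each = 8))
  expect_true(all(is.na(classify_xist(setNames(rep(1, 5), letters[1:5]))$xist_class)))
})

test_that("Y signal requires detection and male-range expression; boundary inclusive", {
  detp <- rbind(matrix(0.001, 2, 4), matrix(0.9, 2, 4))
  rownames(detp) <- sprintf("y%d", 1:4)
  colnames(detp) <- sprintf("s%d", 1:4)
  detp[, 3] <- c(0.001, 0.001, 0.9, 0.9)  # exactly half detected
  detp[, 4] <- 0.9                        # nothing detected
  yx <- matrix(c(9, 9, 9, 6), 3, 4, byrow = FALSE,
               dimnames = list(sprintf("g%d", 1:3), sprintf("s%d", 1:4)))
  yx[, 4] <- 6
  res <- assess_y_signal(detp, yx)
  expect_true(res$y_present[3])   # half detected counts as present
  expect_false(res$y_present[4])  # undetected and low expression
  expect_error(assess_y_signal(detp[1:2, ], yx), "3 Y probes")
})

test_that("heterozygosity is the het fraction of non-missing calls", {
  g <- matrix("AA", 100, 2, dimnames = list(sprintf("s%03d", 1:100), c("a", "b")))
  g[1:30, 2] <- "AB"
  g[31:35, 2] <- NA
  het <- x_heterozygosity(g)
  expect_equal(unname(het["a"]), 0)
  expect_equal(unname(het["b"]), 30 / 95)
  g[, 1] <- NA
  expect_error(x_heterozygosity(g), "missing")
})

test_that("band counting resolves diploid and trisomic BAF structures", {
  withr::with_seed(1, {
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    diploid <- clamp01(c(rnorm(400, 0, 0.01), rnorm(300, 0.5, 0.01),
                         rnorm(400, 1, 0.01)))
    expect_equal(count_baf_bands(diploid)$n_bands, 3L)
    trisomic <- clamp01(c(rnorm(300, 0, 0.01), rnorm(250, 1 / 3, 0.01),
                          rnorm(250, 2 / 3, 0.01), rnorm(300, 1, 0.01)))
    b <- count_baf_bands(trisomic)
    expect_equal(b$n_bands, 4L)
    expect_equal(sort(b$centers), c(0.01, 0.33, 0.67, 0.99), tolerance = 0.05)
    expect_equal(count_baf_bands(rep(0, 300))$n_bands, 1L)
    expect_error(count_baf_bands(runif(100)), "200 BAF values")
  })
})

test_that("band counting matches the configured mode count for noise sd <= 0.03", {
  modes <- list(`1` = 0.5, `2` = c(0, 1), `3` = c(0, 0.5, 1),
                `4` = c(0, 1 / 3, 2 / 3, 1))
  for (seed in 1:5) {
    withr::with_seed(seed, {
      for (sdv in c(0.01, 0.02, 0.03)) {
        for (k in names(modes)) {
          mu <- sample(rep(modes[[k]], length.out = 20000))
          baf <- pmin(pmax(rnorm(20000, mu, sdv), 0), 1)
          expect_equal(count_baf_bands(baf)$n_bands, as.integer(k),
                       info = sprintf("seed %d sd %.2f modes %s", seed, sdv, k))
        }
      }
    })
  }
})

test_that("the karyotype decision table covers its documented cases", {
  ev <- function(...) list(...)
  # the index case's evidence pattern: female-like X, XIST high, Y, het 0.25
  r <- call_karyotype(ev(x_meth_cluster = "female-like", y_present = TRUE,
                         x_het_rate = 0.25, xist_class = "high"),
                      reported_sex = "male")
  expect_equal(r$call, "47,XXY")
  expect_false(r$discordant_with_reported_sex)  # XXY is reported male
  # genotype channel present but unsupportive: indeterminate, not XXY
  r <- call_karyotype(ev(x_meth_cluster = "female-like", y_present = TRUE,
                         x_het_rate = 0.0, baf_band_count = 3L))
  expect_equal(r$call, "indeterminate")
  # 4 BAF bands alone support the call
  r <- call_karyotype(ev(x_meth_cluster = "female-like", y_present = TRUE,
                         baf_band_count = 4L))
  expect_equal(r$call, "47,XXY")
  # no genotype channel at all: methylation + Y suffice
  r <- call_karyotype(ev(x_meth_cluster = "female-like", y_present = TRUE))
  expect_equal(r$call, "47,XXY")
  r <- call_karyotype(ev(x_meth_cluster = "male-like", y_present = TRUE),
                      reported_sex = "male")
  expect_equal(r$call, "46,XY")
  expect_false(r$discordant_with_reported_sex)
  r <- call_karyotype(ev(x_meth_cluster = "female-like", y_present = FALSE),
                      reported_sex = "male")
  expect_equal(r$call, "46,XX")
  expect_true(r$discordant_with_reported_sex)
  r <- call_karyotype(ev(x_meth_cluster = "male-like", y_present = FALSE))
  expect_equal(r$call, "indeterminate")
  # purity: identical evidence gives identical calls
  e <- ev(x_meth_cluster = "female-like", y_present = TRUE, x_het_rate = 0.3)
  expect_identical(call_karyotype(e, "male"), call_karyotype(e, "male"))
})

test_that("cohort-level inference recovers every karyotype on a clean cohort", {
  co <- simulate_cohort(small_cfg(seed = 30))
  k <- infer_karyotypes(co)
  truth <- co$metadata$karyotype[match(k$individual_id, co$metadata$individual_id)]
  expect_identical(k$call, truth)
  expect_equal(k$baf_band_count[k$individual_id == co$index_individual], 4L)
  expect_true(all(k$baf_band_count[truth == "46,XY"] == 3L))
  expect_true(all(k$baf_band_count[truth == "46,XX"] == 3L))
})
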