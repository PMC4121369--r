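# shared fixtures and independent oracles, built in code at test time

small_cfg <- function(seed = 1, ...) {
  defaults <- list(n_individuals = 16L, n_probes_autosomal = 300L,
                   n_probes_x = 120L, n_probes_y = 40L,
                   n_expression_probes = 150L, n_snps_x = 800L,
                   seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...), keep.null = TRUE))
}

# brute-force region oracle, independent of call_dmrs: enumerates every
# candidate probe window on one chromosome, keeps the valid ones
# (all members significant, every inter-member gap <= window on the tested
# grid, span <= window, >= min_probes members), groups probes into maximal
# significant-adjacency components, and within each component repeatedly
# takes the widest valid window starting at the leftmost unconsumed probe.
oracle_dmrs <- function(position, significant, window = 500, min_probes = 2) {
  o <- order(position)
  position <- position[o]; significant <- significant[o]
  n <- length(position)
  valid <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    mem <- i:j
    if (length(mem) < min_probes) next
    if (!all(significant[mem])) next
    if (position[j] - position[i] > window) next
    if (any(diff(position[mem]) > window)) next
    valid[i, j] <- TRUE
  }
  comp <- cumsum(c(TRUE, !(significant[-n] & significant[-1] &
                             diff(position) <= window)))
  out <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    i <- members[1]
    last <- members[length(members)]
    while (i <= last) {
      js <- which(valid[i, ])
      if (!length(js)) { i <- i + 1; next }
      j <- max(js)
      out[[length(out) + 1L]] <- list(start = position[i], end = position[j],
                                      n_probes = j - i + 1L)
      i <- j + 1L
    }
  }
  out
}

# random fixture for oracle-equivalence runs: sorted unique positions,
# random significance pattern
random_dmr_fixture <- function(n_probes, span = 5000) {
  pos <- sort(sample.int(span, n_probes))
  z <- rnorm(n_probes, 0, 2)
  sig <- runif(n_probes) < 0.45
  data.frame(feature_id = sprintf("p%03d", seq_len(n_probes)),
             comparison = "all", z = z, p = 2 * pnorm(-abs(z)),
             effect = z * 0.02, significant = sig, untestable = FALSE,
             position = pos, stringsAsFactors = FALSE)
}

fixture_manifest <- function(fix, chromosome = "1") {
  data.frame(probe_id = fix$feature_id, chromosome = chromosome,
             position = fix$position, stringsAsFactors = FALSE)
}

expect_same_regions <- function(dmrs, oracle) {
  got <- dmrs[order(dmrs$start), c("start", "end", "n_probes"), drop = FALSE]
  exp <- do.call(rbind, lapply(oracle, as.data.frame))
  if (is.null(exp)) {
    expect_equal(nrow(got), 0L)
  } else {
    exp <- exp[order(exp$start), , drop = FALSE]
    rownames(got) <- rownames(exp) <- NULL
    got$start <- as.numeric(got$start); got$end <- as.numeric(got$end)
    exp$start <- as.numeric(exp$start); exp$end <- as.numeric(exp$end)
    got$n_probes <- as.integer(got$n_probes); exp$n_probes <- as.integer(exp$n_probes)
    expect_equal(got, exp)
  }
}

# reference stats for a plain matrix, written out longhand as an
# independent check on reference_statistics
longhand_ref_stats <- function(mat, group) {
  t(vapply(seq_len(nrow(mat)), function(i) {
    v <- as.numeric(mat[i, group])
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    c(mean = m, sd = s)
  }, c(mean = 0, sd = 0)))
}
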