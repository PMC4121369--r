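#' Default spike table for the synthetic cohort
#'
#' Regions/genes at which the index individual is shifted relative to the
#' reference cohort. Methylation spikes are genomic regions (beta-scale
#' effects, probes are planted inside the region); expression spikes are
#' single probes (log2-scale effects). Defaults mirror the headline
#' effects observed in the 47,XXY brain case study: a strong
#' hypermethylated autosomal region (+0.50 beta), a consistent
#' cross-tissue region (+0.13), hypomethylated regions (-0.23, -0.19),
#' and up/down expression shifts including one strong downregulation
#' (-0.83 log2).
#'
#' @return data.frame with columns `type` (`methylation`/`expression`),
#'   `label`, `chromosome`, `start`, `end`, `effect`, `tissue`,
#'   `n_probes`.
#' @export
default_spike_table <- function() {
  rbind(
    data.frame(type = "methylation", label = "hyper_strong",
               chromosome = "5", start = 784832L, end = 784915L,
               effect = 0.50, tissue = "PFC", n_probes = 3L),
    data.frame(type = "methylation", label = "hyper_strong",
               chromosome = "5", start = 784832L, end = 784915L,
               effect = 0.43, tissue = "CER", n_probes = 3L),
    data.frame(type = "methylation", label = "SPAG1_like",
               chromosome = "8", start = 101224915L, end = 101225361L,
               effect = 0.13, tissue = "PFC", n_probes = 5L),
    data.frame(type = "methylation", label = "SPAG1_like",
               chromosome = "8", start = 101224915L, end = 101225361L,
               effect = 0.13, tissue = "CER", n_probes = 5L),
    data.frame(type = "methylation", label = "hypo_pfc",
               chromosome = "2", start = 4931004L, end = 4931074L,
               effect = -0.23, tissue = "PFC", n_probes = 2L),
    data.frame(type = "methylation", label = "hypo_cnv_region",
               chromosome = "17", start = 77680078L, end = 77680232L,
               effect = -0.19, tissue = "CER", n_probes = 2L),
    data.frame(type = "expression", label = "CAMP_like",
               chromosome = "3", start = 48266905L, end = 48266954L,
               effect = 0.20, tissue = "PFC", n_probes = 1L),
    data.frame(type = "expression", label = "CAMP_like",
               chromosome = "3", start = 48266905L, end = 48266954L,
               effect = 0.20, tissue = "CER", n_probes = 1L),
    data.frame(type = "expression", label = "EPCAM_like",
               chromosome = "2", start = 47612328L, end = 47612377L,
               effect = 0.69, tissue = "PFC", n_probes = 1L),
    data.frame(type = "expression", label = "GGA1_like",
               chromosome = "22", start = 38013841L, end = 38013890L,
               effect = -0.83, tissue = "PFC", n_probes = 1L),
    data.frame(type = "expression", label = "NACC1_like",
               chromosome = "19", start = 13251492L, end = 13251541L,
               effect = 0.49, tissue = "CER", n_probes = 1L)
  )
}

#' Default tissue-level repeat-assay parameters
#'
#' Cohort means and SDs of percent methylation for the LINE-1 and Alu
#' pyrosequencing assays in each tissue, plus the shift applied to the
#' index individual. Defaults are the printed cohort statistics of the
#' case study (PFC LINE-1 73.0 +/- 2.3 with index at 67.7, etc.).
#'
#' @return data.frame with `tissue`, `assay`, `ref_mean`, `ref_sd`,
#'   `index_shift` (percentage points).
#' @export
default_global_shifts <- function() {
  data.frame(
    tissue = c("PFC", "PFC", "CER", "CER"),
    assay = c("LINE1", "Alu", "LINE1", "Alu"),
    ref_mean = c(73.0, 28.1, 71.9, 24.8),
    ref_sd = c(2.3, 2.6, 2.1, 0.8),
    index_shift = c(-5.3, -2.6, 6.5, -0.1),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Validated parameter bundle for [simulate_cohort()]. Defaults encode
#' the study conditions of the motivating 47,XXY brain case: 49
#' individuals across two tissues with a single index case, array-like
#' beta noise (Beta precision 100, i.e. SD about 0.05 at beta 0.5),
#' log2-intensity expression noise of 0.12 (typical post-normalization
#' replicate noise for an expressed transcript), and B-allele-frequency noise
#' SD 0.015.
#'
#' @param n_individuals number of individuals (index included when an
#'   index karyotype is configured).
#' @param n_probes_autosomal,n_probes_x,n_probes_y,n_expression_probes,n_snps_x
#'   array sizes (background probes; spiked probes are added on top).
#' @param xtr_fraction fraction of X SNPs lying in the X/Y-homologous
#'   (XTR-like) region where male samples behave diploid due to
#'   cross-hybridization of the Y homolog.
#' @param tissues character vector of tissue labels.
#' @param index_karyotype one of `"47,XXY"`, `"46,XX"`, `"46,XY"`,
#'   `"none"` (no index case).
#' @param spikes spike table, see [default_spike_table()].
#' @param global_shift repeat-assay parameter table, see
#'   [default_global_shifts()].
#' @param meth_precision Beta-distribution precision for beta values
#'   (larger = less noise).
#' @param expression_sd log2-scale SD of expression noise.
#' @param baf_sd SD of Gaussian noise added to B-allele frequencies.
#' @param detection_failure_rate per-entry probability that a good probe
#'   still fails detection (detection p drawn above 0.05).
#' @param beadcount_lambda Poisson mean of per-entry bead counts.
#' @param xci_ratio_by_tissue named numeric vector of true corrected
#'   allele-1 XCI ratios for the index, one per tissue. Defaults give the
#'   case study's 7.5% (PFC) and 0.4% (CER) skewing.
#' @param seed integer seed; a fixed seed makes the cohort byte-identical.
#' @return object of class `sim_config`.
#' @export
cohort_config <- function(n_individuals = 49L,
                          n_probes_autosomal = 1200L,
                          n_probes_x = 300L,
                          n_probes_y = 60L,
                          n_expression_probes = 500L,
                          n_snps_x = 800L,
                          xtr_fraction = 0.3,
                          tissues = c("PFC", "CER"),
                          index_karyotype = c("47,XXY", "46,XX", "46,XY", "none"),
                          spikes = default_spike_table(),
                          global_shift = default_global_shifts(),
                          meth_precision = 100,
                          expression_sd = 0.12,
                          baf_sd = 0.015,
                          detection_failure_rate = 1e-4,
                          beadcount_lambda = 14,
                          xci_ratio_by_tissue = c(PFC = 0.575, CER = 0.504),
                          seed = 1L) {
  index_karyotype <- match.arg(index_karyotype)
  counts <- c(n_individuals = n_individuals,
              n_probes_autosomal = n_probes_autosomal,
              n_probes_x = n_probes_x, n_probes_y = n_probes_y,
              n_expression_probes = n_expression_probes,
              n_snps_x = n_snps_x)
  assert_that(all(counts > 0), "all counts must be positive")
  assert_that(length(tissues) >= 1 && !anyDuplicated(tissues),
              "tissues must be a non-empty set of unique labels")
  assert_that(meth_precision > 0 && expression_sd > 0 && baf_sd >= 0,
              "noise parameters must be positive")
  assert_that(xtr_fraction >= 0 && xtr_fraction < 1,
              "xtr_fraction must be in [0, 1)")
  if (!is.null(spikes) && nrow(spikes)) {
    need <- c("type", "chromosome", "start", "end", "effect", "tissue", "n_probes")
    assert_that(all(need %in% names(spikes)),
                paste("spike table needs columns:", paste(need, collapse = ", ")))
    spikes$chromosome <- norm_chrom(spikes$chromosome)
    assert_that(all(spikes$tissue %in% tissues),
                "spike tissue not in configured tissue list")
    meth <- spikes$type == "methylation"
    assert_that(all(abs(spikes$effect[meth]) <= 1),
                "methylation spike effects must be in [-1, 1]")
    if (index_karyotype == "none") {
      stop("spikes configured but no index case (index_karyotype = 'none')",
           call. = FALSE)
    }
    if (index_karyotype == "46,XX" && any(spikes$chromosome == "Y")) {
      stop("contradictory config: spike on chromosome Y for a 46,XX index",
           call. = FALSE)
    }
  }
  if (index_karyotype != "none") {
    missing_t <- setdiff(tissues, names(xci_ratio_by_tissue))
    assert_that(length(missing_t) == 0 || index_karyotype == "46,XY",
                paste("xci_ratio_by_tissue missing tissues:",
                      paste(missing_t, collapse = ", ")))
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_probes_autosomal = as.integer(n_probes_autosomal),
    n_probes_x = as.integer(n_probes_x),
    n_probes_y = as.integer(n_probes_y),
    n_expression_probes = as.integer(n_expression_probes),
    n_snps_x = as.integer(n_snps_x),
    xtr_fraction = as.numeric(xtr_fraction),
    tissues = as.character(tissues),
    index_karyotype = index_karyotype,
    spikes = spikes,
    global_shift = global_shift,
    meth_precision = as.numeric(meth_precision),
    expression_sd = as.numeric(expression_sd),
    baf_sd = as.numeric(baf_sd),
    detection_failure_rate = as.numeric(detection_failure_rate),
    beadcount_lambda = as.numeric(beadcount_lambda),
    xci_ratio_by_tissue = xci_ratio_by_tissue,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# draw beta values around target means with fixed precision
rbeta_mean <- function(n, mean, precision) {
  mean <- clamp(mean, 0.02, 0.98)
  rbeta(n, shape1 = mean * precision, shape2 = (1 - mean) * precision)
}

#' Simulate a complete multi-omic cohort
#'
#' Generates probe manifest, methylation betas (with beadcount and
#' detection-p side channels), expression log2 intensities (with
#' detection p), X-SNP genotypes and B-allele frequencies, index CNV
#' segments, repeat-assay CpG tables, XCI peak heights and sample
#' metadata, with the sex/karyotype structure the downstream analyses
#' assume: females draw intermediate betas at island-type X probes
#' (X inactivation), males low; XIST expression is bimodal by sex;
#' Y probes are detected only when a Y chromosome is present;
#' 46,XY individuals are hemizygous on X (het rate ~0) while 47,XXY
#' heterozygous BAFs sit at 1/3 and 2/3.
#'
#' @param config a [cohort_config()] object.
#' @return object of class `synthetic_cohort`.
#' @export
simulate_cohort <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_individuals
  has_index <- cfg$index_karyotype != "none"
  individual_id <- sprintf("ID%02d", seq_len(n))
  index_individual <- if (has_index) individual_id[1] else NA_character_

  # balanced sexes among the reference cohort; the index case is recorded
  # with the sex its karyotype would be reported as (47,XXY recorded male)
  ref_ids <- if (has_index) individual_id[-1] else individual_id
  sex_ref <- rep(c("male", "female"), length.out = length(ref_ids))
  karyotype <- setNames(ifelse(sex_ref == "male", "46,XY", "46,XX"), ref_ids)
  if (has_index) karyotype <- c(setNames(cfg$index_karyotype, index_individual), karyotype)
  karyotype <- karyotype[individual_id]
  reported_sex <- ifelse(karyotype == "46,XX", "female", "male")
  has_y <- karyotype %in% c("46,XY", "47,XXY")
  n_x_copies <- ifelse(karyotype == "46,XY", 1L, 2L)
  xist_on <- karyotype %in% c("46,XX", "47,XXY")  # >= 2 X => XCI => XIST

  samples <- expand.grid(individual_id = individual_id, tissue = cfg$tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[order(samples$tissue, samples$individual_id), ]
  samples$sample_id <- paste(samples$individual_id, samples$tissue, sep = "_")
  ns <- nrow(samples)
  s_ind <- match(samples$individual_id, individual_id)

  ## ---- methylation manifest -------------------------------------------
  spikes <- cfg$spikes
  meth_spikes <- if (!is.null(spikes)) spikes[spikes$type == "methylation", , drop = FALSE] else spikes
  spike_regions <- if (!is.null(meth_spikes) && nrow(meth_spikes)) {
    unique(meth_spikes[c("chromosome", "start", "end", "n_probes")])
  } else NULL

  mk_positions <- function(k) as.integer(round(runif(k, 1e5, 2.4e8)))
  auto <- data.frame(
    probe_id = sprintf("cg_auto_%05d", seq_len(cfg$n_probes_autosomal)),
    chromosome = as.character(sample(1:22, cfg$n_probes_autosomal, replace = TRUE)),
    position = mk_positions(cfg$n_probes_autosomal),
    stringsAsFactors = FALSE)
  xpr <- data.frame(
    probe_id = sprintf("cg_x_%05d", seq_len(cfg$n_probes_x)),
    chromosome = "X",
    position = mk_positions(cfg$n_probes_x) %/% 2L + 2700000L,
    stringsAsFactors = FALSE)
  ypr <- data.frame(
    probe_id = sprintf("cg_y_%05d", seq_len(cfg$n_probes_y)),
    chromosome = "Y",
    position = mk_positions(cfg$n_probes_y) %/% 5L + 2700000L,
    stringsAsFactors = FALSE)
  manifest <- rbind(auto, xpr, ypr)
  if (!is.null(spike_regions)) {
    sp <- do.call(rbind, lapply(seq_len(nrow(spike_regions)), function(i) {
      r <- spike_regions[i, ]
      k <- max(2L, as.integer(r$n_probes))
      data.frame(
        probe_id = sprintf("cg_spike_%s_%d_%02d", r$chromosome, r$start, seq_len(k)),
        chromosome = r$chromosome,
        position = as.integer(round(seq(r$start, r$end, length.out = k))),
        stringsAsFactors = FALSE)
    }))
    manifest <- rbind(manifest, sp)
  }
  rownames(manifest) <- NULL
  np <- nrow(manifest)
  manifest$strand <- sample(c("+", "-"), np, replace = TRUE)
  manifest$context <- "CG"
  # a sprinkling of non-CG probes and SNP-confounded probes to exercise QC
  is_bg <- !grepl("^cg_spike", manifest$probe_id)
  ch_idx <- which(is_bg)[seq_len(max(1L, round(0.01 * np)))]
  manifest$context[ch_idx] <- "CH"
  manifest$nearest_snp_distance <- as.integer(round(runif(np, 11, 10000)))
  manifest$nearest_snp_maf <- round(runif(np, 0, 0.5), 4)
  snp_idx <- sample(which(is_bg), max(1L, round(0.02 * np)))
  manifest$nearest_snp_distance[snp_idx] <- as.integer(sample(0:10, length(snp_idx), TRUE))
  manifest$nearest_snp_maf[snp_idx] <- round(runif(length(snp_idx), 0.051, 0.5), 4)
  manifest$cross_reactive <- FALSE
  xr_idx <- sample(which(is_bg), max(1L, round(0.01 * np)))
  manifest$cross_reactive[xr_idx] <- TRUE
  # X-probe strata: half island-type (sex-dimorphic), half escape-like
  manifest$x_stratum <- NA_character_
  xrows <- which(manifest$chromosome == "X")
  island <- sample(xrows, length(xrows) %/% 2)
  manifest$x_stratum[island] <- "island"
  manifest$x_stratum[setdiff(xrows, island)] <- "escape"

  ## ---- per-probe target means -----------------------------------------
  base_mean <- numeric(np)
  a_rows <- which(is_autosome(manifest$chromosome) & !grepl("^cg_spike", manifest$probe_id))
  cls <- sample(1:3, length(a_rows), replace = TRUE, prob = c(0.35, 0.25, 0.40))
  base_mean[a_rows] <- c(runif(sum(cls == 1), 0.05, 0.15),
                         runif(sum(cls == 2), 0.40, 0.60),
                         runif(sum(cls == 3), 0.75, 0.92))[order(order(cls))]
  sp_rows <- which(grepl("^cg_spike", manifest$probe_id))
  base_mean[sp_rows] <- runif(length(sp_rows), 0.30, 0.45)
  isl_rows <- which(manifest$x_stratum %in% "island")
  esc_rows <- which(manifest$x_stratum %in% "escape")
  male_x_mean <- runif(length(isl_rows), 0.08, 0.20)
  female_x_mean <- runif(length(isl_rows), 0.42, 0.58)
  base_mean[esc_rows] <- runif(length(esc_rows), 0.08, 0.25)
  y_rows <- which(manifest$chromosome == "Y")
  base_mean[y_rows] <- runif(length(y_rows), 0.30, 0.70)
  # small per-probe tissue offsets (brain regions differ modestly)
  tissue_delta <- matrix(rnorm(np * length(cfg$tissues), 0, 0.02), nrow = np,
                         dimnames = list(manifest$probe_id, cfg$tissues))

  ## ---- beta matrix -----------------------------------------------------
  betas <- matrix(NA_real_, np, ns, dimnames = list(manifest$probe_id, samples$sample_id))
  spike_effect <- matrix(0, np, ns)
  if (!is.null(meth_spikes) && nrow(meth_spikes) && has_index) {
    for (i in seq_len(nrow(meth_spikes))) {
      r <- meth_spikes[i, ]
      pr <- which(manifest$chromosome == r$chromosome &
                    manifest$position >= r$start & manifest$position <= r$end)
      sc <- which(samples$individual_id == index_individual & samples$tissue == r$tissue)
      spike_effect[pr, sc] <- spike_effect[pr, sc] + r$effect
    }
  }
  for (j in seq_len(ns)) {
    ind <- s_ind[j]
    mu <- base_mean
    mu[isl_rows] <- if (n_x_copies[ind] == 2) female_x_mean else male_x_mean
    mu <- mu + tissue_delta[, samples$tissue[j]] + spike_effect[, j]
    betas[, j] <- rbeta_mean(np, mu, cfg$meth_precision)
  }

  ## ---- side channels ---------------------------------------------------
  beadcount <- matrix(rpois(np * ns, cfg$beadcount_lambda) + 1L, np, ns,
                      dimnames = dimnames(betas))
  low_bead <- sample(which(is_bg), max(1L, round(0.005 * np)))
  beadcount[low_bead, ] <- rpois(length(low_bead) * ns, 1.5)
  detection_p <- matrix(runif(np * ns, 0, 0.01), np, ns, dimnames = dimnames(betas))
  fail <- runif(np * ns) < cfg$detection_failure_rate
  detection_p[fail] <- runif(sum(fail), 0.051, 1)
  bad_probes <- sample(which(is_bg), max(1L, round(0.005 * np)))
  for (p in bad_probes) {
    cols <- runif(ns) < 0.3
    detection_p[p, cols] <- runif(sum(cols), 0.051, 1)
  }
  # Y probes fail detection in samples without a Y chromosome
  no_y_cols <- which(!has_y[s_ind])
  if (length(y_rows) && length(no_y_cols)) {
    detection_p[y_rows, no_y_cols] <- runif(length(y_rows) * length(no_y_cols), 0.1, 1)
    betas[y_rows, no_y_cols] <- runif(length(y_rows) * length(no_y_cols), 0.2, 0.8)
  }

  ## ---- expression ------------------------------------------------------
  expr_spikes <- if (!is.null(spikes)) spikes[spikes$type == "expression", , drop = FALSE] else spikes
  special <- data.frame(
    probe_id = c("expr_XIST", "expr_RPS4Y1", "expr_KDM5D", "expr_UTY",
                 "expr_SLC25A6", "expr_DHRSX", "expr_GTPBP6",
                 "expr_EIF1AX", "expr_KDM6A", "expr_ZFX"),
    gene = c("XIST", "RPS4Y1", "KDM5D", "UTY",
             "SLC25A6", "DHRSX", "GTPBP6", "EIF1AX", "KDM6A", "ZFX"),
    chromosome = c("X", "Y", "Y", "Y", "X", "X", "X", "X", "X", "X"),
    position = c(73040486L, 2841602L, 21867301L, 13248379L,
                 1386152L, 2268800L, 299505L, 20124518L, 44873182L, 24167761L),
    class = c("xist", "y", "y", "y", "par1", "par1", "par1",
              "escape", "escape", "escape"),
    stringsAsFactors = FALSE)
  n_bg <- cfg$n_expression_probes
  bg <- data.frame(
    probe_id = sprintf("expr_auto_%05d", seq_len(n_bg)),
    gene = sprintf("GENE%05d", seq_len(n_bg)),
    chromosome = as.character(sample(1:22, n_bg, replace = TRUE)),
    position = mk_positions(n_bg),
    class = "autosomal",
    stringsAsFactors = FALSE)
  spx <- NULL
  if (!is.null(expr_spikes) && nrow(expr_spikes)) {
    ug <- unique(expr_spikes[c("label", "chromosome", "start", "end")])
    spx <- data.frame(
      probe_id = sprintf("expr_spike_%s", ug$label),
      gene = toupper(ug$label),
      chromosome = ug$chromosome,
      position = as.integer(ug$start),
      class = "spiked",
      stringsAsFactors = FALSE)
  }
  expr_manifest <- rbind(special, bg, spx)
  rownames(expr_manifest) <- NULL
  ne <- nrow(expr_manifest)
  expr_base <- runif(ne, 6.5, 12)
  names(expr_base) <- expr_manifest$probe_id
  expr_base["expr_XIST"] <- 6.5
  expr_base[special$probe_id[special$class == "y"]] <- 9
  expression <- matrix(NA_real_, ne, ns,
                       dimnames = list(expr_manifest$probe_id, samples$sample_id))
  # fixed per-gene index offsets for escape/PAR genes (variable behavior:
  # some up, some down in the index, tissue-heterogeneous for SLC25A6)
  par_escape_offset <- c(expr_SLC25A6 = 0.6, expr_DHRSX = 0.5, expr_GTPBP6 = -0.6,
                         expr_EIF1AX = 0.7, expr_KDM6A = 0.45, expr_ZFX = -0.4)
  for (j in seq_len(ns)) {
    ind <- s_ind[j]
    mu <- expr_base
    if (xist_on[ind]) mu["expr_XIST"] <- mu["expr_XIST"] + 4
    if (!has_y[ind]) mu[special$probe_id[special$class == "y"]] <- 6
    fem_like <- n_x_copies[ind] == 2 && karyotype[ind] != "47,XXY"
    if (fem_like) mu[names(par_escape_offset)] <- mu[names(par_escape_offset)] +
        ifelse(karyotype[ind] == "46,XX", 0.15, 0)
    if (has_index && individual_id[ind] == index_individual &&
        karyotype[ind] == "47,XXY") {
      off <- par_escape_offset
      off["expr_SLC25A6"] <- if (samples$tissue[j] == "CER") 0.6 else 0.05
      mu[names(off)] <- mu[names(off)] + off
    }
    expression[, j] <- rnorm(ne, mu, cfg$expression_sd)
  }
  if (!is.null(expr_spikes) && nrow(expr_spikes) && has_index) {
    for (i in seq_len(nrow(expr_spikes))) {
      r <- expr_spikes[i, ]
      pid <- sprintf("expr_spike_%s", r$label)
      sc <- which(samples$individual_id == index_individual & samples$tissue == r$tissue)
      expression[pid, sc] <- expression[pid, sc] + r$effect
    }
  }
  expr_detection_p <- matrix(runif(ne * ns, 0, 0.005), ne, ns,
                             dimnames = dimnames(expression))
  # Y transcripts undetected without a Y; a 2% background of dead probes
  yg <- special$probe_id[special$class == "y"]
  if (length(no_y_cols)) {
    expr_detection_p[yg, no_y_cols] <- runif(length(yg) * length(no_y_cols), 0.05, 1)
  }
  dead <- sample(bg$probe_id, max(1L, round(0.02 * n_bg)))
  expr_detection_p[dead, ] <- runif(length(dead) * ns, 0.02, 1)

  ## ---- SNP-type probes on the methylation array (identity check) ------
  n_rs <- 60L
  rs_af <- runif(n_rs, 0.2, 0.8)
  rs_geno <- vapply(seq_len(n), function(i) rbinom(n_rs, 2L, rs_af),
                    integer(n_rs))  # copies of B allele per individual
  rs_target <- rs_geno / 2
  snp_probe_betas <- matrix(NA_real_, n_rs, ns,
                            dimnames = list(sprintf("rs_probe_%03d", seq_len(n_rs)),
                                            samples$sample_id))
  for (j in seq_len(ns)) {
    snp_probe_betas[, j] <- clamp(rs_target[, s_ind[j]] + rnorm(n_rs, 0, 0.04), 0, 1)
  }

  ## ---- X SNP genotypes and BAF ----------------------------------------
  n_snp <- cfg$n_snps_x
  n_xtr <- as.integer(round(cfg$xtr_fraction * n_snp))
  region <- c(rep("XTR", n_xtr), rep("X", n_snp - n_xtr))
  snp_info <- data.frame(
    snp_id = sprintf("snpX_%05d", seq_len(n_snp)),
    chromosome = "X",
    position = sort(mk_positions(n_snp) %/% 2L + 2700000L),
    region = sample(region),
    stringsAsFactors = FALSE)
  p_b <- runif(n_snp, 0.1, 0.9)
  geno <- matrix(NA_character_, n_snp, n,
                 dimnames = list(snp_info$snp_id, individual_id))
  baf <- matrix(NA_real_, n_snp, n, dimnames = dimnames(geno))
  is_xtr <- snp_info$region == "XTR"
  for (i in seq_len(n)) {
    # copies at each SNP: XTR-like SNPs read the Y homolog too
    cp <- rep(n_x_copies[i], n_snp)
    cp[is_xtr] <- cp[is_xtr] + as.integer(has_y[i])
    k_b <- rbinom(n_snp, cp, p_b)
    frac <- k_b / cp
    geno[, i] <- ifelse(k_b == 0L, "AA", ifelse(k_b == cp, "BB", "AB"))
    baf[, i] <- clamp(frac + rnorm(n_snp, 0, cfg$baf_sd), 0, 1)
  }
  miss <- runif(n_snp * n) < 0.002
  geno[miss] <- NA_character_
  baf[miss] <- NA_real_

  ## ---- CNV segments for the index -------------------------------------
  cnv <- NULL
  if (has_index) {
    cnv <- data.frame(
      chromosome = c("6", "17", "12"),
      start = c(124125000L, 77679000L, 8100000L),
      end = c(124850000L, 77692000L, 8180000L),
      copy_number = c(4L, 3L, 1L),
      stringsAsFactors = FALSE)
  }

  ## ---- repeat assays ---------------------------------------------------
  gs <- cfg$global_shift
  rep_rows <- list()
  for (g in seq_len(nrow(gs))) {
    if (!gs$tissue[g] %in% cfg$tissues) next
    mean_i <- rnorm(n, gs$ref_mean[g], gs$ref_sd[g])
    if (has_index) mean_i[1] <- gs$ref_mean[g] + gs$index_shift[g]
    cpg <- clamp(matrix(rnorm(3 * n, rep(mean_i, each = 3), 0.6), ncol = 3,
                        byrow = TRUE), 0, 100)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      individual_id = individual_id, tissue = gs$tissue[g], assay = gs$assay[g],
      role = "sample", cpg1 = round(cpg[, 1], 2), cpg2 = round(cpg[, 2], 2),
      cpg3 = round(cpg[, 3], 2), stringsAsFactors = FALSE)
    # assay controls: fully methylated / unmethylated DNA
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      individual_id = c("CTRL_METH", "CTRL_UNMETH"), tissue = gs$tissue[g],
      assay = gs$assay[g], role = c("methylated_control", "unmethylated_control"),
      cpg1 = c(round(runif(1, 94, 98), 2), round(runif(1, 1, 4), 2)),
      cpg2 = c(round(runif(1, 94, 98), 2), round(runif(1, 1, 4), 2)),
      cpg3 = c(round(runif(1, 94, 98), 2), round(runif(1, 1, 4), 2)),
      stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, rep_rows)
  rownames(repeats) <- NULL

  ## ---- XCI peak heights (index only; needs two X chromosomes) ---------
  xci <- NULL
  if (has_index && karyotype[index_individual] %in% c("47,XXY", "46,XX")) {
    xci_rows <- list()
    for (t in cfg$tissues) {
      r <- unname(cfg$xci_ratio_by_tissue[t])
      if (is.na(r)) next
      for (rep_i in 1:3) {
        h1u <- rnorm(1, 2000, 40); h2u <- rnorm(1, 1900, 40)
        digested <- 0.8
        xci_rows[[length(xci_rows) + 1L]] <- data.frame(
          individual_id = index_individual, tissue = t, replicate = rep_i,
          allele1 = 20L, allele2 = 23L,
          h1u = round(h1u, 1), h2u = round(h2u, 1),
          h1d = round(h1u * digested * r * exp(rnorm(1, 0, 0.01)), 1),
          h2d = round(h2u * digested * (1 - r) * exp(rnorm(1, 0, 0.01)), 1),
          h1m = round(h1u * runif(1, 0.005, 0.02), 1),
          h2m = round(h2u * runif(1, 0.005, 0.02), 1),
          stringsAsFactors = FALSE)
      }
    }
    xci <- do.call(rbind, xci_rows)
    rownames(xci) <- NULL
  }

  ## ---- phenotypes ------------------------------------------------------
  cer_mass <- ifelse(reported_sex == "male", rnorm(n, 175, 27), rnorm(n, 160, 15))
  tot_mass <- ifelse(reported_sex == "male", rnorm(n, 1454, 201), rnorm(n, 1325, 92))
  if (has_index && karyotype[index_individual] == "47,XXY") {
    cer_mass[1] <- 111
    tot_mass[1] <- 1417
  }
  metadata <- data.frame(
    sample_id = samples$sample_id,
    individual_id = samples$individual_id,
    tissue = samples$tissue,
    reported_sex = reported_sex[s_ind],
    karyotype = karyotype[s_ind],
    total_brain_mass = round(tot_mass[s_ind], 1),
    cerebellum_mass = round(cer_mass[s_ind], 1),
    stringsAsFactors = FALSE)

  gene_sets <- list(
    escape_xci = special$probe_id[special$class == "escape"],
    PAR1 = special$probe_id[special$class == "par1"],
    PAR2 = character(0))

  structure(list(
    config = cfg,
    manifest = manifest,
    betas = betas,
    beadcount = beadcount,
    detection_p = detection_p,
    expression = expression,
    expr_manifest = expr_manifest,
    expr_detection_p = expr_detection_p,
    snp_probe_betas = snp_probe_betas,
    snps = list(info = snp_info, genotype = geno, baf = baf),
    cnv = cnv,
    repeats = repeats,
    xci = xci,
    metadata = metadata,
    gene_sets = gene_sets,
    index_individual = index_individual
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d individuals x %d tissue(s), index = %s (%s)\n",
              x$config$n_individuals, length(x$config$tissues),
              x$index_individual %||% "none",
              x$config$index_karyotype))
  cat(sprintf("  methylation probes: %d; expression probes: %d; X SNPs: %d\n",
              nrow(x$manifest), nrow(x$expr_manifest), nrow(x$snps$info)))
  invisible(x)
}
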