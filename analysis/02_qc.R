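#!/usr/bin/env Rscript
# Stage 2 -- probe and sample quality control.
#
# Applies the methylation probe filters (SNP proximity, non-CG context,
# cross-reactive blacklist, beadcount/detection pfilter), the expression
# detection filter, and confirms that the two tissues of each individual
# are genotype-concordant via the array's SNP-type probes.

suppressPackageStartupMessages(library(nof1omics))

cohort <- read_cohort("results/cohort")
blacklist <- cohort$manifest$probe_id[cohort$manifest$cross_reactive]

meth <- filter_methylation_probes(cohort$manifest, cohort$betas,
                                  cohort$beadcount, cohort$detection_p,
                                  blacklist = blacklist)
cat("methylation probe filter report:\n")
print(meth$report)
cat(sprintf("surviving methylation probes: %d of %d\n",
            length(meth$surviving), nrow(cohort$manifest)))

expr <- filter_expression_probes(cohort$expression, cohort$expr_detection_p)
cat(sprintf("expression probes removed as non-detectable: %d of %d\n",
            expr$report$n_removed, nrow(cohort$expression)))

md <- cohort$metadata
inds <- unique(md$individual_id)
pairs <- do.call(rbind, lapply(inds, function(i) {
  s <- md$sample_id[md$individual_id == i]
  data.frame(a = s[1], b = s[2], stringsAsFactors = FALSE)
}))
idc <- sample_identity_check(cohort$snp_probe_betas, pairs)
cat(sprintf("cross-tissue identity: %d/%d pairs concordant (min r = %.3f)\n",
            sum(idc$same_individual), nrow(idc), min(idc$r)))

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write_tsv_table(meth$report, "results/qc/methylation_filter_report.tsv")
write_tsv_table(idc, "results/qc/sample_identity.tsv")
writeLines(meth$surviving, "results/qc/surviving_meth_probes.txt")
writeLines(expr$surviving, "results/qc/surviving_expr_probes.txt")
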