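#!/usr/bin/env Rscript
# Stage 4 -- singleton outlier screens.
#
# Tests the index sample per tissue against all references, male
# references and female references (X-linked features vs females only,
# Y-linked vs males only), Bonferroni-corrected within each family,
# for both the methylation and the expression matrix. Also assesses the
# scalar brain-mass phenotypes.

suppressPackageStartupMessages(library(nof1omics))

cohort <- read_cohort("results/cohort")
report <- run_pipeline(cohort, out_dir = "results/pipeline")
screens <- read_tsv_table("results/pipeline/singleton_screen.tsv")

sig <- screens[screens$significant, ]
for (t in cohort$config$tissues) for (a in c("methylation", "expression")) {
  sub <- sig[sig$tissue == t & sig$assay == a & sig$comparison == "all", ]
  cat(sprintf("%s %s vs all: %d up, %d down\n", t, a,
              sum(sub$effect > 0), sum(sub$effect < 0)))
}

ph <- report$phenotypes
cat(sprintf("cerebellum mass: z = %.2f (%s); total brain mass: z = %.2f (%s)\n",
            ph$cerebellum_mass$z,
            ifelse(ph$cerebellum_mass$outlier, "outlier", "within range"),
            ph$total_brain_mass$z,
            ifelse(ph$total_brain_mass$outlier, "outlier", "within range")))

if (!is.null(report$gene_sets)) {
  gs <- report$gene_sets
  cat("XCI-escape / PAR gene directions (expression):\n")
  print(gs[gs$direction %in% c("up", "down"), ])
  write_tsv_table(gs, "results/gene_set_report.tsv")
}
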