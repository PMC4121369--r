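#!/usr/bin/env Rscript
# Stage 5 -- differentially methylated regions and CNV overlap.
#
# Aggregates adjacent significant probes (gap and span <= 500 bp, >= 2
# probes) into regions with Stouffer-combined statistics, and screens
# them against the index case's copy-number segments.

suppressPackageStartupMessages(library(nof1omics))

cohort <- read_cohort("results/cohort")
screens <- read_tsv_table("results/pipeline/singleton_screen.tsv")
meth <- screens[screens$assay == "methylation", ]

dmrs <- call_dmrs(meth, cohort$manifest, window = 500L, min_probes = 2L)
dmrs <- overlap_cnv(dmrs, cohort$cnv)

cat(sprintf("regions called: %d (families: %s)\n", nrow(dmrs),
            paste(unique(dmrs$comparison), collapse = ", ")))
print(dmrs[, c("chromosome", "start", "end", "n_probes", "mean_effect",
               "combined_p", "comparison", "tissue", "cnv_copy_numbers")])
overlapped <- dmrs[dmrs$n_cnv_overlaps > 0, ]
cat(sprintf("%d region(s) overlap a copy-number segment\n", nrow(overlapped)))

write_tsv_table(dmrs, "results/dmrs.tsv")
write_dmr_bed(dmrs, "results/dmrs.bed")
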