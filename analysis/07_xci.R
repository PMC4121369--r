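#!/usr/bin/env Rscript
# Stage 7 -- X-chromosome inactivation skewing.
#
# Computes corrected allelic XCI ratios from the androgen-receptor
# (CAG)n peak-height tables (HpaII digests normalized by undigested
# peaks, MspI digestion controls, triplicates averaged).

suppressPackageStartupMessages(library(nof1omics))

cohort <- read_cohort("results/cohort")
res <- xci_from_peaks(cohort$xci)
print(res)
cat(sprintf("prefrontal cortex skewing: %.1f%%; cerebellum skewing: %.1f%%\n",
            res$skewing_percent[res$tissue == "PFC"],
            res$skewing_percent[res$tissue == "CER"]))
write_tsv_table(res, "results/xci_skewing.tsv")
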