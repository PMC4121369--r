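Transcribed summary statistics from the published 47,XXY brain case
study that this workflow re-implements: per-comparison fold changes
and p values of the differentially expressed genes in prefrontal
cortex (de_genes_pfc.tsv) and cerebellum (de_genes_cer.tsv), printed
cohort statistics for brain-mass phenotypes, repeat-element global
methylation and XCI skewing. Blank cells are non-significant or
not-compared entries (X-linked genes are compared with females only,
Y-linked genes with males only). P values printed as '<2.00E-16' keep
the '<' prefix.
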