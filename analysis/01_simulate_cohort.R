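#!/usr/bin/env Rscript
# Generate the synthetic study cohort and write it to results/cohort/.
#
# The cohort emulates the multi-assay structure of a pan-cancer enhancer
# connectome study: 60 tumor samples from 3 cancer types with H3K27ac peaks,
# enhancer-promoter loops, binned contact maps, CN segment profiles, RNA
# quantification, somatic variants with per-assay allele counts, cell-type
# pseudobulk accessibility, and focal amplifications carrying
# junction-spanning loops. Ground-truth labels for every planted effect are
# kept alongside so each downstream analysis can be scored.

suppressMessages(library(onco3d))

cfg <- cohort_config(seed = 20260924)
co <- simulate_cohort(cfg)
write_cohort(co, "results/cohort")

cat("cohort written to results/cohort/\n")
cat(sprintf("  %d samples (%d cancer types), %d genes, %d peaks, %d loops\n",
            nrow(co$samples), cfg$n_cancer_types, nrow(co$genes),
            nrow(co$peaks), nrow(co$loops)))
cat(sprintf("  %d variants (%.0f%% regulatory), %d amplicons\n",
            nrow(co$variants), 100 * mean(co$variants$regulatory),
            length(co$amplicons)))
cat("driver labels:\n")
print(table(co$truth$gene_driver))
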