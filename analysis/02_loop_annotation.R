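#!/usr/bin/env Rscript
# Annotate loops by regulatory element content (E-P, E-E, P-P, E-N, P-N) and
# tabulate the class composition, the per-cancer-type analogue of a stacked
# bar of loop classes.

suppressMessages(library(onco3d))

co <- cohort_from_manifest("results/cohort/manifest.json")
ann <- classify_loops(co$loops, co$genes, co$peaks[c("chrom", "start", "end")])

write.table(ann, "results/loops_annotated.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
counts <- as.data.frame(loop_class_counts(ann))
names(counts) <- c("class", "n_loops")
write.table(counts, "results/loop_class_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("loop class composition:\n")
print(loop_class_counts(ann))
cat(sprintf("%.1f%% of loops connect an enhancer to a promoter\n",
            100 * mean(as.character(ann$annotation) == "E-P")))
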