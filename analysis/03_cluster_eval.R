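#!/usr/bin/env Rscript
# Which scale of 3D genome organization separates cancer types? Cluster
# samples by (i) subcompartment rank vectors, (ii) CN-corrected 1D H3K27ac
# peak signal and (iii) CN-corrected 2D loop signal, and score each
# clustering against the cancer-type labels with purity and entropy.

suppressMessages(library(onco3d))

co <- cohort_from_manifest("results/cohort/manifest.json")
labs <- co$samples$cancer_type

peak_iv <- co$peaks[c("chrom", "start", "end")]
psig <- cn_correct(normalize_counts(co$peak_counts,
                                    size_factors(co$peak_counts)),
                   peak_iv, co$profiles, "peak")
lsig <- cn_correct(normalize_counts(co$loop_counts,
                                    size_factors(co$loop_counts + 1)),
                   co$loops, co$profiles, "loop")
loop_iv <- data.frame(chrom = co$loops$chrom, start = co$loops$start1,
                      end = co$loops$end2)

ce <- list(
  subcompartments = correlation_cluster(co$subcompartments + 0, NULL, labs,
                                        min_count = 0, min_samples = 0),
  peak_1d = correlation_cluster(psig, peak_iv, labs),
  loop_2d = correlation_cluster(lsig, loop_iv, labs))

tab <- data.frame(feature = names(ce),
                  n_features = vapply(ce, `[[`, 0, "n_features"),
                  purity = vapply(ce, `[[`, 0, "purity"),
                  entropy = vapply(ce, `[[`, 0, "entropy"))
write.table(tab, "results/cluster_metrics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, row.names = FALSE)
cat("higher purity / lower entropy = cleaner cancer-type separation;\n",
    "2D loop signal should lead on this cohort, where type identity is\n",
    "planted mostly in loop usage.\n")
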