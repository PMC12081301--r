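# onco3d

Integrative analysis of tumor enhancer connectomes with copy number.

Chromosome conformation assays targeted to H3K27ac (HiChIP) measure, in one
experiment, the activity of enhancers and their physical contacts with gene
promoters. In tumors this signal is confounded by copy-number (CN)
alterations and mixed with non-malignant cells, and it is reshaped by
structural rearrangements. `onco3d` implements the downstream statistics for
such cohorts:

- **Loop annotation** — classify pre-called loops as E–P, E–E, P–P, E–N,
  P–N by anchor overlap with promoter windows (TSS ± 1 kb) and H3K27ac
  peaks; merge per-sample loop sets into union tables with per-sample signal
  matrices.
- **CN-aware normalization** — median-of-ratios size factors; ploidy as the
  length-weighted mean segment CN; division of 1D peak signal by relative CN
  (and of 2D loop signal by the product over both anchors) where relative
  CN > 1, with CN-0/no-call features set missing; hyper-segmentation QC at
  1,000 segments.
- **Contact-matrix tools** — symmetric (Knight–Ruiz-style) balancing,
  observed/expected transform, A/B compartment eigenvector with
  reference-track sign orientation, and virtual-4C / enhancer interaction
  signal (EIS) profiles.
- **Driver model** — per gene, ordinary least squares `RNA ~ H3K27ac + CN`
  (≤ 5 linked peaks used directly, otherwise 5 principal components), with
  each predictor's share of variance measured by the LMG decomposition
  (incremental R² averaged over all predictor orderings; importances sum to
  R²). The top term classifies the gene as enhancer-driven or copy-driven.
- **TME deconvolution** — label E–P loops as cell-type-specific, shared or
  ambiguous from per-cell-type pseudobulk scATAC peaks; Spearman correlation
  of loop EIS with cell fractions across samples.
- **Regulatory mutations** — allele-specific HiChIP-vs-WGS enrichment
  (Fisher + BH, depth > 30 in both assays), carrier-vs-noncarrier signal
  contrast in a 2-kb/20-bin window (Welch t), and motif gain in the 21-bp
  context with exact PWM score-distribution p-values.
- **SV rewiring** — neoloops (loops spanning an SV breakpoint) per Mb of
  focal amplification, class comparisons (cyclic/ecDNA, BFB, complex,
  linear) by exact rank-sum tests, co-amplification frequency at CN > 4.5.
- **Cluster evaluation** — pairwise-complete Pearson correlation,
  hierarchical clustering, purity/entropy against cancer-type labels.
- **Synthetic cohort** — a generator producing all of the above inputs with
  ground-truth labels (driver classes, loop cell types, regulatory variants,
  planted neoloops), so the whole pipeline is testable without
  controlled-access data.

## Worked example

The `analysis/` directory is a numbered workflow over the package functions.
`01_simulate_cohort.R` writes a synthetic 60-sample, 3-cancer-type cohort to
`results/cohort/`; the later scripts each run one analysis and print what
they found. For example:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/04_driver_model.R
```

prints

```
                 called
truth             copy-driven enhancer-driven unclassified
  copy-driven              20               0            0
  enhancer-driven           0              19            1
  null                      0               1           19
accuracy on planted drivers: 97.5% (n = 40)
null genes called at alpha 0.05: 5.0%
median full-model R^2: 0.81 over 60 genes
```

i.e. of the 40 genes whose expression was generated from enhancer activity
or from CN, 39 are assigned to the correct mechanism, and planted null genes
are called at roughly the nominal 5% rate. `03_cluster_eval.R` shows the
scale comparison (CN-corrected 2D loop signal separates the three cancer
types perfectly — purity 1.00, entropy 0.00 — while subcompartment vectors
reach purity 0.68), `06_regulatory_mutations.R` recovers 91.8% of planted
regulatory variants with zero false discoveries, and `07_sv_rewiring.R`
reports median neoloop rates per Mb of 5.9 (cyclic) vs 1.1 (linear) with
exact recovery of every planted junction-spanning loop.

A minimal interactive session:

```r
library(onco3d)
co  <- simulate_cohort(cohort_config(seed = 1))
ann <- classify_loops(co$loops, co$genes, co$peaks[c("chrom", "start", "end")])
loop_class_counts(ann)
res <- run_driver_model(co$genes, co$rna, co$tpm,
                        co$peaks[c("chrom", "start", "end")],
                        normalize_counts(co$peak_counts), co$loops,
                        co$profiles)
head(res[order(-res$r2), ])
```

## Vignette

`vignettes/methods.Rmd` documents the models and their assumptions, every
tunable threshold with its default and rationale, what the synthetic cohort
does and does not emulate, and the package's numerical choices.
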