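---
title: "Methods: copy-number-aware enhancer connectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number-aware enhancer connectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onco3d)
```

# Scope

`onco3d` implements the integrative statistics used to analyze H3K27ac
HiChIP enhancer connectomes of tumor cohorts jointly with whole-genome
copy-number (CN) profiles, RNA quantification, somatic variants and
single-cell ATAC pseudobulk accessibility. The package deliberately starts
*after* the heavy primary processing: loops arrive pre-called (FitHiChIP-style
tables), peaks pre-called, CN segments pre-segmented, variants pre-genotyped
with per-assay allele counts. What the package owns is the downstream
modeling: loop annotation, normalization and CN correction, contact-matrix
statistics, the expression variance partition, microenvironment
deconvolution, regulatory-mutation nomination, neoloop quantification and
clustering evaluation — plus a synthetic cohort generator that stands in for
controlled-access patient data.

All coordinates are 0-based half-open internally. Formats that are 1-based
inclusive on disk (SEG, gene tables) are converted exactly once at the IO
boundary; BED/BEDPE-style inputs pass through unchanged. Chromosome names
are matched as exact strings — no "chr" aliasing — so mixed-source inputs
fail loudly rather than silently mismatching.

# Loop annotation

Anchors are classified with promoter > enhancer > neither precedence: an
anchor overlapping any promoter window (TSS ± 1 kb, strand-aware, width
2·flank + 1 because inclusivity of the ± 1 kb is otherwise ambiguous) is a
promoter even if it also carries an H3K27ac peak; remaining anchors
overlapping a peak are enhancers. Loop classes are named from the unordered
anchor pair (E–P, E–E, P–P, E–N, P–N). N–N loops are retained with a warning:
peak-to-all loop calling should never produce them, so their presence flags
malformed inputs without aborting a run.

Union loop sets merge loops across samples transitively whenever both anchor
pairs lie within one bin (the merge radius of the upstream merge scripts is
not standardized; one calling bin matches 10-kb resolution). Transitive
merging makes the union independent of sample order and idempotent; union
anchors span their members and may exceed one bin, which the per-sample
signal summation handles by interval overlap.

# Normalization and CN correction

Library depth is equalized by median-of-ratios size factors (the reference is
the geometric mean over features positive in all samples). Note that this
estimator is equivariant to scaling a sample only *relative to the other
samples*: the reference absorbs a factor c^(1/n), so the normalized matrix is
defined up to one global constant. When no feature is positive everywhere the
function stops and suggests a pseudocount rather than silently switching
reference definitions.

CN correction operates on the ratio scale: a feature's relative CN is the
length-weighted mean of total CN over overlapping segments divided by the
sample's ploidy (itself the length-weighted mean CN across all segments, so
the genome-wide average relative CN is 1). Signal is divided by relative CN
only where it exceeds 1 — deletions are not "boosted" — and 2D loop signal is
divided by the product of the two anchors' clamped values. We apply the
clamp on both anchors for symmetry with the 1D rule; whether a
sub-diploid anchor should rescale a loop is genuinely open, and clamping is
the conservative choice. Features on CN-0 segments or without a CN call
become `NA`, and missingness propagates through every later stage rather
than masquerading as zero. Samples with more than 1,000 CN segments are
flagged hyper-segmented and should be excluded as noisy.

For the expression model a different, softer adjustment is used for the peak
predictors: `count / (2·relative_CN + 1)`. Unlike full division this keeps a
CN-proportional component bounded and never inflates signal at deletions
(the denominator is ≥ 1); we read the "ploidy-corrected CN" in this formula
as the relative (ratio-scale) CN, consistent with how gains and losses are
defined elsewhere on that scale.

# Contact-matrix statistics

Balancing finds a positive diagonal D with all unmasked row sums of D·M·D
equal to 1 (tolerance 1e-6, cap 3,000 iterations), using the symmetric
fixed-point iteration `x ← x / sqrt(x ∘ Mx)`; bins with zero marginal are
masked and reported. The observed/expected transform divides each diagonal
by its unmasked mean. The compartment eigenvector is the leading eigenvector
of the Pearson correlation matrix of O/E columns, computed at 500-kb
resolution by convention; its sign is arbitrary, so it is oriented against a
reference track (e.g. a DNA-methylation compartment eigenvector) with
positive = A/open. Orientation is deterministic given the reference.

Virtual 4C profiles — the operational definition of the enhancer interaction
signal (EIS) — are a single anchor bin's raw contact row divided by the total
number of valid pairs, then smoothed with a centered rolling mean. The
smoothing window is not standardized upstream; the default is 5 bins with
windows shrunk at the edges (so edge bins average over what exists), and the
window used is recorded in the returned object.

# Expression variance partition (enhancer- vs copy-driven genes)

Genes expressed above 10 TPM in more than 3 samples (both strict) enter the
model. A peak is linked to a gene when it lies within 1 Mb of the TSS *and*
overlaps the distal anchor of a loop whose other anchor overlaps the gene's
promoter window — proximity alone is not evidence of regulation. With more
than five linked peaks the log2, centered, scaled peak matrix is reduced to
five principal components; with five or fewer, the individual scaled peaks
are used. The response is log2(normalized count + 1) by default (the upstream
convention does not state the response scale; log stabilizes variance, and a
flag disables it). Per gene, complete cases only, minimum 10.

The ordinary least squares fit `RNA ~ H3K27ac + CN` is decomposed with the
LMG method: each predictor's importance is its incremental R² averaged over
all p! predictor orderings, computed exactly via the subset-sum formulation
with weights |S|!·(p−|S|−1)!/p!. Importances are unrelativized, so they sum
to the full-model R² (asserted to 1e-8 in the tests). The winning term is the
argmax importance; CN winning means copy-driven, any enhancer term winning
means enhancer-driven.

Significance of the winning term is the one genuinely open design point: the
winner is *selected* as the best of p terms, so its raw coefficient p-value
is anti-conservative (for six terms a pure-noise gene is "significant" at
0.05 roughly 26% of the time, incompatible with the intended ~5% null rate).
The default therefore Bonferroni-adjusts the winning-term p-value by the
number of candidate terms, which restores approximately nominal null
behavior at negligible cost in power for real effects; the raw rule remains
available (`significance = "winner-raw"`). Genes with response variance ≤ 1
are flagged and excluded from headline rankings but still classified. An
optional cancer-type covariate is handled by residualizing response and
predictors on it before fitting.

# Microenvironment deconvolution

E–P loops are intersected with per-cell-type pseudobulk scATAC peak sets
from the same sample. A loop is cell-type-specific when the promoter anchor
has H3K27ac and scATAC support and the enhancer anchor has H3K27ac support
and is accessible in exactly one cell type; shared when the enhancer is
accessible in several; ambiguous when neither anchor has any scATAC peak.
Accessibility is binary (a peak is called or not) — mirroring the
per-population peak-calling design — and evidence that fits none of the three
rules (e.g. scATAC at the promoter only) is labeled ambiguous with the
reason recorded rather than forced into a class. Samples with fewer than 110
noncancer cells are skipped entirely: pseudobulk peak calling in minor
populations below that is underpowered. Population-level support comes from
Spearman correlation (average ranks on ties) between a loop's EIS and a cell
fraction across samples, with pass cutoffs 0.30 (default) and 0.25 both
exposed since their mapping to specific analyses is not fixed.

# Noncoding regulatory mutations

Three lines of evidence are combined. (1) Allelic enrichment: variants with
read depth > 30 (strict) in both WGS and HiChIP are tested with a two-sided
Fisher exact test on [[wgs_ref, wgs_alt], [hichip_ref, hichip_alt]],
BH-adjusted; sidedness is not standardized upstream, so the test is
two-sided with a separate direction flag (HiChIP AF > WGS AF). (2) Local
signal contrast: the 2-kb window centered on the variant is tiled into 20 ×
100-bp bins; bin values are size-factor- and CN-corrected and carriers are
compared with non-carriers by a two-sided Welch t-test pooled over bins ×
samples. Pooling bins is a deliberate choice for the common single-carrier
case, where a per-sample-summary test has no degrees of freedom; the t score
is signed positive when carriers are higher. (3) Motif gain: the 21-bp
reference and alternate contexts (variant at position 11) are scanned on
both strands at every offset; a hit is a placement whose
log-likelihood-ratio score has p ≤ 0.01 under the exact score distribution
of the background model, computed by dynamic programming over motif
positions (verified against exhaustive 4^w enumeration to 1e-12). The
background defaults to uniform. A variant is nominated when it passes
coverage, fisher_q < 0.05, is HiChIP-enriched, and has a positive t score.

# Rearrangement-driven rewiring

A loop belongs to a focal amplification when both anchors overlap its
intervals, and is a neoloop when an SV breakpoint lies strictly between the
anchors (anchor1.end ≤ breakpoint < anchor2.start). This reference-space
rule is exact for intra-segment junctions; loop calling on rearranged
assemblies could additionally recover inter-chromosomal neoloops, which are
out of scope here and the rule is documented as that approximation. Rates
are neoloops per Mb of amplicon size. Class comparisons (cyclic/ecDNA, BFB,
complex, linear) use two-sided Wilcoxon rank-sum tests — exact by midrank
enumeration when both groups have ≤ 10 amplicons, tie-corrected normal
approximation otherwise — BH-adjusted across class pairs. Co-amplification
frequency is the fraction of samples with CN > 4.5 (the seed-amplicon
cutoff) at both of two intervals, excluding samples lacking a CN call at
either.

# Clustering evaluation

Sample similarity is pairwise Pearson correlation over mutually non-missing
entries of the log2(x + 1) matrix, after dropping chrX/chrY and blacklisted
features and keeping reproducible features (≥ 2 samples with normalized
count ≥ 3). Hierarchical clustering uses distance 1 − r with complete
linkage (the heatmap tool conventionally used defaults to complete; the
linkage is a flag), cut at k = number of cancer types. Quality against the
labels: purity = Σ_k max_j n_kj / n and entropy =
−Σ_kj n_kj log2(n_kj/n_k) / (n log2 C), so perfect clustering scores (1, 0)
and a single cluster over balanced binary classes scores (0.5, 1).

# The synthetic cohort

`simulate_cohort()` generates the full multi-assay bundle with ground truth;
its defaults define the study conditions used throughout the tests and the
acceptance script. One 20-Mb chromosome carries 63 genes in disjoint 300-kb
territories; each gene has 2–8 enhancer peaks placed 45–140 kb from the TSS
(inside the 40 kb–2 Mb loop calling span) with a planted promoter–enhancer
loop per peak. Per-sample CN profiles draw segment CN from
{0, 1, 2, 3, 4, 6, 8} (mostly diploid) on an 800-kb grid; ploidy and
relative CN derive from them. Expression on the log2 scale is 8 + 1.5·z for
enhancer-driven genes (z the shared enhancer activity factor also driving
peak signal), 8 + 2·relative-CN for copy-driven genes, and noise (sd 0.5)
for null genes. Count-like quantities use Poisson noise; peak signal uses
multiplicative log-normal noise — the minimal standard choices. Cell
fractions are Dirichlet(8, 2, 2, 1) over cancer/myeloid/T/B; enhancer
accessibility labels (shared / one cell type / none) generate the pseudobulk
peak sets and the loop-specificity truth. Contact maps follow
(1 + d)^(−1)·CN_i·CN_j with a 6-fold loop enrichment, one loop coupled to
the myeloid fraction for the EIS correlation analysis. Variants (1,000, 5%
regulatory) have WGS AF near 0.4, a +0.3 HiChIP AF shift and a 3× carrier
signal boost in the 2-kb window; coverages are 60–200×. Amplicons (three per
class) carry junction-spanning loops at class-specific rates (cyclic 6,
complex 3, BFB 2, linear 0.8 per Mb — encoding the observation that circular
amplicons rewire most) and are focally co-amplified in ~30% of samples.

All randomness flows from one seed through fixed per-stream sub-seeds, so
the same seed reproduces the same cohort bit for bit and streams can be
regenerated in isolation. What the generator does *not* emulate: read-level
noise, mappability and GC artifacts, subclonal CN, overlapping gene
territories, inter-chromosomal rearrangement, and correlated variant
positions. Passing tests therefore demonstrate correctness of the statistics
under the planted model, not robustness to every artifact of real data.

# Numerical choices and problem sizes

Balancing tolerance 1e-6 with a 3,000-iteration cap and failure (not a
silent partial result) on non-convergence; LMG enumerations capped at 8
predictors (the model never exceeds 6); DP score-distribution states merged
after rounding scores to 10 decimals; Fisher/Wilcoxon exactness delegated to
enumeration below the stated sizes. The test suite and the acceptance script
run the cohort at its default size (60 samples, 63 genes, 1,000 variants,
400-bin contact maps) and trimmed variants of it for per-module property
checks (24 samples, 120-bin maps); replicate counts for the power-style
checks (5–10) were chosen as the smallest giving stable Monte-Carlo
estimates at the planted effect sizes.

# Known limitations

The neoloop rule misses junctions between anchors on different chromosomes;
the deconvolution rules do not model partial accessibility or doublet
contamination; the LMG decomposition assumes the linear model is adequate
and exchanges exactness for an O(2^p) cost; CN correction assigns a single
length-weighted CN to features straddling segment boundaries; and the
significance rule for driver classification, while calibrated under the
null, inherits the usual caveats of post-selection inference.
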