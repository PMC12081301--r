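# Fully synthetic multi-assay cancer cohort with ground-truth labels.
#
# The generator emulates the statistical structure the downstream analyses
# assume: a cohort of tumor samples from several cancer types with H3K27ac
# peaks, enhancer-promoter loops, binned contact maps, CN segment profiles,
# expression, somatic variants with per-assay allele counts, per-cell-type
# pseudobulk accessibility and focal amplifications with junction-spanning
# loops. Expression of enhancer-driven genes follows planted enhancer
# activity, of copy-driven genes the gene's relative CN; regulatory variants
# carry an elevated HiChIP allele fraction and a local signal boost in the
# carrier. Count noise is Poisson; peak signal noise is multiplicative
# log-normal. All randomness flows from the single config seed.

#' Cohort configuration
#'
#' @param n_samples samples in the cohort (default 60).
#' @param n_cancer_types cancer types, assigned round-robin (default 3).
#' @param resolution loop/matrix bin width in bases (default 1e4).
#' @param n_bins chromosome length in bins (default 2000, i.e. 20 Mb).
#' @param n_genes_enh,n_genes_cn,n_genes_null planted gene counts per driver
#'   class (defaults 20/20/20).
#' @param n_genes_low additional low-expression genes that fail the TPM filter
#'   (default 3).
#' @param n_bg_peaks background H3K27ac peaks outside gene territories
#'   (default 40).
#' @param enh_per_gene range of linked enhancers per gene (default 2:8).
#' @param loop_distance allowed TSS-enhancer span in bases (default
#'   c(4e4, 2e6); the generator places enhancers 45-140 kb away).
#' @param decay_exponent contact distance-decay exponent (default 1).
#' @param library_size_range per-sample library scale factors (default
#'   c(0.5, 2)).
#' @param enh_effect,cn_effect,noise_sd expression model: log2-scale slope of
#'   the enhancer factor / relative CN and residual sd (defaults 1.5, 2, 0.5).
#' @param peak_factor_sd sd of the shared enhancer activity factor in log2
#'   peak signal (default 1).
#' @param loop_enrichment multiplicative contact enrichment at loop bin pairs
#'   (default 6).
#' @param contact_bins bins of the per-sample contact maps, covering the
#'   chromosome start (default 400); 0 disables map generation.
#' @param base_depth expected contact count at distance 0 (default 100).
#' @param n_variants,regulatory_fraction,af_shift,coverage_range,clonal_af
#'   somatic variant model (defaults 1000, 0.05, 0.3, c(60, 200), 0.4).
#' @param signal_boost carrier H3K27ac fold-boost at regulatory variants
#'   (default 3).
#' @param window_depth expected counts per 100-bp bin of the variant signal
#'   track (default 30).
#' @param celltypes pseudobulk cell types; the first is the malignant
#'   population (default cancer, myeloid, tcell, bcell).
#' @param celltype_alpha Dirichlet concentration of cell fractions (default
#'   c(8, 2, 2, 1)).
#' @param amplicons_per_class amplicons per class (default 3).
#' @param neoloop_rates planted junction-spanning loops per Mb by class
#'   (default cyclic 6, complex 3, BFB 2, linear 0.8).
#' @param seed master seed; every stream is derived from it (default 1).
#' @return validated list of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 60, n_cancer_types = 3,
                          resolution = 1e4, n_bins = 2000,
                          n_genes_enh = 20, n_genes_cn = 20,
                          n_genes_null = 20, n_genes_low = 3,
                          n_bg_peaks = 40, enh_per_gene = 2:8,
                          loop_distance = c(4e4, 2e6), decay_exponent = 1,
                          library_size_range = c(0.5, 2),
                          enh_effect = 1.5, cn_effect = 2, noise_sd = 0.5,
                          peak_factor_sd = 1, loop_enrichment = 6,
                          contact_bins = 400, base_depth = 100,
                          n_variants = 1000, regulatory_fraction = 0.05,
                          af_shift = 0.3, coverage_range = c(60, 200),
                          clonal_af = 0.4, signal_boost = 3,
                          window_depth = 30,
                          celltypes = c("cancer", "myeloid", "tcell", "bcell"),
                          celltype_alpha = c(8, 2, 2, 1),
                          amplicons_per_class = 3,
                          neoloop_rates = c(cyclic = 6, complex = 3,
                                            BFB = 2, linear = 0.8),
                          seed = 1) {
  cfg <- as.list(environment())
  n_genes <- n_genes_enh + n_genes_cn + n_genes_null + n_genes_low
  stopifnot(n_samples > 0, n_cancer_types > 0, resolution > 0, n_bins > 0,
            af_shift >= 0, af_shift < 1, all(unlist(cfg$neoloop_rates) >= 0))
  territory <- 3e5
  if (n_genes * territory > n_bins * resolution)
    stop("config infeasible: ", n_genes, " gene territories of ", territory,
         " bp do not fit in ", n_bins * resolution, " bp")
  if (loop_distance[1] < 0 || loop_distance[2] > n_bins * resolution)
    stop("config infeasible: loop distance range outside the chromosome span")
  cfg$n_genes <- n_genes
  cfg$territory <- territory
  structure(cfg, class = "CohortConfig")
}

# derived sub-seed; keeps every stream reproducible in isolation
sub_seed <- function(seed, k) (seed * 97 + k * 1009) %% 2147483647

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), alpha, 1)
  x / sum(x)
}

#' Simulate a binned contact map
#'
#' Expected count at bin pair (i, j): `base_depth * (1 + |i - j|)^-decay *
#' cn_i * cn_j`, multiplied by each planted loop's enrichment at its bin
#' pair, with independent Poisson noise; symmetrized.
#'
#' @param n_bins matrix dimension.
#' @param loops NULL or data.frame bin1/bin2 (1-based indices) and
#'   `enrichment`.
#' @param cnv_track per-bin relative CN (NULL = flat 1).
#' @param decay_exponent distance-decay exponent.
#' @param seed RNG seed.
#' @param base_depth expected diagonal count.
#' @param chrom,resolution matrix metadata.
#' @return raw [contact_matrix()].
#' @export
simulate_contact_map <- function(n_bins, loops = NULL, cnv_track = NULL,
                                 decay_exponent = 1, seed = 1,
                                 base_depth = 100, chrom = "chrS",
                                 resolution = 1e4) {
  mu <- contact_expected(n_bins, loops, cnv_track, decay_exponent, base_depth)
  set.seed(seed)
  up <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n_bins, n_bins)
  counts[up] <- rpois(sum(up), mu[up])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, chrom, resolution)
}

#' Expected (noise-free) contact map underlying [simulate_contact_map()]
#' @inheritParams simulate_contact_map
#' @return expected-count matrix.
#' @export
contact_expected <- function(n_bins, loops = NULL, cnv_track = NULL,
                             decay_exponent = 1, base_depth = 100) {
  if (is.null(cnv_track)) cnv_track <- rep(1, n_bins)
  stopifnot(length(cnv_track) == n_bins)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), `-`))
  mu <- base_depth * (1 + d)^(-decay_exponent) * outer(cnv_track, cnv_track)
  if (!is.null(loops) && nrow(loops)) {
    stopifnot(all(loops$bin1 >= 1), all(loops$bin2 <= n_bins))
    for (k in seq_len(nrow(loops))) {
      i <- loops$bin1[k]; j <- loops$bin2[k]
      mu[i, j] <- mu[i, j] * loops$enrichment[k]
      mu[j, i] <- mu[i, j]
    }
  }
  mu
}

#' Simulate somatic variants with per-assay allele counts
#'
#' WGS alt fractions follow the clonal allele fraction; a `regulatory_fraction`
#' of variants is flagged regulatory and draws its HiChIP alt fraction shifted
#' upward by `af_shift` (capped at 0.95); the rest use the WGS fraction in
#' both assays. Coverages are uniform in `coverage_range`. Variant positions
#' are spaced 2 kb apart on chromosome `chrom` so each variant owns one
#' 2-kb signal window.
#'
#' @param n_variants number of variants.
#' @param coverage_range inclusive depth range for both assays.
#' @param regulatory_fraction fraction of planted regulatory variants.
#' @param af_shift HiChIP allele-fraction increment for regulatory variants
#'   (in `[0, 1)`).
#' @param seed RNG seed.
#' @param clonal_af mean WGS alt fraction (default 0.4).
#' @param samples sample names carriers are drawn from.
#' @param chrom chromosome name (default "chrV").
#' @return data.frame: chrom, pos, ref, alt, wgs_ref, wgs_alt, hichip_ref,
#'   hichip_alt, regulatory, carrier.
#' @export
simulate_allele_counts <- function(n_variants, coverage_range = c(60, 200),
                                   regulatory_fraction = 0.05, af_shift = 0.3,
                                   seed = 1, clonal_af = 0.4,
                                   samples = paste0("S", 1:10),
                                   chrom = "chrV") {
  stopifnot(af_shift >= 0, af_shift < 1)
  set.seed(seed)
  pos <- (seq_len(n_variants) - 1) * 2000 + 1000
  reg <- runif(n_variants) < regulatory_fraction
  af_wgs <- pmin(pmax(rnorm(n_variants, clonal_af, 0.05), 0.05), 0.9)
  af_hic <- ifelse(reg, pmin(af_wgs + af_shift, 0.95), af_wgs)
  dw <- floor(runif(n_variants, coverage_range[1], coverage_range[2] + 1))
  dh <- floor(runif(n_variants, coverage_range[1], coverage_range[2] + 1))
  alt_w <- rbinom(n_variants, dw, af_wgs)
  alt_h <- rbinom(n_variants, dh, af_hic)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_variants, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
             wgs_ref = dw - alt_w, wgs_alt = alt_w,
             hichip_ref = dh - alt_h, hichip_alt = alt_h,
             regulatory = reg,
             carrier = sample(samples, n_variants, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate the binned H3K27ac signal track around simulated variants
#'
#' One 2-kb window of 20 x 100-bp bins per variant, tiled consecutively from
#' track offset 0 (matching the positions laid down by
#' [simulate_allele_counts()]). Bin counts are Poisson with a per-variant
#' baseline, scaled by each sample's library factor; the carrier of a
#' regulatory variant gets a `signal_boost`-fold expected-count increase in
#' all 20 bins of its window.
#'
#' @param variants data.frame from [simulate_allele_counts()] (columns
#'   regulatory, carrier).
#' @param lib named per-sample library scale factors.
#' @param window_depth expected baseline count per 100-bp bin (default 30).
#' @param signal_boost carrier fold-boost at regulatory variants (default 3).
#' @param seed RNG seed.
#' @param chrom track chromosome (default "chrV").
#' @return a [signal_track()].
#' @export
simulate_variant_track <- function(variants, lib, window_depth = 30,
                                   signal_boost = 3, seed = 1,
                                   chrom = "chrV") {
  set.seed(seed)
  n_variants <- nrow(variants)
  samples <- names(lib)
  n_track_bins <- n_variants * 20
  lam_bin <- window_depth * rep(exp(rnorm(n_variants, 0, 0.2)), each = 20)
  mu_tr <- outer(lam_bin, lib)
  boost <- matrix(1, n_track_bins, length(lib),
                  dimnames = list(NULL, samples))
  for (i in which(variants$regulatory)) {
    rows <- ((i - 1) * 20 + 1):(i * 20)
    boost[rows, variants$carrier[i]] <- signal_boost
  }
  counts <- matrix(rpois(length(mu_tr), mu_tr * boost), n_track_bins,
                   dimnames = list(NULL, samples))
  signal_track(chrom, 0, 100, counts)
}

#' Simulate a complete synthetic cohort
#'
#' Deterministic given `config$seed`. See [cohort_config()] for the knobs and
#' the package vignette for the generative model.
#'
#' @param config a [cohort_config()].
#' @return list with elements: config, samples, genes, peaks, loops (planted
#'   loop table with per-anchor classes), loop_sets (per-sample loop tables),
#'   peak_counts, loop_counts, rna, tpm, seg, profiles, subcompartments,
#'   contact_maps, v4c_anchor_bin, celltype_peaks, variants, track, amplicons,
#'   amplicon_loops, amplicon_profiles (per-sample CN over the amplicon
#'   chromosome), truth.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  cfg <- config
  chrom <- "chrS"
  chrom_len <- cfg$n_bins * cfg$resolution
  res <- cfg$resolution
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  cancer_type <- paste0("T", rep_len(seq_len(cfg$n_cancer_types),
                                     cfg$n_samples))

  # ---- samples and library factors ----
  set.seed(sub_seed(cfg$seed, 1))
  lib <- runif(cfg$n_samples, cfg$library_size_range[1], cfg$library_size_range[2])
  names(lib) <- samples

  # ---- genes, enhancer peaks, loops ----
  set.seed(sub_seed(cfg$seed, 2))
  n_genes <- cfg$n_genes
  driver <- c(rep("enhancer-driven", cfg$n_genes_enh),
              rep("copy-driven", cfg$n_genes_cn),
              rep("null", cfg$n_genes_null),
              rep("low-expression", cfg$n_genes_low))
  driver <- sample(driver)   # interleave classes across the chromosome
  t0 <- (seq_len(n_genes) - 1) * cfg$territory
  tss <- t0 + cfg$territory / 2
  strand <- rep_len(c("+", "-"), n_genes)
  body_len <- 2e4
  gstart <- ifelse(strand == "+", tss, tss - body_len + 1)
  gend <- ifelse(strand == "+", tss + body_len, tss + 1)
  genes <- gene_models(sprintf("G%03d", seq_len(n_genes)), chrom, gstart,
                       gend, strand)
  stopifnot(all(genes$tss == tss))

  k_enh <- sample(cfg$enh_per_gene, n_genes, replace = TRUE)
  enh_rows <- lapply(seq_len(n_genes), function(i) {
    d <- sample(c(-1, 1), k_enh[i], replace = TRUE) *
      floor(runif(k_enh[i], 4.5e4, 1.4e5))
    ctr <- tss[i] + d
    data.frame(chrom = chrom, start = ctr - 500, end = ctr + 500,
               gene = genes$gene_id[i], type = "enhancer",
               stringsAsFactors = FALSE)
  })
  prom_peaks <- data.frame(chrom = chrom, start = tss - 500, end = tss + 500,
                           gene = genes$gene_id, type = "promoter",
                           stringsAsFactors = FALSE)
  bg_start <- n_genes * cfg$territory
  bg_peaks <- if (cfg$n_bg_peaks > 0) {
    ctr <- floor(runif(cfg$n_bg_peaks, bg_start + 1e3, chrom_len - 1e3))
    data.frame(chrom = chrom, start = ctr - 500, end = ctr + 500,
               gene = NA_character_, type = "background",
               stringsAsFactors = FALSE)
  } else NULL
  peaks <- rbind(do.call(rbind, enh_rows), prom_peaks, bg_peaks)
  rownames(peaks) <- NULL
  peaks$peak_id <- sprintf("P%04d", seq_len(nrow(peaks)))

  # pseudobulk accessibility label per peak
  acc_levels <- c("shared", cfg$celltypes, "none")
  acc_prob <- c(0.5, 0.15, 0.1, 0.1, 0.05, 0.1)[seq_along(acc_levels)]
  acc_prob <- acc_prob / sum(acc_prob)
  peaks$accessibility <- ifelse(
    peaks$type == "enhancer",
    sample(acc_levels, nrow(peaks), replace = TRUE, prob = acc_prob),
    "shared")

  # planted E-P loops: gene promoter bin <-> enhancer peak bin
  enh_idx <- which(peaks$type == "enhancer")
  bin_of <- function(p) (p %/% res) * res
  ep <- data.frame(
    chrom = chrom,
    start1 = bin_of(tss[match(peaks$gene[enh_idx], genes$gene_id)]),
    start2 = bin_of((peaks$start[enh_idx] + peaks$end[enh_idx]) / 2),
    gene = peaks$gene[enh_idx], peak_id = peaks$peak_id[enh_idx],
    stringsAsFactors = FALSE)
  ep$end1 <- ep$start1 + res; ep$end2 <- ep$start2 + res
  # a few promoter-promoter loops between neighboring genes for class variety
  n_pp <- min(10, n_genes - 1)
  pp_i <- sample(seq_len(n_genes - 1), n_pp)
  pp <- data.frame(chrom = chrom, start1 = bin_of(tss[pp_i]),
                   start2 = bin_of(tss[pp_i + 1]),
                   gene = NA_character_, peak_id = NA_character_,
                   stringsAsFactors = FALSE)
  pp$end1 <- pp$start1 + res; pp$end2 <- pp$start2 + res
  loops <- rbind(ep[c("chrom", "start1", "end1", "start2", "end2", "gene", "peak_id")],
                 pp[c("chrom", "start1", "end1", "start2", "end2", "gene", "peak_id")])
  loops$signal <- 0   # placeholder; per-sample signal below
  loops <- canonicalize_loops(loops, res)
  loops$loop_id <- sprintf("L%04d", seq_len(nrow(loops)))

  # ---- CNV segment profiles ----
  set.seed(sub_seed(cfg$seed, 3))
  seg_len <- 8e5
  n_seg <- ceiling(chrom_len / seg_len)
  seg_start <- (seq_len(n_seg) - 1) * seg_len
  seg_end <- pmin(seg_start + seg_len, chrom_len)
  cn_levels <- c(0, 1, 2, 3, 4, 6, 8)
  cn_prob <- c(0.01, 0.10, 0.55, 0.17, 0.10, 0.05, 0.02)
  seg_rows <- lapply(samples, function(s) {
    data.frame(sample = s, chrom = chrom, start = seg_start, end = seg_end,
               total_cn = sample(cn_levels, n_seg, TRUE, cn_prob),
               stringsAsFactors = FALSE)
  })
  # flat diploid segment for the variant chromosome so CN lookups succeed
  var_len <- cfg$n_variants * 2000
  seg_rows <- c(seg_rows, lapply(samples, function(s)
    data.frame(sample = s, chrom = "chrV", start = 0, end = var_len,
               total_cn = 2, stringsAsFactors = FALSE)))
  seg <- do.call(rbind, seg_rows)
  profiles <- cnv_profiles_from_seg(seg)
  profiles <- profiles[samples]

  rel_cn_gene <- sapply(samples, function(s)
    relative_cn(profiles[[s]], genes[c("chrom", "start", "end")]))
  rel_cn_peak <- sapply(samples, function(s)
    relative_cn(profiles[[s]], peaks[c("chrom", "start", "end")]))
  rel_cn_gene[is.na(rel_cn_gene)] <- 0   # CN-0 genes: silenced below
  rel_cn_peak_f <- rel_cn_peak; rel_cn_peak_f[is.na(rel_cn_peak_f)] <- 0

  # ---- expression and peak signal ----
  set.seed(sub_seed(cfg$seed, 4))
  # shared enhancer activity factor per gene x sample
  z <- matrix(rnorm(n_genes * cfg$n_samples), n_genes,
              dimnames = list(genes$gene_id, samples))
  y <- matrix(8, n_genes, cfg$n_samples, dimnames = dimnames(z))
  y <- y + matrix(rnorm(length(y), 0, cfg$noise_sd), n_genes)
  is_enh <- driver == "enhancer-driven"
  is_cn <- driver == "copy-driven"
  is_low <- driver == "low-expression"
  y[is_enh, ] <- y[is_enh, ] + cfg$enh_effect * z[is_enh, ]
  y[is_cn, ] <- y[is_cn, ] + cfg$cn_effect * rel_cn_gene[is_cn, ]
  y[is_low, ] <- y[is_low, ] - 6
  rna <- 2^y - 1
  tpm <- 2^(y - 3)

  # peak counts: library x log-normal(base + shared factor) x CN
  mu_pk <- runif(nrow(peaks), 4, 6)
  g_of_peak <- match(peaks$gene, genes$gene_id)
  logsig <- matrix(rnorm(nrow(peaks) * cfg$n_samples, 0, 0.4), nrow(peaks))
  has_gene <- !is.na(g_of_peak)
  logsig[has_gene & peaks$type == "enhancer", ] <-
    logsig[has_gene & peaks$type == "enhancer", ] +
    cfg$peak_factor_sd * z[g_of_peak[has_gene & peaks$type == "enhancer"], ]
  # cancer-type-specific 1D signal for a quarter of enhancer peaks
  type_of <- setNames(cancer_type, samples)
  pk_type <- rep(NA_character_, nrow(peaks))
  spec_pk <- which(peaks$type == "enhancer" & runif(nrow(peaks)) < 0.25)
  pk_type[spec_pk] <- paste0("T", sample.int(cfg$n_cancer_types,
                                             length(spec_pk), TRUE))
  type_mult_pk <- matrix(1, nrow(peaks), cfg$n_samples)
  for (i in spec_pk)
    type_mult_pk[i, cancer_type == pk_type[i]] <- 3
  peak_counts <- sweep(2^(mu_pk + logsig) * type_mult_pk *
                         pmax(rel_cn_peak_f, 0.05), 2, lib, "*")
  dimnames(peak_counts) <- list(peaks$peak_id, samples)

  # ---- per-sample loop tables and loop count matrix ----
  set.seed(sub_seed(cfg$seed, 5))
  n_loops <- nrow(loops)
  lam <- exp(runif(n_loops, log(15), log(60)))
  loop_type <- rep(NA_character_, n_loops)
  spec_lp <- sample(seq_len(n_loops), round(0.4 * n_loops))
  loop_type[spec_lp] <- paste0("T", sample.int(cfg$n_cancer_types,
                                               length(spec_lp), TRUE))
  type_mult_lp <- matrix(1, n_loops, cfg$n_samples)
  for (i in spec_lp)
    type_mult_lp[i, cancer_type == loop_type[i]] <- 5
  r1 <- sapply(samples, function(s) relative_cn(profiles[[s]], anchor1(loops)))
  r2 <- sapply(samples, function(s) relative_cn(profiles[[s]], anchor2(loops)))
  r1[is.na(r1)] <- 0.05; r2[is.na(r2)] <- 0.05
  mu_lp <- lam * type_mult_lp * r1 * r2
  mu_lp <- sweep(mu_lp, 2, lib, "*")
  loop_counts <- matrix(rpois(length(mu_lp), mu_lp), n_loops,
                        dimnames = list(loops$loop_id, samples))
  loop_sets <- lapply(samples, function(s) {
    out <- loops[c("chrom", "start1", "end1", "start2", "end2")]
    out$signal <- loop_counts[, s]
    out$qvalue <- 10^-runif(n_loops, 2, 8)
    out[out$signal > 0, , drop = FALSE]
  })
  names(loop_sets) <- samples

  # ---- subcompartment rank vectors (weak type signal) ----
  set.seed(sub_seed(cfg$seed, 6))
  base_rank <- sample(1:8, cfg$n_bins, replace = TRUE)
  type_shift <- matrix(0, cfg$n_bins, cfg$n_cancer_types)
  shift_bins <- sample(cfg$n_bins, round(0.05 * cfg$n_bins))
  type_shift[shift_bins, ] <- matrix(sample(-1:1, length(shift_bins) *
                                              cfg$n_cancer_types, TRUE),
                                     length(shift_bins))
  subcomp <- sapply(seq_len(cfg$n_samples), function(s) {
    tt <- as.integer(sub("T", "", cancer_type[s]))
    pmin(pmax(base_rank + type_shift[, tt] +
                sample(-1:1, cfg$n_bins, TRUE, c(0.25, 0.5, 0.25)), 1), 8)
  })
  dimnames(subcomp) <- list(NULL, samples)

  # ---- cell-type pseudobulk accessibility and fractions ----
  set.seed(sub_seed(cfg$seed, 7))
  celltype_peaks <- lapply(cfg$celltypes, function(ct) {
    sel <- peaks$accessibility %in% c("shared", ct)
    peaks[sel, c("chrom", "start", "end")]
  })
  names(celltype_peaks) <- cfg$celltypes
  fracs <- t(sapply(seq_len(cfg$n_samples),
                    function(i) rdirichlet1(cfg$celltype_alpha)))
  colnames(fracs) <- cfg$celltypes
  total_cells <- floor(runif(cfg$n_samples, 1500, 6000))
  # a couple of sparsely sampled cases to exercise the noncancer-cell gate
  low_cells <- sample(cfg$n_samples, min(2, cfg$n_samples))
  total_cells[low_cells] <- floor(runif(length(low_cells), 120, 200))
  cell_counts <- round(fracs * total_cells)

  # ---- contact maps (first contact_bins bins) with a fraction-coupled loop --
  contact_maps <- NULL
  v4c_anchor_bin <- NA_integer_
  coupled_loop <- NULL
  if (cfg$contact_bins > 0) {
    region_len <- cfg$contact_bins * res
    in_region <- loops$start2 + res <= region_len
    lp_bins <- data.frame(bin1 = loops$start1[in_region] / res + 1,
                          bin2 = loops$start2[in_region] / res + 1)
    # couple the first in-region E-P loop's strength to the myeloid fraction
    first_ep <- which(in_region & !is.na(loops$gene))[1]
    v4c_anchor_bin <- loops$start1[first_ep] / res + 1
    coupled_loop <- list(loop_row = first_ep,
                         partner_bin = loops$start2[first_ep] / res + 1)
    contact_maps <- lapply(seq_len(cfg$n_samples), function(si) {
      enr <- rep(cfg$loop_enrichment, nrow(lp_bins))
      k <- which(which(in_region) == first_ep)
      enr[k] <- cfg$loop_enrichment * (0.5 + 4 * fracs[si, "myeloid"])
      cn_track <- relative_cn(
        profiles[[samples[si]]],
        data.frame(chrom = chrom,
                   start = (seq_len(cfg$contact_bins) - 1) * res,
                   end = seq_len(cfg$contact_bins) * res))
      cn_track[is.na(cn_track)] <- 0.05
      simulate_contact_map(cfg$contact_bins, cbind(lp_bins, enrichment = enr),
                           cn_track, cfg$decay_exponent,
                           seed = sub_seed(cfg$seed, 100 + si),
                           base_depth = cfg$base_depth * lib[si],
                           chrom = chrom, resolution = res)
    })
    names(contact_maps) <- samples
  }

  # ---- somatic variants and window signal track ----
  variants <- simulate_allele_counts(
    cfg$n_variants, cfg$coverage_range, cfg$regulatory_fraction, cfg$af_shift,
    seed = sub_seed(cfg$seed, 8), clonal_af = cfg$clonal_af,
    samples = samples)
  track <- simulate_variant_track(variants, lib, cfg$window_depth,
                                  cfg$signal_boost,
                                  seed = sub_seed(cfg$seed, 9))

  # ---- amplicons with junction-spanning loops ----
  set.seed(sub_seed(cfg$seed, 10))
  amp_classes <- rep(names(cfg$neoloop_rates), each = cfg$amplicons_per_class)
  amp_gap <- 4e6
  amplicons <- list(); amplicon_loops <- list(); n_neo_truth <- integer(0)
  cursor <- 0
  n_iv_of <- c(cyclic = 2, BFB = 1, complex = 3, linear = 1)
  n_bp_of <- c(cyclic = 4, BFB = 3, complex = 5, linear = 1)
  for (ai in seq_along(amp_classes)) {
    cl <- amp_classes[ai]
    n_iv <- n_iv_of[[cl]]
    iv_len <- floor(runif(n_iv, 8e5, 1.6e6))
    iv_start <- cursor + cumsum(c(0, head(iv_len, -1) + 2e5))
    iv <- data.frame(chrom = "chrA", start = iv_start,
                     end = iv_start + iv_len)
    cursor <- max(iv$end) + amp_gap
    n_bp <- n_bp_of[[cl]]
    bp_iv <- sample(seq_len(n_iv), n_bp, replace = TRUE)
    bp_pos <- floor(runif(n_bp, iv$start[bp_iv] + 2e5, iv$end[bp_iv] - 2e5))
    bp <- data.frame(chrom = "chrA", pos = bp_pos)
    amp <- amplicon(sprintf("AMP%02d", ai), cl, iv, bp)
    size_mb <- amp$size / 1e6
    # neoloops: anchors bracket a breakpoint within its interval
    n_neo <- max(1L, as.integer(round(cfg$neoloop_rates[[cl]] * size_mb)))
    neo <- lapply(seq_len(n_neo), function(k) {
      b <- bp_pos[sample.int(n_bp, 1)]
      jb <- b %/% res
      d1 <- sample(1:10, 1); d2 <- sample(1:10, 1)
      data.frame(chrom = "chrA", start1 = (jb - d1) * res,
                 end1 = (jb - d1 + 1) * res,
                 start2 = (jb + d2) * res + res,
                 end2 = (jb + d2 + 2) * res, stringsAsFactors = FALSE)
    })
    neo <- do.call(rbind, neo)
    neo$end2 <- neo$start2 + res   # fixed width anchors
    # background loops confined to one breakpoint-free stretch per interval
    n_bg <- max(1L, as.integer(round(2 * size_mb)))
    bg <- lapply(seq_len(n_bg), function(k) {
      ivk <- sample.int(n_iv, 1)
      bps_in <- sort(bp_pos[bp_iv == ivk])
      bounds <- c(iv$start[ivk], bps_in, iv$end[ivk])
      sk <- sample.int(length(bounds) - 1, 1)
      lo <- bounds[sk]; hi <- bounds[sk + 1]
      b1 <- (lo %/% res + 1) * res
      b2 <- b1 + sample(4:8, 1) * res
      if (b2 + res > hi) { b2 <- b1 + res * 2 }
      if (b2 + res > hi) return(NULL)
      data.frame(chrom = "chrA", start1 = b1, end1 = b1 + res,
                 start2 = b2, end2 = b2 + res, stringsAsFactors = FALSE)
    })
    bg <- do.call(rbind, bg)
    al <- rbind(neo, bg)
    al$signal <- rpois(nrow(al), 20) + 1
    al <- canonicalize_loops(al, res)
    amplicons[[amp$amplicon_id]] <- amp
    amplicon_loops[[amp$amplicon_id]] <- al
    n_neo_truth[amp$amplicon_id] <- nrow(neo)
  }
  # per-sample CN over the amplicon chromosome: each amplicon is focally
  # amplified (all its intervals jointly, emulating co-amplification on one
  # molecule) in a random ~30% of samples
  amp_region_end <- cursor + 1e6
  amp_status <- matrix(runif(length(amplicons) * cfg$n_samples) < 0.3,
                       length(amplicons),
                       dimnames = list(names(amplicons), samples))
  amp_cn <- matrix(round(runif(length(amplicons) * cfg$n_samples, 6, 15)),
                   length(amplicons), dimnames = dimnames(amp_status))
  amp_seg_rows <- lapply(samples, function(s) {
    ivs <- do.call(rbind, lapply(names(amplicons), function(id) {
      iv <- amplicons[[id]]$intervals
      iv$total_cn <- if (amp_status[id, s]) amp_cn[id, s] else 2
      iv
    }))
    ivs <- ivs[order(ivs$start), ]
    bounds <- sort(unique(c(0, ivs$start, ivs$end, amp_region_end)))
    pieces <- data.frame(sample = s, chrom = "chrA",
                         start = head(bounds, -1), end = bounds[-1],
                         total_cn = 2, stringsAsFactors = FALSE)
    hit <- overlap_map(pieces[c("chrom", "start", "end")],
                       ivs[c("chrom", "start", "end")])
    for (k in seq_len(nrow(pieces)))
      if (length(hit[[k]])) pieces$total_cn[k] <- ivs$total_cn[hit[[k]][1]]
    pieces
  })
  amplicon_profiles <- cnv_profiles_from_seg(do.call(rbind, amp_seg_rows))
  amplicon_profiles <- amplicon_profiles[samples]

  # ---- ground truth ----
  loop_truth <- rep("shared", nrow(loops))
  acc <- peaks$accessibility[match(loops$peak_id, peaks$peak_id)]
  loop_truth[!is.na(acc) & acc == "none"] <- "ambiguous"
  spec_sel <- !is.na(acc) & acc %in% cfg$celltypes
  loop_truth[spec_sel] <- acc[spec_sel]
  loop_truth[is.na(loops$peak_id)] <- NA   # non-E-P loops
  truth <- list(
    gene_driver = setNames(driver, genes$gene_id),
    loop_celltype = setNames(loop_truth, loops$loop_id),
    peak_type_specific = setNames(pk_type, peaks$peak_id),
    loop_type_specific = setNames(loop_type, loops$loop_id),
    variant_regulatory = setNames(variants$regulatory,
                                  paste0(variants$chrom, ":", variants$pos)),
    amplicon_class = setNames(amp_classes, names(amplicons)),
    n_neoloops = n_neo_truth,
    amplified_samples = amp_status,
    coupled_loop = coupled_loop)

  sample_table <- data.frame(sample = samples, cancer_type = cancer_type,
                             library_factor = unname(lib),
                             total_cells = total_cells,
                             cell_counts, check.names = FALSE,
                             fraction = fracs, stringsAsFactors = FALSE)

  list(config = cfg, samples = sample_table, genes = genes, peaks = peaks,
       loops = loops, loop_sets = loop_sets, peak_counts = peak_counts,
       loop_counts = loop_counts, rna = rna, tpm = tpm, seg = seg,
       profiles = profiles, subcompartments = subcomp,
       contact_maps = contact_maps, v4c_anchor_bin = v4c_anchor_bin,
       celltype_peaks = celltype_peaks, variants = variants, track = track,
       amplicons = amplicons, amplicon_loops = amplicon_loops,
       amplicon_profiles = amplicon_profiles, truth = truth)
}

#' Write a cohort to a directory in the package's text formats
#'
#' Emits peaks (BED), the planted loop table and per-sample loop sets (loop
#' TSV), CN segments (SEG), gene models (GTF-lite TSV), expression and signal
#' matrices (TSV), variants (TSV), the first sample's contact map (triplet
#' text) and a JSON manifest recording the config and seed.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_bed(cohort$peaks, fp("peaks.bed"))
  write_loop_table(cohort$loops, fp("loops.tsv"))
  write_gene_table(cohort$genes, fp("genes.tsv"))
  write_seg(cohort$seg, fp("cnv.seg"))
  write_signal_matrix(cohort$rna, fp("rna_counts.tsv"), "gene_id")
  write_signal_matrix(cohort$tpm, fp("rna_tpm.tsv"), "gene_id")
  write_signal_matrix(cohort$peak_counts, fp("peak_counts.tsv"), "peak_id")
  write_signal_matrix(cohort$loop_counts, fp("loop_counts.tsv"), "loop_id")
  write.table(cohort$variants, fp("variants.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$samples, fp("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cohort$contact_maps))
    write_contact_matrix(cohort$contact_maps[[1]], fp("contact_S01.tsv"))
  amp_tab <- do.call(rbind, lapply(cohort$amplicons, function(a)
    cbind(amplicon_id = a$amplicon_id, class = a$class, a$intervals)))
  write.table(amp_tab, fp("amplicons.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  bp_tab <- do.call(rbind, lapply(cohort$amplicons, function(a)
    cbind(amplicon_id = a$amplicon_id, a$breakpoints)))
  write.table(bp_tab, fp("breakpoints.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- cohort$config
  class(manifest) <- NULL
  manifest$neoloop_rates <- as.list(manifest$neoloop_rates)  # keep names
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Regenerate a cohort from a manifest written by [write_cohort()]
#' @param path path to manifest.json.
#' @return the cohort list (bit-identical to the one that wrote the manifest).
#' @export
cohort_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- m[setdiff(names(m), c("n_genes", "territory"))]
  m$neoloop_rates <- unlist(m$neoloop_rates)
  simulate_cohort(do.call(cohort_config, m))
}
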