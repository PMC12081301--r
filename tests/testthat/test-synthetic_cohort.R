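test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config(n_samples = 8, n_genes_enh = 3, n_genes_cn = 3,
                       n_genes_null = 3, n_genes_low = 1, n_variants = 20,
                       contact_bins = 40, amplicons_per_class = 1, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the data
  cfg2 <- cohort_config(n_samples = 8, n_genes_enh = 3, n_genes_cn = 3,
                        n_genes_null = 3, n_genes_low = 1, n_variants = 20,
                        contact_bins = 40, amplicons_per_class = 1, seed = 6)
  expect_false(identical(a$rna, simulate_cohort(cfg2)$rna))
})

test_that("infeasible configs are rejected", {
  expect_error(cohort_config(n_bins = 10), "do not fit")
  expect_error(cohort_config(loop_distance = c(4e4, 1e9)), "loop distance")
  expect_error(cohort_config(af_shift = 1.2))
})

test_that("generated tables satisfy the core invariants", {
  co <- small_cohort(seed = 13)
  expect_silent(validate_intervals(co$peaks))
  expect_silent(validate_intervals(co$genes))
  expect_true(all(co$loops$start1 < co$loops$start2))
  expect_true(all(co$loops$end1 - co$loops$start1 == co$config$resolution))
  span <- co$loops$start2 - co$loops$start1
  expect_true(all(span >= co$config$loop_distance[1] - co$config$resolution))
  expect_true(all(span <= co$config$loop_distance[2]))
  # every simulated entity carries exactly one ground-truth label
  expect_setequal(names(co$truth$gene_driver), co$genes$gene_id)
  expect_setequal(names(co$truth$loop_celltype), co$loops$loop_id)
  expect_equal(length(co$truth$variant_regulatory), nrow(co$variants))
})

test_that("cohort write/read round-trips through the text formats", {
  co <- small_cohort(seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_equal(read_bed(file.path(dir, "peaks.bed"))[1:3],
               co$peaks[c("chrom", "start", "end")])
  expect_equal(read_gene_table(file.path(dir, "genes.tsv")), co$genes)
  expect_equal(read_seg(file.path(dir, "cnv.seg")), co$seg,
               ignore_attr = TRUE)
  expect_equal(read_signal_matrix(file.path(dir, "rna_counts.tsv")), co$rna)
  lp <- read_loop_table(file.path(dir, "loops.tsv"), co$config$resolution)
  expect_equal(lp[c("start1", "start2", "signal")],
               co$loops[c("start1", "start2", "signal")], ignore_attr = TRUE)
  cm <- read_contact_matrix(file.path(dir, "contact_S01.tsv"))
  expect_equal(cm$mat, co$contact_maps[[1]]$mat)
  # manifest regenerates the identical cohort
  co2 <- cohort_from_manifest(file.path(dir, "manifest.json"))
  expect_equal(co2$rna, co$rna)
  expect_equal(co2$variants, co$variants)
})

test_that("enhancer-driven genes track enhancer signal, not CN", {
  # across replicate cohorts, RNA of enhancer-driven genes correlates more
  # strongly with the planted enhancer factor than with CN for >= 90% of genes
  wins <- 0; total <- 0
  for (seed in 1:5) {
    co <- simulate_cohort(cohort_config(
      n_samples = 60, n_genes_enh = 8, n_genes_cn = 4, n_genes_null = 4,
      n_genes_low = 0, n_variants = 10, contact_bins = 0,
      amplicons_per_class = 1, seed = seed))
    enh_genes <- names(which(co$truth$gene_driver == "enhancer-driven"))
    samples <- co$samples$sample
    rel_cn <- sapply(samples, function(s)
      relative_cn(co$profiles[[s]],
                  co$genes[match(enh_genes, co$genes$gene_id),
                           c("chrom", "start", "end")]))
    for (k in seq_along(enh_genes)) {
      g <- enh_genes[k]
      pk <- co$peaks$peak_id[which(co$peaks$gene == g &
                                     co$peaks$type == "enhancer")]
      enh_sig <- colMeans(log2(co$peak_counts[pk, , drop = FALSE] + 1))
      r_enh <- abs(cor(log2(co$rna[g, ] + 1), enh_sig))
      r_cn <- abs(cor(log2(co$rna[g, ] + 1), rel_cn[k, ]))
      if (is.na(r_cn) || r_enh > r_cn) wins <- wins + 1
      total <- total + 1
    }
  }
  expect_gte(wins / total, 0.9)
})

test_that("null genes show no CN association", {
  # the CN slope of null genes is within 2 SE of zero in >= 93% of fits
  ok <- 0; total <- 0
  for (seed in 1:4) {
    co <- simulate_cohort(cohort_config(
      n_samples = 60, n_genes_enh = 2, n_genes_cn = 2, n_genes_null = 10,
      n_genes_low = 0, n_variants = 10, contact_bins = 0,
      amplicons_per_class = 1, seed = 100 + seed))
    null_genes <- names(which(co$truth$gene_driver == "null"))
    samples <- co$samples$sample
    rel_cn <- sapply(samples, function(s)
      relative_cn(co$profiles[[s]],
                  co$genes[match(null_genes, co$genes$gene_id),
                           c("chrom", "start", "end")]))
    for (k in seq_along(null_genes)) {
      fit <- summary(lm(log2(co$rna[null_genes[k], ] + 1) ~ rel_cn[k, ]))
      est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
      if (abs(est) <= 2 * se) ok <- ok + 1
      total <- total + 1
    }
  }
  expect_gte(ok / total, 0.93)
})

test_that("contact maps follow the decay-CN-loop model", {
  # decay: with no loops and flat CN the mean count falls with distance
  cm <- simulate_contact_map(80, loops = NULL, decay_exponent = 1,
                             seed = 2, base_depth = 300)
  mean_at <- vapply(c(0, 3, 10, 30), function(d) {
    i <- seq_len(80 - d)
    mean(cm$mat[cbind(i, i + d)])
  }, numeric(1))
  expect_true(all(diff(mean_at) < 0))
  # a planted loop enriches its bin pair over distance-matched background
  lp <- data.frame(bin1 = 10, bin2 = 40, enrichment = 10)
  cm2 <- simulate_contact_map(80, lp, decay_exponent = 1, seed = 3,
                              base_depth = 300)
  d <- 30; i <- seq_len(80 - d)
  bg <- cm2$mat[cbind(i, i + d)]
  expect_gt(cm2$mat[10, 40], mean(bg[i != 10]))
  # doubling one bin's CN doubles its expected row sum
  cn <- rep(1, 80)
  mu1 <- contact_expected(80, NULL, cn, 1, 100)
  cn2 <- cn; cn2[25] <- 2
  mu2 <- contact_expected(80, NULL, cn2, 1, 100)
  off <- setdiff(seq_len(80), 25)
  expect_equal(sum(mu2[25, off]), 2 * sum(mu1[25, off]))
})

test_that("allele count simulation honours the AF shift and coverage bounds", {
  v0 <- simulate_allele_counts(2000, c(100, 200), regulatory_fraction = 0.5,
                               af_shift = 0, seed = 4)
  af <- allele_frequencies(v0)
  # af_shift 0: HiChIP and WGS allele fractions agree in expectation
  expect_lt(abs(mean(af$af_hichip) - mean(af$af_wgs)), 0.01)
  # boundary: depth 31 everywhere passes the > 30 filter
  v31 <- simulate_allele_counts(100, c(31, 31), 0.05, 0.3, seed = 5)
  expect_true(all(allele_frequencies(v31)$passes_coverage))
  # depth 30 fails it
  v30 <- simulate_allele_counts(100, c(30, 30), 0.05, 0.3, seed = 6)
  expect_false(any(allele_frequencies(v30)$passes_coverage))
})
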