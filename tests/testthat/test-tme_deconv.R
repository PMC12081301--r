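ep_fixture <- function() {
  # gene at 1 Mb (TSS 1,000,000), enhancer anchor at 1.15 Mb
  genes <- gene_models("g", "chr1", 1e6, 1e6 + 2e4, "+")
  res <- 1e4
  loops <- canonicalize_loops(data.frame(
    chrom = "chr1", start1 = 1e6, end1 = 1e6 + res,
    start2 = 1.15e6, end2 = 1.15e6 + res, signal = 5), res)
  h3 <- genomic_intervals("chr1", c(1e6 - 500, 1.152e6), c(1e6 + 500, 1.153e6))
  ann <- classify_loops(loops, genes, h3)
  list(ann = ann, h3 = h3)
}

test_that("specificity rules separate specific, shared and ambiguous loops", {
  fx <- ep_fixture()
  prom_pk <- genomic_intervals("chr1", 1e6 - 300, 1e6 + 300)
  enh_pk <- genomic_intervals("chr1", 1.1515e6, 1.1525e6)
  counts <- c(cancer = 2000, myeloid = 200, tcell = 150, bcell = 120)
  # enhancer accessible only in myeloid -> myeloid-specific
  ct1 <- list(cancer = prom_pk, myeloid = rbind(prom_pk, enh_pk),
              tcell = prom_pk, bcell = prom_pk)
  r1 <- classify_loop_specificity(fx$ann, fx$h3, ct1, counts)
  expect_equal(r1$class, "specific")
  expect_equal(r1$cell_type, "myeloid")
  # enhancer accessible in three cell types -> shared
  ct2 <- list(cancer = rbind(prom_pk, enh_pk), myeloid = rbind(prom_pk, enh_pk),
              tcell = rbind(prom_pk, enh_pk), bcell = prom_pk)
  expect_equal(classify_loop_specificity(fx$ann, fx$h3, ct2, counts)$class,
               "shared")
  # no scATAC peak anywhere -> ambiguous
  none <- genomic_intervals("chr1", 9e6, 9.001e6)
  ct3 <- list(cancer = none, myeloid = none, tcell = none, bcell = none)
  r3 <- classify_loop_specificity(fx$ann, fx$h3, ct3, counts)
  expect_equal(r3$class, "ambiguous")
  expect_equal(r3$reason, "no_scatac_peak_at_either_anchor")
  # scATAC at the promoter only: matches no rule, ambiguous with reason
  ct4 <- list(cancer = prom_pk, myeloid = prom_pk, tcell = prom_pk,
              bcell = prom_pk)
  r4 <- classify_loop_specificity(fx$ann, fx$h3, ct4, counts)
  expect_equal(r4$class, "ambiguous")
  expect_equal(r4$reason, "evidence_matches_no_rule")
  # classification independent of cell-type listing order
  r1b <- classify_loop_specificity(fx$ann, fx$h3, rev(ct1), counts)
  expect_equal(r1b$class, r1$class)
  expect_equal(r1b$cell_type, r1$cell_type)
  # non-E-P input errors
  bad <- fx$ann; bad$annotation <- factor("P-P", levels = levels(bad$annotation))
  expect_error(classify_loop_specificity(bad, fx$h3, ct1, counts), "E-P")
})

test_that("samples with too few noncancer cells are skipped", {
  fx <- ep_fixture()
  ct <- list(cancer = fx$h3, myeloid = fx$h3)
  low <- c(cancer = 5000, myeloid = 109)
  expect_message(r <- classify_loop_specificity(fx$ann, fx$h3, ct, low),
                 "skipped")
  expect_equal(nrow(r), 0)
  # exactly 110 noncancer cells is enough
  ok <- c(cancer = 5000, myeloid = 110)
  expect_silent(r2 <- classify_loop_specificity(fx$ann, fx$h3, ct, ok))
  expect_equal(nrow(r2), 1)
})

test_that("planted cell-type-specific loops are recovered with high precision", {
  co <- small_cohort(seed = 17)
  ann <- classify_loops(co$loops, co$genes, co$peaks[c("chrom", "start", "end")])
  ep <- ann[as.character(ann$annotation) == "E-P", ]
  cc <- unlist(co$samples[1, co$config$celltypes])
  spec <- classify_loop_specificity(ep, co$peaks[c("chrom", "start", "end")],
                                    co$celltype_peaks, cc)
  truth <- co$truth$loop_celltype[ep$loop_id]
  called <- spec$class == "specific"
  expect_gt(sum(called), 5)
  precision <- mean(spec$cell_type[called] == truth[called])
  expect_gte(precision, 0.9)
})

test_that("EIS-fraction correlation uses average-rank Spearman with cutoffs", {
  # strictly monotone pair
  r <- eis_fraction_correlation(1:6, c(2, 4, 5, 7, 8, 11))
  expect_equal(r$rho, 1)
  expect_true(r$pass)
  # tied data equals the rank-then-Pearson oracle
  x <- c(1, 2, 2, 3, 5, 5, 7); y <- c(2, 1, 4, 4, 6, 8, 8)
  r2 <- eis_fraction_correlation(x, y)
  expect_equal(r2$rho, cor(rank(x), rank(y)))
  # rho below the cutoff fails
  set.seed(30)
  repeat {
    a <- rnorm(10); b <- rnorm(10)
    rho <- cor(a, b, method = "spearman")
    if (rho > 0 && rho < 0.29) break
  }
  expect_false(eis_fraction_correlation(a, b, rho_cutoff = 0.30)$pass)
  # degenerate input fails with a reason rather than passing
  r4 <- eis_fraction_correlation(rep(1, 6), 1:6)
  expect_true(is.na(r4$rho))
  expect_false(r4$pass)
  expect_match(r4$reason, "variance")
  expect_error(eis_fraction_correlation(1:4, 1:4), "5 paired")
})

test_that("coupled loop EIS tracks the myeloid fraction across samples", {
  co <- small_cohort(seed = 17)
  res <- co$config$resolution
  anchor <- genomic_intervals("chrS", (co$v4c_anchor_bin - 1) * res,
                              co$v4c_anchor_bin * res)
  partner <- co$truth$coupled_loop$partner_bin
  eis <- vapply(co$contact_maps, function(cm)
    virtual_4c(cm, anchor, 5)$eis[partner], numeric(1))
  r <- eis_fraction_correlation(eis, co$samples$fraction.myeloid)
  expect_true(r$pass)
})
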