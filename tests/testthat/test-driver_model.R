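test_that("expression filter and loop-supported linking are strict", {
  genes <- gene_models(c("hi4", "hi3", "far"), "chr1",
                       c(1e6, 3e6, 5e6), c(1e6 + 2e4, 3e6 + 2e4, 5e6 + 2e4),
                       "+")
  tpm <- rbind(hi4 = c(11, 11, 11, 11, 1),
               hi3 = c(11, 11, 11, 1, 1),
               far = c(50, 50, 50, 50, 50))
  colnames(tpm) <- paste0("s", 1:5)
  peaks <- genomic_intervals("chr1", c(1.1e6, 6.2e6), c(1.1e6 + 1e3, 6.2e6 + 1e3))
  res <- 1e4
  loops <- canonicalize_loops(data.frame(
    chrom = "chr1",
    start1 = c(1e6, 5e6), end1 = c(1e6, 5e6) + res,
    start2 = c(1.1e6, 6.2e6), end2 = c(1.1e6, 6.2e6) + res,
    signal = 1), res)
  links <- select_and_link(genes, tpm, peaks, loops)
  # TPM 11 in 4 samples retained; in exactly 3 samples dropped
  expect_true("hi4" %in% names(links))
  expect_false("hi3" %in% names(links))
  expect_equal(links$hi4, 1L)
  # peak 1.2 Mb from the TSS is not linked despite its loop
  expect_equal(links$far, integer(0))
  # a gene absent from the TPM matrix is skipped with a message
  g2 <- rbind(genes, gene_models("ghost", "chr1", 7e6, 7e6 + 1e4, "+"))
  expect_message(select_and_link(g2, tpm, peaks, loops), "absent")
})

test_that("peak predictors switch between raw peaks and five PCs", {
  set.seed(2)
  m5 <- matrix(rnorm(40 * 5), 40)
  p5 <- peak_pca(m5)
  expect_equal(ncol(p5), 5)
  expect_equal(colnames(p5), paste0("peak", 1:5))   # no PCA at 5 peaks
  expect_equal(unname(p5), unname(scale(m5)))
  m8 <- matrix(rnorm(40 * 8), 40)
  p8 <- peak_pca(m8)
  expect_equal(colnames(p8), paste0("PC", 1:5))
  # score vectors orthogonal with non-increasing variance
  cp <- crossprod(p8)
  expect_equal(cp[upper.tri(cp)], rep(0, 10), tolerance = 1e-8)
  expect_true(all(diff(apply(p8, 2, var)) <= 1e-8))
  expect_error(peak_pca(matrix(NA_real_, 3, 6)), "complete samples")
})

test_that("LMG equals brute-force averaging over orderings", {
  set.seed(7)
  n <- 80
  X <- matrix(rnorm(n * 3), n) %*% chol(matrix(c(1, .5, .2,
                                                 .5, 1, .4,
                                                 .2, .4, 1), 3))
  colnames(X) <- c("a", "b", "CN")
  y <- X %*% c(1, -0.5, 0.8) + rnorm(n)
  got <- lmg_importance(y, X)
  want <- lmg_by_orderings(y, X)
  expect_equal(got$importance, want, tolerance = 1e-10)
  expect_equal(sum(got$importance), got$r2, tolerance = 1e-8)
  expect_equal(got$r2, summary(lm(y ~ X))$r.squared, tolerance = 1e-10)
})

test_that("LMG handles orthogonal and duplicated-predictor structure", {
  set.seed(8)
  n <- 4000
  a <- rnorm(n); b <- rnorm(n)
  y <- a + 0.5 * b + rnorm(n, 0, 0.5)
  # near-orthogonal predictors: importance approximates marginal R^2
  got <- lmg_importance(y, cbind(a = a, b = b))
  expect_lt(abs(got$importance[["a"]] - cor(y, a)^2), 0.02)
  expect_lt(abs(got$importance[["b"]] - cor(y, b)^2), 0.02)
  # two identical predictors split their shared R^2 equally
  y2 <- a + rnorm(n, 0, 1)
  a2 <- a + rnorm(n, 0, 1e-3)
  got2 <- lmg_importance(y2, cbind(p = a, q = a2))
  expect_equal(unname(got2$importance["p"]), unname(got2$importance["q"]),
               tolerance = 1e-3)
  expect_equal(sum(got2$importance), got2$r2, tolerance = 1e-8)
  # exactly collinear columns error with their names
  expect_error(lmg_importance(y, cbind(u = a, v = a)), "collinear")
})

test_that("LMG is invariant to predictor rescaling", {
  set.seed(9)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rowSums(X) + rnorm(50)
  base <- lmg_importance(y, X)$importance
  scaled <- lmg_importance(y, sweep(X, 2, c(10, 0.1, 3, 1), "*"))$importance
  expect_equal(unname(base), unname(scaled), tolerance = 1e-10)
})

test_that("classification recovers planted copy- and enhancer-driven genes", {
  set.seed(10)
  n <- 60
  acc <- c(copy = 0, enh = 0)
  for (rep in 1:10) {
    cn <- sample(c(0.5, 1, 1.5, 2, 3), n, TRUE)
    enh <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("e", 1:3)))
    y_cn <- 2 * cn + rnorm(n, 0, 0.5)
    y_enh <- enh[, 1] + rnorm(n, 0, 0.5)
    f1 <- fit_and_classify(y_cn, enh, cn)
    f2 <- fit_and_classify(y_enh, enh, cn)
    acc["copy"] <- acc["copy"] + (f1$class == "copy-driven")
    acc["enh"] <- acc["enh"] + (f2$class == "enhancer-driven")
    expect_equal(sum(f1$importance), f1$r2, tolerance = 1e-8)
  }
  expect_gte(acc[["copy"]], 9)
  expect_gte(acc[["enh"]], 9)
})

test_that("pure-noise responses stay unclassified near the nominal rate", {
  set.seed(11)
  n <- 60
  classified <- 0
  for (rep in 1:100) {
    enh <- matrix(rnorm(n * 5), n)
    cn <- sample(c(1, 1.5, 2), n, TRUE)
    f <- fit_and_classify(rnorm(n), enh, cn)
    classified <- classified + (f$class != "unclassified")
  }
  # Bonferroni over the six candidate terms keeps type I near alpha
  expect_lte(classified / 100, 0.10)
})

test_that("variance floor and covariate handling behave", {
  set.seed(12)
  n <- 40
  enh <- matrix(rnorm(n * 2), n)
  cn <- runif(n, 0.5, 3)
  y <- 3 * cn + rnorm(n, 0, 0.3)
  f <- fit_and_classify(y, enh, cn, variance_floor = 1)
  expect_false(f$excluded)    # strong CN effect -> variance > 1
  f2 <- fit_and_classify(rnorm(n, 0, 0.2), enh, cn)
  expect_true(f2$excluded)
  # a cancer-type covariate that carries the signal removes it
  type <- factor(rep(c("A", "B"), each = n / 2))
  y3 <- ifelse(type == "A", 0, 5) + rnorm(n, 0, 0.5)
  f3 <- fit_and_classify(y3, enh, cn, covariate = type)
  expect_equal(f3$class, "unclassified")
})
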