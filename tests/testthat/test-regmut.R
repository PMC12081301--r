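test_that("allele frequencies and the strict coverage filter", {
  v <- data.frame(chrom = "chrV", pos = c(1000, 3000, 5000, 7000),
                  ref = "C", alt = "T",
                  wgs_ref = c(20, 15, 16, 20), wgs_alt = c(11, 15, 15, 11),
                  hichip_ref = c(3, 20, 0, 16), hichip_alt = c(17, 11, 0, 15))
  af <- allele_frequencies(v)
  expect_equal(af$af_hichip[1], 0.85)    # 17 / (17 + 3)
  expect_false(af$passes_coverage[1])    # HiChIP depth 20 is not > 30
  # depth exactly 30 in WGS fails the > 30 rule
  expect_equal(af$wgs_ref[2] + af$wgs_alt[2], 30)
  expect_false(af$passes_coverage[2])
  # zero depth: AF missing, coverage fails
  expect_true(is.na(af$af_hichip[3]))
  expect_false(af$passes_coverage[3])
  # 31 / 31 passes the strict boundary
  expect_true(af$passes_coverage[4])
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  # balanced table: no association
  v <- data.frame(chrom = "c", pos = 0, ref = "A", alt = "G",
                  wgs_ref = 10, wgs_alt = 10, hichip_ref = 10, hichip_alt = 10)
  r <- allelic_enrichment_test(allele_frequencies(v, min_depth = 5))
  expect_equal(r$fisher_p, 1)
  # oracle across all 2x2 tables with total <= 60 (margins from a grid)
  set.seed(40)
  for (k in 1:40) {
    cell <- as.integer(rmultinom(1, sample(8:60, 1), rep(1 / 4, 4)))
    got <- fisher.test(matrix(cell, 2, byrow = TRUE))$p.value
    want <- fisher_enum(cell[1], cell[2], cell[3], cell[4])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # the specific 16/4 vs 4/16 example
  expect_equal(fisher.test(matrix(c(16, 4, 4, 16), 2, byrow = TRUE))$p.value,
               fisher_enum(16, 4, 4, 16), tolerance = 1e-12)
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               c(0.04, 0.04, 0.04, 0.04))
  # monotone in p-rank after the step-up minimum
  set.seed(41)
  p <- sort(runif(20))
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q) >= 0))
})

test_that("local signal contrast window geometry and t score", {
  samples <- paste0("s", 1:5)
  counts <- matrix(50, 40, 5, dimnames = list(NULL, samples))
  tr <- signal_track("chrV", 9000, 100, counts)
  sf <- setNames(rep(1, 5), samples)
  # variant at 10,000: window [9000, 11000), 20 bins of 100 bp
  r <- local_signal_contrast(10000, tr, sf, NULL, carriers = "s1")
  expect_equal(r$window$start, 9000)
  expect_equal(r$window$end, 11000)
  expect_equal(nrow(r$bins), 20)
  # identical carrier and non-carrier signal -> t = 0
  expect_equal(r$t_score, 0)
  # a carrier-specific boost gives a positive t
  counts2 <- counts; counts2[1:20, "s1"] <- 150
  r2 <- local_signal_contrast(10000, signal_track("chrV", 9000, 100, counts2),
                              sf, NULL, carriers = "s1")
  expect_gt(r2$t_score, 0)
  expect_lt(r2$p, 0.01)
  # misaligned or out-of-range windows error
  expect_error(local_signal_contrast(10050, tr, sf, NULL, "s1"), "aligned")
  expect_error(local_signal_contrast(500, tr, sf, NULL, "s1"), "beyond")
  expect_error(local_signal_contrast(10000, tr, sf, NULL,
                                     carriers = samples[1:4]),
               "non-carrier")
})

test_that("nominated variants recover planted regulatory variants", {
  lib <- setNames(runif(30, 0.5, 2), paste0("S", 1:30))
  sens <- fdr <- numeric(3)
  for (k in 1:3) {
    v <- simulate_allele_counts(300, c(60, 200), regulatory_fraction = 0.05,
                                af_shift = 0.3, seed = 50 + k,
                                samples = names(lib))
    tr <- simulate_variant_track(v, lib, signal_boost = 3, seed = 60 + k)
    nom <- nominate_regulatory_variants(v, tr, lib)
    sens[k] <- mean(nom$nominated[nom$regulatory])
    fdr[k] <- if (sum(nom$nominated)) mean(!nom$regulatory[nom$nominated]) else 0
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.1)
})

test_that("PWM score distribution DP matches exhaustive enumeration", {
  for (w in c(2, 4, 6)) {
    pwm <- random_pwm(w, seed = w)
    got <- pwm_score_distribution(pwm)
    want <- pwm_dist_enum(pwm)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$prob, want$prob, tolerance = 1e-12)
    expect_equal(sum(got$prob), 1, tolerance = 1e-12)
  }
  # p-value is the upper tail of the distribution
  pwm <- random_pwm(3, seed = 99)
  d <- pwm_score_distribution(pwm)
  mid <- d$score[ceiling(nrow(d) / 2)]
  expect_equal(pwm_score_pvalue(d, mid), sum(d$prob[d$score >= mid - 1e-9]))
  expect_equal(pwm_score_pvalue(d, min(d$score)), 1, tolerance = 1e-12)
})

test_that("motif gain detects variant-created consensus sites", {
  # consensus PWM matching the alt 6-mer around the variant position
  consensus_pwm <- function(seq) {
    m <- matrix(0.01, 4, nchar(seq), dimnames = list(c("A", "C", "G", "T")))
    for (i in seq_len(nchar(seq))) m[substr(seq, i, i), i] <- 0.97
    m
  }
  ref <- "AAAAAAAAAACAAAAAAAAAA"   # variant base C at position 11
  alt <- "AAAAAAAAAATAAAAAAAAAA"   # C>T
  pwms <- list(gain = consensus_pwm("AAATAA"), none = consensus_pwm("GGGGGG"))
  r <- motif_gain(ref, alt, pwms, p_cutoff = 0.001)
  expect_true(r$gained[r$motif == "gain"])
  expect_false(r$hit_ref[r$motif == "gain"])
  expect_false(r$gained[r$motif == "none"])
  # loss is the converse
  r2 <- motif_gain(alt, ref, list(lost = consensus_pwm("AAATAA")),
                   p_cutoff = 0.001)
  expect_true(r2$lost[1])
  # placements not covering the variant are unaffected: identical flanks
  # can't produce a gain for a motif matching only the flank
  r3 <- motif_gain(ref, alt, list(flank = consensus_pwm("AAAAAA")),
                   p_cutoff = 0.001)
  expect_false(r3$gained[1] || r3$lost[1])
  # non-ACGT context is skipped
  expect_message(r4 <- motif_gain(sub("C", "N", ref), alt, pwms), "non-ACGT")
  expect_null(r4)
})

test_that("reverse-complement scanning is an involution", {
  set.seed(70)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T"), 21, TRUE),
                             collapse = ""))
  pwms <- list(m1 = random_pwm(5, 1), m2 = random_pwm(4, 2))
  rc_str <- function(s) paste(rev(chartr("ACGT", "TGCA",
                                         strsplit(s, "")[[1]])), collapse = "")
  for (s in seqs) {
    a <- motif_gain(s, rc_str(s), pwms, p_cutoff = 0.05)
    # scanning a sequence and its reverse complement yields identical hits
    expect_equal(a$hit_ref, a$hit_alt)
  }
})
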