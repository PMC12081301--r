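test_that("neoloop counting and per-Mb normalization are exact", {
  iv <- genomic_intervals("chrA", 0, 2e6)
  bp <- data.frame(chrom = "chrA", pos = 1e6)
  amp <- amplicon("a1", "cyclic", iv, bp)
  res <- 1e4
  mk <- function(s1, s2) data.frame(chrom = "chrA", start1 = s1,
                                    end1 = s1 + res, start2 = s2,
                                    end2 = s2 + res, signal = 1)
  loops <- canonicalize_loops(rbind(
    mk(9.0e5, 1.2e6),   # spans the breakpoint
    mk(9.5e5, 1.1e6),   # spans it
    mk(9.6e5, 1.3e6),   # spans it
    mk(9.7e5, 1.45e6),  # spans it
    mk(1e5, 3e5),       # both anchors left of the breakpoint
    mk(1.2e6, 1.5e6),   # both anchors right
    mk(3e6, 3.3e6)),    # off the amplicon entirely
    res)
  st <- neoloop_quantify(loops, amp)
  expect_equal(st$n_loops, 6)
  expect_equal(st$n_neoloops, 4)
  expect_equal(st$neoloops_per_mb, 4 / 2)   # 2-Mb amplicon, 4 neoloops
  # invariant to loop order and to duplicated breakpoints
  amp2 <- amplicon("a1", "cyclic", iv, rbind(bp, bp, bp))
  st2 <- neoloop_quantify(loops[sample(nrow(loops)), ], amp2)
  expect_equal(st2$n_neoloops, 4)
  # a breakpoint inside an anchor does not count as spanned
  edge <- canonicalize_loops(mk(9.95e5, 1.2e6), res)  # anchor1 covers 1e6
  expect_equal(neoloop_quantify(edge, amp)$n_neoloops, 0)
  expect_error(amplicon("z", "cyclic", genomic_intervals("c", 0, 1)[0, ], bp),
               "at least one segment|zero size")
})

test_that("neoloop counts match brute force on random loops", {
  set.seed(55)
  res <- 1e4
  iv <- genomic_intervals("chrA", c(0, 3e6), c(2e6, 4e6))
  bp <- data.frame(chrom = "chrA", pos = c(5e5, 1.4e6, 3.5e6))
  amp <- amplicon("r", "complex", iv, bp)
  s1 <- sample(seq(0, 3.8e6, res), 100, TRUE)
  s2 <- s1 + sample(seq(5e4, 1e6, res), 100, TRUE)
  loops <- canonicalize_loops(data.frame(chrom = "chrA", start1 = s1,
                                         end1 = s1 + res, start2 = s2,
                                         end2 = s2 + res, signal = 1), res)
  st <- neoloop_quantify(loops, amp)
  in_amp <- function(a, b) any(a < iv$end & iv$start < b)
  brute <- 0; brute_loops <- 0
  for (i in seq_len(nrow(loops))) {
    if (!(in_amp(loops$start1[i], loops$end1[i]) &&
          in_amp(loops$start2[i], loops$end2[i]))) next
    brute_loops <- brute_loops + 1
    if (any(bp$pos >= loops$end1[i] & bp$pos < loops$start2[i]))
      brute <- brute + 1
  }
  expect_equal(st$n_loops, brute_loops)
  expect_equal(st$n_neoloops, brute)
})

test_that("planted junction-spanning loops are recovered exactly", {
  co <- small_cohort(seed = 23)
  for (id in names(co$amplicons)) {
    st <- neoloop_quantify(co$amplicon_loops[[id]], co$amplicons[[id]])
    expect_equal(st$n_neoloops, unname(co$truth$n_neoloops[id]))
    expect_equal(st$neoloops_per_mb,
                 st$n_neoloops / (co$amplicons[[id]]$size / 1e6))
  }
})

test_that("rank-sum test: exact enumeration, ties and extremes", {
  # full separation of {1,2,3} vs {4,5,6}: 2 of C(6,3)=20 assignments as extreme
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  # identical groups -> p = 1
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p, 1)
  # agreement with wilcox.test where both are exact (no ties)
  set.seed(60)
  for (k in 1:10) {
    x <- rnorm(6); y <- rnorm(5)
    expect_equal(rank_sum_test(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # shifting one group beyond the range attains the minimal p for the sizes
  x <- rnorm(4); y <- rnorm(4)
  pmin_attainable <- 2 / choose(8, 4)
  expect_equal(rank_sum_test(x, y + 100)$p, pmin_attainable)
  # large groups fall back to the tie-corrected normal approximation
  big <- rank_sum_test(rnorm(30), rnorm(30) + 1)
  expect_equal(big$method, "normal")
  expect_lt(big$p, 0.05)
})

test_that("class comparisons are BH-adjusted and skip tiny classes", {
  st <- data.frame(class = rep(c("cyclic", "linear", "BFB"), c(4, 4, 1)),
                   neoloops_per_mb = c(8, 9, 7, 10, 1, 2, 1, 2, 5))
  expect_message(tab <- class_rate_comparison(st), "skipped: BFB")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$class_a, "cyclic")
  expect_equal(tab$q, p.adjust(tab$p, "BH"))
  expect_lt(tab$p, 0.05)
})

test_that("co-amplification frequency counts samples above the CN seed cutoff", {
  mk_prof <- function(s, cn_a, cn_b) {
    seg <- data.frame(sample = s, chrom = "chr7",
                      start = c(0, 1e6), end = c(1e6, 2e6),
                      total_cn = c(cn_a, cn_b))
    cnv_profiles_from_seg(seg)[[1]]
  }
  iva <- genomic_intervals("chr7", 2e5, 4e5)
  ivb <- genomic_intervals("chr7", 1.2e6, 1.4e6)
  profs <- list(
    s1 = mk_prof("s1", 8, 10),   # both amplified
    s2 = mk_prof("s2", 8, 2),    # one only
    s3 = mk_prof("s3", 5, 5),    # both (5 > 4.5)
    s4 = mk_prof("s4", 4.5, 9),  # 4.5 is not > 4.5
    s5 = mk_prof("s5", 2, 2))
  r <- coamplification_frequency(profs, iva, ivb)
  expect_equal(r$frequency, 2 / 5)
  expect_equal(r$n_coamplified, 2L)
  # threshold above every CN -> 0
  expect_equal(coamplification_frequency(profs, iva, ivb,
                                         cn_threshold = 100)$frequency, 0)
  # no evaluable samples -> NA with a reason
  far <- genomic_intervals("chrZ", 0, 100)
  r2 <- coamplification_frequency(profs, far, ivb)
  expect_true(is.na(r2$frequency))
  expect_match(r2$reason, "no sample")
  # brute-force recount on random CN values
  set.seed(61)
  profs_r <- lapply(1:12, function(i) mk_prof(paste0("r", i),
                                              runif(1, 0, 10), runif(1, 0, 10)))
  names(profs_r) <- paste0("r", 1:12)
  r3 <- coamplification_frequency(profs_r, iva, ivb)
  want <- mean(vapply(profs_r, function(p)
    p$segments$total_cn[1] > 4.5 && p$segments$total_cn[2] > 4.5, logical(1)))
  expect_equal(r3$frequency, want)
})
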