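# Quantification of rearrangement-driven enhancer rewiring: neoloop counts
# and per-Mb rates over focal amplifications, class comparisons and
# co-amplification frequency. A neoloop is operationalized in reference
# coordinates as a loop whose anchors bracket an SV breakpoint
# (anchor1.end <= breakpoint < anchor2.start); this is exact for
# intra-segment junctions and an approximation of loop calling on rearranged
# assemblies (inter-chromosomal junctions are out of scope).

#' Construct a focal amplification (amplicon)
#'
#' @param amplicon_id identifier.
#' @param class one of "cyclic", "BFB", "complex", "linear".
#' @param intervals interval data.frame of amplified segments.
#' @param breakpoints data.frame with columns chrom, pos (junction endpoints).
#' @return object of class `Amplicon` with derived `size` (bases).
#' @export
amplicon <- function(amplicon_id, class, intervals, breakpoints) {
  class <- match.arg(class, c("cyclic", "BFB", "complex", "linear"))
  validate_intervals(intervals)
  size <- sum(intervals$end - intervals$start)
  if (size <= 0) stop("amplicon of zero size")
  structure(list(amplicon_id = amplicon_id, class = class,
                 intervals = intervals, breakpoints = breakpoints,
                 size = size),
            class = "Amplicon")
}

#' Count loops and neoloops on an amplicon
#'
#' A loop is counted for the amplicon when both anchors overlap amplicon
#' intervals; it is a neoloop when at least one breakpoint lies strictly
#' between its anchors (`anchor1.end <= pos < anchor2.start`, same
#' chromosome). The rate is neoloops per megabase of amplicon size.
#'
#' @param loops canonical loop data.frame (same chromosome(s) as the
#'   amplicon).
#' @param amp an [amplicon()].
#' @return data.frame: amplicon_id, class, n_loops, n_neoloops,
#'   neoloops_per_mb, size.
#' @export
neoloop_quantify <- function(loops, amp) {
  stopifnot(inherits(amp, "Amplicon"))
  on_amp <- overlaps_any(anchor1(loops), amp$intervals) &
    overlaps_any(anchor2(loops), amp$intervals)
  sub <- loops[on_amp, , drop = FALSE]
  bp <- unique(amp$breakpoints)
  is_neo <- vapply(seq_len(nrow(sub)), function(i) {
    any(bp$chrom == sub$chrom[i] &
          bp$pos >= sub$end1[i] & bp$pos < sub$start2[i])
  }, logical(1))
  data.frame(amplicon_id = amp$amplicon_id, class = amp$class,
             n_loops = nrow(sub), n_neoloops = sum(is_neo),
             neoloops_per_mb = sum(is_neo) / (amp$size / 1e6),
             size = amp$size, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by full enumeration of rank-sum assignments (midranks for
#' ties) when both groups have at most `exact_max` observations; otherwise
#' the normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @param exact_max enumeration limit per group (default 10).
#' @return list with `p`, `statistic` (rank sum of `x`), `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))   # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- combn(r, n1, sum)
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(list(p = p, statistic = w, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - mu) / sqrt(sigma2)
  list(p = min(1, 2 * pnorm(-abs(z))), statistic = w, method = "normal")
}

#' Pairwise comparison of neoloop rates between amplicon classes
#'
#' Two-sided rank-sum tests on `neoloops_per_mb` for every pair of classes
#' with at least `min_n` amplicons each, BH-adjusted across pairs. Pairs with
#' an underpopulated class are skipped with a message.
#'
#' @param stats data.frame of per-amplicon rows from [neoloop_quantify()].
#' @param min_n minimum amplicons per class (default 2).
#' @return data.frame: class_a, class_b, n_a, n_b, median_a, median_b, p, q.
#' @export
class_rate_comparison <- function(stats, min_n = 2) {
  classes <- split(stats$neoloops_per_mb, stats$class)
  ok <- names(classes)[lengths(classes) >= min_n]
  skipped <- setdiff(names(classes), ok)
  if (length(skipped))
    message("class(es) with < ", min_n, " amplicons skipped: ",
            paste(skipped, collapse = ", "))
  if (length(ok) < 2) return(NULL)
  pairs <- combn(sort(ok), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tst <- rank_sum_test(classes[[a]], classes[[b]])
    data.frame(class_a = a, class_b = b,
               n_a = length(classes[[a]]), n_b = length(classes[[b]]),
               median_a = median(classes[[a]]), median_b = median(classes[[b]]),
               p = tst$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Co-amplification frequency of two intervals across samples
#'
#' Fraction of samples in which both intervals have total CN above
#' `cn_threshold` (the seed-amplicon CN cutoff). The CN of an interval is the
#' length-weighted mean total CN over overlapping segments; samples with no
#' CN call at either interval are excluded from the denominator.
#'
#' @param profiles named list of `CnvProfile` objects.
#' @param interval_a,interval_b single-row interval data.frames.
#' @param cn_threshold amplification cutoff (default 4.5).
#' @return list with `frequency` (NA with `reason` when no sample is
#'   evaluable), `n_coamplified`, `n_evaluable`.
#' @export
coamplification_frequency <- function(profiles, interval_a, interval_b,
                                      cn_threshold = 4.5) {
  cn_at <- function(pr, iv) {
    segs <- pr$segments
    hits <- overlap_map(iv, segs)[[1]]
    if (!length(hits)) return(NA_real_)
    ov <- pmin(iv$end, segs$end[hits]) - pmax(iv$start, segs$start[hits])
    sum(ov * segs$total_cn[hits]) / sum(ov)
  }
  cn_a <- vapply(profiles, cn_at, numeric(1), iv = interval_a)
  cn_b <- vapply(profiles, cn_at, numeric(1), iv = interval_b)
  ok <- !is.na(cn_a) & !is.na(cn_b)
  if (!any(ok))
    return(list(frequency = NA_real_, n_coamplified = 0L, n_evaluable = 0L,
                reason = "no sample with CN calls at both intervals"))
  both <- cn_a[ok] > cn_threshold & cn_b[ok] > cn_threshold
  list(frequency = mean(both), n_coamplified = sum(both),
       n_evaluable = sum(ok), reason = NA_character_)
}
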