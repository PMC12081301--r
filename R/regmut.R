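# Nomination of noncoding regulatory mutations from three lines of evidence:
# allele-specific enrichment in H3K27ac HiChIP reads over WGS (Fisher exact +
# BH), a local H3K27ac signal contrast between carrier and non-carrier
# samples in a 2-kb window (20 x 100-bp bins, Welch t), and TF motif gain in
# the 21-bp sequence context (exact PWM score-distribution p-values).

#' Per-assay allele frequencies and coverage filter
#'
#' @param variants data.frame with columns chrom, pos (0-based), ref, alt,
#'   wgs_ref, wgs_alt, hichip_ref, hichip_alt.
#' @param min_depth both assays must exceed this depth (strict; default 30).
#' @return the input with added af_wgs, af_hichip, passes_coverage.
#' @export
allele_frequencies <- function(variants, min_depth = 30) {
  need <- c("wgs_ref", "wgs_alt", "hichip_ref", "hichip_alt")
  stopifnot(all(need %in% names(variants)))
  if (any(unlist(variants[need]) < 0, na.rm = TRUE)) stop("negative read counts")
  dw <- variants$wgs_ref + variants$wgs_alt
  dh <- variants$hichip_ref + variants$hichip_alt
  variants$af_wgs <- ifelse(dw > 0, variants$wgs_alt / dw, NA_real_)
  variants$af_hichip <- ifelse(dh > 0, variants$hichip_alt / dh, NA_real_)
  variants$passes_coverage <- !is.na(dw) & !is.na(dh) &
    dw > min_depth & dh > min_depth
  variants
}

#' Allelic enrichment test (Fisher exact + BH)
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[wgs_ref, wgs_alt], [hichip_ref, hichip_alt]]` for every variant passing
#' coverage, BH-adjusted across all tested variants. The direction flag is
#' TRUE when the HiChIP allele frequency exceeds the WGS allele frequency.
#'
#' @param variants output of [allele_frequencies()].
#' @return the input with added fisher_p, fisher_q, hichip_enriched (all NA
#'   for variants failing coverage).
#' @export
allelic_enrichment_test <- function(variants) {
  stopifnot("passes_coverage" %in% names(variants))
  variants$fisher_p <- NA_real_
  idx <- which(variants$passes_coverage)
  variants$fisher_p[idx] <- vapply(idx, function(i) {
    tab <- matrix(c(variants$wgs_ref[i], variants$wgs_alt[i],
                    variants$hichip_ref[i], variants$hichip_alt[i]),
                  2, 2, byrow = TRUE)
    fisher.test(tab)$p.value
  }, numeric(1))
  variants$fisher_q <- NA_real_
  variants$fisher_q[idx] <- p.adjust(variants$fisher_p[idx], method = "BH")
  variants$hichip_enriched <- variants$af_hichip > variants$af_wgs
  variants
}

#' Construct a binned 1D signal track
#'
#' @param chrom chromosome name.
#' @param start track start offset (0-based).
#' @param bin_size bin width in bases (100 for the mutation-window analysis).
#' @param counts bin x sample matrix of raw signal counts.
#' @return object of class `SignalTrack`.
#' @export
signal_track <- function(chrom, start, bin_size, counts) {
  stopifnot(is.matrix(counts), start >= 0, bin_size > 0)
  structure(list(chrom = chrom, start = start, bin_size = bin_size,
                 counts = counts),
            class = "SignalTrack")
}

#' Local H3K27ac signal contrast around a variant
#'
#' The 2-kb window centered at the variant position (`[pos - 1000,
#' pos + 1000)`) is tiled into 20 bins of 100 bp. Per-bin signal is divided by
#' each sample's size factor and by its relative CN clamped at 1 (amplified
#' features only), then carrier bin values are compared with non-carrier bin
#' values by a two-sided Welch t-test; the t score is positive when the
#' carrier mean is higher.
#'
#' @param pos variant position (0-based offset).
#' @param track a [signal_track()] with 100-bp bins covering the window.
#' @param sf named per-sample size factors.
#' @param profiles named list of `CnvProfile` (NULL skips CN correction).
#' @param carriers character vector of carrier sample names.
#' @param n_bins,bin_size window geometry (defaults 20 x 100 bp).
#' @param rel_cn optional precomputed per-sample relative CN of the window
#'   (named vector), overriding the lookup in `profiles`.
#' @return list with `t_score`, `p`, `carrier_mean`, `noncarrier_mean`,
#'   `window` (interval data.frame), `bins` (normalized bin x sample matrix).
#' @export
local_signal_contrast <- function(pos, track, sf, profiles = NULL, carriers,
                                  n_bins = 20, bin_size = 100, rel_cn = NULL) {
  stopifnot(inherits(track, "SignalTrack"), track$bin_size == bin_size)
  half <- n_bins * bin_size / 2
  w_start <- pos - half; w_end <- pos + half
  if (w_start < track$start ||
      w_end > track$start + nrow(track$counts) * bin_size)
    stop("variant window extends beyond the signal track")
  if ((w_start - track$start) %% bin_size != 0)
    stop("variant window is not aligned to the track bins")
  first <- (w_start - track$start) / bin_size + 1
  bins <- track$counts[first:(first + n_bins - 1), , drop = FALSE]
  samples <- colnames(bins)
  stopifnot(all(samples %in% names(sf)))
  norm <- sweep(bins, 2, sf[samples], "/")
  if (is.null(rel_cn) && !is.null(profiles)) {
    win <- data.frame(chrom = track$chrom, start = w_start, end = w_end)
    rel_cn <- vapply(samples, function(s) relative_cn(profiles[[s]], win),
                     numeric(1))
  }
  if (!is.null(rel_cn)) norm <- sweep(norm, 2, pmax(rel_cn[samples], 1), "/")
  carr <- intersect(samples, carriers)
  non <- setdiff(samples, carriers)
  if (length(carr) < 1 || length(non) < 2)
    stop("need >= 1 carrier and >= 2 non-carrier samples")
  xc <- as.vector(norm[, carr, drop = FALSE])
  xn <- as.vector(norm[, non, drop = FALSE])
  if (sd(xc, na.rm = TRUE) == 0 && sd(xn, na.rm = TRUE) == 0) {
    # degenerate constant groups: no evidence (equal) or infinite contrast
    d <- mean(xc, na.rm = TRUE) - mean(xn, na.rm = TRUE)
    tt <- if (d == 0) list(statistic = c(t = 0), p.value = 1)
          else list(statistic = c(t = sign(d) * Inf), p.value = 0)
  } else {
    tt <- t.test(xc, xn)
  }
  list(t_score = unname(tt$statistic), p = tt$p.value,
       carrier_mean = mean(xc, na.rm = TRUE),
       noncarrier_mean = mean(xn, na.rm = TRUE),
       window = data.frame(chrom = track$chrom, start = w_start, end = w_end),
       bins = norm)
}

#' Nominate regulatory variants by combined evidence
#'
#' Runs [allele_frequencies()], [allelic_enrichment_test()] and
#' [local_signal_contrast()] (BH-adjusted across variants) and flags variants
#' satisfying: coverage pass, fisher_q < `alpha`, HiChIP AF > WGS AF, and
#' positive t score.
#'
#' @param variants variant data.frame (see [allele_frequencies()]); needs a
#'   `carrier` column naming the carrier sample of each variant (comma
#'   separated for several).
#' @param track,sf,profiles passed to [local_signal_contrast()].
#' @param alpha FDR level for the Fisher q-value (default 0.05).
#' @param min_depth coverage filter (default 30).
#' @return the variant table with test columns plus `t_score`, `t_p`, `t_q`,
#'   `nominated`.
#' @export
nominate_regulatory_variants <- function(variants, track, sf, profiles = NULL,
                                         alpha = 0.05, min_depth = 30) {
  v <- allele_frequencies(variants, min_depth)
  v <- allelic_enrichment_test(v)
  samples <- colnames(track$counts)
  rel_cn_mat <- NULL
  if (!is.null(profiles)) {
    wins <- data.frame(chrom = track$chrom, start = v$pos - 1000,
                       end = v$pos + 1000)
    rel_cn_mat <- sapply(samples, function(s)
      relative_cn(profiles[[s]], wins))
    if (!is.matrix(rel_cn_mat)) rel_cn_mat <- matrix(rel_cn_mat, nrow = nrow(v),
                                                     dimnames = list(NULL, samples))
  }
  contrasts <- lapply(seq_len(nrow(v)), function(i) {
    local_signal_contrast(v$pos[i], track, sf, profiles = NULL,
                          carriers = strsplit(v$carrier[i], ",")[[1]],
                          rel_cn = if (is.null(rel_cn_mat)) NULL
                                   else rel_cn_mat[i, ])
  })
  v$t_score <- vapply(contrasts, `[[`, numeric(1), "t_score")
  v$t_p <- vapply(contrasts, `[[`, numeric(1), "p")
  v$t_q <- p.adjust(v$t_p, method = "BH")
  v$nominated <- v$passes_coverage & !is.na(v$fisher_q) & v$fisher_q < alpha &
    v$hichip_enriched & v$t_score > 0
  v
}

# ---- PWM scanning with exact score-distribution p-values ---------------------

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(seq_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[seq_chars]))
}

#' Read JASPAR-style PWMs from matrix text
#'
#' Format: records starting with ">motif_id", followed by four lines
#' "A  [ 1 2 3 ]" (or bare numbers) in ACGT order; counts are converted to
#' per-position probabilities.
#'
#' @param path file path.
#' @return named list of 4 x width probability matrices (rownames ACGT).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  stopifnot(length(starts) >= 1)
  ends <- c(starts[-1] - 1, length(lines))
  out <- list()
  for (k in seq_along(starts)) {
    id <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    block <- lines[(starts[k] + 1):ends[k]]
    block <- block[nzchar(trimws(block))][1:4]
    rows <- lapply(block, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    m <- do.call(rbind, rows)
    rownames(m) <- DNA_BASES
    out[[id]] <- sweep(m, 2, colSums(m), "/")
  }
  out
}

pwm_check <- function(pwm) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4)
  if (is.null(rownames(pwm))) rownames(pwm) <- DNA_BASES
  if (any(abs(colSums(pwm) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  pwm
}

# log-likelihood-ratio score matrix vs background
pwm_llr <- function(pwm, bg = rep(0.25, 4), pseudo = 1e-4) {
  pwm <- pwm_check(pwm)
  log2(sweep(pwm + pseudo, 2, colSums(pwm + pseudo), "/") / bg)
}

#' Exact PWM score distribution under a background model
#'
#' Dynamic programme over motif positions: the distribution of the
#' log-likelihood-ratio score of a random background sequence is built by
#' convolving the per-position score/probability pairs, merging states whose
#' accumulated scores agree after rounding to `digits` decimals.
#'
#' @param pwm 4 x width probability matrix.
#' @param bg background base frequencies (default uniform).
#' @param digits score rounding used to merge DP states (default 10).
#' @return data.frame with columns `score` (ascending) and `prob`.
#' @export
pwm_score_distribution <- function(pwm, bg = rep(0.25, 4), digits = 10) {
  S <- pwm_llr(pwm, bg)
  dist <- c(`0` = 1)   # named by rounded score
  scores <- c(0)
  for (pos in seq_len(ncol(S))) {
    new_scores <- as.vector(outer(scores, S[, pos], `+`))
    new_probs <- as.vector(outer(unname(dist), bg, `*`))
    key <- format(round(new_scores, digits), digits = 15)
    agg <- tapply(new_probs, key, sum)
    rep_score <- tapply(new_scores, key, `[`, 1)
    dist <- as.numeric(agg)
    scores <- as.numeric(rep_score)
    names(dist) <- names(agg)
  }
  ord <- order(scores)
  data.frame(score = scores[ord], prob = unname(dist[ord]))
}

#' P-value of a PWM score under the background model
#' @param dist output of [pwm_score_distribution()].
#' @param score observed log-likelihood-ratio score.
#' @return `P(S >= score)` under the background model.
#' @export
pwm_score_pvalue <- function(dist, score) {
  sum(dist$prob[dist$score >= score - 1e-9])
}

pwm_score_at <- function(S, seq_chars, offset) {
  idx <- match(seq_chars[offset:(offset + ncol(S) - 1)], DNA_BASES)
  sum(S[cbind(idx, seq_len(ncol(S)))])
}

# best (minimum) placement p-value of a PWM over a sequence, both strands
pwm_best_pvalue <- function(pwm, seq_chars, bg, dist) {
  S <- pwm_llr(pwm, bg)
  w <- ncol(S)
  n <- length(seq_chars)
  if (n < w) return(1)
  best <- 1
  rc <- revcomp(seq_chars)
  for (off in seq_len(n - w + 1)) {
    for (sq in list(seq_chars, rc)) {
      p <- pwm_score_pvalue(dist, pwm_score_at(S, sq, off))
      if (p < best) best <- p
    }
  }
  best
}

#' Motif gain and loss caused by a variant
#'
#' Scans the 21-bp reference and alternate sequence contexts (variant base at
#' position 11) on both strands at every offset with each PWM. A hit is any
#' placement whose score p-value, from the exact score distribution under the
#' background model, is at or below `p_cutoff`. A motif is gained when it hits
#' the alternate but not the reference context, and lost in the converse case.
#'
#' @param ref_context,alt_context 21-base strings (characters ACGT).
#' @param pwms named list of 4 x width probability matrices.
#' @param p_cutoff placement p-value cutoff (default 0.01).
#' @param bg background base frequencies (default uniform).
#' @return data.frame: motif, p_ref, p_alt, hit_ref, hit_alt, gained, lost;
#'   NULL (with a message) if a context contains non-ACGT characters.
#' @export
motif_gain <- function(ref_context, alt_context, pwms, p_cutoff = 0.01,
                       bg = rep(0.25, 4)) {
  refc <- strsplit(toupper(ref_context), "")[[1]]
  altc <- strsplit(toupper(alt_context), "")[[1]]
  stopifnot(length(refc) == 21, length(altc) == 21)
  if (!all(c(refc, altc) %in% DNA_BASES)) {
    message("variant context contains non-ACGT characters; skipped")
    return(NULL)
  }
  rows <- lapply(names(pwms), function(id) {
    pwm <- pwms[[id]]
    dist <- pwm_score_distribution(pwm, bg)
    p_ref <- pwm_best_pvalue(pwm, refc, bg, dist)
    p_alt <- pwm_best_pvalue(pwm, altc, bg, dist)
    data.frame(motif = id, p_ref = p_ref, p_alt = p_alt,
               hit_ref = p_ref <= p_cutoff, hit_alt = p_alt <= p_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gained <- out$hit_alt & !out$hit_ref
  out$lost <- out$hit_ref & !out$hit_alt
  out
}
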