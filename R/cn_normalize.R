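# Library-size normalization and copy-number correction of peak/loop signal.
#
# The CN rules follow the convention that the "relative CN" of a feature is
# the length-weighted mean of total_cn / ploidy over the CN segments it
# overlaps, so the sample-wide average is 1; correction only divides signal
# for amplified features (relative CN > 1), and features on CN = 0 segments or
# without a CN call become missing.

#' Median-of-ratios size factors
#'
#' The reference is the per-row geometric mean computed over rows positive in
#' every sample; each sample's factor is the median ratio of its counts to the
#' reference over those rows.
#'
#' @param counts non-negative feature x sample matrix.
#' @return positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  use <- rowSums(counts > 0 & !is.na(counts)) == ncol(counts)
  if (!any(use))
    stop("no feature is positive in all samples; supply a pseudo-reference ",
         "(e.g. add a pseudocount) before calling size_factors")
  logref <- rowMeans(log(counts[use, , drop = FALSE]))
  sf <- apply(counts[use, , drop = FALSE], 2,
              function(cnt) exp(median(log(cnt) - logref)))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("non-finite size factors")
  sf
}

#' Divide each sample column by its size factor
#' @param counts feature x sample matrix.
#' @param sf size factors from [size_factors()].
#' @return normalized matrix.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Build a per-sample CNV profile with ploidy and segmentation QC
#'
#' Ploidy is the length-weighted mean total CN across segments. Samples whose
#' segment count exceeds `hyperseg_threshold` are flagged hyper-segmented
#' (noisy calls that should be excluded from downstream analysis).
#'
#' @param sample_id sample name.
#' @param segments data.frame chrom/start/end/total_cn (internal coordinates).
#' @param hyperseg_threshold flag when `n_segments` exceeds this (default 1000).
#' @return object of class `CnvProfile`.
#' @export
cnv_profile <- function(sample_id, segments, hyperseg_threshold = 1000) {
  validate_intervals(segments)
  if (!nrow(segments)) stop("CNV profile needs at least one segment")
  len <- segments$end - segments$start
  if (sum(len) <= 0) stop("zero total segment length")
  ploidy <- sum(len * segments$total_cn) / sum(len)
  structure(list(sample_id = sample_id, segments = segments, ploidy = ploidy,
                 n_segments = nrow(segments),
                 hyper_segmented = nrow(segments) > hyperseg_threshold),
            class = "CnvProfile")
}

#' @export
print.CnvProfile <- function(x, ...) {
  cat(sprintf("CnvProfile %s: %d segments, ploidy %.3f%s\n", x$sample_id,
              x$n_segments, x$ploidy,
              if (x$hyper_segmented) " [hyper-segmented]" else ""))
  invisible(x)
}

#' Build CnvProfiles for every sample in a SEG table
#' @param seg data.frame from [read_seg()].
#' @param hyperseg_threshold passed to [cnv_profile()].
#' @return named list of `CnvProfile` objects.
#' @export
cnv_profiles_from_seg <- function(seg, hyperseg_threshold = 1000) {
  lapply(split(seg, seg$sample), function(s)
    cnv_profile(s$sample[1], s[c("chrom", "start", "end", "total_cn")],
                hyperseg_threshold))
}

#' Relative CN of features under a CNV profile
#'
#' Length-weighted mean of total_cn / ploidy over the segments each feature
#' overlaps. Features overlapping a CN = 0 segment, or with no overlapping
#' segment at all, get `NA`.
#'
#' @param profile a `CnvProfile`.
#' @param features interval data.frame.
#' @return numeric vector (length `nrow(features)`), NA where undefined.
#' @export
relative_cn <- function(profile, features) {
  stopifnot(inherits(profile, "CnvProfile"))
  validate_intervals(features)
  segs <- profile$segments
  hits <- overlap_map(features, segs)
  vapply(seq_len(nrow(features)), function(i) {
    s <- hits[[i]]
    if (!length(s)) return(NA_real_)
    if (any(segs$total_cn[s] == 0)) return(NA_real_)
    ov <- pmin(features$end[i], segs$end[s]) - pmax(features$start[i], segs$start[s])
    sum(ov * segs$total_cn[s] / profile$ploidy) / sum(ov)
  }, numeric(1))
}

#' Copy-number correction of normalized peak or loop signal
#'
#' Peaks: signal divided by `max(r, 1)` where r is the feature's relative CN
#' (so only amplified features are corrected). Loops: divided by
#' `max(r1, 1) * max(r2, 1)` over the two anchors. Features with undefined
#' relative CN (CN 0 or no call) become `NA` for that sample.
#'
#' @param signal size-factor-normalized feature x sample matrix; column names
#'   must match the names of `profiles`.
#' @param features for mode "peak": interval data.frame (one row per matrix
#'   row); for mode "loop": canonical loop data.frame.
#' @param profiles named list of `CnvProfile` objects (one per sample).
#' @param mode "peak" or "loop".
#' @return corrected matrix with `NA` where CN is undefined.
#' @export
cn_correct <- function(signal, features, profiles, mode = c("peak", "loop")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(signal))
  missing_samp <- setdiff(colnames(signal), names(profiles))
  if (length(missing_samp))
    stop("no CNV profile for sample(s): ", paste(missing_samp, collapse = ", "))
  n_feat <- if (mode == "peak") nrow(features) else nrow(features)
  stopifnot(nrow(signal) == n_feat)
  out <- signal
  for (s in colnames(signal)) {
    pr <- profiles[[s]]
    if (mode == "peak") {
      r <- relative_cn(pr, features)
      denom <- pmax(r, 1)
    } else {
      r1 <- relative_cn(pr, anchor1(features))
      r2 <- relative_cn(pr, anchor2(features))
      denom <- pmax(r1, 1) * pmax(r2, 1)
    }
    out[, s] <- signal[, s] / denom   # NA denom -> NA, as required
  }
  out
}

#' CN-adjusted peak count for expression regression
#'
#' The peak predictor entering the expression model is
#' `normalized_count / (relative_cn * 2 + 1)`, damping (rather than fully
#' removing) the CN contribution so the enhancer term retains signal at
#' unamplified loci. The denominator is always >= 1.
#'
#' @param normalized_count size-factor-normalized peak count (>= 0).
#' @param rel_cn ploidy-corrected relative CN (>= 0).
#' @return adjusted count.
#' @export
regression_peak_normalize <- function(normalized_count, rel_cn) {
  stopifnot(all(normalized_count >= 0, na.rm = TRUE),
            all(rel_cn >= 0, na.rm = TRUE))
  normalized_count / (rel_cn * 2 + 1)
}
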