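# Deconvolution of enhancer-promoter loops into tumor-microenvironment cell
# types using per-cell-type pseudobulk scATAC peak sets, and correlation of
# EIS with cell fractions across samples.

#' Classify E-P loops by cell-type specificity
#'
#' Rules, applied per loop of one sample:
#' * cell-type-specific: the promoter anchor overlaps both an H3K27ac peak and
#'   at least one scATAC peak, and the enhancer anchor overlaps an H3K27ac
#'   peak and scATAC peaks of exactly one cell type;
#' * shared: promoter as above, enhancer anchor has H3K27ac and scATAC support
#'   in more than one cell type;
#' * ambiguous: neither anchor overlaps any scATAC peak, or the evidence fits
#'   none of the rules (the reason is recorded).
#'
#' The whole sample is skipped (empty result with a message) when it has fewer
#' than `min_noncancer_cells` noncancer cells, since pseudobulk peak calling
#' in minor populations is underpowered below that.
#'
#' @param ep_loops loop data.frame annotated by [classify_loops()]; all rows
#'   must be E-P.
#' @param h3k27ac_peaks interval data.frame of bulk H3K27ac peaks.
#' @param celltype_peaks named list of interval data.frames, one per cell
#'   type's pseudobulk scATAC peak set.
#' @param cell_counts named integer vector of cells per cell type in this
#'   sample; the name given by `cancer_label` is treated as the malignant
#'   population.
#' @param min_noncancer_cells threshold for skipping the sample (default 110).
#' @param cancer_label name of the malignant cell type (default "cancer").
#' @return data.frame: loop_id, class ("specific"/"shared"/"ambiguous"),
#'   cell_type (for specific loops), reason, n_celltypes_enhancer.
#' @export
classify_loop_specificity <- function(ep_loops, h3k27ac_peaks, celltype_peaks,
                                      cell_counts, min_noncancer_cells = 110,
                                      cancer_label = "cancer") {
  if (!all(as.character(ep_loops$annotation) == "E-P"))
    stop("classify_loop_specificity expects E-P loops only")
  empty <- data.frame(loop_id = integer(0), class = character(0),
                      cell_type = character(0), reason = character(0),
                      n_celltypes_enhancer = integer(0))
  noncancer <- sum(cell_counts[setdiff(names(cell_counts), cancer_label)])
  if (noncancer < min_noncancer_cells) {
    message("sample skipped: ", noncancer, " noncancer cells < ",
            min_noncancer_cells)
    return(empty)
  }
  # orient anchors: promoter side vs enhancer side
  prom_is_1 <- ep_loops$anchor1_class == "P"
  prom <- anchor1(ep_loops); enh <- anchor2(ep_loops)
  prom[!prom_is_1, ] <- anchor2(ep_loops)[!prom_is_1, ]
  enh[!prom_is_1, ] <- anchor1(ep_loops)[!prom_is_1, ]
  prom_h3 <- overlaps_any(prom, h3k27ac_peaks)
  enh_h3 <- overlaps_any(enh, h3k27ac_peaks)
  ct_names <- sort(names(celltype_peaks))   # listing-order invariant
  prom_ct <- sapply(ct_names, function(ct) overlaps_any(prom, celltype_peaks[[ct]]))
  enh_ct <- sapply(ct_names, function(ct) overlaps_any(enh, celltype_peaks[[ct]]))
  if (!is.matrix(prom_ct)) prom_ct <- matrix(prom_ct, nrow = nrow(ep_loops))
  if (!is.matrix(enh_ct)) enh_ct <- matrix(enh_ct, nrow = nrow(ep_loops))
  n_prom <- rowSums(prom_ct); n_enh <- rowSums(enh_ct)
  cls <- character(nrow(ep_loops)); ctype <- NA_character_; reason <- character(nrow(ep_loops))
  ctype <- rep(NA_character_, nrow(ep_loops))
  for (i in seq_len(nrow(ep_loops))) {
    if (n_prom[i] == 0 && n_enh[i] == 0) {
      cls[i] <- "ambiguous"; reason[i] <- "no_scatac_peak_at_either_anchor"
    } else if (prom_h3[i] && n_prom[i] >= 1 && enh_h3[i] && n_enh[i] == 1) {
      cls[i] <- "specific"
      ctype[i] <- ct_names[which(enh_ct[i, ])]
      reason[i] <- "uniquely_accessible_enhancer"
    } else if (prom_h3[i] && n_prom[i] >= 1 && enh_h3[i] && n_enh[i] > 1) {
      cls[i] <- "shared"; reason[i] <- "enhancer_accessible_in_multiple_celltypes"
    } else {
      cls[i] <- "ambiguous"; reason[i] <- "evidence_matches_no_rule"
    }
  }
  data.frame(loop_id = seq_len(nrow(ep_loops)), class = cls, cell_type = ctype,
             reason = reason, n_celltypes_enhancer = n_enh,
             stringsAsFactors = FALSE)
}

#' Correlate EIS with cell fractions across samples
#'
#' Spearman correlation (average ranks on ties) between a loop's
#' enhancer interaction signal and a cell-type fraction across samples; the
#' record passes when rho meets `rho_cutoff`.
#'
#' @param eis per-sample EIS values.
#' @param fraction per-sample cell fractions (same samples, same order).
#' @param rho_cutoff pass threshold (default 0.30; 0.25 is the laxer
#'   alternative).
#' @return list with `rho`, `pass`, `n`, `reason` (when rho is undefined).
#' @export
eis_fraction_correlation <- function(eis, fraction, rho_cutoff = 0.30) {
  stopifnot(length(eis) == length(fraction))
  ok <- !is.na(eis) & !is.na(fraction)
  if (sum(ok) < 5) stop("need at least 5 paired samples")
  x <- eis[ok]; y <- fraction[ok]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, pass = FALSE, n = sum(ok),
                reason = "zero variance"))
  rho <- cor(x, y, method = "spearman")
  list(rho = rho, pass = rho >= rho_cutoff, n = sum(ok), reason = NA_character_)
}
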