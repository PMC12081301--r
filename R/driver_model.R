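# Partition variance in gene expression between copy number and linked
# enhancer activity. The model is RNA ~ H3K27ac + CN per gene, with relative
# importance of each predictor measured by the LMG decomposition (incremental
# R^2 averaged over all predictor orderings, unrelativized so the importances
# sum to the full-model R^2).

#' Select expressed genes and link enhancer peaks through loops
#'
#' Keeps genes expressed above `tpm_cutoff` TPM in more than `min_samples`
#' samples (both strict). A peak is linked to a gene when it (1) lies within
#' `window` bases of the TSS and (2) overlaps the non-promoter anchor of a
#' loop whose other anchor overlaps the gene's promoter window.
#'
#' @param genes data.frame from [gene_models()].
#' @param tpm gene x sample TPM matrix (rownames = gene_id).
#' @param peaks interval data.frame of union H3K27ac peaks.
#' @param loops canonical loop data.frame.
#' @param window max TSS-peak distance (default 1e6).
#' @param flank promoter window half-width (default 1000).
#' @param tpm_cutoff,min_samples expression filter (defaults 10 and 3, strict).
#' @return named list: per retained gene, integer indices into `peaks`.
#' @export
select_and_link <- function(genes, tpm, peaks, loops, window = 1e6,
                            flank = 1000, tpm_cutoff = 10, min_samples = 3) {
  known <- genes$gene_id %in% rownames(tpm)
  if (any(!known))
    message(sum(!known), " gene(s) absent from the TPM matrix; skipped")
  genes <- genes[known, , drop = FALSE]
  expressed <- rowSums(tpm[genes$gene_id, , drop = FALSE] > tpm_cutoff) > min_samples
  genes <- genes[expressed, , drop = FALSE]
  prom <- promoter_window(genes, flank)
  a1 <- anchor1(loops); a2 <- anchor2(loops)
  p1 <- overlap_map(prom, a1)  # promoter windows hitting anchor1
  p2 <- overlap_map(prom, a2)
  pk1 <- overlap_map(anchor1(loops), peaks)
  pk2 <- overlap_map(anchor2(loops), peaks)
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    win <- data.frame(chrom = genes$chrom[i],
                      start = max(genes$tss[i] - window, 0),
                      end = genes$tss[i] + window + 1)
    near <- which(overlaps_any(peaks, win))
    # peaks at the distal anchor of loops touching this gene's promoter
    linked <- unique(c(unlist(pk2[p1[[i]]]), unlist(pk1[p2[[i]]])))
    out[[i]] <- sort(intersect(near, linked))
  }
  out
}

#' Reduce linked peak signal to regression predictors
#'
#' With more than `ncomp` peaks the predictors are the first `ncomp` principal
#' component scores of the centered, scaled peak matrix; with `ncomp` or fewer
#' peaks the individual (scaled) peak signals are used directly.
#'
#' @param peak_mat sample x peak matrix of log2(x+1)-transformed signal.
#' @param ncomp maximum number of components (default 5).
#' @return sample x predictor matrix with named columns.
#' @export
peak_pca <- function(peak_mat, ncomp = 5) {
  stopifnot(is.matrix(peak_mat))
  cc <- complete.cases(peak_mat)
  if (sum(cc) < 2) stop("fewer than 2 complete samples for PCA")
  if (ncol(peak_mat) <= ncomp) {
    out <- scale(peak_mat)
    colnames(out) <- paste0("peak", seq_len(ncol(out)))
    return(out)
  }
  pc <- prcomp(peak_mat[cc, , drop = FALSE], center = TRUE, scale. = TRUE)
  scores <- matrix(NA_real_, nrow(peak_mat), ncomp,
                   dimnames = list(rownames(peak_mat), paste0("PC", seq_len(ncomp))))
  scores[cc, ] <- pc$x[, seq_len(ncomp), drop = FALSE]
  scores
}

# R^2 of y on the columns of X indexed by S (standardized via covariances),
# with intercept.
r2_subset <- function(Syy, Sxy, Sxx, S) {
  if (!length(S)) return(0)
  b <- solve(Sxx[S, S, drop = FALSE], Sxy[S])
  as.numeric(crossprod(Sxy[S], b) / Syy)
}

#' LMG relative importance decomposition
#'
#' For each predictor j, the LMG importance is the incremental R^2 of adding j,
#' averaged over all orderings of the predictors; equivalently a sum over
#' subsets S not containing j weighted by `|S|! (p-|S|-1)! / p!`. Importances
#' are not relativized, so they sum to the full-model R^2.
#'
#' @param y response vector.
#' @param X numeric predictor matrix (p <= 8 columns; subsets are enumerated
#'   exhaustively).
#' @return list with `importance` (named, per predictor), `r2` (full model)
#'   and `n` (complete cases used).
#' @export
lmg_importance <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 1, p <= 8)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  cc <- complete.cases(cbind(y, X))
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  n <- length(y)
  if (n < p + 2) stop("need at least p + 2 complete samples")
  if (qr(cbind(1, X))$rank < p + 1) {
    qx <- qr(scale(X, scale = FALSE))
    dep <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  Syy <- var(y)
  Sxy <- drop(cov(X, y))
  Sxx <- cov(X)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  r2s <- vapply(subsets, function(S) r2_subset(Syy, Sxy, Sxx, S), numeric(1))
  names(r2s) <- vapply(subsets, function(S) paste(S, collapse = ","), "")
  key <- function(S) paste(sort(S), collapse = ",")
  imp <- setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    for (idx in seq_along(subsets)) {
      S <- subsets[[idx]]
      if (j %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      imp[j] <- imp[j] + w * (r2s[[key(c(S, j))]] - r2s[[idx]])
    }
  }
  list(importance = imp, r2 = r2s[[key(seq_len(p))]], n = n)
}

#' Fit the expression model and classify a gene as enhancer- or copy-driven
#'
#' Ordinary least squares fit of expression on enhancer terms plus a CN term;
#' the winning term is the one with the largest LMG importance. The gene is
#' copy-driven when CN wins and enhancer-driven when any H3K27ac term wins,
#' unless the winning term is not significant, in which case it is
#' unclassified. By default the winning-term coefficient p-value is
#' Bonferroni-adjusted for the number of candidate terms before comparison
#' with `alpha`, which keeps the null misclassification rate near `alpha`
#' despite the argmax selection; `significance = "winner-raw"` uses the raw
#' winning-term p-value instead.
#'
#' @param y per-sample response (log2 expression recommended; see
#'   [run_driver_model()]).
#' @param enh sample x enhancer-term matrix (peak signals or PC scores).
#' @param cn per-sample relative CN of the gene.
#' @param alpha significance level (default 0.05).
#' @param variance_floor genes with `var(y)` at or below this are flagged
#'   `excluded` from headline ranking (default 1).
#' @param covariate optional factor (e.g. cancer type); response and
#'   predictors are residualized on it before fitting.
#' @param significance "bonferroni" (default) or "winner-raw".
#' @param min_n minimum complete samples (default 10).
#' @return list with `class` ("enhancer-driven", "copy-driven",
#'   "unclassified"), `winner`, `p_winner` (adjusted as per `significance`),
#'   `importance`, `r2`, `n`, `excluded`, `response_variance`.
#' @export
fit_and_classify <- function(y, enh, cn, alpha = 0.05, variance_floor = 1,
                             covariate = NULL,
                             significance = c("bonferroni", "winner-raw"),
                             min_n = 10) {
  significance <- match.arg(significance)
  enh <- as.matrix(enh)
  if (is.null(colnames(enh))) colnames(enh) <- paste0("enh", seq_len(ncol(enh)))
  X <- cbind(enh, CN = cn)
  cc <- complete.cases(cbind(y, X))
  if (!is.null(covariate)) cc <- cc & !is.na(covariate)
  p <- ncol(X)
  if (sum(cc) < max(p + 2, min_n))
    stop("fewer than ", max(p + 2, min_n), " complete samples")
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  resp_var <- var(y)
  if (!is.null(covariate)) {
    covariate <- factor(covariate[cc])
    y <- stats::resid(lm(y ~ covariate))
    X <- apply(X, 2, function(col) stats::resid(lm(col ~ covariate)))
  }
  fit <- lm(y ~ X)
  coefs <- summary(fit)$coefficients
  pvals <- setNames(rep(NA_real_, p), colnames(X))
  rows <- match(paste0("X", colnames(X)), rownames(coefs))
  pvals[!is.na(rows)] <- coefs[rows[!is.na(rows)], "Pr(>|t|)"]
  lmg <- lmg_importance(y, X)
  winner <- names(which.max(lmg$importance))
  p_win <- pvals[[winner]]
  if (significance == "bonferroni") p_win <- min(p_win * p, 1)
  cls <- if (is.na(p_win) || p_win >= alpha) "unclassified"
         else if (winner == "CN") "copy-driven" else "enhancer-driven"
  list(class = cls, winner = winner, p_winner = unname(p_win),
       importance = lmg$importance, r2 = lmg$r2, n = lmg$n,
       excluded = resp_var <= variance_floor, response_variance = resp_var)
}

#' Run the driver model over a cohort
#'
#' Links peaks to genes, builds per-gene predictors (CN-adjusted, log2,
#' scaled peak signal reduced by PCA when > 5 peaks; gene-body relative CN)
#' and classifies every gene with at least one linked peak.
#'
#' @param genes data.frame from [gene_models()].
#' @param rna gene x sample matrix of normalized expression counts.
#' @param tpm gene x sample TPM matrix (expression filter).
#' @param peaks union peak interval data.frame.
#' @param peak_signal peak x sample matrix of size-factor-normalized signal.
#' @param loops canonical loop data.frame.
#' @param profiles named list of `CnvProfile` (one per sample).
#' @param log_response log2(x+1)-transform the response (default TRUE).
#' @param covariate optional per-sample factor passed to [fit_and_classify()].
#' @param ... further arguments to [fit_and_classify()].
#' @return data.frame: gene, class, winner, p_winner, r2, lmg_cn,
#'   lmg_enh (largest enhancer-term importance), n_peaks, n_samples, excluded.
#' @export
run_driver_model <- function(genes, rna, tpm, peaks, peak_signal, loops,
                             profiles, log_response = TRUE, covariate = NULL,
                             ...) {
  stopifnot(identical(colnames(rna), colnames(peak_signal)))
  samples <- colnames(rna)
  links <- select_and_link(genes, tpm, peaks, loops)
  links <- links[lengths(links) > 0]
  # per-sample relative CN of every peak and gene body
  rel_cn_peaks <- sapply(samples, function(s) relative_cn(profiles[[s]], peaks))
  gsub_ <- genes[match(names(links), genes$gene_id), , drop = FALSE]
  rel_cn_genes <- sapply(samples, function(s)
    relative_cn(profiles[[s]], gsub_[c("chrom", "start", "end")]))
  if (!is.matrix(rel_cn_genes))
    rel_cn_genes <- matrix(rel_cn_genes, nrow = nrow(gsub_))
  res <- vector("list", length(links))
  for (i in seq_along(links)) {
    g <- names(links)[i]
    pk <- links[[i]]
    adj <- regression_peak_normalize(peak_signal[pk, samples, drop = FALSE],
                                     rel_cn_peaks[pk, , drop = FALSE])
    enh <- peak_pca(log2(t(adj) + 1))
    y <- rna[g, samples]
    if (log_response) y <- log2(y + 1)
    fit <- tryCatch(
      fit_and_classify(y, enh, rel_cn_genes[i, ], covariate = covariate, ...),
      error = function(e) NULL)
    if (is.null(fit)) next
    enh_imp <- fit$importance[setdiff(names(fit$importance), "CN")]
    res[[i]] <- data.frame(
      gene = g, class = fit$class, winner = fit$winner,
      p_winner = fit$p_winner, r2 = fit$r2,
      lmg_cn = unname(fit$importance["CN"]),
      lmg_enh = if (length(enh_imp)) max(enh_imp) else NA_real_,
      n_peaks = length(pk), n_samples = fit$n, excluded = fit$excluded,
      response_variance = fit$response_variance, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
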