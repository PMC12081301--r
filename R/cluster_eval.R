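# Pairwise-correlation hierarchical clustering of feature x sample signal
# matrices and external cluster quality (purity / entropy) against cancer-type
# labels.

#' Correlation-based hierarchical clustering of samples
#'
#' Drops features on excluded chromosomes (chrX/chrY by default) or
#' overlapping blacklist regions, keeps reproducible features (at least
#' `min_samples` samples with normalized count >= `min_count`), log2-transforms
#' with a prior count, computes pairwise Pearson correlations over mutually
#' non-missing entries, clusters on distance `1 - r` and cuts the tree at
#' `k` = number of unique labels.
#'
#' @param mat feature x sample matrix of normalized (CN-corrected) counts;
#'   `NA` allowed.
#' @param feature_intervals interval data.frame (one row per matrix row), or
#'   NULL to skip location-based filtering.
#' @param labels per-sample class labels (cancer types); NULL skips cutting
#'   and quality metrics.
#' @param blacklist interval data.frame of excluded regions (optional).
#' @param exclude_chroms chromosomes removed outright (default chrX, chrY).
#' @param min_count,min_samples reproducibility filter (defaults 3 and 2).
#' @param prior log2 prior count (default 1).
#' @param linkage hclust method (default "complete").
#' @param k number of clusters; defaults to the number of unique labels.
#' @return object of class `ClusterEval`: list with `correlation`, `hclust`,
#'   `clusters`, `purity`, `entropy`, `n_features`.
#' @export
correlation_cluster <- function(mat, feature_intervals = NULL, labels = NULL,
                                blacklist = NULL,
                                exclude_chroms = c("chrX", "chrY"),
                                min_count = 3, min_samples = 2, prior = 1,
                                linkage = "complete", k = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 3)
  keep <- rep(TRUE, nrow(mat))
  if (!is.null(feature_intervals)) {
    stopifnot(nrow(feature_intervals) == nrow(mat))
    keep <- keep & !(feature_intervals$chrom %in% exclude_chroms)
    if (!is.null(blacklist) && nrow(blacklist))
      keep <- keep & !overlaps_any(feature_intervals, blacklist)
  }
  keep <- keep & rowSums(mat >= min_count, na.rm = TRUE) >= min_samples
  sub <- log2(mat[keep, , drop = FALSE] + prior)
  C <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
  if (any(is.na(C))) {
    npairs <- crossprod(!is.na(sub))
    bad <- which(npairs < 3 & upper.tri(npairs), arr.ind = TRUE)
    stop("sample pair(s) with fewer than 3 mutually non-missing features; ",
         "correlation undefined for linkage (e.g. columns ",
         if (nrow(bad)) paste(bad[1, ], collapse = ","), ")")
  }
  hc <- hclust(as.dist(1 - C), method = linkage)
  clusters <- purity <- entropy <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(mat))
    if (is.null(k)) k <- length(unique(labels))
    clusters <- cutree(hc, k = k)
    pe <- purity_entropy(clusters, labels)
    purity <- pe$purity; entropy <- pe$entropy
  }
  structure(list(correlation = C, hclust = hc, clusters = clusters,
                 purity = purity, entropy = entropy, n_features = sum(keep)),
            class = "ClusterEval")
}

#' @export
print.ClusterEval <- function(x, ...) {
  cat(sprintf("ClusterEval: %d features, %d samples", x$n_features,
              ncol(x$correlation)))
  if (!is.null(x$purity))
    cat(sprintf("; purity %.3f, entropy %.3f", x$purity, x$entropy))
  cat("\n")
  invisible(x)
}

#' External cluster quality: purity and entropy
#'
#' With counts `n_kj` of true class j in cluster k (cluster sizes `n_k`, C
#' true classes, n samples): purity = `sum_k max_j n_kj / n`; entropy =
#' `-(1 / (n log2 C)) sum_k sum_j n_kj log2(n_kj / n_k)` with `0 log 0 = 0`.
#' Purity 1 and entropy 0 iff every cluster is label-pure.
#'
#' @param clusters cluster assignment vector.
#' @param truth true class labels (same length; needs >= 2 distinct classes).
#' @return list with `purity` and `entropy`, both in \[0, 1\].
#' @export
purity_entropy <- function(clusters, truth) {
  stopifnot(length(clusters) == length(truth))
  C <- length(unique(truth))
  if (C < 2) stop("entropy undefined for a single true class (log2 1 = 0)")
  tab <- table(clusters, truth)
  n <- sum(tab)
  purity <- sum(apply(tab, 1, max)) / n
  nk <- rowSums(tab)
  frac <- sweep(tab, 1, nk, "/")
  terms <- tab * ifelse(tab > 0, log2(frac), 0)
  entropy <- -sum(terms) / (n * log2(C))
  list(purity = purity, entropy = entropy)
}
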