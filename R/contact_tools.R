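# Matrix-level computations on binned contact maps: balancing to a doubly
# stochastic form, observed/expected transform, compartment eigenvector with
# reference-track sign orientation, and virtual 4C profiles.

#' Knight-Ruiz style symmetric matrix balancing
#'
#' Finds a positive diagonal scaling D such that all unmasked row sums of
#' `D %*% M %*% D` equal 1 within `tol`, by the symmetric fixed-point
#' iteration `x <- x / sqrt(x * (M x))`. Bins with zero marginal are masked
#' out (rows/columns set to `NA`) and reported in the result.
#'
#' @param cm raw [contact_matrix()].
#' @param tol convergence tolerance on `max |row sum - 1|` (default 1e-6).
#' @param max_iter iteration cap (default 3000).
#' @return the balanced `ContactMatrix`, with attributes `scaling` (per-bin
#'   scaling vector, NA for masked bins) and `masked` (logical per bin).
#' @export
kr_balance <- function(cm, tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(cm, "ContactMatrix"))
  if (cm$state != "raw") stop("kr_balance expects a raw matrix")
  M <- cm$mat
  masked <- rowSums(M, na.rm = TRUE) == 0
  sub <- M[!masked, !masked, drop = FALSE]
  n <- nrow(sub)
  if (n == 0) stop("all bins masked; nothing to balance")
  x <- rep(1, n)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    s <- x * as.vector(sub %*% x)
    resid <- max(abs(s - 1))
    if (resid <= tol) break
    x <- x / sqrt(s)
  }
  if (resid > tol)
    stop(sprintf("balancing did not converge in %d iterations (residual %.3g)",
                 max_iter, resid))
  bal <- matrix(NA_real_, nrow(M), ncol(M))
  bal[!masked, !masked] <- sub * outer(x, x)
  scaling <- rep(NA_real_, nrow(M)); scaling[!masked] <- x
  out <- contact_matrix(bal, cm$chrom, cm$resolution, cm$total_valid_pairs,
                        state = "balanced")
  attr(out, "scaling") <- scaling
  attr(out, "masked") <- masked
  out
}

#' Observed / expected transform
#'
#' Divides every entry by the mean of its diagonal (distance stratum) taken
#' over unmasked bins. Diagonals whose mean is zero become `NA`.
#'
#' @param cm a balanced `ContactMatrix`.
#' @return `ContactMatrix` in "oe" state.
#' @export
oe_transform <- function(cm) {
  stopifnot(inherits(cm, "ContactMatrix"))
  if (cm$state != "balanced") stop("oe_transform expects a balanced matrix")
  M <- cm$mat
  n <- nrow(M)
  oe <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d); j <- i + d
    vals <- M[cbind(i, j)]
    mu <- mean(vals, na.rm = TRUE)
    if (is.na(mu) || mu == 0) next
    oe[cbind(i, j)] <- vals / mu
    oe[cbind(j, i)] <- oe[cbind(i, j)]
  }
  out <- contact_matrix(oe, cm$chrom, cm$resolution, cm$total_valid_pairs,
                        state = "oe")
  attr(out, "masked") <- attr(cm, "masked")
  out
}

#' A/B compartment eigenvector with reference-track orientation
#'
#' Computes the Pearson correlation matrix of the O/E columns over unmasked
#' bins, takes its leading eigenvector, and flips the sign if the eigenvector
#' correlates negatively with `reference_track` (e.g. a DNA methylation
#' compartment eigenvector), so that positive values consistently indicate the
#' A (open) compartment.
#'
#' @param cm an O/E `ContactMatrix`.
#' @param reference_track numeric vector of length `n_bins` (NA allowed).
#' @return numeric per-bin eigenvector, NA at masked bins.
#' @export
compartment_eigenvector <- function(cm, reference_track) {
  stopifnot(inherits(cm, "ContactMatrix"))
  if (cm$state != "oe") stop("compartment_eigenvector expects an O/E matrix")
  n <- cm$n_bins
  stopifnot(length(reference_track) == n)
  masked <- attr(cm, "masked")
  if (is.null(masked)) masked <- apply(cm$mat, 1, function(r) all(is.na(r)))
  sub <- cm$mat[!masked, !masked, drop = FALSE]
  if (any(apply(sub, 2, function(col) sd(col, na.rm = TRUE)) == 0))
    stop("degenerate (constant) O/E column; correlation matrix undefined")
  C <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
  if (any(!is.finite(C))) stop("correlation matrix has undefined entries")
  ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
  ref <- reference_track[!masked]
  rho <- suppressWarnings(cor(ev, ref, use = "complete.obs"))
  if (!is.na(rho) && rho < 0) ev <- -ev
  out <- rep(NA_real_, n)
  out[!masked] <- ev
  out
}

#' Virtual 4C / enhancer interaction signal profile
#'
#' The interaction profile of the bin containing the anchor: its row of the
#' raw contact matrix divided by the total number of valid read pairs, then
#' smoothed with a centered rolling mean (window shrunk at the edges). This is
#' the operational definition of the enhancer interaction signal (EIS): the
#' profile reflects both 1D signal strength and contact frequency with the
#' anchor.
#'
#' @param cm raw `ContactMatrix`.
#' @param anchor single-row interval data.frame; must lie within one bin.
#' @param window_bins rolling-mean width in bins (default 5).
#' @return object of class `Virtual4C`: list with `anchor_bin` (1-based bin
#'   index), `eis` (smoothed profile), `raw` (unsmoothed normalized profile)
#'   and `window_bins`.
#' @export
virtual_4c <- function(cm, anchor, window_bins = 5) {
  stopifnot(inherits(cm, "ContactMatrix"), nrow(anchor) == 1, window_bins >= 1)
  if (cm$state != "raw") stop("virtual_4c expects a raw matrix")
  if (!identical(anchor$chrom[1], cm$chrom))
    stop("anchor chromosome does not match the matrix")
  bin <- anchor$start[1] %/% cm$resolution
  if (anchor$end[1] > (bin + 1) * cm$resolution)
    stop("anchor spans more than one bin")
  if (bin < 0 || bin >= cm$n_bins) stop("anchor outside the matrix")
  prof <- cm$mat[bin + 1, ] / cm$total_valid_pairs
  eis <- as.numeric(zoo::rollapply(zoo::zoo(prof), window_bins, mean,
                                   partial = TRUE, align = "center"))
  structure(list(anchor_bin = bin + 1L, eis = eis, raw = prof,
                 window_bins = window_bins, chrom = cm$chrom,
                 resolution = cm$resolution),
            class = "Virtual4C")
}

#' Write a virtual 4C profile as bedGraph
#' @param v4c a `Virtual4C` object.
#' @param path output file path.
#' @export
write_v4c_bedgraph <- function(v4c, path) {
  n <- length(v4c$eis)
  df <- data.frame(chrom = v4c$chrom, start = (seq_len(n) - 1) * v4c$resolution,
                   end = seq_len(n) * v4c$resolution, value = v4c$eis)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
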