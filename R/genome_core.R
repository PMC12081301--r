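#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats cor complete.cases cov fisher.test lm median p.adjust
#'   pnorm prcomp quantile rbinom rgamma rnorm rpois runif resid sd setNames
#'   t.test var as.dist cutree hclust
#' @importFrom utils combn read.delim write.table head
NULL

# ---- genomic intervals -------------------------------------------------------
#
# All coordinates are 0-based half-open throughout the package; 1-based input
# formats (SEG, gene TSV) are converted exactly once at the IO boundary.

#' Construct a table of genomic intervals
#'
#' @param chrom character vector of chromosome names (exact-string matching,
#'   no "chr" aliasing is ever applied).
#' @param start,end integer vectors, 0-based half-open.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate interval invariants (start >= 0, end > start, non-empty chrom)
#' @param df data.frame with chrom/start/end columns.
#' @return invisibly, the input.
#' @export
validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df)) {
    if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
      stop("intervals with empty chromosome name")
    if (any(df$start < 0)) stop("intervals with negative start")
    if (any(df$end <= df$start)) stop("intervals with end <= start")
  }
  invisible(df)
}

# GRanges bridge: internal 0-based half-open -> 1-based closed
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

#' Map query intervals onto subject intervals (half-open overlap)
#'
#' A pair (q, s) is reported iff both intervals are on the same chromosome and
#' `q.start < s.end && s.start < q.end`.
#'
#' @param query,subject interval data.frames (chrom/start/end).
#' @return list of length `nrow(query)`; element i holds the integer indices of
#'   overlapping subject rows (possibly empty).
#' @export
overlap_map <- function(query, subject) {
  validate_intervals(query); validate_intervals(subject)
  if (!nrow(query)) return(list())
  if (!nrow(subject)) return(rep(list(integer(0)), nrow(query)))
  # chromosomes absent from one side are legitimate non-overlaps, not worth
  # the seqlevel-universe warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(query), as_granges0(subject)))
  out <- rep(list(integer(0)), nrow(query))
  if (length(hits)) {
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  out
}

#' Which query intervals overlap any subject interval
#' @inheritParams overlap_map
#' @return logical vector of length `nrow(query)`.
#' @export
overlaps_any <- function(query, subject) {
  lengths(overlap_map(query, subject)) > 0
}

# ---- gene models -------------------------------------------------------------

#' Construct gene models with strand-aware TSS
#'
#' The TSS base is `start` for + strand genes and `end - 1` for - strand genes.
#'
#' @param gene_id character vector.
#' @param chrom,start,end interval columns (0-based half-open).
#' @param strand "+" or "-".
#' @return data.frame with an extra `tss` column.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- genomic_intervals(chrom, start, end)
  df <- cbind(data.frame(gene_id = as.character(gene_id),
                         stringsAsFactors = FALSE), df)
  df$strand <- rep_len(strand, nrow(df))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df
}

#' Promoter window around the TSS
#'
#' Returns an interval of width `2 * flank + 1` centered on the strand-aware
#' TSS base, clipped at coordinate 0.
#'
#' @param genes data.frame from [gene_models()].
#' @param flank bases to extend on each side of the TSS (default 1000).
#' @return interval data.frame, one row per gene, carrying `gene_id`.
#' @export
promoter_window <- function(genes, flank = 1000) {
  stopifnot(flank >= 0, "tss" %in% names(genes))
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = pmax(genes$tss - flank, 0),
                    end = genes$tss + flank + 1, stringsAsFactors = FALSE)
  validate_intervals(out)
  out
}

# ---- loop tables -------------------------------------------------------------

#' Canonicalize a loop table
#'
#' Reorders anchors so anchor1 precedes anchor2 (by start coordinate) and
#' checks LoopRecord invariants: anchors on one chromosome, width equal to the
#' declared resolution, non-negative signal.
#'
#' @param loops data.frame with columns chrom, start1, end1, start2, end2,
#'   signal and optionally qvalue.
#' @param resolution anchor width in bases; NULL skips the width check (used
#'   for merged union loops whose anchors may span several bins).
#' @return the canonicalized data.frame.
#' @export
canonicalize_loops <- function(loops, resolution = NULL) {
  need <- c("chrom", "start1", "end1", "start2", "end2", "signal")
  stopifnot(all(need %in% names(loops)))
  swap <- loops$start2 < loops$start1
  if (any(swap)) {
    s1 <- loops$start1[swap]; e1 <- loops$end1[swap]
    loops$start1[swap] <- loops$start2[swap]
    loops$end1[swap] <- loops$end2[swap]
    loops$start2[swap] <- s1; loops$end2[swap] <- e1
  }
  if (nrow(loops)) {
    if (any(loops$signal < 0)) stop("negative loop signal")
    if (!is.null(resolution)) {
      w <- c(loops$end1 - loops$start1, loops$end2 - loops$start2)
      if (any(w != resolution))
        stop("loop anchor width differs from declared resolution")
    }
  }
  rownames(loops) <- NULL
  loops
}

anchor1 <- function(loops) {
  data.frame(chrom = loops$chrom, start = loops$start1, end = loops$end1,
             stringsAsFactors = FALSE)
}
anchor2 <- function(loops) {
  data.frame(chrom = loops$chrom, start = loops$start2, end = loops$end2,
             stringsAsFactors = FALSE)
}

#' Read a loop table (FitHiChIP-style TSV)
#'
#' Expects a tab-delimited file with header columns chr1, start1, end1, chr2,
#' start2, end2, signal and optionally qvalue (0-based half-open anchors).
#' Inter-chromosomal rows are skipped; the number skipped is attached as the
#' `"n_interchrom"` attribute and reported with a message.
#'
#' @param path file path.
#' @param resolution declared anchor width (bases).
#' @return canonical loop data.frame (columns chrom, start1, end1, start2,
#'   end2, signal[, qvalue]).
#' @export
read_loop_table <- function(path, resolution) {
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chr1", "start1", "end1", "chr2", "start2", "end2", "signal")
  if (!all(need %in% names(raw)))
    stop("loop table missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "))
  num_cols <- c("start1", "end1", "start2", "end2", "signal")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed loop row at line %d (column %s)", bad[1] + 1L, cc))
    raw[[cc]] <- v
  }
  inter <- raw$chr1 != raw$chr2
  if (any(inter))
    message(sum(inter), " inter-chromosomal loop row(s) skipped")
  raw <- raw[!inter, , drop = FALSE]
  out <- data.frame(chrom = raw$chr1, start1 = raw$start1, end1 = raw$end1,
                    start2 = raw$start2, end2 = raw$end2, signal = raw$signal,
                    stringsAsFactors = FALSE)
  if ("qvalue" %in% names(raw)) out$qvalue <- as.numeric(raw$qvalue)
  out <- canonicalize_loops(out, resolution)
  validate_intervals(anchor1(out)); validate_intervals(anchor2(out))
  attr(out, "n_interchrom") <- sum(inter)
  out
}

#' Write a loop table
#' @param loops canonical loop data.frame.
#' @param path output file path.
#' @export
write_loop_table <- function(loops, path) {
  out <- data.frame(chr1 = loops$chrom, start1 = loops$start1, end1 = loops$end1,
                    chr2 = loops$chrom, start2 = loops$start2, end2 = loops$end2,
                    signal = loops$signal, stringsAsFactors = FALSE)
  if ("qvalue" %in% names(loops)) out$qvalue <- loops$qvalue
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- BED ---------------------------------------------------------------------

#' Read a BED3/BED6 file (0-based half-open, no conversion needed)
#' @param path file path.
#' @return interval data.frame; BED6 name/score/strand kept when present.
#' @export
read_bed <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (ncol(raw) >= 6) names(raw)[4:6] <- c("name", "score", "strand")
  validate_intervals(raw)
  raw
}

#' Write intervals as BED
#' @param df interval data.frame.
#' @param path output file path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(df))
  write.table(df[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- SEG (1-based inclusive on disk) -----------------------------------------

#' Read CN segments (SEG-like TSV: sample, chrom, start, end, total_cn)
#'
#' Coordinates on disk are 1-based inclusive and are converted to the internal
#' 0-based half-open convention here, exactly once.
#'
#' @param path file path.
#' @return data.frame sample/chrom/start/end/total_cn (internal coordinates).
#' @export
read_seg <- function(path) {
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn")
  if (!all(need %in% names(raw)))
    stop("SEG file missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "))
  raw$start <- raw$start - 1
  validate_intervals(raw)
  if (any(raw$total_cn < 0)) stop("negative total_cn in SEG file")
  raw
}

#' Write CN segments as SEG-like TSV (converting back to 1-based inclusive)
#' @param seg segment data.frame in internal coordinates.
#' @param path output file path.
#' @export
write_seg <- function(seg, path) {
  out <- seg[c("sample", "chrom", "start", "end", "total_cn")]
  out$start <- out$start + 1
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene TSV (GTF-lite, 1-based inclusive on disk) --------------------------

#' Read gene models from a GTF-lite TSV (gene_id, chrom, start, end, strand)
#' @param path file path (1-based inclusive coordinates on disk).
#' @return data.frame from [gene_models()].
#' @export
read_gene_table <- function(path) {
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(raw)))
    stop("gene table missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "))
  gene_models(raw$gene_id, raw$chrom, raw$start - 1, raw$end, raw$strand)
}

#' Write gene models as GTF-lite TSV (1-based inclusive)
#' @param genes data.frame from [gene_models()].
#' @param path output file path.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start + 1, end = genes$end,
                    strand = genes$strand, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- contact matrices --------------------------------------------------------

#' Construct a ContactMatrix
#'
#' Symmetric binned intra-chromosomal contact counts at fixed resolution.
#'
#' @param mat symmetric non-negative numeric matrix.
#' @param chrom chromosome name.
#' @param resolution bin width in bases.
#' @param total_valid_pairs total valid read pairs backing the matrix
#'   (defaults to the sum of the upper triangle including the diagonal).
#' @param state one of "raw", "balanced", "oe".
#' @return object of class `ContactMatrix` (a list).
#' @export
contact_matrix <- function(mat, chrom, resolution, total_valid_pairs = NULL,
                           state = "raw") {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  state <- match.arg(state, c("raw", "balanced", "oe"))
  if (any(mat < 0, na.rm = TRUE)) stop("contact matrix has negative entries")
  if (max(abs(mat - t(mat)), na.rm = TRUE) > 1e-8 * (1 + max(abs(mat), na.rm = TRUE)))
    stop("contact matrix is not symmetric")
  if (is.null(total_valid_pairs))
    total_valid_pairs <- sum(mat[upper.tri(mat, diag = TRUE)], na.rm = TRUE)
  structure(list(mat = mat, chrom = chrom, resolution = resolution,
                 n_bins = nrow(mat), total_valid_pairs = total_valid_pairs,
                 state = state),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %g bp [%s], %g valid pairs\n",
              x$chrom, x$n_bins, x$resolution, x$state, x$total_valid_pairs))
  invisible(x)
}

#' Read a contact matrix from bin-pair triplet text
#'
#' Format: leading '#key=value' header lines (chrom, resolution, n_bins,
#' total_valid_pairs) followed by a tab-separated triplet table with header
#' bin1_start, bin2_start, count (bin starts in bases).
#'
#' @param path file path.
#' @return a [contact_matrix()] in raw state.
#' @export
read_contact_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "=")
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  for (k in c("chrom", "resolution", "n_bins", "total_valid_pairs"))
    if (is.na(meta[k])) stop("contact matrix header missing ", k)
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), header = TRUE)
  res <- as.numeric(meta["resolution"])
  n <- as.integer(meta["n_bins"])
  i <- df$bin1_start / res + 1; j <- df$bin2_start / res + 1
  if (any(i != round(i)) || any(j != round(j)))
    stop("bin starts not multiples of the resolution")
  mat <- matrix(0, n, n)
  mat[cbind(i, j)] <- df$count
  mat[cbind(j, i)] <- df$count
  contact_matrix(mat, meta[["chrom"]], res,
                 total_valid_pairs = as.numeric(meta["total_valid_pairs"]))
}

#' Write a contact matrix as triplet text (upper triangle, non-zero entries)
#' @param cm a [contact_matrix()].
#' @param path output file path.
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "ContactMatrix"))
  idx <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat != 0, arr.ind = TRUE)
  df <- data.frame(bin1_start = (idx[, 1] - 1) * cm$resolution,
                   bin2_start = (idx[, 2] - 1) * cm$resolution,
                   count = cm$mat[idx])
  df <- df[order(df$bin1_start, df$bin2_start), ]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#%s=%s",
                     c("chrom", "resolution", "n_bins", "total_valid_pairs"),
                     c(cm$chrom, cm$resolution, cm$n_bins, cm$total_valid_pairs)),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- generic matrix TSV ------------------------------------------------------

#' Read a feature x sample signal matrix TSV (first column = feature id)
#' @param path file path.
#' @return numeric matrix with feature rownames.
#' @export
read_signal_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a feature x sample signal matrix TSV
#' @param m numeric matrix with rownames.
#' @param path output file path.
#' @param id_col name for the feature id column.
#' @export
write_signal_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
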