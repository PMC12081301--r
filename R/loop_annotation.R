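# Classification of loops by regulatory element content, union loop sets and
# per-sample loop signal matrices.

LOOP_CLASSES <- c("P-P", "E-P", "P-N", "E-E", "E-N", "N-N")

classify_anchor <- function(anchors, promoters, peaks) {
  is_p <- overlaps_any(anchors, promoters)
  is_e <- !is_p & overlaps_any(anchors, peaks)
  ifelse(is_p, "P", ifelse(is_e, "E", "N"))
}

#' Classify loops by anchor regulatory content
#'
#' Each anchor is labeled promoter ("P") if it overlaps any promoter window
#' (TSS +/- `flank`), else enhancer ("E") if it overlaps any H3K27ac peak,
#' else neither ("N"). The loop class is formed from the unordered anchor pair
#' with P > E > N naming precedence: P-P, E-P, P-N, E-E, E-N, N-N. N-N loops
#' (which peak-to-all calling normally forbids) are kept with a warning so
#' malformed inputs stay visible.
#'
#' @param loops canonical loop data.frame.
#' @param genes data.frame from [gene_models()].
#' @param peaks interval data.frame of H3K27ac peaks.
#' @param flank promoter window half-width (default 1000).
#' @return `loops` with added columns `anchor1_class`, `anchor2_class`,
#'   `annotation`.
#' @export
classify_loops <- function(loops, genes, peaks, flank = 1000) {
  prom <- promoter_window(genes, flank)
  c1 <- classify_anchor(anchor1(loops), prom, peaks)
  c2 <- classify_anchor(anchor2(loops), prom, peaks)
  pair <- function(a, b) {
    key <- paste(pmin(a, b), pmax(a, b))   # alphabetical: E < N < P
    c("E E" = "E-E", "E N" = "E-N", "E P" = "E-P",
      "N N" = "N-N", "N P" = "P-N", "P P" = "P-P")[key]
  }
  ann <- unname(pair(c1, c2))
  if (any(ann == "N-N"))
    warning(sum(ann == "N-N"), " loop(s) with neither anchor at a promoter or peak (N-N)")
  loops$anchor1_class <- c1
  loops$anchor2_class <- c2
  loops$annotation <- factor(ann, levels = LOOP_CLASSES)
  loops
}

#' Tabulate loop classes
#' @param annotated output of [classify_loops()].
#' @return named integer vector over all loop classes.
#' @export
loop_class_counts <- function(annotated) {
  table(annotated$annotation)
}

#' Merge per-sample loop sets into a union loop table
#'
#' Loops whose anchor pairs each lie within `slack` bases (anchor1 within
#' slack of anchor1, anchor2 of anchor2) are collapsed transitively into one
#' union record whose anchors span the merged members. Union anchors may
#' therefore exceed one bin.
#'
#' @param loop_sets list of canonical loop data.frames (one per sample).
#' @param resolution common calling resolution of all sets.
#' @param slack merge tolerance in bases (default: one bin, i.e. `resolution`).
#' @return union loop data.frame with `signal` = summed member signal and a
#'   `n_members` column.
#' @export
merge_loop_sets <- function(loop_sets, resolution, slack = resolution) {
  stopifnot(length(loop_sets) >= 1)
  all_loops <- do.call(rbind, lapply(loop_sets, function(x)
    x[c("chrom", "start1", "end1", "start2", "end2", "signal")]))
  rownames(all_loops) <- NULL
  n <- nrow(all_loops)
  if (!n) return(all_loops)
  # union-find over pairs whose two anchor gaps are both within slack
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(all_loops$chrom, all_loops$start1)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (all_loops$chrom[j] != all_loops$chrom[i]) break
      if (all_loops$start1[j] - all_loops$end1[i] > slack) break
      near1 <- all_loops$start1[j] < all_loops$end1[i] + slack &&
               all_loops$start1[i] < all_loops$end1[j] + slack
      near2 <- all_loops$start2[j] < all_loops$end2[i] + slack &&
               all_loops$start2[i] < all_loops$end2[j] + slack
      if (near1 && near2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(split(seq_len(n), comp), function(idx) {
    m <- all_loops[idx, , drop = FALSE]
    data.frame(chrom = m$chrom[1],
               start1 = min(m$start1), end1 = max(m$end1),
               start2 = min(m$start2), end2 = max(m$end2),
               signal = sum(m$signal), n_members = nrow(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start1, out$start2), ]
  rownames(out) <- NULL
  canonicalize_loops(out, resolution = NULL)
}

#' Per-sample loop signal over a union loop set
#'
#' Entry (l, s) is the summed signal of sample-s loops whose anchor pairs
#' overlap union loop l (anchor1 with anchor1 and anchor2 with anchor2, both
#' half-open); 0 when no sample loop overlaps.
#'
#' @param union_loops output of [merge_loop_sets()].
#' @param loop_sets named list of per-sample canonical loop data.frames.
#' @return numeric matrix (union loop x sample).
#' @export
loop_signal_matrix <- function(union_loops, loop_sets) {
  nl <- nrow(union_loops)
  out <- matrix(0, nl, length(loop_sets),
                dimnames = list(NULL, names(loop_sets)))
  ua1 <- anchor1(union_loops); ua2 <- anchor2(union_loops)
  for (s in seq_along(loop_sets)) {
    sl <- loop_sets[[s]]
    if (!nrow(sl)) next
    h1 <- overlap_map(ua1, anchor1(sl))
    h2 <- overlap_map(ua2, anchor2(sl))
    for (l in seq_len(nl)) {
      both <- intersect(h1[[l]], h2[[l]])
      if (length(both)) out[l, s] <- sum(sl$signal[both])
    }
  }
  out
}
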