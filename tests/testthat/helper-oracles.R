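# Independent oracles and small fixtures shared across test files. Oracles
# deliberately use brute-force formulations distinct from the package's
# implementation paths.

# all-pairs O(n^2) interval overlap scan (half-open)
brute_overlap <- function(query, subject) {
  lapply(seq_len(nrow(query)), function(i) {
    which(subject$chrom == query$chrom[i] &
            query$start[i] < subject$end &
            subject$start < query$end[i])
  })
}

# LMG by explicit averaging over all p! predictor orderings, with R^2 from
# lm() fits (independent of the package's covariance-based subset route)
lmg_by_orderings <- function(y, X) {
  p <- ncol(X)
  r2_of <- function(S) {
    if (!length(S)) return(0)
    summary(lm(y ~ X[, S, drop = FALSE]))$r.squared
  }
  perms <- gtools_permutations(p)
  imp <- numeric(p)
  for (k in seq_len(nrow(perms))) {
    pi <- perms[k, ]
    for (pos in seq_len(p)) {
      j <- pi[pos]
      before <- pi[seq_len(pos - 1)]
      imp[j] <- imp[j] + (r2_of(c(before, j)) - r2_of(before))
    }
  }
  setNames(imp / nrow(perms), colnames(X))
}

# all permutations of 1..n (tiny n)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
  }))
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  aa <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(aa, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive PWM score distribution over all 4^w background sequences
pwm_dist_enum <- function(pwm, bg = rep(0.25, 4), digits = 10) {
  S <- onco3d:::pwm_llr(pwm, bg)
  w <- ncol(S)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- vapply(seq_len(nrow(grid)), function(k)
    sum(S[cbind(grid[k, ], seq_len(w))]), numeric(1))
  probs <- vapply(seq_len(nrow(grid)), function(k)
    prod(bg[grid[k, ]]), numeric(1))
  key <- format(round(scores, digits), digits = 15)
  agg <- tapply(probs, key, sum)
  rep_score <- tapply(scores, key, `[`, 1)
  ord <- order(as.numeric(rep_score))
  data.frame(score = as.numeric(rep_score)[ord], prob = as.numeric(agg)[ord])
}

# random probability PWM
random_pwm <- function(w, seed) {
  set.seed(seed)
  m <- matrix(rgamma(4 * w, 1), 4)
  rownames(m) <- c("A", "C", "G", "T")
  sweep(m, 2, colSums(m), "/")
}

# a trimmed cohort for fast per-module tests
small_cohort <- function(seed = 11, contact_bins = 120, ...) {
  simulate_cohort(cohort_config(
    n_samples = 24, n_genes_enh = 6, n_genes_cn = 6, n_genes_null = 6,
    n_genes_low = 1, n_bg_peaks = 10, n_variants = 60,
    contact_bins = contact_bins, amplicons_per_class = 2, seed = seed, ...))
}

sample_lib <- function(cohort) {
  setNames(cohort$samples$library_factor, cohort$samples$sample)
}
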