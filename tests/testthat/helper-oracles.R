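# Independent oracles used across tests. These are deliberately written as
# naive loops / direct transcriptions, separate from the package internals.

# Hamming distance by explicit site-by-site comparison.
oracle_hamming <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

# Independent transcription of the stepwise parsimony-probability recursion:
# explicit loop, Jukes-Cantor inversion written out directly.
oracle_parsimony_prob <- function(j, m) {
  p <- 1
  for (i in seq_len(j)) {
    q <- min(i / m, 0.749999)
    mu <- -(3 / 4) * log(1 - (4 / 3) * q)
    p <- p * (mu * exp(-mu) / q)
  }
  p
}

oracle_connection_limit <- function(m, conf) {
  j <- 0
  while (j < m && oracle_parsimony_prob(j + 1, m) >= conf) j <- j + 1
  j
}

# Monte-Carlo estimate of the single-substitution probability at divergence q
# under the same finite-sites model: hits at a site are Poisson(mu(q)); a
# 4-state site is visibly different with the JC probability. Returns
# P(exactly one hit | visibly different).
mc_single_hit_prob <- function(q, n = 2e5) {
  mu <- -(3 / 4) * log(1 - (4 / 3) * q)
  hits <- rpois(n, mu)
  # visible difference: odd/even state walk on 4 states; P(diff | k hits)
  p_diff_given_k <- (3 / 4) * (1 - (-1 / 3)^hits)
  visible <- runif(n) < p_diff_given_k
  sum(visible & hits == 1) / sum(visible)
}

# Brute-force confusion matrix by explicit enumeration.
oracle_confusion <- function(pred, truth) {
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fn <- sum(!pred & truth); fp <- sum(pred & !truth)
  list(accuracy = (tp + tn) / length(truth),
       fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
       fpr = if (tn + fp > 0) fp / (tn + fp) else NA_real_)
}

# Adjusted Rand index between two label vectors (via mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small complete haplotype matrix with known strings.
toy_matrix <- function(strings, ids = NULL) {
  a <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  haplotype_matrix(a, individuals = ids %||% paste0("i", seq_along(strings)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
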