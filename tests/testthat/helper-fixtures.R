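# Shared fixtures and statistical helpers for the suite. All corpora are
# built in code; nothing is read from disk.

# A tiny hand-specified corpus for exact-count checks.
toy_corpus <- function() {
  labeled_corpus(list(
    list(doc_id = "d1", tokens = c("a", "b"), labels = "l1"),
    list(doc_id = "d2", tokens = c("c"), labels = c("l1", "l2"))
  ), label_catalog = c("l1", "l2"))
}

# n examples all carrying one label each, uniform over `labels`.
single_label_corpus <- function(n, labels, seed = 1L) {
  set.seed(seed)
  labs <- sample(labels, n, replace = TRUE)
  labeled_corpus(lapply(seq_len(n), function(i) {
    list(doc_id = sprintf("d%03d", i), tokens = c("tok", labs[i]),
         labels = labs[i])
  }), label_catalog = sort(labels))
}

# Family-wise z check for multinomial draw counts: returns TRUE when every
# per-category |z| stays below the Bonferroni-adjusted 3-sigma threshold
# (family error held at the 3-sigma level 2*pnorm(-3)).
multinomial_within_3sigma <- function(counts, probs) {
  n <- sum(counts)
  expected <- n * probs
  z <- (counts - expected) / sqrt(pmax(expected * (1 - probs), 1e-12))
  alpha <- 2 * stats::pnorm(-3)
  zcrit <- stats::qnorm(1 - alpha / (2 * length(counts)))
  ok_z <- all(abs(z[expected >= 10]) <= zcrit)
  # chi-square GOF at the 3-sigma level, pooling small-expectation bins
  small <- expected < 5
  if (any(small)) {
    counts <- c(counts[!small], sum(counts[small]))
    expected <- c(expected[!small], sum(expected[small]))
  }
  stat <- sum((counts - expected)^2 / expected)
  p <- stats::pchisq(stat, df = length(counts) - 1L, lower.tail = FALSE)
  ok_z && p > alpha
}

# Brute-force per-cell confusion tallies (independent oracle for the
# metrics module): explicit loops, no vectorized shortcuts.
oracle_label_tallies <- function(pred, gold) {
  L <- ncol(gold)
  out <- data.frame(tp = integer(L), fp = integer(L), fn = integer(L))
  for (l in seq_len(L)) {
    for (i in seq_len(nrow(gold))) {
      if (pred[i, l] == 1 && gold[i, l] == 1) out$tp[l] <- out$tp[l] + 1L
      if (pred[i, l] == 1 && gold[i, l] == 0) out$fp[l] <- out$fp[l] + 1L
      if (pred[i, l] == 0 && gold[i, l] == 1) out$fn[l] <- out$fn[l] + 1L
    }
  }
  out
}

# Direct-summation KL oracle (unsmoothed), independent of the package path.
oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  s
}
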