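# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (double loops, textbook formulas, rank statistics) and
# share no code with the package internals they check.

random_sequence <- function(L) {
  paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
}

tiny_dataset <- function(n = 4L, L = 30L, labels = NULL) {
  apo_dataset(sprintf("rec%02d", seq_len(n)),
              vapply(rep(L, n), random_sequence, character(1)),
              labels = labels)
}

# Naive k-spaced pair count: scan every start position with a double loop.
naive_pair_counts <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  counts <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in seq_len(L)) {
    j <- i + k + 1L
    if (j <= L) counts[chars[i], chars[j]] <- counts[chars[i], chars[j]] + 1L
  }
  counts
}

# Textbook one-way ANOVA F via sums of squares, no shared code with
# anova_rank().
naive_anova_f <- function(x, g) {
  g <- as.factor(g)
  grand <- mean(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    xi <- x[g == lev]
    ssb <- ssb + length(xi) * (mean(xi) - grand)^2
    ssw <- ssw + sum((xi - mean(xi))^2)
  }
  dfb <- nlevels(g) - 1
  dfw <- length(x) - nlevels(g)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / dfb) / (ssw / dfw)
}

# Mann-Whitney AUC via average ranks (ties counted 1/2).
rank_auc <- function(scores, truth) {
  r <- rank(scores)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Independent re-coding of the pseudo-amino-acid composition formula,
# written from the definition with explicit loops.
naive_pseaac <- function(sequence, gamma, w) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  f <- sapply(AA_ALPHABET, function(a) sum(chars == a) / L)
  props <- apofam:::pseaac_properties()
  taus <- c()
  for (j in seq_len(gamma)) {
    for (p in seq_len(nrow(props))) {
      acc <- 0
      for (i in seq_len(L - j)) {
        acc <- acc + props[p, chars[i]] * props[p, chars[i + j]]
      }
      taus <- c(taus, acc / (L - j))
    }
  }
  denom <- sum(f) + w * sum(taus)
  unname(c(f / denom, w * taus / denom))
}
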