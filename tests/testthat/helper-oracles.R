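# Independent oracles, deliberately distinct from the package's own
# algorithms.

# Exhaustive maximization over all subsets of pairwise-compatible hits
# (two hits compatible when their envelopes share at most tol residues).
# Bitmask enumeration; feasible up to ~12 hits.
brute_force_best_bits <- function(env_from, env_to, bits, tol = 0L) {
  n <- length(bits)
  if (n == 0L) return(0)
  masks <- 0:(2^n - 1L)
  valid <- rep(TRUE, length(masks))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ov <- min(env_to[i], env_to[j]) - max(env_from[i], env_from[j]) + 1L
      if (ov > tol) {
        both <- bitwAnd(masks, 2L^(i - 1L) + 2L^(j - 1L)) ==
          2L^(i - 1L) + 2L^(j - 1L)
        valid[both] <- FALSE
      }
    }
  }
  score <- numeric(length(masks))
  for (i in seq_len(n)) {
    score <- score + bits[i] * (bitwAnd(masks, 2L^(i - 1L)) > 0L)
  }
  max(score[valid])
}

random_hit_instance <- function(n, query = "d1", span = 300L) {
  from <- sample.int(span - 20L, n, replace = TRUE)
  len <- sample(10:80, n, replace = TRUE)
  hit_row(from, pmin(from + len, span), round(runif(n, 5, 120), 1),
          acc = sprintf("PF%05d", sample.int(99999, n)), query = query)
}

# Literal transcription of the diversity-score formula: per-rank ratio of
# distinct taxa to member count, weighted sum.
diversity_oracle <- function(lin, w = c(species = 0.30, family = 0.25,
                                        order = 0.20, class = 0.15,
                                        phylum = 0.10)) {
  n <- nrow(lin)
  total <- 0
  for (rank in names(w)) {
    labels <- lin[[rank]]
    labels <- labels[labels != "unresolved"]
    total <- total + w[[rank]] * (length(unique(labels)) / n)
  }
  total
}
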