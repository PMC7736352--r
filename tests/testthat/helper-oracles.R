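# Independent oracles used to cross-check the package's fast paths.
# Deliberately plain implementations: no code shared with R/.

# Gotoh affine-gap dynamic programming over three score layers.
# A gap of length k costs gap_open + k * gap_extend.
oracle_align_score <- function(a, b, matrix, gap_open = 11, gap_extend = 1,
                               mode = c("local", "global")) {
  mode <- match.arg(mode)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)   # av[i] aligned to bv[j]
  X <- matrix(neg, n + 1, m + 1)   # gap in b (a residue over a gap)
  Y <- matrix(neg, n + 1, m + 1)   # gap in a
  if (mode == "local") {
    # Classic Smith-Waterman/Gotoh: H carries the zero reset, E/F the gaps.
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(neg, n + 1, m + 1)
    F <- matrix(neg, n + 1, m + 1)
    best <- 0
    for (i in 2:(n + 1)) {
      for (j in 2:(m + 1)) {
        s <- matrix[av[i - 1], bv[j - 1]]
        E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                       E[i, j - 1] - gap_extend)
        F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                       F[i - 1, j] - gap_extend)
        H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
        best <- max(best, H[i, j])
      }
    }
    return(best)
  }
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- matrix[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Direct complex-exponential evaluation of the mean hydrophobic moment.
oracle_moment <- function(window_sequence, scale, delta_deg = 100) {
  res <- strsplit(window_sequence, "")[[1]]
  h <- scale[res]
  delta <- delta_deg * pi / 180
  Mod(sum(h * exp(1i * seq_along(h) * delta))) / length(h)
}

# Brute-force screen filter: strict thresholds, then top-k by score with
# lexicographic subject-id tie-break.
oracle_filter <- function(hits, min_sim = 30, min_cov = 70, top_k = 250) {
  keep <- hits[hits$similarity_pct > min_sim & hits$coverage_pct > min_cov, ]
  ord <- order(-keep$rank_score, keep$subject_id)
  keep[ord, ][seq_len(min(top_k, nrow(keep))), ]
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, replace = TRUE),
        collapse = "")
}
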