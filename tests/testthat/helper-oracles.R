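# Independent oracles, written as plainly as possible and kept separate
# from the implementation paths they check.

# Plain-R Gotoh dynamic program for the optimal local alignment score under
# affine gaps (gap of length k costs open + k * ext). Returns only the
# score, 0 meaning "empty alignment is optimal".
sw_score_oracle <- function(q, s, mat, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in s (consumes q)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in q (consumes s)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- mat[qc[i], sc[j]]
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + sub)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Probability of >= 2 successes among three independent Bernoulli draws,
# by explicit enumeration of the 8 joint outcomes.
majority_prob_oracle <- function(p) {
  total <- 0
  for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1) {
    if (o1 + o2 + o3 >= 2) {
      pr <- prod(ifelse(c(o1, o2, o3) == 1, p, 1 - p))
      total <- total + pr
    }
  }
  total
}

# Mann-Whitney concordance: fraction of (positive, negative) pairs ranked
# correctly, ties counting one half.
auc_concordance_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force best placement of an ungapped profile along a sequence.
profile_scan_oracle <- function(residues, profile) {
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars); L <- profile$length
  score_at <- function(pro_pos, seq_pos) {
    ch <- chars[seq_pos]
    if (!(ch %in% colnames(profile$match_log_odds))) return(0)
    profile$match_log_odds[pro_pos, ch]
  }
  best <- -Inf
  if (n >= L) {
    for (shift in 0:(n - L)) {
      tot <- 0
      for (i in 1:L) tot <- tot + score_at(i, shift + i)
      best <- max(best, tot)
    }
  } else {
    for (off in 0:(L - n)) {
      tot <- 0
      for (i in 1:n) tot <- tot + score_at(off + i, i)
      best <- max(best, tot)
    }
  }
  best
}

random_protein <- function(n, alphabet = famtrio:::AA_ALPHABET20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
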