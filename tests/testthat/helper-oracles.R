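# Independent oracles used against the package implementations.

# Random RNA string(s).
rand_rna <- function(len, n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "U", "C", "G"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Brute-force convolution: explicit double loop over windows and cells.
conv_oracle <- function(M, w, b) {
  h <- ncol(w)
  L <- ncol(M)
  out <- numeric(L - h + 1)
  for (i in seq_len(L - h + 1)) {
    s <- 0
    for (r in 1:4) {
      for (j in 1:h) {
        s <- s + w[r, j] * M[r, i + j - 1]
      }
    }
    out[i] <- max(0, s + b)
  }
  out
}

# Brute-force AUC: mean over all positive/negative pairs of
# [score_pos > score_neg] + 0.5 * [tie].
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# All distinct permutations of a character multiset (recursive).
multiset_perms <- function(chars) {
  if (length(chars) <= 1) {
    return(paste(chars, collapse = ""))
  }
  out <- character(0)
  for (u in unique(chars)) {
    rest <- chars[-match(u, chars)]
    out <- c(out, paste0(u, multiset_perms(rest)))
  }
  out
}

# The complete set of dinucleotide-preserving rearrangements of `seq`,
# found by enumerating every permutation of the inner characters and
# keeping those with identical dinucleotide counts.
shuffle_universe <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  inner <- multiset_perms(chars[2:(n - 1)])
  cand <- paste0(chars[1], inner, chars[n])
  ref <- dinucleotide_counts(seq)
  cand[vapply(cand, function(x) identical(dinucleotide_counts(x), ref), logical(1))]
}

# Best Hamming-similarity match position (0-based, leftmost tie) of a
# probe string within a sequence.
hamming_best_match <- function(seq, probe) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(probe, "")[[1]]
  w <- length(pc)
  best <- -1
  at <- 0L
  for (i in 0:(length(sc) - w)) {
    m <- sum(sc[(i + 1):(i + w)] == pc)
    if (m > best) {
      best <- m
      at <- i
    }
  }
  at
}

# Small labelled record tibble for I/O and split tests.
toy_records <- function(n = 6, len = 20, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = paste0("r", seq_len(n)),
      seq = rand_rna(len, n),
      label = rep(c("positive", "negative"), length.out = n)
    )
  })
}
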