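#' One-hot encode an RNA sequence
#'
#' Maps a fragment `s1 s2 ... sL` over `{A,U,C,G}` to a sparse 4 x L
#' binary matrix: column `j` holds a single 1 in the row of symbol `sj`
#' under the fixed row order A, U, C, G.
#'
#' @param seq A single RNA string over `{A,U,C,G}`.
#' @return 4 x L integer matrix with rownames `c("A","U","C","G")`; every
#'   column sums to exactly 1.
#' @examples
#' one_hot_encode("AUCG") # the 4x4 identity matrix
#' @export
one_hot_encode <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, ONEHOT_ALPHABET)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    abort(paste0(
      "cannot encode character '", chars[bad], "' at position ", bad,
      ": alphabet is {A,U,C,G}"
    ))
  }
  L <- length(codes)
  m <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(ONEHOT_ALPHABET, NULL))
  m[cbind(codes, seq_len(L))] <- 1L
  m
}

#' Decode a one-hot matrix back to its RNA sequence
#'
#' @param m 4 x L one-hot matrix (row order A, U, C, G; every column must
#'   sum to 1).
#' @return The unique RNA string whose encoding is `m`.
#' @export
one_hot_decode <- function(m) {
  if (!is.matrix(m) || nrow(m) != 4) {
    abort("expected a 4 x L matrix")
  }
  if (any(colSums(m) != 1) || any(!(m %in% c(0, 1)))) {
    abort("not a one-hot matrix: every column must contain a single 1")
  }
  paste(ONEHOT_ALPHABET[apply(m, 2, which.max)], collapse = "")
}

#' Normalised k-mer composition features
#'
#' Counts overlapping k-mers (stride 1) and divides by the number of
#' windows `L - k + 1`, giving the normalised frequency vector used by the
#' conventional baseline classifiers. Entries are ordered
#' lexicographically over A, C, G, U, so `k = 3` yields the standard
#' 64-dimensional vector.
#'
#' @param seq A single RNA string, length >= `k`.
#' @param k Word size (default 3).
#' @return Named numeric vector of length `4^k` summing to 1.
#' @examples
#' kmer_features("ACGU", k = 3) # 0.5 at ACG and CGU
#' @export
kmer_features <- function(seq, k = 3L) {
  L <- nchar(seq)
  if (L < k) abort(paste0("sequence length ", L, " is below k = ", k))
  lv <- all_kmers(k)
  words <- substring(seq, seq_len(L - k + 1L), k:L)
  cnt <- tabulate(factor(words, levels = lv), nbins = length(lv))
  setNames(cnt / (L - k + 1L), lv)
}

all_kmers <- function(k) {
  grid <- expand.grid(rep(list(PFM_ALPHABET), k), stringsAsFactors = FALSE)
  # vary the first position slowest -> lexicographic order
  sort(do.call(paste0, grid))
}

#' k-mer feature matrix for a set of records
#'
#' @param records Records tibble (or character vector of sequences).
#' @param k Word size (default 3).
#' @return Numeric matrix, one row per record, `4^k` columns.
#' @export
kmer_feature_matrix <- function(records, k = 3L) {
  seqs <- if (is.character(records)) records else records$seq
  t(vapply(seqs, kmer_features, numeric(4^k), k = k, USE.NAMES = FALSE))
}

#' Batch one-hot encoder
#'
#' Encodes a set of equal-length records into a 3-axis array
#' (records x 4 x L) plus a parallel label vector, the layout consumed by
#' the convolutional model.
#'
#' @param records Records tibble with `id`, `seq` and (optionally)
#'   `label`.
#' @return List with `x` (N x 4 x L array), `ids`, and `labels` (1 for
#'   positive, 0 otherwise, `NA` when unlabelled).
#' @export
encode_records <- function(records) {
  lens <- unique(nchar(records$seq))
  if (length(lens) > 1) {
    abort(paste0("sequences must share one length; found: ", paste(lens, collapse = ", ")))
  }
  L <- lens
  n <- nrow(records)
  x <- array(0L, dim = c(n, 4L, L), dimnames = list(NULL, ONEHOT_ALPHABET, NULL))
  for (i in seq_len(n)) {
    x[i, , ] <- one_hot_encode(records$seq[i])
  }
  labels <- if ("label" %in% names(records)) {
    ifelse(is.na(records$label), NA_integer_, as.integer(records$label == "positive"))
  } else {
    rep(NA_integer_, n)
  }
  list(x = x, ids = records$id, labels = labels)
}

# Integer codes (1..4 over A,U,C,G) for the fast training path.
seqs_to_int <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) > 1) abort("sequences must share one length")
  codes <- match(unlist(strsplit(seqs, ""), use.names = FALSE), ONEHOT_ALPHABET)
  if (anyNA(codes)) abort("sequence contains characters outside {A,U,C,G}")
  matrix(codes, nrow = L) # L x N, one column per sequence
}
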