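#' Read binding-site fragments from a FASTA file
#'
#' Reads a (multi-)FASTA file into a records tibble. Sequences are
#' uppercased and DNA `T` is mapped to RNA `U`. Records containing any
#' character outside `A,C,G,T,U` (e.g. ambiguity codes such as `N`) are
#' rejected with a warning, because the one-hot encoding admits only the
#' four RNA symbols.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` and `label` (`NA` until
#'   assigned). One row per retained FASTA entry.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(set) == 0) {
    return(tibble(id = character(), seq = character(), label = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(toupper(as.character(set)))
  ok <- !grepl("[^ACGTU]", seqs)
  if (any(!ok)) {
    warn(paste0(
      sum(!ok), " record(s) rejected for characters outside {A,C,G,T,U}: ",
      paste(head(ids[!ok], 5), collapse = ", ")
    ))
  }
  tibble(
    id = ids[ok],
    seq = rna_from_dna(seqs[ok]),
    label = NA_character_
  )
}

#' Write records to a FASTA file
#'
#' @param records Records tibble with `id` and `seq` columns.
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a BED6 interval file
#'
#' Intervals are returned in the BED dialect used throughout the package:
#' 0-based, half-open coordinates.
#'
#' @param path Path to a BED file (3-6 columns).
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`. Missing strand is reported as `"+"` with a single message.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  strand <- as.character(df$strand)
  if (any(strand == "*")) {
    inform("intervals without strand treated as '+'")
    strand[strand == "*"] <- "+"
  }
  tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start - 1L), # GRanges is 1-based closed
    end = as.integer(df$end),
    name = if ("name" %in% names(df)) as.character(df$name) else paste0("site_", seq_len(nrow(df))),
    score = if ("score" %in% names(df)) df$score else NA_real_,
    strand = strand
  )
}

#' Read a genome (or any chromosome set) from multi-FASTA
#'
#' @param path Multi-FASTA with one entry per chromosome.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

rna_from_dna <- function(x) chartr("T", "U", toupper(x))

dna_from_rna <- function(x) chartr("U", "T", toupper(x))

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna_from_rna(x))))
}

#' Retain fragments within a length window
#'
#' Binding sites shorter than about half the model input carry too little
#' signal and longer ones would be truncated, so only fragments with
#' `min_len <= nchar(seq) <= max_len` are kept (defaults keep strictly
#' between 50 and 100 nt). Order is preserved.
#'
#' @param records Records tibble with a `seq` column.
#' @param min_len,max_len Inclusive length bounds (defaults 51 and 99).
#' @return The filtered records tibble.
#' @export
filter_by_length <- function(records, min_len = 51L, max_len = 99L) {
  if (min_len > max_len) {
    abort("min_len must not exceed max_len")
  }
  len <- nchar(records$seq)
  records[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Extend intervals to a fixed length, centred on the peak midpoint
#'
#' Each interval is replaced by a window of exactly `target_len`
#' nucleotides centred on `floor((start + end) / 2)` in 0-based half-open
#' coordinates, and the corresponding sequence is extracted from the
#' genome. Minus-strand intervals are reverse-complemented; T is mapped to
#' U. Windows that would run past either chromosome end are dropped (not
#' clamped) so every emitted record has exactly `target_len` nt.
#'
#' @param intervals Interval tibble as from [read_bed()].
#' @param genome Named character vector (chromosome name -> sequence) as
#'   from [read_genome()].
#' @param target_len Window length in nt (default 100).
#' @return Records tibble with columns `id`, `seq`, `chrom`, `start`,
#'   `end`, `strand`, `label`; `seq` is always `target_len` long.
#' @export
extend_to_fixed_length <- function(intervals, genome, target_len = 100L) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) {
    return(tibble(
      id = character(), seq = character(), chrom = character(),
      start = integer(), end = integer(), strand = character(),
      label = character()
    ))
  }
  missing_chrom <- setdiff(unique(intervals$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from genome: ", paste(missing_chrom, collapse = ", ")))
  }
  if (any(intervals$end - intervals$start > target_len)) {
    abort("interval longer than target_len; filter lengths first")
  }
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep("+", nrow(intervals))
  name <- if ("name" %in% names(intervals)) intervals$name else paste0("site_", seq_len(nrow(intervals)))

  center <- floor((intervals$start + intervals$end) / 2)
  new_start <- as.integer(center - floor(target_len / 2))
  new_end <- as.integer(new_start + target_len)
  chrom_len <- nchar(genome)[intervals$chrom]
  keep <- new_start >= 0L & new_end <= chrom_len
  if (any(!keep)) {
    inform(paste0(sum(!keep), " interval(s) dropped: extended window exceeds chromosome bounds"))
  }
  idx <- which(keep)
  seqs <- substr(
    genome[intervals$chrom[idx]],
    new_start[idx] + 1L, new_end[idx]
  )
  minus <- strand[idx] == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  tibble(
    id = name[idx],
    seq = rna_from_dna(unname(seqs)),
    chrom = intervals$chrom[idx],
    start = new_start[idx],
    end = new_end[idx],
    strand = strand[idx],
    label = NA_character_
  )
}

#' Remove redundant binding-site records
#'
#' A record is redundant when its genomic interval tuple
#' `(chrom, start, end, strand)` -- or, for interval-free records, its
#' exact sequence string -- matches an earlier record. The first
#' occurrence is kept.
#'
#' @param records Records tibble.
#' @return Deduplicated records tibble, original order preserved.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  has_interval <- all(c("chrom", "start", "end", "strand") %in% names(records)) &&
    !all(is.na(records$chrom))
  key <- if (has_interval) {
    ifelse(
      is.na(records$chrom),
      paste0("seq:", records$seq),
      paste(records$chrom, records$start, records$end, records$strand, sep = ":")
    )
  } else {
    paste0("seq:", records$seq)
  }
  records[!duplicated(key), , drop = FALSE]
}

#' Shuffle a sequence preserving its exact dinucleotide composition
#'
#' Rearranges a sequence so that the multiset of overlapping dinucleotides
#' (and hence the mononucleotide counts, length, first and last character)
#' is conserved exactly. Implemented as a random Eulerian path over the
#' dinucleotide transition multigraph (the Altschul-Erickson scheme used
#' by the MEME suite's `fasta-dinucleotide-shuffle`).
#'
#' @param seq A single sequence string (length >= 2).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return The shuffled sequence string.
#' @examples
#' dinucleotide_shuffle("ACGUACGUACGU", seed = 1)
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, dinucleotide_shuffle(seq)))
  }
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 2) {
    warn("sequence shorter than 2 nt cannot be dinucleotide-shuffled; returned unchanged")
    return(seq)
  }
  verts <- unique(chars)
  if (length(verts) == 1) return(seq)
  from <- chars[-n]
  to <- chars[-1]
  adj <- split(to, factor(from, levels = verts))
  sink <- chars[n]
  # Vertices (other than the sink) that have outgoing edges each reserve a
  # random "last edge"; the reserved edges must form paths that all reach
  # the sink (an arborescence), which guarantees an Eulerian walk exists.
  nonterm <- setdiff(verts[lengths(adj) > 0], sink)
  last_edge <- character(0)
  if (length(nonterm) > 0) {
    repeat {
      last_edge <- vapply(nonterm, function(v) {
        out <- adj[[v]]
        out[[sample.int(length(out), 1L)]]
      }, character(1))
      if (reaches_sink(last_edge, nonterm, sink)) break
    }
  }
  ordered <- lapply(verts, function(v) {
    out <- adj[[v]]
    if (length(out) == 0) return(character(0))
    if (v %in% nonterm) {
      le <- last_edge[[v]]
      out <- out[-match(le, out)]
      c(shuffle_vec(out), le)
    } else {
      shuffle_vec(out)
    }
  })
  names(ordered) <- verts
  # Walk the Eulerian path from the original first character.
  res <- character(n)
  res[1] <- chars[1]
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][[ptr[[cur]]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

# Does following each vertex's reserved last edge always reach the sink?
reaches_sink <- function(last_edge, nonterm, sink) {
  for (v in nonterm) {
    cur <- v
    steps <- 0L
    while (cur != sink) {
      if (!(cur %in% nonterm)) return(FALSE) # dead end before the sink
      cur <- last_edge[[cur]]
      steps <- steps + 1L
      if (steps > length(nonterm)) return(FALSE) # cycle
    }
  }
  TRUE
}

# sample() on a length-1 vector resamples 1:x; avoid that.
shuffle_vec <- function(x) {
  if (length(x) <= 1) return(x)
  x[sample.int(length(x))]
}

#' Count overlapping dinucleotides
#'
#' @param seq A single sequence string.
#' @return Named integer vector of length 16 over the RNA alphabet
#'   (lexicographic A,C,G,U), counting overlapping dinucleotide
#'   occurrences.
#' @export
dinucleotide_counts <- function(seq) {
  lv <- as.vector(outer(PFM_ALPHABET, PFM_ALPHABET, paste0))
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 2) {
    return(setNames(integer(16), sort(lv)))
  }
  di <- paste0(chars[-length(chars)], chars[-1])
  cnt <- table(factor(di, levels = sort(lv)))
  setNames(as.integer(cnt), names(cnt))
}

#' Generate dinucleotide-matched negative records
#'
#' Builds one negative per positive by dinucleotide-preserving shuffling,
#' so negatives match their source positives in length, mono- and
#' dinucleotide composition but destroy positional sequence signal.
#'
#' @param positives Records tibble of positive-labelled fragments.
#' @param seed Integer seed; the whole negative set is a pure function of
#'   it.
#' @return Records tibble of negatives with `id = paste0(id, "_neg")`,
#'   `label = "negative"` and `pair_id` pointing at the source positive.
#' @export
make_negatives <- function(positives, seed) {
  if (nrow(positives) > 0 && "label" %in% names(positives) &&
    any(!is.na(positives$label) & positives$label != "positive")) {
    abort("make_negatives expects positive-labelled records")
  }
  withr::with_seed(fork_seed(seed, "shuffle"), {
    shuffled <- vapply(positives$seq, dinucleotide_shuffle, character(1), USE.NAMES = FALSE)
  })
  tibble(
    id = paste0(positives$id, "_neg"),
    seq = shuffled,
    label = "negative",
    pair_id = positives$id
  )
}

#' Split records into train / validation / test partitions
#'
#' Random split stratified by label, with shuffle pairs coupled: a
#' positive and its dinucleotide-shuffled negative always land in the same
#' partition, so no sequence composition leaks across partitions. The
#' test partition receives `test_fraction` of the data and the validation
#' partition (used for early stopping) `validation_fraction_of_train` of
#' the remaining training side.
#'
#' @param records Labelled records tibble; a `pair_id` column (as created
#'   by [make_negatives()]) couples shuffle partners.
#' @param test_fraction Fraction held out for testing (default 1/5).
#' @param validation_fraction_of_train Fraction of the training side used
#'   for validation (default 1/10).
#' @param seed Integer seed; the assignment is a pure function of it.
#' @return A `dataset_split` object: list with tibbles `train`,
#'   `validation`, `test` and the `seed`.
#' @export
split_dataset <- function(records, test_fraction = 0.2,
                          validation_fraction_of_train = 0.1, seed = 1L) {
  if (!"label" %in% names(records) || any(is.na(records$label))) {
    abort("split_dataset requires labelled records")
  }
  if (nrow(records) < 10) {
    abort("need at least 10 records to populate train/validation/test")
  }
  pair <- if ("pair_id" %in% names(records)) {
    ifelse(is.na(records$pair_id), records$id, records$pair_id)
  } else {
    sub("_neg$", "", records$id)
  }
  groups <- split(seq_len(nrow(records)), pair)
  # stratify by the label composition of each pair group
  strat_key <- vapply(groups, function(ix) {
    paste(sort(unique(records$label[ix])), collapse = "/")
  }, character(1))
  assign <- character(length(groups))
  names(assign) <- names(groups)
  withr::with_seed(fork_seed(seed, "split"), {
    for (k in unique(strat_key)) {
      g <- names(groups)[strat_key == k]
      g <- g[sample.int(length(g))]
      n_test <- round(length(g) * test_fraction)
      n_val <- round((length(g) - n_test) * validation_fraction_of_train)
      assign[g] <- rep(c("test", "validation", "train"),
        c(n_test, n_val, length(g) - n_test - n_val)
      )
    }
  })
  part_of_record <- assign[pair]
  out <- list(
    train = records[part_of_record == "train", , drop = FALSE],
    validation = records[part_of_record == "validation", , drop = FALSE],
    test = records[part_of_record == "test", , drop = FALSE],
    seed = as.integer(seed)
  )
  structure(out, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>\n")
  for (p in c("train", "validation", "test")) {
    lab <- table(x[[p]]$label)
    cat(sprintf(
      "  %-10s %5d records (%s)\n", p, nrow(x[[p]]),
      paste(names(lab), lab, sep = "=", collapse = ", ")
    ))
  }
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
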