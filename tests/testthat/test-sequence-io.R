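test_that("read_fasta maps T to U, rejects ambiguity codes, handles empty files", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">y desc here", "acgu", ">z", "ACGN"), fa)
  expect_warning(recs <- read_fasta(fa), "rejected")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$seq, c("ACGU", "ACGU"))
  expect_equal(recs$id, c("x", "y"))

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0)
})

test_that("FASTA write/read round-trips records exactly", {
  recs <- toy_records(n = 8, len = 120)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, fa)
  back <- read_fasta(fa)
  expect_equal(back$id, recs$id)
  expect_equal(back$seq, recs$seq)
})

test_that("filter_by_length applies strict 50 < L < 100 bounds and is idempotent", {
  lens <- c(30, 50, 51, 75, 99, 100, 120)
  recs <- tibble::tibble(
    id = paste0("r", seq_along(lens)),
    seq = vapply(lens, function(l) strrep("A", l), character(1))
  )
  kept <- filter_by_length(recs)
  expect_equal(nchar(kept$seq), c(51, 75, 99))
  expect_equal(filter_by_length(kept), kept)
  expect_equal(nrow(filter_by_length(recs[0, ])), 0)
  expect_equal(filter_by_length(recs, 10, 200), recs)
  expect_error(filter_by_length(recs, 99, 51), "min_len")
})

test_that("peak extension emits exactly target_len nt centred on the midpoint", {
  withr::local_seed(7)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = ""))
  # length-73 interval centred near position 1000
  iv <- tibble::tibble(
    chrom = "chr1", start = 964L, end = 1037L, name = "p1",
    score = 0, strand = "+"
  )
  rec <- extend_to_fixed_length(iv, genome, target_len = 100)
  expect_equal(nchar(rec$seq), 100)
  center <- floor((964 + 1037) / 2)
  expect_equal(rec$start, center - 50L)
  expect_equal(rec$end, center + 50L)
  expect_equal(rec$seq, unname(chartr("T", "U", substr(genome, rec$start + 1, rec$end))))

  # interval already 100 nt: sequence unchanged
  iv2 <- tibble::tibble(
    chrom = "chr1", start = 200L, end = 300L, name = "p2",
    score = 0, strand = "+"
  )
  rec2 <- extend_to_fixed_length(iv2, genome, target_len = 100)
  expect_equal(rec2$seq, unname(chartr("T", "U", substr(genome, 201, 300))))
})

test_that("windows overhanging a chromosome end are dropped, not clamped", {
  genome <- c(mini = strrep("ACGT", 25)) # 100 nt
  iv <- tibble::tibble(
    chrom = "mini", start = 10L, end = 70L, name = "edge",
    score = 0, strand = "+"
  )
  expect_message(out <- extend_to_fixed_length(iv, genome, 100), "dropped")
  expect_equal(nrow(out), 0)

  # property: emitted records always have exactly target_len nt
  withr::local_seed(11)
  genome2 <- c(c2 = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""))
  ivs <- tibble::tibble(
    chrom = "c2",
    start = sample(0:450, 40, TRUE)
  )
  ivs$end <- pmin(ivs$start + sample(51:99, 40, TRUE), 500L)
  out2 <- suppressMessages(extend_to_fixed_length(ivs, genome2, 100))
  expect_true(all(nchar(out2$seq) == 100))
})

test_that("minus-strand intervals are reverse-complemented before T->U", {
  genome <- c(chr = strrep("AAAC", 50))
  iv <- tibble::tibble(
    chrom = "chr", start = 60L, end = 120L, name = "m",
    score = 0, strand = "-"
  )
  rec <- extend_to_fixed_length(iv, genome, 100)
  fwd <- substr(genome, rec$start + 1, rec$end)
  expected <- chartr(
    "T", "U",
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  )
  expect_equal(rec$seq, expected)
})

test_that("deduplicate keys on interval tuple, else on sequence", {
  recs <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    seq = c("ACGU", "ACGU", "ACGU", "UGCA"),
    chrom = c("chr1", "chr1", "chr2", NA),
    start = c(0L, 0L, 0L, NA),
    end = c(4L, 4L, 4L, NA),
    strand = c("+", "+", "+", NA)
  )
  out <- deduplicate(recs)
  expect_equal(out$id, c("a", "c", "d")) # b duplicates a's interval
  seq_only <- tibble::tibble(id = c("x", "y", "z"), seq = c("AA", "AA", "CC"))
  expect_equal(deduplicate(seq_only)$id, c("x", "z"))
  distinct <- tibble::tibble(id = c("p", "q"), seq = c("AC", "GU"))
  expect_equal(deduplicate(distinct), distinct)
})

test_that("dinucleotide_shuffle conserves the dinucleotide count vector exactly", {
  withr::local_seed(5)
  for (i in 1:300) {
    len <- sample(2:200, 1)
    s <- rand_rna(len)
    out <- dinucleotide_shuffle(s)
    expect_identical(dinucleotide_counts(out), dinucleotide_counts(s))
    expect_equal(nchar(out), len)
    expect_equal(substr(out, 1, 1), substr(s, 1, 1))
    expect_equal(substr(out, len, len), substr(s, len, len))
  }
})

test_that("dinucleotide_shuffle handles degenerate inputs", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  expect_warning(out <- dinucleotide_shuffle("A"), "shorter")
  expect_equal(out, "A")
  expect_equal(dinucleotide_shuffle("ACGU", seed = 3), dinucleotide_shuffle("ACGU", seed = 3))
})

test_that("shuffled 12-mers lie in the enumerated set of valid rearrangements", {
  s <- "ACGUACGUACGU"
  universe <- shuffle_universe(s)
  expect_true(s %in% universe)
  for (seed in 1:20) {
    expect_true(dinucleotide_shuffle(s, seed = seed) %in% universe)
  }
})

test_that("shuffling actually moves most random 100-mers", {
  withr::local_seed(9)
  moved <- vapply(1:100, function(i) {
    s <- rand_rna(100)
    dinucleotide_shuffle(s) != s
  }, logical(1))
  expect_gte(mean(moved), 0.95)
})

test_that("make_negatives yields one composition-matched negative per positive", {
  pos <- toy_records(n = 10, len = 60)
  pos$label <- "positive"
  neg <- make_negatives(pos, seed = 3)
  expect_equal(nrow(neg), 10)
  expect_true(all(neg$label == "negative"))
  expect_equal(neg$pair_id, pos$id)
  for (i in 1:10) {
    expect_identical(dinucleotide_counts(neg$seq[i]), dinucleotide_counts(pos$seq[i]))
  }
  expect_identical(make_negatives(pos, seed = 3), neg)
  bad <- pos
  bad$label <- "negative"
  expect_error(make_negatives(bad, seed = 1), "positive")
})

test_that("split_dataset is pair-coupled, stratified, 4:1 and reproducible", {
  pos <- tibble::tibble(
    id = sprintf("p%04d", 1:1000),
    seq = rand_rna(100, 1000),
    label = "positive", pair_id = sprintf("p%04d", 1:1000)
  )
  neg <- make_negatives(pos, seed = 2)
  recs <- dplyr::bind_rows(pos, neg)
  sp <- split_dataset(recs, seed = 4)
  n_total <- nrow(recs)
  expect_equal(nrow(sp$test) / n_total, 0.2, tolerance = 1 / n_total)
  expect_equal(nrow(sp$validation), round((1000 - 200) * 0.1) * 2)
  # disjoint ids
  ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_equal(length(ids), length(unique(ids)))
  expect_setequal(ids, recs$id)
  # label balance within 1 in each partition
  for (p in c("train", "validation", "test")) {
    tab <- table(sp[[p]]$label)
    expect_lte(abs(tab[["positive"]] - tab[["negative"]]), 1)
  }
  # pair coupling: every test id has its partner in test
  test_pairs <- sub("_neg$", "", sp$test$id)
  expect_true(all(table(test_pairs) == 2))
  # reproducibility
  sp2 <- split_dataset(recs, seed = 4)
  expect_identical(sp$test$id, sp2$test$id)
  expect_error(split_dataset(recs[1:5, ], seed = 1), "at least 10")
})
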