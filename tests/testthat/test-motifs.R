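# A model whose first width-8 kernel is the scaled one-hot matrix of a
# probe string: its feature map scores windows by match count.
probe_model <- function(probe, L = 60, scale = 1) {
  cfg <- model_config(
    kernel_sizes = c(nchar(probe)), kernels_per_size = 2L, seed = 1L
  )
  m <- build_model(cfg, L = L)
  m$branches[[1]]$W[1, ] <- as.vector(one_hot_encode(probe)) * scale
  m$branches[[1]]$b[1] <- 0
  m$trained <- TRUE
  m
}

test_that("scan_kernel locates a planted exact match with activation = width", {
  probe <- "UAGGUAGG"
  background <- strrep("C", 60)
  seq <- paste0(substr(background, 1, 23), probe, substr(background, 32, 60))
  m <- probe_model(probe, L = 60)
  recs <- tibble::tibble(id = "hit", seq = seq)
  hits <- scan_kernel(m, 1, recs)
  expect_equal(hits$position, 23)
  expect_equal(hits$activation, 8)
  expect_equal(hits$record_id, "hit")
})

test_that("scan_kernel equals the Hamming best-match oracle for one-hot kernels", {
  withr::local_seed(31)
  probe <- rand_rna(8)
  m <- probe_model(probe, L = 60)
  recs <- tibble::tibble(id = paste0("s", 1:40), seq = rand_rna(60, 40))
  hits <- scan_kernel(m, 1, recs)
  for (i in 1:40) {
    expect_equal(hits$position[i], hamming_best_match(recs$seq[i], probe))
  }
  expect_true(all(hits$position >= 0 & hits$position <= 60 - 8))
})

test_that("an all-zero kernel gives zero activation at the first window", {
  m <- probe_model("ACGUACGU", L = 40, scale = 0)
  recs <- tibble::tibble(id = paste0("s", 1:5), seq = rand_rna(40, 5))
  hits <- scan_kernel(m, 1, recs)
  expect_true(all(hits$activation == 0))
  expect_true(all(hits$position == 0))
  expect_error(scan_kernel(m, 99, recs), "kernel_id")
})

test_that("build_pfm tallies aligned subsequences with threshold and pseudocount", {
  recs <- tibble::tibble(
    id = paste0("r", 1:10),
    seq = paste0(strrep("C", 5), "ACGUACGU", strrep("C", 7))
  )
  hits <- tibble::tibble(
    kernel_id = 1L, record_id = recs$id, position = 5L, activation = 8
  )
  pfm <- build_pfm(hits, recs, h = 8, pseudocount = 0)
  expect_equal(pfm$nsites, 10)
  expect_equal(pfm_consensus(pfm), "ACGUACGU")
  expect_true(all(apply(pfm$probs, 2, max) == 1))
  expect_equal(colSums(pfm$probs), rep(1, 8))

  # mixed stack: AAAA and CCCC give (0.5, 0.5, 0, 0) columns over (A, C)
  recs2 <- tibble::tibble(id = c("a", "b"), seq = c("AAAA", "CCCC"))
  hits2 <- tibble::tibble(
    kernel_id = 2L, record_id = c("a", "b"), position = 0L, activation = c(4, 4)
  )
  pfm2 <- build_pfm(hits2, recs2, h = 4, pseudocount = 0)
  expect_equal(unname(pfm2$probs["A", ]), rep(0.5, 4))
  expect_equal(unname(pfm2$probs["C", ]), rep(0.5, 4))
  expect_equal(unname(pfm2$probs["G", ]), rep(0, 4))

  # activation threshold: hits under half the kernel max are excluded
  hits3 <- hits
  hits3$activation <- c(8, rep(3, 9))
  pfm3 <- build_pfm(hits3, recs, h = 8)
  expect_equal(pfm3$nsites, 1)
  hits4 <- hits
  hits4$activation <- 0
  expect_error(build_pfm(hits4, recs, h = 8), "inactive")
})

test_that("MEME minimal format round-trips probabilities", {
  withr::local_seed(17)
  pfms <- lapply(c(8, 20), function(w) {
    counts <- matrix(stats::runif(4 * w, 0.1, 5), nrow = 4,
      dimnames = list(c("A", "C", "G", "U"), NULL)
    )
    circsites:::new_pfm(counts, nsites = 30, kernel_id = w)
  })
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pfms, path, background = c(0.3, 0.2, 0.2, 0.3))
  back <- read_meme(path)
  expect_length(back, 2)
  expect_lt(max(abs(back[["KER_8"]]$probs - pfms[[1]]$probs)), 1e-6)
  expect_lt(max(abs(back[["KER_20"]]$probs - pfms[[2]]$probs)), 1e-6)
  expect_equal(ncol(back[["KER_20"]]$probs), 20)
  expect_equal(back[["KER_8"]]$nsites, 30)

  # header-only file for an empty motif list is still valid
  empty_path <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(), empty_path)
  expect_length(read_meme(empty_path), 0)

  # missing version line rejected
  bad <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MOTIF X", "letter-probability matrix: alength= 4 w= 2"), bad)
  expect_error(read_meme(bad), "version")
  expect_error(write_meme(pfms, path, background = c(1, 1, 1, 1)), "summing")
})

test_that("compare_pfm finds identity and shifted alignments", {
  withr::local_seed(23)
  # non-periodic sharp motif so the best offset is unambiguous
  a <- motif_pwm("ACGGAUUC", 0.9)
  expect_equal(compare_pfm(a, a), list(best_offset = 0L, score = 1))

  # b carries a's columns starting at its column 3 => offset 2
  flanks <- matrix(stats::runif(8), nrow = 4)
  flanks <- sweep(flanks, 2, colSums(flanks), `/`)
  b <- cbind(flanks, a)
  cmp <- compare_pfm(a, b)
  expect_equal(cmp$best_offset, 2L)
  expect_equal(cmp$score, 1, tolerance = 1e-9)

  # uniform columns have zero variance and contribute 0
  u <- matrix(0.25, nrow = 4, ncol = 6)
  expect_equal(compare_pfm(u, u)$score, 0)

  expect_error(compare_pfm(a[, 1:3, drop = FALSE], a), "overlap")
})

test_that("discover_motifs exports active kernels per branch", {
  cfg <- synthetic_config(n_pairs = 40, pwm = motif_pwm("UAGGUAGG", 1.0), seed = 3)
  ds <- generate_dataset(cfg)
  m <- probe_model("UAGGUAGG", L = 100)
  pos <- dplyr::filter(ds$records, label == "positive")
  pfms <- suppressMessages(discover_motifs(m, pos, branch = 8))
  expect_gte(length(pfms), 1)
  expect_true(all(grepl("^KER_", names(pfms))))
  # the engineered kernel recovers the planted consensus
  expect_equal(pfm_consensus(pfms[["KER_1"]]), "UAGGUAGG")
  expect_error(discover_motifs(m, pos, branch = 12), "no branch")
})
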