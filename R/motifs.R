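#' Scan sequences with one learnt convolution kernel
#'
#' The convolution kernels act as motif scanners: for each record the
#' position of the maximum entry of the kernel's ReLU feature map is
#' taken as the start of a putative motif instance, and the maximum
#' itself as the activation. Ties resolve to the leftmost position.
#'
#' @param model A trained `rbp_cnn`.
#' @param kernel_id Global kernel index, 1-based across branches in
#'   config order (branch 1 kernels first).
#' @param records Records tibble, sequences of the model input length.
#' @return Tibble with `kernel_id`, `record_id`, `position` (0-based
#'   window start) and `activation` (>= 0), one row per record.
#' @export
scan_kernel <- function(model, kernel_id, records) {
  loc <- locate_kernel(model, kernel_id)
  br <- model$branches[[loc$branch]]
  kernel <- list(h = br$h, W = br$W[loc$k, , drop = FALSE], b = br$b[loc$k])
  idx <- window_flat_index(br$h, model$L)
  codes <- seqs_to_int(records$seq)
  N <- ncol(codes)
  pos <- integer(N)
  act <- numeric(N)
  for (start in seq(1L, N, by = 512L)) {
    take <- start:min(start + 511L, N)
    X <- onehot_batch(codes[, take, drop = FALSE])
    sc <- branch_forward(X, kernel, idx)
    pos[take] <- as.integer(sc$J[1, ]) - 1L
    act[take] <- sc$P[1, ]
  }
  tibble(
    kernel_id = as.integer(kernel_id),
    record_id = records$id,
    position = pos,
    activation = act
  )
}

locate_kernel <- function(model, kernel_id) {
  K <- nrow(model$branches[[1]]$W)
  total <- K * length(model$branches)
  if (kernel_id < 1 || kernel_id > total) {
    abort(paste0("kernel_id must be in 1..", total))
  }
  list(
    branch = ((kernel_id - 1L) %/% K) + 1L,
    k = ((kernel_id - 1L) %% K) + 1L
  )
}

#' Aggregate kernel hits into a position frequency matrix
#'
#' Keeps the hits whose activation reaches at least
#' `min_activation_fraction` of the kernel's maximum over the scanned set
#' (and is strictly positive), stacks the aligned h-long subsequences,
#' and tallies symbols per column with a uniform pseudocount.
#'
#' @param hits Hit tibble from [scan_kernel()] (one kernel only).
#' @param records Records tibble containing every `record_id` in `hits`.
#' @param h Kernel width.
#' @param min_activation_fraction Activation threshold as a fraction of
#'   the kernel's maximum (default 0.5).
#' @param pseudocount Added to every count cell (default 0.25).
#' @return A `pfm` object: list with `counts` and column-stochastic
#'   `probs` (4 x h, rows A,C,G,U), `nsites`, and `kernel_id`.
#' @export
build_pfm <- function(hits, records, h, min_activation_fraction = 0.5,
                      pseudocount = 0.25) {
  if (length(unique(hits$kernel_id)) > 1) {
    abort("hits must come from a single kernel")
  }
  seqs <- setNames(records$seq, records$id)
  if (!all(hits$record_id %in% names(seqs))) {
    abort("records must contain every record_id in hits")
  }
  amax <- max(hits$activation)
  keep <- hits$activation > 0 & hits$activation >= min_activation_fraction * amax
  if (!any(keep)) {
    abort(paste0("kernel ", hits$kernel_id[1], " inactive: no hits pass the threshold"))
  }
  kept <- hits[keep, , drop = FALSE]
  subseq <- substr(seqs[kept$record_id], kept$position + 1L, kept$position + h)
  counts <- matrix(pseudocount,
    nrow = 4, ncol = h,
    dimnames = list(PFM_ALPHABET, NULL)
  )
  chars <- matrix(unlist(strsplit(subseq, ""), use.names = FALSE), nrow = h)
  for (j in seq_len(h)) {
    tab <- table(factor(chars[j, ], levels = PFM_ALPHABET))
    counts[, j] <- counts[, j] + as.integer(tab)
  }
  new_pfm(counts, nsites = nrow(kept), kernel_id = hits$kernel_id[1])
}

new_pfm <- function(counts, nsites, kernel_id = NA_integer_, name = NULL) {
  probs <- sweep(counts, 2, colSums(counts), `/`)
  structure(
    list(
      counts = counts, probs = probs, nsites = as.integer(nsites),
      kernel_id = as.integer(kernel_id),
      name = name %||% paste0("KER_", kernel_id),
      alphabet = PFM_ALPHABET
    ),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat(
    "<pfm> ", x$name, ": width ", ncol(x$probs), ", nsites ", x$nsites,
    ", consensus ", pfm_consensus(x), "\n",
    sep = ""
  )
  invisible(x)
}

#' Consensus string of a PFM
#'
#' @param pfm A `pfm` object.
#' @return Character string of per-column modal symbols.
#' @export
pfm_consensus <- function(pfm) {
  paste(PFM_ALPHABET[apply(pfm$probs, 2, which.max)], collapse = "")
}

#' Discover motifs from all kernels of a trained model
#'
#' Scans the given (typically positive, bound-class) sequences with every
#' kernel of the selected branch width(s) and converts each active kernel
#' into a position frequency matrix. Inactive kernels (no hit passing the
#' activation threshold) are skipped with a message.
#'
#' @param model A trained `rbp_cnn`.
#' @param records Records tibble to scan (positive class recommended).
#' @param branch Kernel width to export, or `"all"` (default).
#' @param min_activation_fraction,pseudocount Passed to [build_pfm()].
#' @return List of `pfm` objects named by kernel (`KER_<i>`).
#' @export
discover_motifs <- function(model, records, branch = "all",
                            min_activation_fraction = 0.5, pseudocount = 0.25) {
  if (!model$trained) abort("model must be trained before motif discovery")
  K <- nrow(model$branches[[1]]$W)
  widths <- vapply(model$branches, `[[`, integer(1), "h")
  sel_branches <- if (identical(branch, "all")) {
    seq_along(widths)
  } else {
    which(widths == as.integer(branch))
  }
  if (length(sel_branches) == 0) {
    abort(paste0("no branch of width ", branch, "; available: ", paste(widths, collapse = ", ")))
  }
  pfms <- list()
  skipped <- 0L
  for (bi in sel_branches) {
    for (k in seq_len(K)) {
      kid <- (bi - 1L) * K + k
      hits <- scan_kernel(model, kid, records)
      pfm <- tryCatch(
        build_pfm(hits, records, widths[bi],
          min_activation_fraction = min_activation_fraction,
          pseudocount = pseudocount
        ),
        error = function(e) NULL
      )
      if (is.null(pfm)) {
        skipped <- skipped + 1L
      } else {
        pfms[[pfm$name]] <- pfm
      }
    }
  }
  if (skipped > 0) inform(paste0(skipped, " inactive kernel(s) skipped"))
  pfms
}

#' Write motifs in MEME minimal format
#'
#' Writes an RNA-alphabet MEME minimal motif file (version line,
#' `ALPHABET= ACGU`, background frequencies, one `MOTIF` block with a
#' letter-probability matrix per PFM) accepted by the MEME suite parsers.
#'
#' @param pfms List of `pfm` objects (possibly empty).
#' @param path Output path.
#' @param background Length-4 background frequency vector over A,C,G,U;
#'   defaults to uniform.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfms, path, background = rep(0.25, 4)) {
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
    abort("background must be 4 frequencies summing to 1")
  }
  lines <- c(
    "MEME version 4",
    "",
    "ALPHABET= ACGU",
    "",
    "Background letter frequencies",
    paste(
      sprintf("%s %.6f", PFM_ALPHABET, background),
      collapse = " "
    ),
    ""
  )
  for (pfm in pfms) {
    w <- ncol(pfm$probs)
    lines <- c(
      lines,
      paste0("MOTIF ", pfm$name),
      sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
        w, pfm$nsites
      ),
      vapply(seq_len(w), function(j) {
        paste(sprintf("%10.6f", pfm$probs[, j]), collapse = " ")
      }, character(1)),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' @param path Path to a MEME minimal motif file.
#' @return List of `pfm` objects (probabilities as printed; `nsites`
#'   parsed when present, otherwise 20).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    abort(paste0("not a MEME minimal file (missing version line): ", path))
  }
  motif_at <- grep("^MOTIF\\s+", lines)
  pfms <- list()
  for (mi in motif_at) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    li <- mi + 1L
    while (li <= length(lines) && !grepl("^letter-probability matrix", lines[li])) {
      if (li - mi > 5 || grepl("^MOTIF", lines[li])) {
        abort(paste0("malformed motif block at line ", mi, ": no letter-probability matrix"))
      }
      li <- li + 1L
    }
    hdr <- lines[li]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    } else {
      20L
    }
    if (is.na(w)) abort(paste0("cannot parse motif width at line ", li))
    rows <- lines[(li + 1L):(li + w)]
    vals <- lapply(seq_along(rows), function(r) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[r]), "\\s+")[[1]]))
      if (length(v) != 4 || anyNA(v)) {
        abort(paste0("malformed probability row at line ", li + r))
      }
      v
    })
    probs <- matrix(unlist(vals),
      nrow = 4,
      dimnames = list(PFM_ALPHABET, NULL)
    )
    kid <- suppressWarnings(as.integer(sub("^KER_", "", name)))
    pfm <- new_pfm(probs * nsites, nsites = nsites, kernel_id = kid, name = name)
    pfm$probs <- probs # as printed, not renormalised
    pfms[[name]] <- pfm
  }
  pfms
}

#' Ungapped alignment similarity of two PFMs
#'
#' Slides `b` across `a` over every ungapped offset with at least
#' `min_overlap` aligned columns and scores each offset by the mean
#' per-column Pearson correlation of the probability columns
#' (zero-variance columns contribute 0). Used to verify motif recovery
#' against a known (e.g. planted) PWM without an external alignment
#' service.
#'
#' @param a,b `pfm` objects (or bare 4 x w probability matrices over
#'   A,C,G,U), widths >= `min_overlap`.
#' @param min_overlap Minimum aligned columns (default 4).
#' @return List with `best_offset` (offset `d` aligning column `j` of
#'   `a` with column `j + d` of `b`, so a positive offset means `a`'s
#'   content sits `d` columns into `b`; ties resolve to the smallest
#'   offset) and `score` in `[-1, 1]`.
#' @export
compare_pfm <- function(a, b, min_overlap = 4L) {
  pa <- if (inherits(a, "pfm")) a$probs else a
  pb <- if (inherits(b, "pfm")) b$probs else b
  wa <- ncol(pa)
  wb <- ncol(pb)
  if (min(wa, wb) < min_overlap) {
    abort(paste0("PFM widths must allow an overlap of ", min_overlap, " columns"))
  }
  offsets <- seq(-(wa - min_overlap), wb - min_overlap)
  best <- list(best_offset = NA_integer_, score = -Inf)
  for (d in offsets) {
    ja <- max(1L, 1L - d):min(wa, wb - d) # columns of a in the overlap
    jb <- ja + d
    sc <- mean(vapply(seq_along(ja), function(i) {
      x <- pa[, ja[i]]
      y <- pb[, jb[i]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
      stats::cor(x, y)
    }, numeric(1)))
    if (sc > best$score) best <- list(best_offset = as.integer(d), score = sc)
  }
  best
}
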