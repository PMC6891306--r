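#' Build a position weight matrix from a consensus string
#'
#' Each column puts `sharpness` probability on the consensus symbol and
#' spreads the remainder uniformly over the other three, giving a planted
#' motif whose strength is tunable from near-degenerate (`sharpness` close
#' to 1) to invisible (0.25).
#'
#' @param consensus RNA consensus string, e.g. `"UAGGUAGG"`.
#' @param sharpness Probability of the consensus symbol per column
#'   (default 0.85).
#' @return 4 x w column-stochastic matrix with rows A,C,G,U.
#' @export
motif_pwm <- function(consensus = "UAGGUAGG", sharpness = 0.85) {
  chars <- strsplit(toupper(consensus), "")[[1]]
  if (any(!chars %in% PFM_ALPHABET)) abort("consensus must be over {A,C,G,U}")
  if (sharpness <= 0 || sharpness > 1) abort("sharpness must be in (0, 1]")
  w <- length(chars)
  pwm <- matrix((1 - sharpness) / 3,
    nrow = 4, ncol = w,
    dimnames = list(PFM_ALPHABET, NULL)
  )
  pwm[cbind(match(chars, PFM_ALPHABET), seq_len(w))] <- sharpness
  pwm
}

default_background <- function() {
  # mildly skewed first-order transitions so that dinucleotide shuffling
  # is non-trivial (a uniform i.i.d. background would make mono- and
  # dinucleotide matching coincide)
  trans <- rbind(
    c(0.3, 0.3, 0.2, 0.2),
    c(0.2, 0.3, 0.3, 0.2),
    c(0.2, 0.2, 0.3, 0.3),
    c(0.3, 0.2, 0.2, 0.3)
  )
  dimnames(trans) <- list(PFM_ALPHABET, PFM_ALPHABET)
  list(initial = setNames(rep(0.25, 4), PFM_ALPHABET), transition = trans)
}

#' Configuration for the planted-motif synthetic benchmark
#'
#' Describes a dataset with the statistical structure the classifier
#' assumes: positives are fragments from a first-order Markov background
#' carrying one embedded motif instance sampled from a PWM, negatives are
#' dinucleotide-preserving shuffles of the positives.
#'
#' @param n_pairs Number of positive/negative pairs.
#' @param length Fragment length in nt (default 100).
#' @param background List with `initial` (length-4) and `transition`
#'   (4 x 4 row-stochastic) over A,C,G,U; default mildly skewed.
#' @param pwm Planted motif PWM (default [motif_pwm()] of `"UAGGUAGG"`
#'   at sharpness 0.85).
#' @param plant_probability Probability that a positive actually receives
#'   a motif instance (default 1; 0 yields a no-signal null dataset).
#' @param seed Integer seed; the dataset is a pure function of it.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_pairs, length = 100L, background = default_background(),
                             pwm = motif_pwm(), plant_probability = 1, seed = 1L) {
  if (any(abs(rowSums(background$transition) - 1) > 1e-9)) {
    abort("background transition rows must sum to 1")
  }
  if (abs(sum(background$initial) - 1) > 1e-9) {
    abort("background initial distribution must sum to 1")
  }
  if (any(abs(colSums(pwm) - 1) > 1e-9)) abort("pwm columns must sum to 1")
  if (ncol(pwm) > length) abort("pwm width exceeds fragment length")
  if (plant_probability < 0 || plant_probability > 1) {
    abort("plant_probability must be in [0, 1]")
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs), length = as.integer(length),
      background = background, pwm = pwm,
      plant_probability = plant_probability, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Sample fragments from the Markov background
#'
#' The first symbol is drawn from the initial distribution, each later
#' symbol from the transition row of its predecessor.
#'
#' @param config A `synthetic_config`.
#' @param n Number of fragments (default 1).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Character vector of `n` RNA fragments of `config$length` nt.
#' @export
sample_background <- function(config, n = 1L, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(fork_seed(seed, "background"), sample_background(config, n)))
  }
  L <- config$length
  init <- config$background$initial
  trans <- config$background$transition
  codes <- matrix(0L, nrow = L, ncol = n)
  codes[1, ] <- sample.int(4, n, replace = TRUE, prob = init)
  for (j in seq_len(L - 1L)) {
    prev <- codes[j, ]
    nxt <- integer(n)
    for (s in 1:4) {
      at <- prev == s
      if (any(at)) nxt[at] <- sample.int(4, sum(at), replace = TRUE, prob = trans[s, ])
    }
    codes[j + 1L, ] <- nxt
  }
  apply(codes, 2, function(cc) paste(PFM_ALPHABET[cc], collapse = ""))
}

#' Plant one PWM instance into a fragment
#'
#' Samples a string from the PWM (independent columns) and overwrites the
#' fragment at a uniformly random offset chosen so the instance never
#' straddles a fragment edge.
#'
#' @param seq Fragment string.
#' @param pwm 4 x w column-stochastic matrix over A,C,G,U.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List with `seq` (modified fragment), `position` (0-based
#'   instance start) and `planted` (the sampled instance string).
#' @export
plant_motif <- function(seq, pwm, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(fork_seed(seed, "plant"), plant_motif(seq, pwm)))
  }
  w <- ncol(pwm)
  L <- nchar(seq)
  if (w > L) abort("pwm wider than the fragment")
  inst <- paste(
    PFM_ALPHABET[vapply(seq_len(w), function(j) {
      sample.int(4, 1, prob = pwm[, j])
    }, integer(1))],
    collapse = ""
  )
  pos <- sample.int(L - w + 1L, 1) - 1L # 0-based
  list(
    seq = paste0(substr(seq, 1, pos), inst, substr(seq, pos + w + 1L, L)),
    position = pos,
    planted = inst
  )
}

#' Generate a labelled planted-motif dataset
#'
#' Draws `n_pairs` background fragments, plants a PWM instance into each
#' with probability `plant_probability` (these are the positives), and
#' produces one dinucleotide-preserving shuffle per positive as its
#' matched negative. Ground truth (instance positions and the PWM) is
#' retained for motif-recovery checks.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (labelled, pair-coupled records tibble of
#'   `2 * n_pairs` rows) and `truth` (tibble `id`, `position`, `planted`;
#'   `position` is `NA` for unplanted positives) plus the `pwm` used.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_pairs
  withr::with_seed(fork_seed(config$seed, "background"), {
    seqs <- sample_background(config, n)
    planted_flag <- stats::runif(n) < config$plant_probability
    position <- rep(NA_integer_, n)
    planted <- rep(NA_character_, n)
    for (i in which(planted_flag)) {
      pl <- plant_motif(seqs[i], config$pwm)
      seqs[i] <- pl$seq
      position[i] <- pl$position
      planted[i] <- pl$planted
    }
  })
  positives <- tibble(
    id = sprintf("pos_%05d", seq_len(n)),
    seq = seqs,
    label = "positive",
    pair_id = sprintf("pos_%05d", seq_len(n))
  )
  negatives <- make_negatives(positives, seed = config$seed)
  list(
    records = bind_rows(positives, negatives),
    truth = tibble(id = positives$id, position = position, planted = planted),
    pwm = config$pwm
  )
}
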