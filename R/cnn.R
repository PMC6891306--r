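#' Configuration for the multi-branch convolutional classifier
#'
#' The model runs one convolution layer per kernel size ("branch") over
#' the one-hot input, applies ReLU and global max-pooling per kernel,
#' concatenates the pooled features from all branches, and classifies
#' them with a dropout-regularised two-unit softmax dense layer. Defaults
#' follow the full-scale setting (three branches of sizes 8/20/38 with
#' 1024 kernels each, Adam, batch 512, at most 50 epochs with early
#' stopping on validation accuracy); tests and desk-scale experiments
#' shrink `kernels_per_size`, `batch_size` and `max_epochs`.
#'
#' @param kernel_sizes Integer vector of convolution widths (default
#'   `c(8, 20, 38)`).
#' @param kernels_per_size Number of kernels per branch (default 1024).
#' @param dropout_rate Dropout fraction before the dense layer, in
#'   `[0, 1)` (default 0.5).
#' @param batch_size Minibatch size (default 512).
#' @param max_epochs Maximum training epochs (default 50).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience in epochs without validation
#'   accuracy improvement (default 5).
#' @param seed Integer seed controlling initialisation, batch order and
#'   dropout.
#' @return A `model_config` object.
#' @export
model_config <- function(kernel_sizes = c(8L, 20L, 38L), kernels_per_size = 1024L,
                         dropout_rate = 0.5, batch_size = 512L, max_epochs = 50L,
                         learning_rate = 1e-3, patience = 5L, seed = 1L) {
  if (kernels_per_size < 1) abort("kernels_per_size must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  if (any(kernel_sizes < 1)) abort("kernel sizes must be positive")
  structure(
    list(
      kernel_sizes = as.integer(kernel_sizes),
      kernels_per_size = as.integer(kernels_per_size),
      dropout_rate = dropout_rate,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      learning_rate = learning_rate,
      patience = as.integer(patience),
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

#' Build an (untrained) convolutional binding-site model
#'
#' Allocates seeded Glorot-uniform weights for every branch and for the
#' dense softmax layer. Two builds with the same config and input length
#' have bit-identical initial weights.
#'
#' @param config A [model_config()].
#' @param L Input fragment length in nt (default 100).
#' @return An `rbp_cnn` model object (untrained).
#' @export
build_model <- function(config, L = 100L) {
  if (!inherits(config, "model_config")) abort("config must be a model_config")
  if (any(config$kernel_sizes > L)) {
    abort(paste0(
      "kernel size ", max(config$kernel_sizes),
      " exceeds input length L = ", L
    ))
  }
  K <- config$kernels_per_size
  withr::with_seed(fork_seed(config$seed, "init"), {
    branches <- lapply(config$kernel_sizes, function(h) {
      fan_in <- 4L * h
      lim <- sqrt(6 / (fan_in + K))
      list(
        h = as.integer(h),
        W = matrix(runif(K * fan_in, -lim, lim), nrow = K), # K x 4h
        b = numeric(K)
      )
    })
    nf <- length(config$kernel_sizes) * K
    lim2 <- sqrt(6 / (nf + 2))
    W2 <- matrix(runif(2 * nf, -lim2, lim2), nrow = 2)
    b2 <- numeric(2)
  })
  structure(
    list(
      config = config, L = as.integer(L),
      branches = branches, W2 = W2, b2 = b2,
      trained = FALSE, history = NULL,
      best_epoch = NA_integer_
    ),
    class = "rbp_cnn"
  )
}

# Flat one-hot row indices of the sliding windows: a 4h x (L-h+1) matrix
# whose column j indexes the 4xh window starting at position j of a
# column-major flattened 4xL one-hot matrix.
window_flat_index <- function(h, L) {
  outer(seq_len(4L * h), (0:(L - h)) * 4L, `+`)
}

# Dense 4L x B one-hot batch from an L x B integer-code matrix.
onehot_batch <- function(codes) {
  L <- nrow(codes)
  B <- ncol(codes)
  X <- matrix(0, 4L * L, B)
  rows <- as.vector(codes) + rep((seq_len(L) - 1L) * 4L, times = B)
  X[cbind(rows, rep(seq_len(B), each = L))] <- 1
  X
}

# One branch forward: returns pooled activations P (K x B), argmax window
# J (K x B, 1-based) and, when cached, the im2col matrix A.
branch_forward <- function(X, branch, idx, keep_cache = FALSE) {
  h <- branch$h
  B <- ncol(X)
  Wn <- ncol(idx)
  A <- matrix(X[as.vector(idx), , drop = FALSE], nrow = 4L * h) # 4h x (Wn*B)
  Z <- branch$W %*% A + branch$b
  Z[Z < 0] <- 0
  P <- Z[, seq(1L, by = Wn, length.out = B), drop = FALSE]
  J <- matrix(1L, nrow(P), B)
  if (Wn > 1) {
    for (j in 2:Wn) {
      Zj <- Z[, seq(j, by = Wn, length.out = B), drop = FALSE]
      upd <- Zj > P
      J[upd] <- j
      P[upd] <- Zj[upd]
    }
  }
  out <- list(P = P, J = J)
  if (keep_cache) out$A <- A
  out
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), `/`)
}

# Full forward over an integer-coded batch. Returns class probabilities
# (2 x B, rows negative/positive) and caches for backprop when asked.
cnn_forward_batch <- function(model, codes, idx_list, dropout_mask = NULL,
                              keep_cache = FALSE) {
  X <- onehot_batch(codes)
  br <- lapply(seq_along(model$branches), function(i) {
    branch_forward(X, model$branches[[i]], idx_list[[i]], keep_cache = keep_cache)
  })
  F <- do.call(rbind, lapply(br, `[[`, "P")) # (nbranch*K) x B
  Fd <- if (is.null(dropout_mask)) F else F * dropout_mask
  logits <- model$W2 %*% Fd + model$b2
  probs <- softmax_cols(logits)
  out <- list(probs = probs, F = F, Fd = Fd)
  if (keep_cache) out$branches <- br
  out
}

#' Convolve one kernel over a one-hot matrix
#'
#' Computes the ReLU feature map `c[i] = max(0, sum(w * M[, i:(i+h-1)]) + b)`
#' over all valid (unpadded) window positions `i = 1..L-h+1`.
#'
#' @param M 4 x L one-hot matrix (as from [one_hot_encode()]).
#' @param w 4 x h kernel weight matrix.
#' @param b Scalar bias.
#' @return Numeric feature map of length `L - h + 1`, all entries >= 0.
#' @export
conv_forward <- function(M, w, b = 0) {
  if (!is.matrix(M) || nrow(M) != 4) abort("M must be a 4 x L matrix")
  if (!is.matrix(w) || nrow(w) != 4) abort("w must be a 4 x h matrix")
  h <- ncol(w)
  L <- ncol(M)
  if (h > L) abort("kernel width exceeds sequence length")
  idx <- window_flat_index(h, L)
  A <- matrix(as.vector(M)[idx], nrow = 4L * h)
  z <- as.vector(crossprod(A, as.vector(w))) + b
  pmax(z, 0)
}

#' Global max-pooling of a feature map
#'
#' @param c Numeric feature map (non-empty).
#' @return Its maximum entry.
#' @export
global_max_pool <- function(c) {
  if (length(c) == 0) abort("cannot pool an empty feature map")
  max(c)
}

#' Forward pass for a single fragment
#'
#' Applies every branch's kernels, global max-pooling, concatenation and
#' the softmax dense layer (dropout inactive at inference).
#'
#' @param model An `rbp_cnn` model.
#' @param M 4 x L one-hot matrix; `L` must match the model input length.
#' @return Named probability pair `c(negative = , positive = )` summing
#'   to 1.
#' @export
forward <- function(model, M) {
  if (!inherits(model, "rbp_cnn")) abort("model must be an rbp_cnn")
  if (!is.matrix(M) || nrow(M) != 4 || ncol(M) != model$L) {
    abort(paste0("input must be a 4 x ", model$L, " one-hot matrix"))
  }
  codes <- matrix(apply(M, 2, which.max), ncol = 1)
  idx_list <- lapply(model$branches, function(br) window_flat_index(br$h, model$L))
  p <- cnn_forward_batch(model, codes, idx_list)$probs[, 1]
  setNames(p, c("negative", "positive"))
}

# ---- Adam ----

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

collect_params <- function(model) {
  out <- list()
  for (i in seq_along(model$branches)) {
    out[[paste0("convW", i)]] <- model$branches[[i]]$W
    out[[paste0("convb", i)]] <- model$branches[[i]]$b
  }
  out$denseW <- model$W2
  out$denseb <- model$b2
  out
}

set_params <- function(model, params) {
  for (i in seq_along(model$branches)) {
    model$branches[[i]]$W <- params[[paste0("convW", i)]]
    model$branches[[i]]$b <- params[[paste0("convb", i)]]
  }
  model$W2 <- params$denseW
  model$b2 <- params$denseb
  model
}

#' Train the convolutional binding-site classifier
#'
#' Minimises the softmax cross-entropy with Adam over seeded shuffled
#' minibatches. After every epoch the model is evaluated on the
#' validation partition; training stops when `max_epochs` is reached or
#' validation accuracy has not improved for `patience` epochs, and the
#' weights from the best validation-accuracy epoch are returned.
#'
#' @param model An `rbp_cnn` from [build_model()].
#' @param split A `dataset_split` (or a list with labelled `train` and
#'   `validation` record tibbles).
#' @param config Optional [model_config()] overriding `model$config`.
#' @param verbose Print one line per epoch (default FALSE).
#' @return The trained `rbp_cnn` with `history` (per-epoch tibble of loss
#'   and accuracy on train and validation) and `best_epoch` filled in.
#' @export
train_model <- function(model, split, config = model$config, verbose = FALSE) {
  if (nrow(split$train) == 0 || nrow(split$validation) == 0) {
    abort("train and validation partitions must be non-empty")
  }
  lens <- unique(nchar(c(split$train$seq, split$validation$seq)))
  if (length(lens) != 1 || lens != model$L) {
    abort(paste0("all sequences must have length L = ", model$L))
  }
  Xtr <- seqs_to_int(split$train$seq)
  ytr <- as.integer(split$train$label == "positive")
  Xval <- seqs_to_int(split$validation$seq)
  yval <- as.integer(split$validation$label == "positive")
  idx_list <- lapply(model$branches, function(br) window_flat_index(br$h, model$L))
  N <- ncol(Xtr)
  B <- min(config$batch_size, N)
  p_drop <- config$dropout_rate
  K <- nrow(model$branches[[1]]$W)
  nfeat <- length(model$branches) * K

  params <- collect_params(model)
  states <- adam_init(params)
  t_step <- 0L
  history <- list()
  best_acc <- -Inf
  best_params <- params
  best_epoch <- 0L
  since_improve <- 0L

  withr::with_seed(fork_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      model <- set_params(model, params)
      perm <- sample.int(N)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1L, N, by = B)) {
        take <- perm[start:min(start + B - 1L, N)]
        nb <- length(take)
        codes <- Xtr[, take, drop = FALSE]
        y <- ytr[take]
        mask <- if (p_drop > 0) {
          matrix(stats::rbinom(nfeat * nb, 1L, 1 - p_drop), nfeat, nb) / (1 - p_drop)
        } else {
          NULL
        }
        fw <- cnn_forward_batch(model, codes, idx_list,
          dropout_mask = mask, keep_cache = TRUE
        )
        probs <- fw$probs
        Tmat <- rbind(1 - y, y)
        loss <- -mean(log(pmax(probs[cbind(y + 1L, seq_len(nb))], 1e-12)))
        if (!is.finite(loss)) abort("non-finite training loss; aborting")
        ep_loss <- ep_loss + loss * nb
        ep_correct <- ep_correct + sum((probs[2, ] > 0.5) == (y == 1))

        # backward
        dlogits <- (probs - Tmat) / nb # 2 x nb
        grads <- list()
        grads$denseW <- dlogits %*% t(fw$Fd)
        grads$denseb <- rowSums(dlogits)
        dFd <- crossprod(model$W2, dlogits) # nfeat x nb
        dF <- if (is.null(mask)) dFd else dFd * mask
        for (i in seq_along(model$branches)) {
          rows <- ((i - 1L) * K + 1L):(i * K)
          br <- fw$branches[[i]]
          Wn <- ncol(idx_list[[i]])
          dP <- dF[rows, , drop = FALSE]
          dP[br$P <= 0] <- 0
          dZ <- matrix(0, K, Wn * nb)
          cols <- rep((seq_len(nb) - 1L) * Wn, each = K) + as.vector(br$J)
          dZ[cbind(rep(seq_len(K), nb), cols)] <- as.vector(dP)
          grads[[paste0("convW", i)]] <- dZ %*% t(br$A)
          grads[[paste0("convb", i)]] <- rowSums(dZ)
        }
        t_step <- t_step + 1L
        for (nm in names(params)) {
          upd <- adam_update(params[[nm]], grads[[nm]], states[[nm]],
            lr = config$learning_rate, t = t_step
          )
          params[[nm]] <- upd$p
          states[[nm]] <- upd$st
        }
        model <- set_params(model, params)
      }
      model <- set_params(model, params)
      val <- evaluate_on(model, Xval, yval, idx_list)
      tr_loss <- ep_loss / N
      tr_acc <- ep_correct / N
      history[[epoch]] <- tibble(
        epoch = epoch, train_loss = tr_loss, train_accuracy = tr_acc,
        val_loss = val$loss, val_accuracy = val$accuracy
      )
      if (verbose) {
        inform(sprintf(
          "epoch %2d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
          epoch, tr_loss, tr_acc, val$loss, val$accuracy
        ))
      }
      if (val$accuracy > best_acc) {
        best_acc <- val$accuracy
        best_params <- params
        best_epoch <- epoch
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= config$patience) break
      }
    }
  })
  model <- set_params(model, best_params)
  model$trained <- TRUE
  model$history <- bind_rows(history)
  model$best_epoch <- best_epoch
  model$config <- config
  model
}

evaluate_on <- function(model, codes, y, idx_list, batch = 512L) {
  N <- ncol(codes)
  loss <- 0
  correct <- 0
  for (start in seq(1L, N, by = batch)) {
    take <- start:min(start + batch - 1L, N)
    probs <- cnn_forward_batch(model, codes[, take, drop = FALSE], idx_list)$probs
    yi <- y[take]
    loss <- loss + sum(-log(pmax(probs[cbind(yi + 1L, seq_along(take))], 1e-12)))
    correct <- correct + sum((probs[2, ] > 0.5) == (yi == 1))
  }
  list(loss = loss / N, accuracy = correct / N)
}

#' Predict binding-site probabilities for records
#'
#' @param object A trained `rbp_cnn`.
#' @param records Records tibble (or character vector of sequences), all
#'   of the model's input length.
#' @param batch_size Prediction batch size (default 512).
#' @param ... Unused.
#' @return Tibble with `id` and `score` (probability of the positive,
#'   i.e. bound, class), one row per record in input order.
#' @export
predict.rbp_cnn <- function(object, records, batch_size = 512L, ...) {
  seqs <- if (is.character(records)) records else records$seq
  ids <- if (is.character(records)) {
    paste0("seq_", seq_along(records))
  } else if ("id" %in% names(records)) records$id else paste0("seq_", seq_len(nrow(records)))
  bad <- which(nchar(seqs) != object$L)
  if (length(bad) > 0) {
    abort(paste0(
      "sequence length must equal model input length ", object$L,
      "; offending record(s): ", paste(head(ids[bad], 3), collapse = ", ")
    ))
  }
  codes <- seqs_to_int(seqs)
  idx_list <- lapply(object$branches, function(br) window_flat_index(br$h, object$L))
  N <- ncol(codes)
  score <- numeric(N)
  for (start in seq(1L, N, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, N)
    score[take] <- cnn_forward_batch(object, codes[, take, drop = FALSE], idx_list)$probs[2, ]
  }
  tibble(id = ids, score = score)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the configuration and all
#' weight tensors; a load after save restores the config exactly and the
#' weights to full precision.
#'
#' @param model An `rbp_cnn`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `rbp_cnn` (load).
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "rbp_cnn")) abort("model must be an rbp_cnn")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rbp_cnn")) abort("checkpoint does not contain an rbp_cnn model")
  model
}

#' @export
print.rbp_cnn <- function(x, ...) {
  cfg <- x$config
  cat("<rbp_cnn> ", if (x$trained) "trained" else "untrained", "\n", sep = "")
  cat(
    "  input length:", x$L, "nt | branches:",
    paste(cfg$kernel_sizes, collapse = "/"),
    "x", cfg$kernels_per_size, "kernels\n"
  )
  if (x$trained) {
    best <- x$history[x$best_epoch, ]
    cat(sprintf(
      "  best epoch %d: val accuracy %.3f (of %d epochs run)\n",
      x$best_epoch, best$val_accuracy, nrow(x$history)
    ))
  }
  invisible(x)
}

#' @describeIn train_model broom-style per-epoch training history.
#' @param x A trained `rbp_cnn`.
#' @export
tidy.rbp_cnn <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(
      epoch = integer(), train_loss = numeric(), train_accuracy = numeric(),
      val_loss = numeric(), val_accuracy = numeric()
    ))
  }
  x$history
}

#' @describeIn train_model broom-style one-row model summary.
#' @export
glance.rbp_cnn <- function(x, ...) {
  n_par <- sum(vapply(collect_params(x), length, integer(1)))
  tibble(
    n_branches = length(x$branches),
    kernels_per_size = x$config$kernels_per_size,
    n_parameters = n_par,
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_accuracy = if (is.null(x$history)) NA_real_ else x$history$val_accuracy[x$best_epoch]
  )
}
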