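#' Rank-based ROC AUC
#'
#' The area under the ROC curve computed from the Mann-Whitney rank
#' statistic: the probability that a random positive outscores a random
#' negative, with ties counted one half.
#'
#' @param labels Binary vector (1/TRUE = positive, 0/FALSE = negative).
#' @param scores Numeric score vector of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 0), c(0.9, 0.1)) # 1
#' @export
roc_auc <- function(labels, scores) {
  y <- as.integer(as.logical(labels))
  if (length(y) != length(scores)) abort("labels and scores must have equal length")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One point per distinct score threshold (ties grouped), from (0, 0) to
#' (1, 1); the trapezoidal area under these points equals the rank-based
#' AUC.
#'
#' @inheritParams roc_auc
#' @return Tibble with `threshold`, `fpr`, `tpr`, monotone non-decreasing
#'   in both coordinates.
#' @export
roc_points <- function(labels, scores) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  grp_last <- c(ss[-length(ss)] != ss[-1], TRUE) # last index of each tie group
  tp <- cumsum(ys)[grp_last]
  fp <- cumsum(1 - ys)[grp_last]
  tibble(
    threshold = c(Inf, ss[grp_last]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Threshold classification metrics plus ROC/AUC
#'
#' @inheritParams roc_auc
#' @param threshold Score cut for calling a positive (default 0.5).
#' @return An `eval_report`: accuracy, precision (`NA` with a flag when
#'   no positives are called), rank-based `auc`, the ROC points, the
#'   threshold and class counts. Access tidily via [tidy()] (ROC points)
#'   and [glance()] (one-row summary).
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision_defined <- (tp + fp) > 0
  if (!precision_defined) {
    warn("no records called positive at this threshold; precision undefined")
  }
  structure(
    list(
      accuracy = (tp + tn) / length(y),
      precision = if (precision_defined) tp / (tp + fp) else NA_real_,
      precision_defined = precision_defined,
      auc = roc_auc(y, scores),
      roc_points = roc_points(y, scores),
      threshold = threshold,
      n_pos = sum(y == 1),
      n_neg = sum(y == 0)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf(
    "  accuracy %.4f | precision %s | AUC %.4f (threshold %.2f; %d pos / %d neg)\n",
    x$accuracy,
    if (x$precision_defined) sprintf("%.4f", x$precision) else "undefined",
    x$auc, x$threshold, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @describeIn classification_metrics ROC points as a tibble.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$roc_points

#' @describeIn classification_metrics one-row metric summary.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    accuracy = x$accuracy, precision = x$precision, auc = x$auc,
    threshold = x$threshold, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Fit a conventional baseline classifier on k-mer features
#'
#' Fits an off-the-shelf learner (multilayer perceptron, support vector
#' machine, random forest, or logistic regression) on normalised k-mer
#' composition features and returns positive-class scores for the test
#' features. Learner internals are delegated to the respective packages
#' with their seeded defaults.
#'
#' @param train_x Numeric feature matrix (rows = training records), e.g.
#'   from [kmer_feature_matrix()].
#' @param train_labels Binary labels for `train_x` (1/TRUE = positive).
#' @param test_x Feature matrix with the same number of columns.
#' @param learner One of `"mlp"`, `"svm"`, `"rf"`, `"logistic"`.
#' @param seed Integer seed for the learner's randomness.
#' @return Numeric vector of positive-class scores, one per test row.
#' @export
baseline_fit_predict <- function(train_x, train_labels, test_x,
                                 learner = c("mlp", "svm", "rf", "logistic"),
                                 seed = 1L) {
  learner <- match.arg(learner)
  if (ncol(train_x) != ncol(test_x)) abort("train and test feature dimensions differ")
  y <- as.integer(as.logical(train_labels))
  withr::with_seed(fork_seed(seed, "baseline"), {
    scores <- switch(learner,
      logistic = {
        df <- data.frame(y = y, train_x)
        fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
        as.vector(suppressWarnings(
          stats::predict(fit, newdata = data.frame(test_x), type = "response")
        ))
      },
      mlp = {
        fit <- nnet::nnet(train_x, y,
          size = 16, decay = 1e-3, maxit = 200,
          entropy = TRUE, trace = FALSE, MaxNWts = 10000
        )
        as.vector(stats::predict(fit, test_x))
      },
      svm = {
        fit <- e1071::svm(train_x, factor(y, levels = c(0, 1)), probability = TRUE)
        pr <- stats::predict(fit, test_x, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      },
      rf = {
        fit <- randomForest::randomForest(train_x, factor(y, levels = c(0, 1)))
        stats::predict(fit, test_x, type = "prob")[, "1"]
      }
    )
  })
  unname(scores)
}
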