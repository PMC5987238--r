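# 1-nearest-neighbour evaluation with stratified cross-validation and the
# pooled-confusion metrics ACC / SE / SP / ROCA.
#
# Positive means hypertension history. Features are min-max normalized to
# [0,1] using training ranges only (the feature bank mixes seconds, a.u. and
# entropies, so unnormalized Euclidean distance would be dominated by scale).

#' 1-NN prediction with nearest-per-class margin scores
#'
#' Euclidean distance on features min-max normalized with training ranges
#' (a zero-range feature contributes nothing); each query is assigned the
#' label of its nearest training row, distance ties broken by the smallest
#' training row index. Because a hard 1-NN emits no probability, the ROC
#' score is the signed margin \eqn{1/(1+d_+) - 1/(1+d_-)} between the
#' nearest positive and nearest negative neighbour distances.
#'
#' @param train data.frame/matrix of training features.
#' @param train_labels binary labels (0/1) for `train`.
#' @param query data.frame/matrix of query rows, same feature names.
#' @param k neighbourhood size (only `k = 1` is supported).
#' @param normalize min-max normalize with training ranges (default TRUE).
#' @return List: `labels` (integer 0/1), `scores` (numeric margins).
#' @export
knn_predict <- function(train, train_labels, query, k = 1L, normalize = TRUE) {
  if (k != 1L) stop_invalid("only k = 1 is supported")
  train <- as.matrix(train); query <- as.matrix(query)
  if (is.null(colnames(train)) != is.null(colnames(query)) ||
      !identical(colnames(train), colnames(query))) {
    stop_invalid("train and query feature names differ")
  }
  if (nrow(train) == 0L) stop_invalid("empty training set")
  train_labels <- as.integer(train_labels)
  if (anyNA(train)) {
    # missing values (shape-dependent TD columns) are median-imputed from
    # the training portion so distances stay defined
    for (j in seq_len(ncol(train))) {
      if (anyNA(train[, j]) || anyNA(query[, j])) {
        med <- median(train[, j], na.rm = TRUE)
        if (is.na(med)) med <- 0
        train[is.na(train[, j]), j] <- med
        query[is.na(query[, j]), j] <- med
      }
    }
  } else if (anyNA(query)) {
    for (j in seq_len(ncol(query))) {
      if (anyNA(query[, j])) {
        med <- median(train[, j])
        query[is.na(query[, j]), j] <- med
      }
    }
  }
  if (normalize) {
    lo <- apply(train, 2L, min)
    hi <- apply(train, 2L, max)
    rng <- hi - lo
    rng[rng == 0] <- Inf          # zero-range feature -> contributes 0
    train <- sweep(sweep(train, 2L, lo), 2L, rng, "/")
    query <- sweep(sweep(query, 2L, lo), 2L, rng, "/")
  }
  # squared distances: ||q||^2 + ||t||^2 - 2 q.t
  cross <- tcrossprod(query, train)
  d2 <- outer(rowSums(query^2), rowSums(train^2), "+") - 2 * cross
  d2[d2 < 0] <- 0
  pos <- train_labels == 1L
  if (!any(pos) || all(pos)) {
    nn <- apply(d2, 1L, which.min)     # which.min takes the first (lowest id)
    return(list(labels = train_labels[nn], scores = rep(0, nrow(query))))
  }
  nn <- apply(d2, 1L, which.min)
  dpos <- sqrt(apply(d2[, pos, drop = FALSE], 1L, min))
  dneg <- sqrt(apply(d2[, !pos, drop = FALSE], 1L, min))
  list(labels = train_labels[nn],
       scores = 1 / (1 + dpos) - 1 / (1 + dneg))
}

#' Confusion-matrix metrics
#'
#' Sensitivity `SE = TP/(TP+FN) x 100`, specificity `SP = TN/(TN+FP) x 100`,
#' accuracy `ACC = (TP+TN)/total x 100`, plus the ROC axes
#' `FPR = 100 - SP` and `TPR = SE`. Positive means hypertension history.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return Named numeric `c(ACC, SE, SP, FPR, TPR)` in percent.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || anyNA(counts)) stop_invalid("invalid confusion counts")
  if (tp + fn == 0) stop_invalid("no positive instances: SE undefined")
  if (tn + fp == 0) stop_invalid("no negative instances: SP undefined")
  se <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  c(ACC = 100 * (tp + tn) / sum(counts), SE = se, SP = sp,
    FPR = 100 - sp, TPR = se)
}

#' Area under the empirical ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random positive
#' scores above a random negative, ties counting one half. Identical to
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1).
#' @return Scalar in `[0, 1]`.
#' @export
roc_area <- function(scores, labels) {
  check_finite_numeric(scores, "scores")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_invalid("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated 1-NN evaluation of a feature subset
#'
#' Stratified folds (seeded), confusions pooled over folds, metrics from the
#' pooled confusion, ROC area from the pooled per-instance margin scores.
#'
#' @param data data.frame of numeric features.
#' @param labels binary labels (0/1); positive = 1.
#' @param subset feature names to use (default: all columns).
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param normalize passed to [knn_predict()].
#' @return List of class `evaluation_report`: `ACC`, `SE`, `SP`, `ROCA`,
#'   `confusion` (tp/tn/fp/fn), `subset`, `n_folds`, `seed`.
#' @export
cross_validate <- function(data, labels, subset = names(data),
                           n_folds = 10L, seed = 1, normalize = TRUE) {
  labels <- as.integer(labels)
  if (length(subset) == 0L) stop_invalid("empty feature subset")
  x <- data[, subset, drop = FALSE]
  fold <- stratified_folds(labels, n_folds, seed)
  tp <- tn <- fp <- fn <- 0L
  scores <- numeric(length(labels))
  for (f in seq_len(n_folds)) {
    te <- fold == f
    pred <- knn_predict(x[!te, , drop = FALSE], labels[!te],
                        x[te, , drop = FALSE], normalize = normalize)
    truth <- labels[te]
    tp <- tp + sum(pred$labels == 1L & truth == 1L)
    tn <- tn + sum(pred$labels == 0L & truth == 0L)
    fp <- fp + sum(pred$labels == 1L & truth == 0L)
    fn <- fn + sum(pred$labels == 0L & truth == 1L)
    scores[te] <- pred$scores
  }
  m <- classification_metrics(tp, tn, fp, fn)
  structure(list(ACC = m[["ACC"]], SE = m[["SE"]], SP = m[["SP"]],
                 ROCA = roc_area(scores, labels),
                 confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
                 subset = subset, n_folds = n_folds, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report: %d features, %d-fold 1-NN>\n  ACC %.2f%%  SE %.2f%%  SP %.2f%%  ROCA %.3f\n",
    length(x$subset), x$n_folds, x$ACC, x$SE, x$SP, x$ROCA))
  invisible(x)
}

#' Occurrence-frequency sweep evaluation
#'
#' Evaluates 1-NN performance for the feature-subset ladder built from a
#' selection result: the full feature bank, all ever-selected features, and
#' one subset per distinct OF level (features with OF at or above that
#' level), mirroring the subgroup structure of an OF-threshold experiment.
#'
#' @param data data.frame of numeric features.
#' @param labels binary labels.
#' @param selection a [fold_selection_of()] result.
#' @param n_folds,seed,normalize passed to [cross_validate()].
#' @return data.frame of class `of_sweep`: one row per subset
#'   (`group`, `threshold`, `n_features`, `ACC`, `SE`, `SP`, `ROCA`).
#' @export
of_sweep_report <- function(data, labels, selection, n_folds = 10L, seed = 1,
                            normalize = TRUE) {
  thresholds <- sort(unique(selection$of$OF))
  groups <- c(list(list(group = "all_features", threshold = NA_real_,
                        subset = names(data))),
              if (nrow(selection$of) > 0L)
                list(list(group = "all_selected", threshold = NA_real_,
                          subset = subset_by_of(selection, min(thresholds)))),
              lapply(thresholds, function(th) {
                list(group = sprintf("OF>=%g", th), threshold = th,
                     subset = subset_by_of(selection, th))
              }))
  rows <- lapply(groups, function(g) {
    if (length(g$subset) == 0L) return(NULL)
    rep <- cross_validate(data, labels, g$subset, n_folds, seed, normalize)
    data.frame(group = g$group, threshold = g$threshold,
               n_features = length(g$subset), ACC = rep$ACC, SE = rep$SE,
               SP = rep$SP, ROCA = rep$ROCA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("of_sweep", "data.frame")
  out
}

#' Plot an OF-sweep report
#'
#' Line chart of ACC / SE / SP across the subset ladder.
#'
#' @param x an `of_sweep` data.frame.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.of_sweep <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x)), x[, c("ACC", "SE", "SP")],
                    type = "b", pch = 1:3, lty = 1, xaxt = "n",
                    xlab = "feature group", ylab = "percent", ...)
  graphics::axis(1, at = seq_len(nrow(x)), labels = x$group, las = 2,
                 cex.axis = 0.7)
  graphics::legend("bottomleft", legend = c("ACC", "SE", "SP"),
                   pch = 1:3, lty = 1, col = 1:3, bty = "n")
  invisible(x)
}
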