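# Correlation-based feature subset selection (CFS) with best-first search,
# repeated over stratified folds to produce per-feature occurrence
# frequencies (OF).
#
# Feature-class and feature-feature "correlations" are symmetric
# uncertainties computed on supervised MDL-discretized copies of the numeric
# columns, so the evaluator behaves like the classical CFS subset evaluator.

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Supervised MDL discretization of a numeric column
#'
#' Recursive entropy-based binning with the minimum-description-length
#' stopping rule: a binary cut is accepted only when its information gain
#' exceeds the MDL coding cost \eqn{(\log_2(N-1) + \Delta)/N}. Columns with
#' no accepted cut collapse to a single bin. Missing values map to their own
#' bin.
#'
#' @param column numeric vector.
#' @param labels class labels (binary, any two values).
#' @return Integer vector of bin ids (1-based); cut points in attribute
#'   `"cuts"`.
#' @export
discretize_mdl <- function(column, labels) {
  if (length(column) != length(labels)) stop_invalid("length mismatch")
  labels <- as.integer(factor(labels))
  ok <- !is.na(column)
  cuts <- sort(mdl_cuts(column[ok], labels[ok]))
  out <- rep(NA_integer_, length(column))
  out[ok] <- findInterval(column[ok], cuts) + 1L
  out[!ok] <- max(out, 1L, na.rm = TRUE) + 1L
  attr(out, "cuts") <- cuts
  out
}

mdl_cuts <- function(x, y) {
  ord <- order(x)
  mdl_cuts_sorted(x[ord], y[ord])
}

# entropy (bits) per row of a count matrix
row_entropy <- function(m) {
  tot <- rowSums(m)
  p <- m / ifelse(tot > 0, tot, 1)
  -rowSums(ifelse(p > 0, p * log2(p), 0))
}

mdl_cuts_sorted <- function(xs, ys) {
  n <- length(xs)
  if (n < 2L) return(numeric())
  distinct <- which(diff(xs) > 0)
  if (!length(distinct)) return(numeric())
  classes <- sort(unique(ys))
  k <- length(classes)
  cum <- vapply(classes, function(cl) cumsum(ys == cl), numeric(n))
  totals <- cum[n, ]
  ent <- entropy_bits(totals)
  left <- cum[distinct, , drop = FALSE]
  right <- rep(totals, each = length(distinct)) - left
  dim(right) <- dim(left)
  e1 <- row_entropy(left)
  e2 <- row_entropy(right)
  gain <- ent - (distinct / n) * e1 - ((n - distinct) / n) * e2
  b <- which.max(gain)
  best_i <- distinct[b]
  k1 <- sum(left[b, ] > 0); k2 <- sum(right[b, ] > 0)
  delta <- log2(3^k - 2) - (k * ent - k1 * e1[b] - k2 * e2[b])
  threshold <- (log2(n - 1) + delta) / n
  if (gain[b] <= threshold) return(numeric())
  cut <- (xs[best_i] + xs[best_i + 1L]) / 2
  c(mdl_cuts_sorted(xs[1:best_i], ys[1:best_i]),
    cut,
    mdl_cuts_sorted(xs[(best_i + 1L):n], ys[(best_i + 1L):n]))
}

#' Symmetric uncertainty between two discrete variables
#'
#' \eqn{SU(X,Y) = 2 (H(X) + H(Y) - H(X,Y)) / (H(X) + H(Y))}, in `[0, 1]`;
#' defined as 0 when both variables are constant.
#'
#' @param x,y integer/factor vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
symmetric_uncertainty <- function(x, y) {
  x <- as.integer(factor(x)); y <- as.integer(factor(y))
  hx <- entropy_bits(tabulate(x))
  hy <- entropy_bits(tabulate(y))
  if (hx + hy == 0) return(0)
  hxy <- entropy_bits(as.vector(table(x, y)))
  max(0, 2 * (hx + hy - hxy) / (hx + hy))
}

# Correlation cache: discretizes once, computes feature-class SU eagerly and
# feature-feature SU lazily.
cfs_cache <- function(data, labels) {
  disc <- lapply(data, discretize_mdl, labels = labels)
  p <- length(disc)
  rcf <- vapply(disc, symmetric_uncertainty, 0, y = labels)
  env <- new.env(parent = emptyenv())
  env$disc <- disc
  env$rcf <- rcf
  env$rff <- matrix(NA_real_, p, p, dimnames = list(names(data), names(data)))
  diag(env$rff) <- 1
  env$names <- names(data)
  env
}

cache_rff <- function(cache, i, j) {
  v <- cache$rff[i, j]
  if (is.na(v)) {
    v <- symmetric_uncertainty(cache$disc[[i]], cache$disc[[j]])
    cache$rff[i, j] <- v
    cache$rff[j, i] <- v
  }
  v
}

merit_from_sums <- function(k, sum_rcf, sum_rff_pairs) {
  if (k == 0L) return(0)
  rbar_cf <- sum_rcf / k
  denom <- k + 2 * sum_rff_pairs   # k + k(k-1) * mean over ordered pairs
  if (denom <= 0) return(0)
  k * rbar_cf / sqrt(denom)
}

#' CFS merit of a feature subset
#'
#' \deqn{Merit = k \bar r_{cf} / \sqrt{k + k(k-1) \bar r_{ff}}}
#' where `k` is the subset size, \eqn{\bar r_{cf}} the mean feature-class
#' correlation and \eqn{\bar r_{ff}} the mean feature-feature
#' inter-correlation (both symmetric uncertainties on discretized data).
#' Subsets highly correlated with the class but mutually uncorrelated score
#' highest; the empty subset has merit 0.
#'
#' @param subset character vector of feature names (may be empty).
#' @param data data.frame of numeric features.
#' @param labels class labels.
#' @param cache internal correlation cache (optional).
#' @return Scalar merit.
#' @export
cfs_merit <- function(subset, data, labels, cache = NULL) {
  if (length(subset) == 0L) return(0)
  if (is.null(cache)) cache <- cfs_cache(data, labels)
  idx <- match(subset, cache$names)
  if (anyNA(idx)) stop_invalid("unknown feature in subset")
  sum_rcf <- sum(cache$rcf[idx])
  sum_ff <- 0
  if (length(idx) > 1L) {
    pr <- utils::combn(idx, 2L)
    sum_ff <- sum(vapply(seq_len(ncol(pr)),
                         function(q) cache_rff(cache, pr[1L, q], pr[2L, q]),
                         0))
  }
  merit_from_sums(length(idx), sum_rcf, sum_ff)
}

#' Best-first search over feature subsets
#'
#' Forward search from the empty set: an open list ordered by CFS merit is
#' maintained; at each step the best unexpanded subset is expanded by every
#' single-feature addition. The search stops after `stale_limit` consecutive
#' expansions that fail to improve on the best merit seen (backtracking is
#' implicit in the open list). Deterministic, with lexicographic
#' tie-breaking on feature names.
#'
#' @param data data.frame of numeric features.
#' @param labels class labels.
#' @param stale_limit consecutive non-improving expansions allowed
#'   (default 5).
#' @param cache internal correlation cache (optional).
#' @return List: `subset` (character, canonical column order), `merit`.
#' @export
best_first_search <- function(data, labels, stale_limit = 5L, cache = NULL) {
  if (ncol(data) < 1L) stop_invalid("need at least one feature")
  if (is.null(cache)) cache <- cfs_cache(data, labels)
  p <- length(cache$names)
  ord <- order(cache$names)           # lexicographic candidate order
  key <- function(members) paste0("s", paste(which(members), collapse = ","))
  # node: logical membership vector + cached sums
  start <- list(members = rep(FALSE, p), sum_rcf = 0, sum_ff = 0, merit = 0)
  open <- list(start)
  visited <- new.env(parent = emptyenv())
  assign(key(start$members), TRUE, envir = visited)
  best <- start
  stale <- 0L
  while (length(open) > 0L && stale < stale_limit) {
    merits <- vapply(open, `[[`, 0, "merit")
    bi <- which.max(merits)
    node <- open[[bi]]
    open[[bi]] <- NULL
    improved <- FALSE
    for (j in ord) {
      if (node$members[j]) next
      members <- node$members
      members[j] <- TRUE
      kk <- key(members)
      if (exists(kk, envir = visited, inherits = FALSE)) next
      assign(kk, TRUE, envir = visited)
      add_ff <- 0
      for (i in which(node$members)) add_ff <- add_ff + cache_rff(cache, i, j)
      child <- list(members = members,
                    sum_rcf = node$sum_rcf + cache$rcf[j],
                    sum_ff = node$sum_ff + add_ff)
      child$merit <- merit_from_sums(sum(members), child$sum_rcf, child$sum_ff)
      open[[length(open) + 1L]] <- child
      if (child$merit > best$merit + 1e-10) {
        best <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  list(subset = cache$names[best$members], merit = best$merit)
}

#' Occurrence frequency of a selected feature
#'
#' \eqn{OF = (\mathrm{folds\ chosen} / n_{folds}) \times 100}: a feature
#' chosen in 5 of 10 selection folds has OF = 50%.
#'
#' @param folds_chosen number of folds in which the feature was selected.
#' @param n_folds total number of folds.
#' @return OF in percent.
#' @export
occurrence_frequency <- function(folds_chosen, n_folds) {
  if (any(folds_chosen < 0) || any(folds_chosen > n_folds)) {
    stop_invalid("folds_chosen must lie in [0, n_folds]")
  }
  100 * folds_chosen / n_folds
}

#' Fold-wise CFS selection with occurrence frequencies
#'
#' Runs CFS + best-first search on the training portion of each of
#' `n_folds` stratified folds and reports, per feature, the occurrence
#' frequency \eqn{OF = (\mathrm{folds\ chosen} / n_{folds}) \times 100} —
#' e.g. a feature chosen in 5 of 10 folds has OF = 50%.
#'
#' @param data data.frame of numeric features.
#' @param labels binary class labels.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the stratified fold assignment.
#' @param stale_limit passed to [best_first_search()].
#' @return List of class `selection_result`: `of` (data.frame feature /
#'   folds_chosen / OF, features with OF = 0 omitted, canonical column
#'   order), `fold_subsets`, `fold_merits`, `n_folds`, `seed`.
#' @export
fold_selection_of <- function(data, labels, n_folds = 10L, seed = 1,
                              stale_limit = 5L) {
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, n_folds, seed)
  subsets <- vector("list", n_folds)
  merits <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    res <- best_first_search(data[tr, , drop = FALSE], labels[tr],
                             stale_limit = stale_limit)
    subsets[[f]] <- res$subset
    merits[f] <- res$merit
  }
  chosen <- table(factor(unlist(subsets), levels = names(data)))
  keep <- chosen > 0
  of <- data.frame(feature = names(chosen)[keep],
                   folds_chosen = as.integer(chosen[keep]),
                   OF = occurrence_frequency(as.integer(chosen[keep]), n_folds),
                   stringsAsFactors = FALSE)
  structure(list(of = of, fold_subsets = subsets, fold_merits = merits,
                 n_folds = n_folds, seed = seed,
                 feature_order = names(data)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d folds, %d features ever chosen>\n",
              x$n_folds, nrow(x$of)))
  print(x$of[order(-x$of$OF), ], row.names = FALSE)
  invisible(x)
}

#' Features at or above an occurrence-frequency threshold
#'
#' @param result a [fold_selection_of()] result.
#' @param threshold OF threshold in percent, in `(0, 100]`.
#' @return Character vector of feature names (canonical column order).
#' @export
subset_by_of <- function(result, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 100) {
    stop_invalid("threshold must lie in (0, 100]")
  }
  feats <- result$of$feature[result$of$OF >= threshold]
  feats[order(match(feats, result$feature_order))]
}
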