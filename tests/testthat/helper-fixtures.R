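# Shared fixture builders. Everything is generated in code; no stored data.

# noise-free, jitter-free configuration: annotated onsets at exact multiples
# of the period
clean_config <- function(duration_s = 10, rate = 500) {
  cohort_config(duration_s = duration_s, rate = rate,
                wander_amp = 0, white_sd = 0, period_jitter_sd = 0)
}

# independent trapezoidal ROC oracle (threshold sweep), used to cross-check
# the rank-statistic implementation
roc_trapezoid <- function(scores, labels) {
  th <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# brute-force nearest-neighbour scan on a pre-normalized matrix
knn_brute <- function(train, labels, query) {
  vapply(seq_len(nrow(query)), function(i) {
    d <- sqrt(colSums((t(train) - query[i, ])^2))
    labels[which.min(d)]
  }, integer(1L))
}

# feature matrix with `n_eff` designated columns shifted by `effect` SDs in
# class 1; remaining columns pure noise. Column names follow the pulse
# feature bank (age, bmi, TD, HOS, E).
effect_matrix <- function(n_per_class, effect, designated, seed) {
  set.seed(seed)
  nms <- c("age", "bmi", paste0("td", 1:20), paste0("HOS", 1:90),
           paste0("E", 1:30))
  n <- 2L * n_per_class
  m <- as.data.frame(matrix(rnorm(n * length(nms)), n, length(nms)))
  names(m) <- nms
  labels <- rep(0:1, each = n_per_class)
  for (f in designated) m[[f]] <- m[[f]] + effect * labels
  list(data = m, labels = labels)
}
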