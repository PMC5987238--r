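# End-to-end experiment runner: generate -> preprocess -> segment -> extract
# -> select -> evaluate, once per blood-pressure grade, with hypertension
# history as the binary label. Everything is seeded and reproducible.

#' Build the per-cycle feature matrix of a cohort
#'
#' Preprocesses and segments every recording, drops rejected cycles, and
#' extracts per cycle the subject covariates (age, BMI), the 20 time-domain
#' features and the 120 wavelet-packet features — 142 columns plus
#' bookkeeping (subject, group, label).
#'
#' @param cohort a [generate_cohort()] result (or a list shaped like one).
#' @param min_cycle_samples cycles shorter than this are skipped for the
#'   wavelet stage (default `2^4`).
#' @return data.frame: `subject_id`, `bp_group`, `history`, `cycle_index`,
#'   then `age`, `bmi` and the 140 signal features.
#' @export
extract_features <- function(cohort, min_cycle_samples = 16L) {
  rows <- list()
  for (s in cohort$subjects) {
    cyc <- segment_recording(s$recording)
    cyc <- cyc[cyc$quality == "ok", ]
    if (nrow(cyc) == 0L) next
    rate <- attr(cyc, "rate")
    for (i in seq_len(nrow(cyc))) {
      samples <- cycle_samples(cyc, i)
      if (length(samples) < min_cycle_samples) next
      td <- tryCatch(extract_td(samples, rate), error = function(e) NULL)
      if (is.null(td)) next
      wpd <- extract_wpd_features(samples)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$profile$subject_id,
        bp_group = s$profile$bp_group,
        history = s$profile$hypertension_history,
        cycle_index = cyc$cycle_index[i],
        age = s$profile$age, bmi = s$profile$bmi,
        t(td), t(wpd),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop_invalid("no usable cycles in cohort")
  do.call(rbind, rows)
}

feature_columns <- function(fm) {
  setdiff(names(fm), c("subject_id", "bp_group", "history", "cycle_index"))
}

# Columns that are NA everywhere (landmark never detectable in a group)
# cannot be discretized or normalized; they are dropped with a note.
drop_empty_columns <- function(x) {
  keep <- vapply(x, function(col) !all(is.na(col)), logical(1L))
  x[, keep, drop = FALSE]
}

#' Run the full pulse-wave experiment on a synthetic cohort
#'
#' For each requested blood-pressure grade: build the per-cycle feature
#' matrix, run fold-wise CFS selection with occurrence-frequency voting,
#' and evaluate 1-NN accuracy over the OF-threshold subset ladder.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; cohort generation, fold selection and
#'   evaluation folds all derive from it.
#' @param groups grades to analyse (default all three).
#' @param n_folds folds for both selection and evaluation (default 10).
#' @return List of class `pulse_experiment`: per-group `bundles` (each with
#'   `features`, `selection`, `report`), plus `config` and `seed`.
#' @export
run_pulse_experiment <- function(config = cohort_config(), seed = 1,
                                 groups = c("NG", "HerG", "HestG"),
                                 n_folds = 10L) {
  cohort <- generate_cohort(config, seed = seed)
  fm <- extract_features(cohort)
  bundles <- list()
  for (g in groups) {
    sub <- fm[fm$bp_group == g, , drop = FALSE]
    if (nrow(sub) == 0L) next
    labels <- sub$history
    feats <- drop_empty_columns(sub[, feature_columns(sub), drop = FALSE])
    sel_seed <- derive_seed(seed, match(g, groups))
    selection <- fold_selection_of(feats, labels, n_folds = n_folds,
                                   seed = sel_seed)
    report <- of_sweep_report(feats, labels, selection, n_folds = n_folds,
                              seed = derive_seed(seed, 10 + match(g, groups)))
    bundles[[g]] <- list(group = g, features = sub, selection = selection,
                        report = report)
  }
  structure(list(bundles = bundles, config = config, seed = seed),
            class = "pulse_experiment")
}

#' @export
print.pulse_experiment <- function(x, ...) {
  cat(sprintf("<pulse_experiment: %d group(s), seed %s>\n",
              length(x$bundles), format(x$seed)))
  for (b in x$bundles) {
    best <- b$report[which.max(b$report$ACC), ]
    cat(sprintf("  %-5s %4d cycles | %2d features ever selected | best ACC %.2f%% (%s)\n",
                b$group, nrow(b$features), nrow(b$selection$of),
                best$ACC, best$group))
  }
  invisible(x)
}

#' @export
summary.pulse_experiment <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$bundles, function(b) {
    cbind(experiment = b$group, b$report)
  }))
  rownames(tab) <- NULL
  tab
}

#' Cross-experiment selection summary
#'
#' Merges per-group selection results into one table keyed by
#' (experiment, feature, OF); features never selected in any fold are
#' absent.
#'
#' @param experiment a [run_pulse_experiment()] result.
#' @return data.frame: `experiment`, `feature`, `folds_chosen`, `OF`.
#' @export
summarize_selection <- function(experiment) {
  out <- do.call(rbind, lapply(experiment$bundles, function(b) {
    if (nrow(b$selection$of) == 0L) return(NULL)
    cbind(experiment = b$group, b$selection$of)
  }))
  rownames(out) <- NULL
  out
}

#' Plot per-experiment OF histograms
#'
#' Bar chart of occurrence frequencies of the ever-selected features, one
#' panel per experiment group.
#'
#' @param x a `pulse_experiment`.
#' @param ... unused.
#' @return Invisibly, `x`.
#' @export
plot.pulse_experiment <- function(x, ...) {
  ng <- length(x$bundles)
  if (ng == 0L) return(invisible(x))
  op <- graphics::par(mfrow = c(ng, 1L), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(op))
  for (b in x$bundles) {
    of <- b$selection$of
    if (nrow(of) == 0L) next
    graphics::barplot(of$OF, names.arg = of$feature, las = 2,
                      cex.names = 0.6, ylab = "OF (%)", main = b$group,
                      ylim = c(0, 100))
  }
  invisible(x)
}

#' Write experiment artifacts to disk
#'
#' Feature matrices, selection tables and evaluation reports as CSV; the
#' configuration echo and seed as JSON. Re-running with the same config and
#' seed reproduces identical files.
#'
#' @param experiment a [run_pulse_experiment()] result.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in experiment$bundles) {
    write.csv(b$features,
              file.path(dir, sprintf("features_%s.csv", b$group)),
              row.names = FALSE)
    write.csv(b$selection$of,
              file.path(dir, sprintf("selection_%s.csv", b$group)),
              row.names = FALSE)
    write.csv(b$report, file.path(dir, sprintf("report_%s.csv", b$group)),
              row.names = FALSE)
  }
  cfg <- unclass(experiment$config)
  cfg$cells <- as.list(cfg$cells)
  jsonlite::write_json(list(seed = experiment$seed, config = cfg),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
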