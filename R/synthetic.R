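# Seeded synthetic pulse-cohort generator with analytic ground truth.
#
# Each beat is a sum of three positive Gaussian bumps — percussion, tidal and
# dicrotic components — which keeps the fiducial ground truth analytic: the
# realized landmark times/amplitudes are read off the noise-free waveform, so
# segmentation and fiducial detectors can be scored against a known answer.

#' Assign a blood-pressure grade
#'
#' Classifies a (systolic, diastolic) reading into the three blood-pressure
#' grades used to stratify an elderly cohort: normal grade (`NG`, systolic
#' below 120 mmHg or diastolic below 80 mmHg), higher grade (`HerG`, systolic
#' 130-139 mmHg or diastolic 80-89 mmHg) and highest grade (`HestG`, systolic
#' above 140 mmHg or diastolic above 90 mmHg). Because the three "or" rules
#' overlap, they are evaluated in precedence order HestG, then HerG, then NG;
#' readings matching none (systolic 120-129 mmHg or exactly 140 mmHg,
#' combined with a diastolic of exactly 90 mmHg) return `"unclassified"`
#' and are excluded from cohort analyses.
#'
#' @param sbp systolic blood pressure, mmHg (vectorised).
#' @param dbp diastolic blood pressure, mmHg.
#' @return Character vector over `{"NG","HerG","HestG","unclassified"}`.
#' @examples
#' assign_bp_group(150, 95)  # "HestG"
#' assign_bp_group(135, 85)  # "HerG"
#' assign_bp_group(110, 70)  # "NG"
#' @export
assign_bp_group <- function(sbp, dbp) {
  if (!is.numeric(sbp) || !is.numeric(dbp) || anyNA(sbp) || anyNA(dbp) ||
      any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    stop_invalid("blood pressures must be finite numeric")
  }
  if (any(sbp <= 0) || any(dbp <= 0) || any(sbp <= dbp)) {
    stop_invalid("require sbp > dbp > 0")
  }
  out <- rep("unclassified", length(sbp))
  out[sbp > 140 | dbp > 90] <- "HestG"
  idx <- out == "unclassified" &
    ((sbp >= 130 & sbp <= 139) | (dbp >= 80 & dbp <= 89))
  out[idx] <- "HerG"
  idx <- out == "unclassified" & (sbp < 120 | dbp < 80)
  out[idx] <- "NG"
  out
}

#' Beat template parameters
#'
#' Nominal landmark placement for one synthetic pulse cycle. The waveform is
#' the sum of three Gaussian bumps centred at the percussion peak (`t1`,
#' `h1`), tidal crest (`t3`, `h3`) and dicrotic crest (`t5`, `h5`); the tidal
#' onset (`t2`) and dicrotic onset (`t4`) then arise as the inter-bump local
#' minima of the summed waveform. Defaults portray a healthy elderly radial
#' pulse: a dominant systolic percussion wave, a late-systolic tidal
#' (reflection) wave, and a diastolic dicrotic wave after the notch.
#'
#' @param period cycle duration `t`, seconds.
#' @param t1,h1 percussion-peak time (s from onset) and amplitude (a.u.).
#' @param t3,h3 tidal-crest time and amplitude.
#' @param t5,h5 dicrotic-crest time and amplitude.
#' @param sigma_p,sigma_t,sigma_d Gaussian widths (s) of the three bumps.
#' @return Named numeric vector of class `beat_template`.
#' @export
beat_template <- function(period = 1.0,
                          t1 = 0.13, h1 = 1.0,
                          t3 = 0.32, h3 = 0.62,
                          t5 = 0.52, h5 = 0.45,
                          sigma_p = 0.04, sigma_t = 0.07, sigma_d = 0.08) {
  p <- c(period = period, t1 = t1, h1 = h1, t3 = t3, h3 = h3,
         t5 = t5, h5 = h5, sigma_p = sigma_p, sigma_t = sigma_t,
         sigma_d = sigma_d)
  validate_template(p)
  structure(p, class = "beat_template")
}

validate_template <- function(p) {
  if (anyNA(p) || any(!is.finite(p))) stop_invalid("template params must be finite")
  if (p[["period"]] <= 0) stop_invalid("period must be positive")
  if (!(0 < p[["t1"]] && p[["t1"]] < p[["t3"]] && p[["t3"]] < p[["t5"]] &&
        p[["t5"]] < p[["period"]])) {
    stop_invalid("require 0 < t1 < t3 < t5 < period")
  }
  if (any(p[c("h1", "h3", "h5")] < 0)) stop_invalid("amplitudes must be >= 0")
  if (p[["h1"]] < p[["h3"]]) stop_invalid("require h1 >= h3 (percussion dominant)")
  if (any(p[c("sigma_p", "sigma_t", "sigma_d")] <= 0)) {
    stop_invalid("bump widths must be positive")
  }
  invisible(p)
}

# Local maxima / minima (strict sign changes of the first difference).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  d <- diff(y)
  which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
}
local_minima <- function(y) local_maxima(-y)

# Read realized fiducials off a noise-free beat: global max is the percussion
# peak; the alternating min/max sequence after it gives tidal onset/crest and
# dicrotic onset/crest. Undetectable landmarks come back NA.
realized_fiducials <- function(y, rate) {
  pk <- which.max(y)
  tt <- function(i) (i - 1L) / rate
  out <- c(t1 = tt(pk), h1 = y[pk], t2 = NA_real_, h2 = NA_real_,
           t3 = NA_real_, h3 = NA_real_, t4 = NA_real_, h4 = NA_real_,
           t5 = NA_real_, h5 = NA_real_)
  mins <- local_minima(y); mins <- mins[mins > pk]
  maxs <- local_maxima(y); maxs <- maxs[maxs > pk]
  if (length(mins) >= 1L) {
    t2i <- mins[1L]
    mx <- maxs[maxs > t2i]
    if (length(mx) >= 1L) {
      t3i <- mx[1L]
      out[c("t2", "h2", "t3", "h3")] <- c(tt(t2i), y[t2i], tt(t3i), y[t3i])
      mn <- mins[mins > t3i]
      if (length(mn) >= 1L) {
        t4i <- mn[1L]
        mx2 <- maxs[maxs > t4i]
        if (length(mx2) >= 1L) {
          t5i <- mx2[1L]
          out[c("t4", "h4", "t5", "h5")] <- c(tt(t4i), y[t4i], tt(t5i), y[t5i])
        }
      }
    }
  }
  out
}

#' Generate one synthetic pulse cycle
#'
#' Evaluates the three-bump beat model on a uniform sample grid and returns
#' the waveform together with the realized fiducial ground truth (landmarks
#' of the actual summed curve, which differ slightly from the nominal bump
#' centres where bumps overlap).
#'
#' @param params a [beat_template()].
#' @param rate sampling rate, Hz.
#' @return List with `samples` (length `round(period * rate)`), `rate`,
#'   `params`, and `fiducials` (named vector t1..t5, h1..h5, realized).
#' @export
generate_beat <- function(params, rate = 500) {
  validate_template(params)
  check_scalar_pos(rate, "rate")
  n <- round(params[["period"]] * rate)
  if (n < 4L) stop_invalid("period too short for sampling rate")
  tt <- (seq_len(n) - 1L) / rate
  bump <- function(tc, h, s) h * exp(-(tt - tc)^2 / (2 * s^2))
  y <- bump(params[["t1"]], params[["h1"]], params[["sigma_p"]]) +
    bump(params[["t3"]], params[["h3"]], params[["sigma_t"]]) +
    bump(params[["t5"]], params[["h5"]], params[["sigma_d"]])
  fid <- if (all(params[c("h1", "h3", "h5")] == 0)) {
    c(t1 = NA_real_, h1 = 0, t2 = NA_real_, h2 = NA_real_, t3 = NA_real_,
      h3 = NA_real_, t4 = NA_real_, h4 = NA_real_, t5 = NA_real_,
      h5 = NA_real_)
  } else {
    realized_fiducials(y, rate)
  }
  list(samples = y, rate = rate, params = params, fiducials = fid)
}

#' Cohort configuration
#'
#' Bundles every tunable of the synthetic cohort: per-cell subject counts,
#' recording geometry, noise levels, covariate distributions and the additive
#' between-class shifts ("effect sizes") applied to beat-template parameters
#' for the hypertension-history class. Defaults emulate a community cohort of
#' elderly subjects (age about 72 +/- 6 years) split across three
#' blood-pressure grades, with cell proportions matching a 770-subject study
#' population.
#'
#' @param cells data.frame with columns `bp_group`, `history` (0/1), `n`.
#' @param duration_s recording length, seconds (default 10).
#' @param rate sampling rate, Hz (default 500; must be >= 100).
#' @param wander_amp,wander_freq baseline-wander sinusoid amplitude (a.u.)
#'   and frequency (Hz, below 0.5).
#' @param white_sd additive white-noise standard deviation (a.u.).
#' @param period_jitter_sd per-beat period jitter SD, seconds.
#' @param param_sds named numeric: between-subject SDs of beat-template
#'   parameters.
#' @param effect named numeric: additive shifts applied to template
#'   parameters for subjects with hypertension history.
#' @param age_mean,age_sd,age_effect age distribution (years) and additive
#'   shift for the history class.
#' @param bmi_mean,bmi_sd,bmi_effect BMI distribution (kg/m^2) and shift.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(cells = default_cells(),
                          duration_s = 10, rate = 500,
                          wander_amp = 0.10, wander_freq = 0.25,
                          white_sd = 0.02,
                          period_jitter_sd = 0.03,
                          param_sds = c(period = 0.08, t1 = 0.008, h1 = 0.07,
                                        t3 = 0.015, h3 = 0.05, t5 = 0.02,
                                        h5 = 0.04),
                          effect = c(h3 = 0.08, h5 = 0.04, period = -0.05),
                          age_mean = 72, age_sd = 6, age_effect = 1,
                          bmi_mean = 24.5, bmi_sd = 3.2, bmi_effect = 0.8) {
  stopifnot(is.data.frame(cells),
            all(c("bp_group", "history", "n") %in% names(cells)))
  if (any(cells$n < 0)) stop_invalid("cell counts must be >= 0")
  check_scalar_pos(duration_s, "duration_s")
  if (rate < 100) stop_invalid("sampling rate must be >= 100 Hz")
  if (wander_freq >= 0.5) stop_invalid("wander frequency must be below 0.5 Hz")
  cfg <- list(cells = cells, duration_s = duration_s, rate = rate,
              wander_amp = wander_amp, wander_freq = wander_freq,
              white_sd = white_sd, period_jitter_sd = period_jitter_sd,
              param_sds = param_sds, effect = effect,
              age_mean = age_mean, age_sd = age_sd, age_effect = age_effect,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_effect = bmi_effect)
  class(cfg) <- "cohort_config"
  cfg
}

# Default per-cell subject counts: a 770-subject cohort with cell proportions
# following the study population (groups NG / HerG / HestG, history no / yes).
default_cells <- function() {
  data.frame(
    bp_group = rep(c("NG", "HerG", "HestG"), each = 2L),
    history = rep(c(0L, 1L), 3L),
    n = c(78L, 25L, 68L, 65L, 225L, 309L)
  )
}

# Draw a blood-pressure reading consistent with a target grade (rejection
# sampling from grade-specific normals; deterministic under the caller's RNG).
draw_bp <- function(group) {
  mu <- switch(group,
               NG = c(110, 70), HerG = c(134.5, 84.5), HestG = c(152, 95))
  sdv <- switch(group, NG = c(5, 5), HerG = c(2.5, 2.5), HestG = c(8, 5))
  for (i in seq_len(1000L)) {
    sbp <- rnorm(1L, mu[1L], sdv[1L])
    dbp <- rnorm(1L, mu[2L], sdv[2L])
    if (sbp > dbp && dbp > 0 && assign_bp_group(sbp, dbp) == group) {
      return(c(sbp = sbp, dbp = dbp))
    }
  }
  stop_invalid("failed to draw a %s blood pressure", group)
}

# Subject-level beat template: population template perturbed by
# between-subject SDs, plus the class effect for history == 1.
draw_subject_template <- function(config, history) {
  base <- beat_template()
  p <- unclass(base)
  for (nm in names(config$param_sds)) {
    p[[nm]] <- p[[nm]] + rnorm(1L, 0, config$param_sds[[nm]])
  }
  if (history == 1L) {
    for (nm in names(config$effect)) p[[nm]] <- p[[nm]] + config$effect[[nm]]
  }
  # keep the template physiologic: clamp into the validity region
  p[["t1"]] <- max(p[["t1"]], 0.06)
  p[["h1"]] <- max(p[["h1"]], 0.4)
  p[["h3"]] <- min(max(p[["h3"]], 0), p[["h1"]])
  p[["h5"]] <- max(p[["h5"]], 0)
  p[["t3"]] <- max(p[["t3"]], p[["t1"]] + 0.08)
  p[["t5"]] <- max(p[["t5"]], p[["t3"]] + 0.10)
  p[["period"]] <- max(p[["period"]], p[["t5"]] + 0.25)
  do.call(beat_template, as.list(p))
}

#' Generate a synthetic subject profile
#'
#' @param subject_id identifier string.
#' @param bp_group target grade (`"NG"`, `"HerG"`, `"HestG"`).
#' @param history hypertension history, 0 or 1.
#' @param config a [cohort_config()].
#' @param seed integer seed (optional; draws under current RNG if `NULL`).
#' @return List of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, bp_group, history, config = cohort_config(),
                            seed = NULL) {
  with_seed(seed, {
    bp <- draw_bp(bp_group)
    age <- max(60, rnorm(1L, config$age_mean +
                           if (history == 1L) config$age_effect else 0,
                         config$age_sd))
    bmi <- max(15, rnorm(1L, config$bmi_mean +
                           if (history == 1L) config$bmi_effect else 0,
                         config$bmi_sd))
    structure(list(subject_id = subject_id, age = age, bmi = bmi,
                   sbp = bp[["sbp"]], dbp = bp[["dbp"]],
                   hypertension_history = as.integer(history),
                   bp_group = bp_group),
              class = "subject_profile")
  })
}

#' Generate a synthetic 10-s pulse recording with ground truth
#'
#' Concatenates beats drawn from a subject-level template (per-beat period
#' jitter and a small amplitude jitter), then adds a sub-0.5 Hz baseline-
#' wander sinusoid and white noise. The returned annotation carries the true
#' beat onsets, the percussion-peak index of each noise-free beat, and the
#' realized per-beat fiducials, so detector output can be scored exactly.
#'
#' @param template a [beat_template()] (subject-level template).
#' @param config a [cohort_config()] (noise and geometry settings).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param id recording identifier.
#' @return List with `recording` (a [pulse_recording()], stage `"raw"`),
#'   `clean` (noise-free samples) and `annotation` (list: `onset_idx`,
#'   `peak_idx`, `beats` data.frame of realized fiducials + period). The
#'   recording closes at the final complete beat boundary, so it can be up
#'   to one period shorter than `duration_s`.
#' @export
generate_recording <- function(template = beat_template(),
                               config = cohort_config(),
                               seed = NULL, id = NULL) {
  validate_template(template)
  n_total <- round(config$duration_s * config$rate)
  if (config$duration_s < template[["period"]]) {
    stop_invalid("duration (%g s) shorter than one period (%g s)",
                 config$duration_s, template[["period"]])
  }
  with_seed(seed, {
    clean <- numeric(0L)
    onset_idx <- integer(0L)
    peak_idx <- integer(0L)
    beats <- list()
    while (length(clean) < n_total) {
      p <- unclass(template)
      if (config$period_jitter_sd > 0) {
        p[["period"]] <- max(p[["t5"]] + 0.2,
                             p[["period"]] + rnorm(1L, 0, config$period_jitter_sd))
      }
      amp <- if (config$period_jitter_sd > 0) exp(rnorm(1L, 0, 0.02)) else 1
      for (nm in c("h1", "h3", "h5")) p[[nm]] <- p[[nm]] * amp
      bt <- generate_beat(do.call(beat_template, as.list(p)), config$rate)
      onset_idx <- c(onset_idx, length(clean) + 1L)
      peak_idx <- c(peak_idx, length(clean) + which.max(bt$samples))
      beats[[length(beats) + 1L]] <- c(bt$fiducials, period = p[["period"]])
      clean <- c(clean, bt$samples)
    }
    # drop the beat that would run past the nominal end, and close the
    # recording at the final complete beat boundary: a truncated partial
    # beat at the edge is not annotatable and only distorts the envelope
    ends <- onset_idx +
      round(vapply(beats, function(b) b[["period"]], 0) * config$rate) - 1L
    keep <- ends <= n_total
    onset_idx <- onset_idx[keep]
    peak_idx <- peak_idx[keep]
    beats <- beats[keep]
    n_used <- min(n_total, max(ends[keep]))
    clean <- clean[seq_len(n_used)]
    n_total <- n_used
    tt <- (seq_len(n_total) - 1L) / config$rate
    noisy <- clean +
      config$wander_amp * sin(2 * pi * config$wander_freq * tt +
                                if (config$wander_amp > 0) runif(1L, 0, 2 * pi) else 0) +
      if (config$white_sd > 0) rnorm(n_total, 0, config$white_sd) else 0
    list(
      recording = pulse_recording(noisy, config$rate, stage = "raw", id = id),
      clean = clean,
      annotation = list(
        onset_idx = onset_idx,
        peak_idx = peak_idx,
        beats = as.data.frame(do.call(rbind, beats))
      )
    )
  })
}

#' Generate a labelled synthetic cohort
#'
#' Draws subject covariates and beat templates from class-conditional
#' distributions for every (blood-pressure grade x hypertension history)
#' cell of the configuration, then synthesises one annotated recording per
#' subject. The injected between-class parameter shifts are echoed in the
#' result so downstream recovery is checkable.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; the whole cohort is deterministic given
#'   (config, seed).
#' @return List of class `pulse_cohort`: `subjects` (list of per-subject
#'   records with `profile`, `recording`, `clean`, `annotation`),
#'   `manifest` (data.frame), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  if (sum(config$cells$n) == 0L) stop_invalid("all cohort cells are empty")
  subjects <- list()
  manifest <- list()
  k <- 0L
  for (ci in seq_len(nrow(config$cells))) {
    cell <- config$cells[ci, ]
    for (j in seq_len(cell$n)) {
      k <- k + 1L
      sid <- sprintf("S%04d", k)
      s_seed <- derive_seed(seed, k)
      prof <- subject_profile(sid, cell$bp_group, cell$history, config,
                              seed = s_seed)
      tpl <- with_seed(s_seed + 1, draw_subject_template(config, cell$history))
      rec <- generate_recording(tpl, config, seed = s_seed + 2, id = sid)
      subjects[[k]] <- list(profile = prof, template = tpl,
                            recording = rec$recording, clean = rec$clean,
                            annotation = rec$annotation)
      manifest[[k]] <- data.frame(
        subject_id = sid, bp_group = cell$bp_group, history = cell$history,
        age = prof$age, bmi = prof$bmi, sbp = prof$sbp, dbp = prof$dbp,
        n_beats = length(rec$annotation$onset_idx)
      )
    }
  }
  structure(list(subjects = subjects,
                 manifest = do.call(rbind, manifest),
                 config = config, seed = seed),
            class = "pulse_cohort")
}

#' @export
print.pulse_cohort <- function(x, ...) {
  cat(sprintf("<pulse_cohort: %d subjects, %g s @ %g Hz, seed %s>\n",
              length(x$subjects), x$config$duration_s, x$config$rate,
              format(x$seed)))
  print(table(group = x$manifest$bp_group, history = x$manifest$history))
  invisible(x)
}

#' Write a recording (and sidecar annotation) to disk
#'
#' The signal goes to CSV (`time_s`, `amplitude`); profile, annotation and a
#' config echo go to a JSON sidecar next to it.
#'
#' @param subject one element of a [generate_cohort()] result.
#' @param dir output directory.
#' @param rate sampling rate override (defaults to the recording's).
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(subject, dir, rate = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- subject$recording
  r <- if (is.null(rate)) rec$rate else rate
  sid <- subject$profile$subject_id
  csv <- file.path(dir, paste0(sid, ".csv"))
  write.csv(data.frame(time_s = (seq_along(rec$samples) - 1L) / r,
                       amplitude = rec$samples),
            csv, row.names = FALSE)
  side <- list(profile = unclass(subject$profile),
               annotation = list(onset_idx = subject$annotation$onset_idx,
                                 peak_idx = subject$annotation$peak_idx),
               rate = r)
  jsonlite::write_json(side, file.path(dir, paste0(sid, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv)
}
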