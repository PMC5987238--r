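# Shape-conditional fiducial detection and the 20 time-domain features.
#
# A standard pulse cycle carries three component waves: percussion (t1, h1),
# tidal (onset t2/h2, crest t3/h3) and dicrotic (onset t4/h4, crest t5/h5).
# Cycles are first classed by morphology, then landmarks are searched with
# shape-appropriate rules: distinct crests via local extrema, merged
# ("shoulder") tidal waves via second-derivative sign changes.

# prominence-filtered local maxima: keep maxima rising at least `prom`
# above the higher of the two flanking minima
prominent_maxima <- function(y, prom) {
  mx <- local_maxima(y)
  if (!length(mx)) return(integer())
  mn <- c(1L, local_minima(y), length(y))
  keep <- vapply(mx, function(i) {
    left <- mn[mn < i]; right <- mn[mn > i]
    base <- max(if (length(left)) y[max(left)] else y[1L],
                if (length(right)) y[min(right)] else y[length(y)])
    (y[i] - base) >= prom
  }, logical(1L))
  mx[keep]
}

# keep only minima followed by a genuine rebound (a later sample rising at
# least `prom` above the minimum) — flat-tail smoothing ripple has none
rebound_minima <- function(ys, mn, prom) {
  n <- length(ys)
  mn[vapply(mn, function(i) max(ys[i:n]) - ys[i] >= prom, logical(1L))]
}

# shoulder: an inflection pair on the descending limb after the main peak
# (second difference swings negative -> positive -> negative with no
# intervening local maximum)
has_shoulder <- function(ys, peak, upto) {
  if (upto - peak < 6L) return(FALSE)
  seg <- ys[peak:upto]
  d2 <- diff(seg, differences = 2L)
  s <- sign(d2)
  pos <- which(s[-1L] > 0 & s[-length(s)] <= 0)  # - to + inflection
  if (!length(pos)) return(FALSE)
  any(vapply(pos, function(i) any(s[(i + 1L):length(s)] < 0), logical(1L)))
}

#' Classify the morphology of a pulse cycle
#'
#' Deterministic decision tree over (number of prominent local maxima after
#' mild smoothing, presence of a post-peak shoulder via the second-derivative
#' sign pattern, presence of a dicrotic-notch minimum). Eight classes:
#' \describe{
#'   \item{1}{three distinct waves (percussion, tidal, dicrotic) — the
#'     standard three-wave cycle}
#'   \item{2}{two peaks with a tidal shoulder on the percussion downslope}
#'   \item{3}{two peaks, second in late cycle (dicrotic present, tidal absent)}
#'   \item{4}{two peaks, second in early cycle (tidal present, dicrotic absent)}
#'   \item{5}{single peak with shoulder and a notch minimum}
#'   \item{6}{single peak with shoulder only}
#'   \item{7}{single peak with notch only}
#'   \item{8}{single monotone bump}
#' }
#'
#' @param samples numeric cycle samples (onset to onset).
#' @param rate sampling rate, Hz.
#' @param prominence minimum peak prominence as a fraction of cycle range
#'   (default 0.03: low enough to keep a shallow but genuine dicrotic crest,
#'   high enough to ignore smoothing ripple).
#' @return Integer shape class in 1..8.
#' @export
classify_shape <- function(samples, rate, prominence = 0.03) {
  check_finite_numeric(samples, "samples")
  n <- length(samples)
  if (n / rate < 0.3) stop_invalid("cycle shorter than 0.3 s")
  y <- remove_cycle_baseline(samples)
  ys <- moving_average(y, max(3L, round(0.02 * rate)))
  rng <- diff(range(ys))
  if (rng == 0) stop_invalid("flat cycle")
  mx <- prominent_maxima(ys, prominence * rng)
  if (!length(mx)) mx <- which.max(ys)
  peak <- mx[which.max(ys[mx])]
  after <- mx[mx > peak]
  nmax <- 1L + length(after)
  upto <- min(n, peak + as.integer(round(0.6 * n)))
  shoulder_upto <- if (length(after)) min(after[1L], upto) else upto
  shoulder <- has_shoulder(ys, peak, shoulder_upto)
  notch <- {
    mn <- local_minima(ys)
    mn <- mn[mn > peak & mn < n - 1L]
    length(rebound_minima(ys, mn, prominence * rng)) > 0L
  }
  if (nmax >= 3L) return(1L)
  if (nmax == 2L) {
    if (shoulder) return(2L)
    if ((after[1L] - 1L) / n > 0.5) return(3L)
    return(4L)
  }
  if (shoulder && notch) return(5L)
  if (shoulder) return(6L)
  if (notch) return(7L)
  8L
}

# baseline = linear interpolation between cycle onset and cycle end values,
# removing residual in-cycle drift before amplitudes are measured
remove_cycle_baseline <- function(samples) {
  n <- length(samples)
  samples - seq(samples[1L], samples[n], length.out = n)
}

#' Detect fiducial points of a pulse cycle
#'
#' The percussion peak is the global maximum of the baseline-removed cycle.
#' Tidal onset/crest and dicrotic onset/crest are then read from the
#' alternating minimum/maximum sequence after the peak; for shoulder-type
#' shapes (merged tidal wave) the tidal landmarks fall back to the
#' second-derivative inflection pair on the descending limb. Amplitudes are
#' measured above the onset-to-end baseline line. Landmarks that the shape
#' does not support are returned as `NA` and flagged, never zero-filled.
#'
#' @param samples numeric cycle samples.
#' @param rate sampling rate, Hz.
#' @param shape_class optional precomputed [classify_shape()] result.
#' @return List of class `fiducial_points`: `times` (t1..t5, s from onset),
#'   `amplitudes` (h1..h5, a.u. above baseline), `detected` (named logical),
#'   `shape_class`.
#' @export
detect_fiducials <- function(samples, rate, shape_class = NULL) {
  check_finite_numeric(samples, "samples")
  n <- length(samples)
  y <- remove_cycle_baseline(samples)
  if (diff(range(y)) == 0) stop_invalid("flat cycle: no percussion peak")
  if (is.null(shape_class)) shape_class <- classify_shape(samples, rate)
  ys <- moving_average(y, max(3L, round(0.02 * rate)))
  peak <- which.max(y)
  tt <- function(i) (i - 1L) / rate
  times <- c(t1 = tt(peak), t2 = NA_real_, t3 = NA_real_, t4 = NA_real_,
             t5 = NA_real_)
  amps <- c(h1 = y[peak], h2 = NA_real_, h3 = NA_real_, h4 = NA_real_,
            h5 = NA_real_)
  prom <- 0.01 * amps[["h1"]]
  mx <- prominent_maxima(ys, prom); mx <- mx[mx > peak]
  mn <- local_minima(ys); mn <- mn[mn > peak & mn < n - 1L]
  mn <- rebound_minima(ys, mn, prom)
  t3i <- NA_integer_
  if (length(mn) && length(mx)) {
    t2i <- mn[1L]
    cand <- mx[mx > t2i]
    if (length(cand)) {
      t3i <- cand[1L]
      times[c("t2", "t3")] <- c(tt(t2i), tt(t3i))
      amps[c("h2", "h3")] <- c(y[t2i], y[t3i])
    }
  }
  if (is.na(t3i) && shape_class %in% c(2L, 5L, 6L)) {
    # merged tidal wave: inflection pair on the descending limb
    upto <- min(n, peak + as.integer(round(0.5 * n)))
    if (upto - peak >= 6L) {
      seg <- ys[peak:upto]
      d2 <- diff(seg, differences = 2L)
      s <- sign(d2)
      rises <- which(s[-1L] > 0 & s[-length(s)] <= 0)   # t2: curvature turns up
      if (length(rises)) {
        falls <- which(s[-1L] < 0 & s[-length(s)] >= 0) # t3: curvature turns down
        falls <- falls[falls > rises[1L]]
        if (length(falls)) {
          t2i <- peak + rises[1L]
          t3i <- peak + falls[1L]
          times[c("t2", "t3")] <- c(tt(t2i), tt(t3i))
          amps[c("h2", "h3")] <- c(y[t2i], y[t3i])
        }
      }
    }
  }
  start4 <- if (!is.na(t3i)) t3i else peak
  mn4 <- mn[mn > start4]
  if (length(mn4)) {
    t4i <- mn4[1L]
    mx5 <- mx[mx > t4i]
    if (length(mx5)) {
      times[c("t4", "t5")] <- c(tt(t4i), tt(mx5[1L]))
      amps[c("h4", "h5")] <- c(y[t4i], y[mx5[1L]])
    } else {
      times["t4"] <- tt(t4i)
      amps["h4"] <- y[t4i]
    }
  }
  structure(list(times = times, amplitudes = amps,
                 detected = !is.na(times), shape_class = shape_class),
            class = "fiducial_points")
}

# total time y exceeds `thr`, with linearly interpolated crossings
width_above <- function(y, thr, rate) {
  n <- length(y)
  above <- y > thr
  if (!any(above)) return(0)
  total <- 0
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      left <- if (i == 1L) i - 1 else (i - 1) - (y[i] - thr) / (y[i] - y[i - 1L])
      right <- if (j == n) j - 1 else (j - 1) + (thr - y[j]) / (y[j + 1L] - y[j])
      total <- total + (right - left)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  total / rate
}

#' Extract the 20 time-domain features of a pulse cycle
#'
#' Durations t1..t5 and cycle length t; amplitudes h1..h5 above the onset
#' baseline; threshold-crossing widths `w31`/`w51` (total time the cycle
#' exceeds one third / one fifth of the percussion amplitude) and their
#' ratios to t; slope and amplitude ratios `h1/t1`, `h3/h1`, `h4/h1`; and the
#' systolic/diastolic areas `As` (onset to t4) and `Ad` (t4 to cycle end) by
#' trapezoidal integration. Features depending on undetected fiducials are
#' `NA`.
#'
#' @param samples numeric cycle samples.
#' @param rate sampling rate, Hz.
#' @param fiducials optional precomputed [detect_fiducials()] result.
#' @return Named numeric vector of length 20 with names
#'   `t1,t2,t3,t4,t5,h1,h2,h3,h4,h5,w31,w51,w31_t,w51_t,h1_t1,h3_h1,h4_h1,t,As,Ad`.
#' @export
extract_td <- function(samples, rate, fiducials = NULL) {
  if (is.null(fiducials)) fiducials <- detect_fiducials(samples, rate)
  y <- remove_cycle_baseline(samples)
  tm <- fiducials$times
  am <- fiducials$amplitudes
  h1 <- am[["h1"]]
  if (is.na(h1) || h1 <= 0) stop_invalid("nonpositive percussion amplitude")
  n <- length(samples)
  tdur <- (n - 1L) / rate
  w31 <- width_above(y, h1 / 3, rate)
  w51 <- width_above(y, h1 / 5, rate)
  As <- Ad <- NA_real_
  if (!is.na(tm[["t4"]])) {
    k <- as.integer(round(tm[["t4"]] * rate)) + 1L
    k <- min(max(k, 2L), n - 1L)
    As <- trapz_uniform(y[1:k], 1 / rate)
    Ad <- trapz_uniform(y[k:n], 1 / rate)
  }
  c(t1 = tm[["t1"]], t2 = tm[["t2"]], t3 = tm[["t3"]], t4 = tm[["t4"]],
    t5 = tm[["t5"]],
    h1 = h1, h2 = am[["h2"]], h3 = am[["h3"]], h4 = am[["h4"]],
    h5 = am[["h5"]],
    w31 = w31, w51 = w51, w31_t = w31 / tdur, w51_t = w51 / tdur,
    h1_t1 = h1 / tm[["t1"]], h3_h1 = am[["h3"]] / h1,
    h4_h1 = am[["h4"]] / h1,
    t = tdur, As = As, Ad = Ad)
}

#' @export
print.fiducial_points <- function(x, ...) {
  cat(sprintf("<fiducial_points: shape class %d, %d/5 detected>\n",
              x$shape_class, sum(x$detected)))
  print(rbind(time_s = x$times, amp = x$amplitudes))
  invisible(x)
}
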