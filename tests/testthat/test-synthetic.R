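# Synthetic cohort generator: grade assignment, beat model, recordings,
# cohorts.

test_that("blood-pressure grades follow the overlapping or-rules with precedence", {
  expect_equal(assign_bp_group(150, 95), "HestG")
  expect_equal(assign_bp_group(135, 85), "HerG")
  expect_equal(assign_bp_group(110, 70), "NG")
  # precedence: dbp > 90 wins over the NG systolic rule
  expect_equal(assign_bp_group(110, 92), "HestG")
  # dbp in 80-89 wins over the NG systolic rule (HerG before NG)
  expect_equal(assign_bp_group(110, 85), "HerG")
  # dbp < 80 satisfies the normal-grade rule even with sbp in 120-129
  expect_equal(assign_bp_group(125, 75), "NG")
  # genuinely uncovered: sbp 120-129 with dbp exactly 90
  expect_equal(assign_bp_group(125, 90), "unclassified")
  expect_error(assign_bp_group(-10, 5), "finite|sbp")
  expect_error(assign_bp_group(80, 90), "sbp > dbp")
  expect_error(assign_bp_group(NA_real_, 70), "finite")
})

test_that("beat generator places bumps and behaves linearly", {
  tpl <- beat_template()
  b <- generate_beat(tpl, 500)
  expect_length(b$samples, round(tpl[["period"]] * 500))
  # global maximum within 2 samples of the percussion centre
  expect_lte(abs(which.max(b$samples) - (tpl[["t1"]] * 500 + 1)), 2)
  # zero amplitudes -> flat zero cycle
  z <- generate_beat(beat_template(h1 = 0, h3 = 0, h5 = 0), 500)
  expect_equal(z$samples, numeric(length(z$samples)))
  # a lone percussion bump peaks on its centre sample
  lone <- generate_beat(beat_template(t1 = 0.15, h1 = 1, h3 = 1e-9,
                                      h5 = 1e-9), 500)
  expect_lte(abs(which.max(lone$samples) - 76), 2)
  # doubling all amplitudes doubles the waveform exactly
  d <- generate_beat(beat_template(h1 = 2, h3 = 1.24, h5 = 0.9), 500)
  expect_equal(d$samples,
               2 * generate_beat(beat_template(h1 = 1, h3 = 0.62,
                                               h5 = 0.45), 500)$samples)
  expect_error(generate_beat(beat_template(t1 = 0.5, t3 = 0.3)), "t1 < t3")
})

test_that("noise-free fixed-period recording has onsets at period multiples", {
  r <- generate_recording(beat_template(), clean_config(), seed = 1)
  expect_equal(r$annotation$onset_idx, seq(1, 4501, by = 500))
  expect_length(r$annotation$peak_idx, 10)
  # annotated peak is the global maximum of its noise-free beat
  for (k in seq_along(r$annotation$onset_idx)) {
    lo <- r$annotation$onset_idx[k]
    hi <- min(lo + 499, length(r$clean))
    expect_lte(abs((lo - 1 + which.max(r$clean[lo:hi])) -
                     r$annotation$peak_idx[k]), 2)
  }
})

test_that("recordings are bit-identical under a fixed seed", {
  a <- generate_recording(beat_template(), cohort_config(), seed = 77)
  b <- generate_recording(beat_template(), cohort_config(), seed = 77)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$annotation, b$annotation)
  c <- generate_recording(beat_template(), cohort_config(), seed = 78)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("injected baseline wander dominates the residual spectrum at its frequency", {
  cfg <- cohort_config(wander_amp = 0.5, wander_freq = 0.2, white_sd = 0,
                       period_jitter_sd = 0)
  r <- generate_recording(beat_template(), cfg, seed = 3)
  resid <- r$recording$samples - r$clean
  n <- length(resid)
  spec <- Mod(fft(resid))[2:(n / 2)]
  f <- (1:(n / 2 - 1)) * cfg$rate / n
  expect_lt(abs(f[which.max(spec)] - 0.2), 0.05)
})

test_that("recording duration must cover at least one period", {
  expect_error(generate_recording(beat_template(period = 1.2),
                                  cohort_config(duration_s = 1)),
               "duration")
})

test_that("cohort bookkeeping matches the configured cell counts", {
  cells <- data.frame(bp_group = c("NG", "NG", "HestG"),
                      history = c(0L, 1L, 1L), n = c(3L, 2L, 4L))
  cfg <- cohort_config(cells = cells, duration_s = 3)
  co <- generate_cohort(cfg, seed = 5)
  expect_length(co$subjects, 9)
  tab <- table(co$manifest$bp_group, co$manifest$history)
  expect_equal(unname(tab["NG", "0"]), 3)
  expect_equal(unname(tab["NG", "1"]), 2)
  expect_equal(unname(tab["HestG", "1"]), 4)
  # profiles consistent with their grade
  expect_true(all(assign_bp_group(co$manifest$sbp, co$manifest$dbp) ==
                    co$manifest$bp_group))
  expect_error(generate_cohort(cohort_config(cells = data.frame(
    bp_group = "NG", history = 0L, n = 0L))), "empty")
})

test_that("an injected h1 shift is recovered from ground-truth annotations", {
  cells <- data.frame(bp_group = rep("NG", 2), history = 0:1, n = c(200L, 200L))
  cfg <- cohort_config(cells = cells, duration_s = 3,
                       effect = c(h1 = 0.3))
  co <- generate_cohort(cfg, seed = 11)
  h1_mean <- function(hist) {
    vals <- unlist(lapply(co$subjects[co$manifest$history == hist],
                          function(s) s$annotation$beats$h1))
    mean(vals, na.rm = TRUE)
  }
  expect_lt(abs((h1_mean(1) - h1_mean(0)) - 0.3), 0.05)
})

test_that("zero effect sizes make history classes exchangeable", {
  cells <- data.frame(bp_group = rep("NG", 2), history = 0:1, n = c(120L, 120L))
  cfg <- cohort_config(cells = cells, duration_s = 3, effect = numeric(),
                       age_effect = 0, bmi_effect = 0)
  co <- generate_cohort(cfg, seed = 19)
  h1 <- lapply(0:1, function(hist) {
    unlist(lapply(co$subjects[co$manifest$history == hist],
                  function(s) s$annotation$beats$h1))
  })
  expect_gt(t.test(h1[[1]], h1[[2]])$p.value, 0.01)
})

test_that("recordings round-trip to CSV with a JSON sidecar", {
  cells <- data.frame(bp_group = "NG", history = 0L, n = 1L)
  co <- generate_cohort(cohort_config(cells = cells, duration_s = 3), seed = 2)
  dir <- withr::local_tempdir()
  csv <- write_recording(co$subjects[[1]], dir)
  expect_true(file.exists(csv))
  back <- utils::read.csv(csv)
  expect_equal(back$amplitude, co$subjects[[1]]$recording$samples)
  side <- jsonlite::read_json(sub("csv$", "json", csv), simplifyVector = TRUE)
  expect_equal(side$annotation$onset_idx,
               co$subjects[[1]]$annotation$onset_idx)
})
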