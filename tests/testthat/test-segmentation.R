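# SEEHT beat detection and cycle segmentation.

test_that("percussion emphasis band-pass has the expected response", {
  tone <- function(f) sin(2 * pi * f * (0:9999) / 500)
  amp <- function(y) max(abs(y[3000:7000]))
  expect_lt(abs(amp(emphasize_percussion(tone(2), rate = 500)) - 1), 0.05)
  expect_lt(amp(emphasize_percussion(tone(10), rate = 500)), 0.15)
  expect_equal(emphasize_percussion(numeric(500), rate = 500), numeric(500))
  expect_error(emphasize_percussion(tone(2), rate = 7), "exceed")
})

test_that("Shannon energy envelope matches its closed form", {
  # normalized samples at +-1 have zero Shannon energy
  se <- shannon_energy_envelope(c(0.5, 1, -1, 0.2), smooth = FALSE)
  expect_equal(se[2], 0)
  expect_equal(se[3], 0)
  # u = e^(-1/2): SE = -u^2 ln u^2 = e^(-1)
  x <- c(exp(-0.5), 1)
  expect_equal(shannon_energy_envelope(x, smooth = FALSE)[1], exp(-1))
  # even in x
  set.seed(9)
  v <- rnorm(100)
  expect_equal(shannon_energy_envelope(v, smooth = FALSE),
               shannon_energy_envelope(-v, smooth = FALSE))
  # all-zero input: no normalization blow-up
  expect_equal(shannon_energy_envelope(numeric(50), smooth = FALSE),
               numeric(50))
  expect_true(all(shannon_energy_envelope(rnorm(100), smooth = FALSE) >= 0))
})

test_that("Hilbert zero-crossings find one candidate per envelope bump", {
  rate <- 500
  tt <- (0:4999) / rate
  centers <- seq(0.5, 9.5, by = 1)
  env <- rowSums(vapply(centers,
                        function(c0) exp(-(tt - c0)^2 / (2 * 0.08^2)),
                        numeric(length(tt))))
  cand <- hilbert_zero_cross_peaks(env, rate)
  expect_length(cand, length(centers))
  # each candidate sits on a bump apex (brute-force argmax oracle per bump)
  apices <- round(centers * rate) + 1
  expect_true(all(vapply(cand, function(cc) min(abs(apices - cc)) <= 5,
                         logical(1))))
  # zero / constant envelope: no candidates
  expect_length(hilbert_zero_cross_peaks(numeric(1000), rate), 0)
  expect_length(hilbert_zero_cross_peaks(rep(2, 1000), rate), 0)
  # time reversal mirrors the candidates (within edge effects)
  cand_rev <- hilbert_zero_cross_peaks(rev(env), rate)
  mirrored <- sort(length(env) + 1 - cand_rev)
  expect_equal(length(mirrored), length(cand))
  expect_true(all(abs(sort(cand) - mirrored) <= 5))
})

test_that("peak refinement is a windowed argmax, idempotent, deduplicating", {
  rate <- 500
  tt <- (0:999) / rate
  sig <- exp(-(tt - 1)^2 / (2 * 0.03^2))   # true peak at sample 501
  # candidate 0.02 s (10 samples) left of the truth
  expect_equal(refine_peaks(491L, sig, rate), 501L)
  expect_equal(refine_peaks(501L, sig, rate), 501L)   # idempotent
  expect_equal(refine_peaks(c(492L, 510L), sig, rate), 501L)  # dedup
  expect_length(refine_peaks(integer(), sig, rate), 0)
})

test_that("clean 10-beat recording segments into 9 cycles with accurate feet", {
  r <- generate_recording(beat_template(), clean_config(), seed = 1)
  cyc <- segment_recording(r$recording)
  expect_equal(nrow(cyc), 9)
  expect_true(all(cyc$quality == "ok"))
  expect_true(all(diff(cyc$onset_idx) > 0))
  expect_equal(cyc$end_idx[-nrow(cyc)], cyc$onset_idx[-1])  # non-overlap
  onset_err_s <- (cyc$onset_idx - r$annotation$onset_idx[seq_len(nrow(cyc))]) /
    r$recording$rate
  expect_true(all(abs(onset_err_s) <= 0.02))
  peak_err <- abs(cyc$peak_idx - r$annotation$peak_idx[seq_len(nrow(cyc))])
  expect_true(all(peak_err <= 2))
})

test_that("a single beat yields no complete cycles", {
  cfg <- clean_config(duration_s = 1.0)
  r <- generate_recording(beat_template(period = 0.9), cfg, seed = 1)
  band <- bandpass_pulse(r$recording)
  pk <- detect_beats(band)$peaks
  expect_warning(cyc <- segment_cycles(band, pk[1]), "fewer than 2")
  expect_equal(nrow(cyc), 0)
})

test_that("quality rules flag short cycles and honour the exclusion list", {
  r <- generate_recording(beat_template(), clean_config(), seed = 2)
  cyc <- segment_recording(r$recording)
  expect_true(all(cyc$quality == "ok"))
  # inject an implausibly short cycle
  bad <- cyc
  bad$duration_s[2] <- 0.1
  flagged <- quality_filter(bad)
  expect_equal(flagged$quality[2], "rejected")
  expect_match(flagged$reason[2], "duration")
  # exclusion list overrides the rules
  ex <- quality_filter(cyc, exclusion_list = 3L)
  expect_equal(ex$quality[3], "rejected")
  expect_match(ex$reason[3], "excluded")
  expect_true(all(ex$quality[-3] == "ok"))
  # samples never mutated
  expect_identical(attr(ex, "band"), attr(cyc, "band"))
})

test_that("beat detection meets recovery targets on seeded cohorts", {
  # noise-free (period jitter only): virtually all beats, <= 2-sample error
  hits <- 0; total <- 0
  cfg <- cohort_config(wander_amp = 0, white_sd = 0)
  for (s in 1:20) {
    r <- generate_recording(beat_template(), cfg, seed = s)
    pk <- detect_beats(bandpass_pulse(r$recording))$peaks
    err <- vapply(r$annotation$peak_idx,
                  function(p) min(abs(pk - p)), 0)
    hits <- hits + sum(err <= 2)
    total <- total + length(err)
  }
  expect_gte(hits / total, 0.99)
  # 5% amplitude white noise: >= 95% of beats within +-0.05 s
  hits <- 0; total <- 0
  cfg5 <- cohort_config(wander_amp = 0, white_sd = 0.05)
  for (s in 1:20) {
    r <- generate_recording(beat_template(), cfg5, seed = s)
    pk <- detect_beats(bandpass_pulse(r$recording))$peaks
    err <- vapply(r$annotation$peak_idx,
                  function(p) min(abs(pk - p)), 0)
    hits <- hits + sum(err <= 0.05 * cfg5$rate)
    total <- total + length(err)
  }
  expect_gte(hits / total, 0.95)
})
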