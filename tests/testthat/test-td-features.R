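# Shape classification, fiducial detection and the 20 time-domain features.

test_that("shape classes for canonical morphologies", {
  # three distinct waves -> standard three-wave class
  b <- generate_beat(beat_template(), 500)
  expect_equal(classify_shape(b$samples, 500), 1L)
  # single monotone bump, no shoulder -> single-peak class
  tt <- (0:399) / 500
  g <- exp(-(tt - 0.25)^2 / (2 * 0.08^2))
  expect_equal(classify_shape(g, 500), 8L)
  # tidal crest merged into the percussion downslope -> shoulder class;
  # oracle: brute-force second-difference sign pattern on the template
  m <- generate_beat(beat_template(t3 = 0.24, h3 = 0.55, sigma_t = 0.06), 500)
  ys <- m$samples
  pk <- which.max(ys)
  d2s <- sign(diff(ys[pk:(pk + 240)], differences = 2))
  rises <- which(d2s[-1] > 0 & d2s[-length(d2s)] <= 0)
  expect_gt(length(rises), 0)           # inflection pair exists
  expect_equal(classify_shape(m$samples, 500), 2L)
  expect_error(classify_shape(g[1:100], 500), "0.3 s")
})

test_that("fiducials recover the generator ground truth on noise-free templates", {
  for (tpl in list(beat_template(),
                   beat_template(period = 0.85, t3 = 0.30, h3 = 0.55),
                   beat_template(period = 1.15, h1 = 1.3, h5 = 0.5))) {
    b <- generate_beat(tpl, 500)
    fid <- detect_fiducials(b$samples, 500)
    truth <- b$fiducials
    for (nm in c("t1", "t2", "t3", "t4", "t5")) {
      expect_lt(abs(fid$times[[nm]] - truth[[nm]]), 0.011,
                label = sprintf("%s error", nm))
    }
    for (nm in c("h1", "h3", "h5")) {
      hn <- sub("t", "h", nm)
      expect_lt(abs(fid$amplitudes[[hn]] - truth[[hn]]) / truth[[hn]], 0.02,
                label = sprintf("%s relative error", hn))
    }
  }
})

test_that("a symmetric bump yields only the percussion point", {
  tt <- (0:399) / 500
  g <- exp(-(tt - 0.25)^2 / (2 * 0.08^2))
  fid <- detect_fiducials(g, 500)
  expect_true(fid$detected[["t1"]])
  expect_false(any(fid$detected[c("t2", "t3", "t4", "t5")]))
  expect_true(all(is.na(fid$times[c("t2", "t3", "t4", "t5")])))
  expect_error(detect_fiducials(rep(1, 400), 500), "flat")
})

test_that("fiducials are scale-equivariant", {
  b <- generate_beat(beat_template(), 500)
  f1 <- detect_fiducials(b$samples, 500)
  f3 <- detect_fiducials(3 * b$samples, 500)
  expect_equal(f3$times, f1$times)
  expect_equal(f3$amplitudes, 3 * f1$amplitudes)
})

test_that("triangle pulse reproduces the closed-form widths", {
  # unit-height isoceles triangle of base 1 s: similar triangles give
  # w31 = 2/3 s and w51 = 4/5 s
  tri <- c(seq(0, 1, length.out = 251), seq(1, 0, length.out = 251)[-1])
  td <- extract_td(tri, 500)
  expect_equal(td[["w31"]], 2 / 3, tolerance = 1 / 500)
  expect_equal(td[["w51"]], 4 / 5, tolerance = 1 / 500)
  expect_gte(td[["w51"]], td[["w31"]])   # lower threshold, wider crossing
  expect_lte(td[["w51"]], td[["t"]])
})

test_that("the 20 features are complete, consistent and additive", {
  b <- generate_beat(beat_template(), 500)
  td <- extract_td(b$samples, 500)
  expect_length(td, 20)
  expect_named(td, c("t1", "t2", "t3", "t4", "t5", "h1", "h2", "h3", "h4",
                     "h5", "w31", "w51", "w31_t", "w51_t", "h1_t1", "h3_h1",
                     "h4_h1", "t", "As", "Ad"))
  # ratios consistent with their components
  expect_equal(td[["w31_t"]], td[["w31"]] / td[["t"]], tolerance = 1e-9)
  expect_equal(td[["h3_h1"]], td[["h3"]] / td[["h1"]], tolerance = 1e-9)
  expect_equal(td[["h1_t1"]], td[["h1"]] / td[["t1"]], tolerance = 1e-9)
  # systolic + diastolic area = total cycle area
  y <- b$samples - seq(b$samples[1], b$samples[length(b$samples)],
                       length.out = length(b$samples))
  total <- sum(y[-1] + y[-length(y)]) / 2 / 500
  expect_equal(td[["As"]] + td[["Ad"]], total, tolerance = 1e-9)
  # h3/h1 identity when the tidal crest equals the percussion height
  fid <- detect_fiducials(b$samples, 500)
  fid$amplitudes[["h3"]] <- fid$amplitudes[["h1"]]
  expect_equal(extract_td(b$samples, 500, fid)[["h3_h1"]], 1)
})

test_that("amplitude features scale with gain; time features do not", {
  b <- generate_beat(beat_template(), 500)
  td1 <- extract_td(b$samples, 500)
  td5 <- extract_td(5 * b$samples, 500)
  tf <- c("t1", "t2", "t3", "t4", "t5", "t", "w31", "w51", "w31_t", "w51_t",
          "h3_h1", "h4_h1")
  expect_equal(td5[tf], td1[tf], tolerance = 1e-6)
  expect_equal(td5[c("h1", "h3", "As", "Ad")],
               5 * td1[c("h1", "h3", "As", "Ad")], tolerance = 1e-6)
})

test_that("features are stable under resampling to twice the rate", {
  td500 <- extract_td(generate_beat(beat_template(), 500)$samples, 500)
  td1k <- extract_td(generate_beat(beat_template(), 1000)$samples, 1000)
  for (nm in names(td500)) {
    if (is.na(td500[[nm]])) next
    expect_lt(abs(td1k[[nm]] - td500[[nm]]) / max(abs(td500[[nm]]), 1e-6),
              0.01, label = nm)
  }
})

test_that("missing fiducials propagate as missing features, not zeros", {
  tt <- (0:399) / 500
  g <- exp(-(tt - 0.25)^2 / (2 * 0.08^2))
  td <- extract_td(g, 500)
  expect_true(is.na(td[["t4"]]))
  expect_true(is.na(td[["As"]]))
  expect_true(is.na(td[["Ad"]]))
  expect_false(is.na(td[["w31"]]))
  # nonpositive percussion amplitude is an error, not a silent zero
  bad <- detect_fiducials(g, 500)
  bad$amplitudes[["h1"]] <- 0
  expect_error(extract_td(g, 500, bad), "percussion")
})
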