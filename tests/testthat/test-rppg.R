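test_that("rgb_to_ycbcr matches the BT.601 full-range transform", {
  gray <- array(128, dim = c(2, 2, 3))
  yc <- rgb_to_ycbcr(gray)
  expect_equal(yc[, , 1], matrix(128, 2, 2))
  expect_equal(yc[, , 2], matrix(128, 2, 2))
  expect_equal(yc[, , 3], matrix(128, 2, 2))

  black <- array(0, dim = c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_ycbcr(black)), c(0, 128, 128))

  # independent scalar evaluation of the published coefficients
  # (Cr = 128 + 0.5*255 = 255.5 clips to the 8-bit ceiling)
  red <- array(c(255, 0, 0), dim = c(1, 1, 3))
  expect_equal(as.numeric(rgb_to_ycbcr(red)),
               pmin(255, c(0.299 * 255, 128 - 0.168736 * 255, 128 + 0.5 * 255)))

  set.seed(7)
  fr <- array(runif(5 * 4 * 3, 0, 255), dim = c(5, 4, 3))
  yc <- rgb_to_ycbcr(fr)
  i <- 3; j <- 2
  px <- fr[i, j, ]
  expect_equal(yc[i, j, 1], 0.299 * px[1] + 0.587 * px[2] + 0.114 * px[3])
  expect_error(rgb_to_ycbcr(matrix(1, 2, 2)), class = "prvkit_invalid_frames")
})

test_that("skin_mask equals the per-pixel bound predicate", {
  cfg <- skin_config()
  uniform <- array(rep(c(150, 110, 150), each = 6), dim = c(2, 3, 3))
  expect_true(all(skin_mask(uniform, cfg)))

  dark <- array(rep(c(150, 0, 0), each = 6), dim = c(2, 3, 3))
  expect_error(skin_mask(dark, cfg), class = "prvkit_no_skin")

  # half skin / half out-of-range: mask covers exactly the skin half
  half <- uniform
  half[2, , 2] <- 20
  m <- skin_mask(half, cfg)
  expect_true(all(m[1, ]) && !any(m[2, ]))

  # oracle equivalence on random frames
  set.seed(11)
  for (k in 1:5) {
    fr <- array(runif(8 * 8 * 3, 0, 255), dim = c(8, 8, 3))
    y <- fr[, , 1]; cb <- fr[, , 2]; cr <- fr[, , 3]
    expected <- y >= cfg$y_min & cb >= cfg$cb_min & cb <= cfg$cb_max &
      cr >= cfg$cr_min & cr <= cfg$cr_max
    got <- tryCatch(skin_mask(fr, cfg), prvkit_no_skin = function(e) NULL)
    if (is.null(got)) expect_false(any(expected)) else expect_identical(got, expected)
  }
})

test_that("cluster_center is the Cb-Cr centroid", {
  expect_equal(cluster_center(100, 150), c(cb = 100, cr = 150))
  expect_equal(cluster_center(c(100, 102), c(150, 152)), c(cb = 101, cr = 151))
  set.seed(3)
  cb <- rnorm(1000, 110, 4); cr <- rnorm(1000, 150, 4)
  ctr <- cluster_center(cb, cr)
  expect_equal(unname(ctr), c(mean(cb), mean(cr)))
  expect_lt(abs(ctr["cb"] - 110), 3 * 4 / sqrt(1000) + 1e-9)
  expect_error(cluster_center(numeric(0), numeric(0)),
               class = "prvkit_invalid_argument")
})

test_that("random_expansion is centered, seeded, and convergent", {
  cfg0 <- skin_config(expansion_scale = 0)
  expect_equal(random_expansion(c(cb = 100, cr = 150), cfg0),
               c(cb = 100, cr = 150))

  cfg <- skin_config(n_expansion = 100, expansion_scale = 1)
  set.seed(99); a <- random_expansion(c(cb = 100, cr = 150), cfg)
  set.seed(99); b <- random_expansion(c(cb = 100, cr = 150), cfg)
  expect_identical(a, b)

  # law of large numbers: mean offset within 3*scale/sqrt(n)
  cfg_big <- skin_config(n_expansion = 10000, expansion_scale = 1)
  set.seed(17)
  ex <- random_expansion(c(cb = 100, cr = 150), cfg_big)
  expect_lt(abs(ex["cb"] - 100), 3 / sqrt(10000))
  expect_lt(abs(ex["cr"] - 150), 3 / sqrt(10000))

  # precomputed offsets are honored (reused across frames)
  off <- list(cb = rep(1, 5), cr = rep(-1, 5))
  cfg5 <- skin_config(n_expansion = 5)
  expect_equal(random_expansion(c(cb = 10, cr = 20), cfg5, off),
               c(cb = 11, cr = 19))
})

test_that("chrominance_to_bvp combines standardized chroma", {
  t <- seq(0, 10, by = 1 / 30)
  s <- sin(2 * pi * t)

  # constant Cb: BVP follows the Cr sinusoid alone
  bvp <- chrominance_to_bvp(rep(5, length(s)), 100 + s)
  expect_equal(mean(bvp), 0, tolerance = 1e-12)
  expect_gt(abs(cor(bvp, s)), 0.999)

  # identical series cancel exactly
  expect_true(all(chrominance_to_bvp(100 + s, 100 + s) == 0))

  # antiphase sinusoids double the standardized amplitude
  one <- chrominance_to_bvp(rep(0, length(s)), s)
  both <- chrominance_to_bvp(-s, s)
  expect_equal(max(abs(both)), 2 * max(abs(one)), tolerance = 1e-9)

  expect_error(chrominance_to_bvp(rep(1, 10), rep(2, 10)),
               class = "prvkit_degenerate_signal")
})

test_that("detrend_respiration removes slow trends and keeps the pulse band", {
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.05 * t)
  expect_lt(power_ratio(detrend_respiration(slow, fs), slow), 0.10)

  fast <- sin(2 * pi * 1.2 * t)
  expect_gt(power_ratio(detrend_respiration(fast, fs), fast), 0.90)

  expect_true(all(detrend_respiration(rep(3, 500), fs) == 0))
  expect_error(detrend_respiration(rep(1, 10), fs),
               class = "prvkit_too_few_samples")
})

test_that("bandpass_butterworth passes the pulse band and rejects outside it", {
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  mid <- t > 10 & t < 50  # avoid filter edge transients

  y1 <- bandpass_butterworth(sin(2 * pi * 1 * t), fs)
  expect_gt(max(abs(y1[mid])), 0.95)
  expect_lt(max(abs(y1[mid])), 1.05)

  y5 <- bandpass_butterworth(sin(2 * pi * 5 * t), fs)
  expect_lt(max(abs(y5[mid])), 0.10)

  expect_true(all(bandpass_butterworth(rep(0, 1000), fs) == 0))
  expect_error(bandpass_butterworth(rnorm(100), fs, 0.5, 20),
               class = "prvkit_invalid_argument")
})

test_that("extract_bvp recovers the pulse frequency from synthetic frames", {
  for (rate_bpm in c(60, 72)) {
    cfg <- simulation_config(duration_s = 360, mean_rate_bpm = rate_bpm,
                             lf_depth = 0, hf_depth = 0,
                             artifact_rate_per_min = 0, seed = 8)
    truth <- simulate_beats(cfg)
    fr <- simulate_face_frames(truth, fps = 30, size = c(30, 30),
                               duration_s = 40)
    bvp <- extract_bvp(fr)
    expect_equal(bvp$fs, 30)
    expect_equal(dominant_frequency(bvp), rate_bpm / 60, tolerance = 0.05)
  }
})

test_that("extract_bvp ignores background content and is reproducible", {
  cfg <- simulation_config(duration_s = 360, mean_rate_bpm = 60,
                           lf_depth = 0, hf_depth = 0,
                           artifact_rate_per_min = 0, seed = 8)
  truth <- simulate_beats(cfg)
  fr <- simulate_face_frames(truth, fps = 30, size = c(30, 30),
                             duration_s = 30, skin_fraction = 0.5)
  b1 <- extract_bvp(fr)

  # permute the non-skin background pixels: extraction must not change
  fr2 <- fr
  set.seed(1)
  for (i in seq_along(fr2$frames)) {
    bg <- fr2$frames[[i]][16:30, , ]
    fr2$frames[[i]][16:30, , ] <- bg[sample(15), , ]
  }
  b2 <- extract_bvp(fr2)
  expect_identical(b1$samples, b2$samples)

  b3 <- extract_bvp(fr)
  expect_identical(b1$samples, b3$samples)
})

test_that("extract_bvp flags degenerate and skinless input", {
  cfg <- simulation_config(duration_s = 360, mean_rate_bpm = 60,
                           lf_depth = 0, hf_depth = 0,
                           artifact_rate_per_min = 0, seed = 8)
  truth <- simulate_beats(cfg)
  static <- simulate_face_frames(truth, fps = 30, size = c(20, 20),
                                 duration_s = 20, modulation_depth = 0,
                                 noise_sd = 0)
  expect_error(extract_bvp(static), class = "prvkit_degenerate_signal")

  # >10% of frames without skin aborts with an extraction-quality error
  fr <- simulate_face_frames(truth, fps = 30, size = c(20, 20), duration_s = 20)
  blue <- array(rep(c(20, 40, 230), each = 400), dim = c(20, 20, 3))
  for (i in 1:100) fr$frames[[i]] <- blue
  expect_error(extract_bvp(fr), class = "prvkit_extraction_quality")
})
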