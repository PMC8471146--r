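test_that("IPFM beats are exact for constant rates", {
  cfg <- simulation_config(duration_s = 360, mean_rate_bpm = 60,
                           lf_depth = 0, hf_depth = 0, seed = 1)
  truth <- simulate_beats(cfg)
  expect_equal(truth$beat_times_ms,
               seq(0, by = 1000, length.out = length(truth$beat_times_ms)),
               tolerance = 1e-6)

  cfg75 <- simulation_config(duration_s = 360, mean_rate_bpm = 75,
                             lf_depth = 0, hf_depth = 0, seed = 1)
  expect_true(all(abs(simulate_beats(cfg75)$true_nni_ms - 800) < 0.1))
})

test_that("LF-only modulation shows up at the configured tachogram frequency", {
  cfg <- simulation_config(duration_s = 400, lf_depth = 0.1, hf_depth = 0,
                           artifact_rate_per_min = 0, seed = 2)
  truth <- simulate_beats(cfg)
  psd <- tachogram_psd(truth$true_nni_ms)
  expect_equal(psd$freq[which.max(psd$density)], 0.10, tolerance = 1 / 120 + 1e-9)
})

test_that("config validation rejects non-physical settings", {
  expect_error(simulation_config(duration_s = 100), class = "prvkit_invalid_config")
  expect_error(simulation_config(lf_freq_hz = 0.2), class = "prvkit_invalid_config")
  expect_error(simulation_config(lf_depth = 0.6), class = "prvkit_invalid_config")
  expect_error(simulation_config(artifact_magnitude = 0.7),
               class = "prvkit_invalid_config")
})

test_that("inject_artifacts perturbs recorded beats and nothing else", {
  cfg <- simulation_config(duration_s = 400, seed = 3)
  truth <- simulate_beats(cfg)

  none <- simulation_config(duration_s = 400, artifact_rate_per_min = 0, seed = 3)
  expect_identical(inject_artifacts(truth, none), truth)

  pert <- inject_artifacts(truth, cfg)
  expect_gt(length(pert$artifact_indices), 0)
  moved <- which(pert$beat_times_ms != truth$beat_times_ms)
  expect_identical(moved, as.integer(pert$artifact_indices))
  # shift magnitude: exactly artifact_magnitude times the local interval
  i <- pert$artifact_indices[1]
  local_nni <- min(diff(truth$beat_times_ms)[c(i - 1, i)])
  expect_equal(abs(pert$beat_times_ms[i] - truth$beat_times_ms[i]),
               cfg$artifact_magnitude * local_nni)
})

test_that("a magnitude-0.5 artifact splits an interval into ~400/1200 ms", {
  cfg <- simulation_config(duration_s = 360, mean_rate_bpm = 75,
                           lf_depth = 0, hf_depth = 0,
                           artifact_rate_per_min = 1,
                           artifact_magnitude = 0.499, seed = 60)
  truth <- simulate_beats(cfg)
  pert <- inject_artifacts(truth, cfg)
  # pick an artifact with no neighbor artifact so the pair is clean
  iso <- pert$artifact_indices[
    !(pert$artifact_indices - 1) %in% pert$artifact_indices &
      !(pert$artifact_indices + 1) %in% pert$artifact_indices][1]
  iv <- diff(pert$beat_times_ms)[c(iso - 1, iso)]
  expect_equal(sort(iv), c(800 * 0.501, 800 * 1.499), tolerance = 0.01)
})

test_that("z-score normalization flags most injected artifacts", {
  cfg <- simulation_config(duration_s = 660, seed = 13)
  rec <- simulate_dual_recording(cfg)
  bt <- rec$truth$camera_beat_times_ms
  ppi <- ppi_series(bt)
  nni <- ppi_to_nni(ppi)
  # each shifted beat i perturbs intervals i-1 and i; count artifacts whose
  # interval pair intersects the replaced set
  art <- rec$truth$artifact_indices
  hit <- vapply(art, function(i) any(c(i - 1, i) %in% nni$replaced_indices),
                logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("beats_to_bvp renders recoverable pulse peaks", {
  cfg <- simulation_config(duration_s = 360, artifact_rate_per_min = 0, seed = 5)
  truth <- simulate_beats(cfg)

  one <- truth
  one$beat_times_ms <- 5000
  one$config$duration_s <- 360
  b <- beats_to_bvp(one, fs = 255)
  expect_equal((which.max(b$samples) - 1) / 255, 5, tolerance = 0.5 / 255 + 1e-9)

  # noise-free rendering: every beat recovered within +/- 4 ms
  b255 <- beats_to_bvp(truth, fs = 255)
  pk <- detect_peaks(bvp_signal(bandpass_butterworth(b255$samples, 255),
                                fs = 255))
  interior <- truth$beat_times_ms[truth$beat_times_ms > 2000 &
                                    truth$beat_times_ms < 358000]
  err <- vapply(interior, function(tb) min(abs(pk - tb)), numeric(1))
  expect_lt(max(err), 4 + 1e-9)

  # heavy noise: >= 95% of beats still recovered after bandpass
  bn <- beats_to_bvp(truth, fs = 255, noise_sd = 0.3, seed = 10)
  pkn <- detect_peaks(bvp_signal(bandpass_butterworth(bn$samples, 255),
                                 fs = 255))
  errn <- vapply(interior, function(tb) min(abs(pkn - tb)), numeric(1))
  expect_gte(mean(errn < 100), 0.95)
})

test_that("dual recordings are paired, seeded, and segment as configured", {
  rec <- short_recording()
  expect_equal(rec$contact$fs, 255)
  expect_equal(rec$camera$fs, 30)
  expect_identical(length(rec$contact$samples), 420L * 255L)

  # artifact-free, noise-free channels give matching NNI
  cfg0 <- simulation_config(duration_s = 420, artifact_rate_per_min = 0,
                            channel_noise_sd = 0, seed = 42)
  rec0 <- simulate_dual_recording(cfg0)
  nni_c <- run_ppi_pipeline(rec0$contact)[[1]]$nni$intervals_ms
  nni_k <- run_ppi_pipeline(rec0$camera)[[1]]$nni$intervals_ms
  k <- min(length(nni_c), length(nni_k))
  expect_lt(max(abs(nni_c[seq_len(k)] - nni_k[seq_len(k)])), 2 * 1000 / 255 + 1e-9)

  # bit-reproducible given the seed
  again <- simulate_dual_recording(simulation_config(duration_s = 420, seed = 42))
  expect_identical(again$contact$samples, rec$contact$samples)
  expect_identical(again$camera$samples, rec$camera$samples)

  # 660 s recording yields 11 segments per channel
  rec11 <- simulate_dual_recording(simulation_config(duration_s = 660, seed = 1))
  expect_length(run_ppi_pipeline(rec11$camera), 11)
})

test_that("face frames carry the pulse in chrominance", {
  cfg <- simulation_config(duration_s = 360, mean_rate_bpm = 60,
                           lf_depth = 0, hf_depth = 0,
                           artifact_rate_per_min = 0, seed = 6)
  truth <- simulate_beats(cfg)
  fr <- simulate_face_frames(truth, fps = 30, size = c(24, 24),
                             duration_s = 30, skin_fraction = 0.5)
  expect_s3_class(fr, "frame_sequence")
  expect_length(fr$frames, 900)
  # bottom half is non-skin background
  yc <- rgb_to_ycbcr(fr$frames[[1]])
  m <- tryCatch(skin_mask(yc), prvkit_no_skin = function(e) NULL)
  expect_true(all(m[1:12, ]))
  expect_false(any(m[13:24, ]))

  bvp <- extract_bvp(fr)
  expect_equal(dominant_frequency(bvp), 1.0, tolerance = 0.05)
})
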