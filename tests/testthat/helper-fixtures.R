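# Shared fixtures built in code.

# Sinusoidal BVP at a given frequency.
sine_bvp <- function(freq_hz, dur_s, fs, t0 = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  bvp_signal(sin(2 * pi * freq_hz * t), fs = fs, t0 = t0)
}

# Brute-force oracle for the z-score normalization rule: an independent
# re-statement of the contract, kept free of ppi_to_nni's code path.
oracle_nni <- function(x, T = 2) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(list(values = x, replaced = integer(0)))
  flagged <- which(abs((x - m) / s) >= T)
  y <- x
  for (i in flagged) {
    nb <- c(if (i > 1) y[i - 1], if (i < length(x)) x[i + 1])
    y[i] <- median(nb)
  }
  list(values = y, replaced = flagged)
}

# Fraction of total signal power retained in the output (oracle for
# filtering/detrending checks).
power_ratio <- function(out, input) sum(out^2) / sum(input^2)

# A small dual recording shared by slower end-to-end tests (memoized).
.fixture_env <- new.env(parent = emptyenv())
short_recording <- function() {
  if (is.null(.fixture_env$rec)) {
    cfg <- simulation_config(duration_s = 420, seed = 42)
    .fixture_env$rec <- c(simulate_dual_recording(cfg), list(config = cfg))
  }
  .fixture_env$rec
}

# Full-length (660 s) default-configuration recording with both pipelines,
# shared by the acceptance checks (memoized; ~5 s to build).
full_recording <- function() {
  if (is.null(.fixture_env$full)) {
    cfg <- simulation_config(duration_s = 660, seed = 101)
    rec <- simulate_dual_recording(cfg)
    .fixture_env$full <- list(
      config = cfg,
      rec = rec,
      contact = run_ppi_pipeline(rec$contact),
      camera = run_ppi_pipeline(rec$camera)
    )
  }
  .fixture_env$full
}
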