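test_that("sweep averaging filters, rejects artifacts, and reduces noise", {
  fs <- 25000
  t <- (0:249) / fs * 1000
  clean <- 0.8 * exp(-((t - 5.7) / 0.25)^2 / 2) -
    0.8 * exp(-((t - 5.2) / 0.25)^2 / 2)
  # identical noiseless sweeps: the average equals one filtered sweep
  sweeps <- matrix(rep(clean, each = 200), 200)
  rec <- average_sweeps(sweeps, fs)
  flt <- signal::butter(2, c(100, 3000) / (fs / 2), type = "pass")
  expect_equal(rec$waveform_uv, signal::filtfilt(flt, clean),
               tolerance = 1e-10)
  # a single huge artifact among 500 is rejected and barely felt
  set.seed(81)
  noisy <- matrix(rep(clean, each = 500), 500) +
    matrix(rnorm(500 * 250, sd = 2), 500)
  spoiled <- noisy
  spoiled[7, ] <- spoiled[7, ] + 100 * sin(2 * pi * 700 * t / 1000)
  rec_ok <- average_sweeps(noisy, fs)
  rec_sp <- average_sweeps(spoiled, fs)
  expect_gte(rec_sp$n_rejected, 1)
  expect_lt(max(abs(rec_sp$waveform_uv - rec_ok$waveform_uv)),
            0.01 * max(abs(rec_ok$waveform_uv)) + 0.02)
  # residual noise shrinks like 1/sqrt(n)
  pure_noise <- matrix(rnorm(500 * 250, sd = 2), 500)
  rec_n <- average_sweeps(pure_noise, fs, band_hz = NULL)
  expect_equal(stats::sd(rec_n$waveform_uv), 2 / sqrt(500),
               tolerance = 0.1)
  # too many impulsive artifacts is a data-quality error
  bad <- matrix(rnorm(200 * 250, sd = 2), 200)
  bad[1:120, 100] <- 1000  # single-sample transients: huge peak, modest SD
  expect_error(average_sweeps(bad, fs), "data-quality")
})

test_that("wave V is the band-limited peak nearest 5.7 ms", {
  fs <- 25000
  t <- (0:249) / fs * 1000
  mk_rec <- function(w) structure(list(waveform_uv = w, t_ms = t,
                                       half1 = w, half2 = w,
                                       n_sweeps = 500, n_rejected = 0,
                                       sample_rate_hz = fs, stim = NULL),
                                  class = "abr_record")
  # trough -0.3 at 5.2 ms, peak +1.0 at 5.7 ms: amplitude 1.3 (the lobe
  # coefficients compensate the 4.4% overlap of the two Gaussians)
  w <- 1.0152 * exp(-((t - 5.7) / 0.2)^2 / 2) -
    0.3451 * exp(-((t - 5.2) / 0.2)^2 / 2)
  wv <- detect_wave_v(mk_rec(w))
  expect_lt(abs(wv$latency_ms - 5.7), 1000 / fs + 1e-9)
  expect_equal(wv$amplitude_uv, max(w) - min(w[t < 5.7]),
               tolerance = 0.02)
  expect_equal(wv$amplitude_uv, 1.3, tolerance = 0.05)
  # flat record: undefined
  wv0 <- quiet(detect_wave_v(mk_rec(rep(0, 250))))
  expect_true(is.na(wv0$latency_ms))
  # two candidate peaks at 5.0 and 6.2 ms: 6.2 is nearer to 5.7
  w2 <- exp(-((t - 5.0) / 0.2)^2 / 2) + exp(-((t - 6.2) / 0.2)^2 / 2)
  expect_equal(detect_wave_v(mk_rec(w2))$latency_ms, 6.2,
               tolerance = 0.05)
})

test_that("wave I requires split-half repeatability above the noise floor", {
  sp <- abr_spec()
  sw <- simulate_abr(sp, 16, seed = 82)
  rec <- average_sweeps(sw$sweeps, sp$sample_rate_hz)
  wi <- detect_wave_i(rec)
  expect_equal(wi$amplitude_uv, sp$waveI_amp_vs_freq[["16"]],
               tolerance = 0.12)
  expect_lt(abs(wi$latency_ms - sp$wave_latencies_ms[1]), 0.2)
  # split halves disagreeing by more than 0.5 ms: gate refuses
  t <- rec$t_ms
  bump <- function(at) exp(-((t - at) / 0.2)^2 / 2) -
    exp(-((t - at + 0.5) / 0.2)^2 / 2)
  rec2 <- rec
  rec2$waveform_uv <- bump(1.5)
  rec2$half1 <- bump(1.5)
  rec2$half2 <- bump(2.6)  # only peak near the band sits 1.1 ms away
  wi2 <- quiet(detect_wave_i(rec2))
  expect_true(is.na(wi2$amplitude_uv))
  # noise-only records stay undefined in at least 95% of simulations
  null_sp <- abr_spec(waveI_amp_vs_freq = c("8" = 0),
                      waveV_amp_vs_freq = c("8" = 0),
                      mid_wave_amps_uv = c(0, 0, 0))
  fp <- sum(vapply(1:100, function(r) {
    swn <- simulate_abr(null_sp, 8, seed = 8200 + r)
    recn <- average_sweeps(swn$sweeps, null_sp$sample_rate_hz)
    !is.na(quiet(detect_wave_i(recn))$amplitude_uv)
  }, logical(1)))
  expect_lte(fp / 100, 0.05)
})

test_that("the objective ABR threshold finds the lowest supra-criterion level", {
  mk_rec <- function(ampV, seed) {
    s <- abr_spec(waveI_amp_vs_freq = c("8" = 0.3 * ampV),
                  waveV_amp_vs_freq = c("8" = ampV),
                  mid_wave_amps_uv = c(0.2, 0.15, 0.2) * ampV,
                  noise_sd_uv = 2)
    quiet(average_sweeps(simulate_abr(s, 8, seed = seed)$sweeps,
                         s$sample_rate_hz))
  }
  levels <- seq(15, 75, by = 10)
  # amplitude 0 below 35 dB SPL, growing linearly above
  amps <- pmax(0, (levels - 35) * 0.04)
  recs <- Map(mk_rec, amps, 8300 + seq_along(amps))
  th <- quiet(abr_threshold(recs, levels))
  expect_false(th$above_max)
  expect_lte(abs(th$threshold_db - 35), 10)
  # doubling every amplitude cannot raise the threshold
  recs2 <- Map(mk_rec, amps * 2, 8300 + seq_along(amps))
  th2 <- quiet(abr_threshold(recs2, levels))
  expect_lte(th2$threshold_db, th$threshold_db)
  # pure noise at every level: threshold above the tested range
  recs0 <- Map(mk_rec, rep(0, 7), 8400 + seq_len(7))
  th0 <- quiet(abr_threshold(recs0, levels))
  expect_true(th0$above_max)
})

test_that("recovered wave amplitudes preserve the frequency ordering", {
  # amplitudes averaged over 5 simulated animals, as in the recordings
  sp <- abr_spec()
  freqs <- c(8, 16, 32, 64, 80)
  wv <- wi <- matrix(NA_real_, 5, 5)
  for (a in 1:5) for (i in seq_along(freqs)) {
    sw <- simulate_abr(sp, freqs[i], seed = 8500 + 10 * a + i)
    rec <- average_sweeps(sw$sweeps, sp$sample_rate_hz)
    wv[a, i] <- detect_wave_v(rec)$amplitude_uv
    wi[a, i] <- quiet(detect_wave_i(rec))$amplitude_uv
  }
  expect_gt(stats::cor(colMeans(wv), unname(sp$waveV_amp_vs_freq),
                       method = "spearman"), 0.9)
  expect_gt(stats::cor(colMeans(wi, na.rm = TRUE),
                       unname(sp$waveI_amp_vs_freq),
                       method = "spearman"), 0.9)
})
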