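test_that("tone pips are gated sinusoids at the calibrated amplitude", {
  x <- make_tone_pip(20, 94, duration_ms = 50, ramp_ms = 2,
                     sample_rate_hz = 192000)
  expect_length(x, 9600)
  expect_equal(x[1], 0)
  expect_equal(x[9600], 0)
  # steady-state RMS of a unit-amplitude (94 dB) sine is 1/sqrt(2)
  steady <- x[round(0.004 * 192000):round(0.046 * 192000)]
  expect_equal(sqrt(mean(steady^2)), 1 / sqrt(2), tolerance = 1e-3)
  # level scaling: -20 dB is a factor 10 in amplitude
  y <- make_tone_pip(20, 74, sample_rate_hz = 192000)
  expect_equal(max(abs(y)), max(abs(x)) / 10, tolerance = 1e-6)
  expect_error(make_tone_pip(100, 80, sample_rate_hz = 192000),
               "parameter error")
  expect_error(make_tone_pip(20, 80, duration_ms = 3, ramp_ms = 2),
               "parameter error")
})

test_that("synthetic calls sweep log-linearly within the 60-90 kHz band", {
  cs <- call_spec("c", 40, 70, 70, 80)
  x <- make_call(cs, 192000)
  expect_length(x, round(0.040 * 192000))
  # constant-frequency call: spectral peak at 70 kHz
  expect_equal(segment_peak_freq_khz(x, 192000, 5, 35), 70,
               tolerance = 0.3)
  # sweep endpoints recovered from short-time spectra (STFT oracle)
  cs2 <- call_spec("c2", 42, 64, 76, 80)
  x2 <- make_call(cs2, 192000)
  expect_equal(segment_peak_freq_khz(x2, 192000, 0, 2.5), 64,
               tolerance = 1)
  expect_equal(segment_peak_freq_khz(x2, 192000, 39.5, 42), 76,
               tolerance = 1)
  expect_error(call_spec("bad", 40, 70, 95, 80), "parameter error")
  expect_error(call_spec("bad", 20, 70, 80, 80), "parameter error")
  # the standard battery: nine calls, all inside the band, levels 80/90
  calls <- default_calls()
  expect_length(calls, 9)
  for (cc in calls) {
    f <- call_freq_khz(cc, seq(0, cc$duration_ms, by = 0.5))
    expect_true(all(f >= 60 & f <= 90))
    expect_true(cc$level_db_spl %in% c(80, 90))
    expect_true(cc$duration_ms >= 30 && cc$duration_ms <= 60)
  }
})

test_that("the V-shaped rate model drives tones and calls as specified", {
  nn <- neuron_spec(cf_khz = 25, threshold_db = 30, spont_rate_hz = 10)
  # tone at CF, 30 dB above threshold: driven above spont
  rp <- rate_function(nn, list(kind = "tone", freq_khz = 25,
                               level_db_spl = 60, duration_ms = 50))
  expect_gt(max(rp$rate_hz), nn$spont_rate_hz + 50)
  # 3 octaves off CF at 15 dB: purely spontaneous
  rp2 <- rate_function(nn, list(kind = "tone", freq_khz = 200,
                                level_db_spl = 15, duration_ms = 50))
  expect_equal(rp2$rate_hz, rep(nn$spont_rate_hz, length(rp2$rate_hz)))
  # onset class: back to spont within 10 ms of response onset
  on <- neuron_spec(cf_khz = 25, threshold_db = 30, psth_class = "onset",
                    spont_rate_hz = 10, fsl_ms = 3)
  rp3 <- rate_function(on, list(kind = "tone", freq_khz = 25,
                                level_db_spl = 60, duration_ms = 50))
  late <- rp3$t_ms > on$fsl_ms + 10 & rp3$t_ms < 50
  expect_true(all(rp3$rate_hz[late] < on$spont_rate_hz + 0.05 *
                    max(rp3$rate_hz)))
  # call predicate: high-CF neuron driven, low-CF not
  call <- call_spec("c", 40, 70, 80, 80)
  expect_true(call_drives(neuron_spec(cf_khz = 75, threshold_db = 40),
                          call))
  expect_false(call_drives(neuron_spec(cf_khz = 20, threshold_db = 30),
                           call))
  # and the rate profile agrees with the predicate
  rp4 <- rate_function(neuron_spec(cf_khz = 75, threshold_db = 40), call)
  expect_gt(max(rp4$rate_hz), 50)
  rp5 <- rate_function(neuron_spec(cf_khz = 20, threshold_db = 30), call)
  expect_equal(max(rp5$rate_hz), 10)
})

test_that("gamma-renewal spike trains have the designed count and CV", {
  # constant 100 Hz for 100 s, Poisson case
  st <- simulate_spike_train(rep(100, 2e5), 0.5, gamma_order = 1, seed = 1)
  expect_lt(abs(length(st) - 10000), 3 * 100)
  isi <- diff(st)
  expect_equal(stats::sd(isi) / mean(isi), 1, tolerance = 0.05)
  # order 4: CV 1/2
  st4 <- simulate_spike_train(rep(100, 2e5), 0.5, gamma_order = 4,
                              seed = 2)
  isi4 <- diff(st4)
  expect_equal(stats::sd(isi4) / mean(isi4), 0.5, tolerance = 0.05)
  expect_identical(simulate_spike_train(rep(0, 100), 1, seed = 3),
                   numeric(0))
  expect_error(simulate_spike_train(c(5, -1), 1), "parameter error")
  # reproducibility under a fixed seed
  expect_identical(simulate_spike_train(rep(50, 1000), 1, 2, 1, seed = 9),
                   simulate_spike_train(rep(50, 1000), 1, 2, 1, seed = 9))
})

test_that("rendered traces are the template-convolved trains plus noise", {
  fs <- 24414
  tpl <- spike_template(fs)
  u <- unit_spikes("u", "a", "AN", 10, "simulated")
  tr <- render_trace(list(u), list(list(waveform = tpl, channel = 1,
                                        gain = 2)),
                     noise_sd = 0, sample_rate_hz = fs, duration_ms = 30)
  k <- round(10 / 1000 * fs) + 1
  expect_equal(tr$samples[1, k:(k + length(tpl) - 1)], 2 * tpl)
  expect_true(all(tr$samples[1, seq_len(k - 1)] == 0))
  # doubling the gain doubles the waveform exactly
  tr2 <- render_trace(list(u), list(list(waveform = tpl, channel = 1,
                                         gain = 4)),
                      noise_sd = 0, sample_rate_hz = fs, duration_ms = 30)
  expect_identical(tr2$samples, 2 * tr$samples)
  # no units: pure Gaussian noise at the stated SD
  trn <- render_trace(list(), list(), noise_sd = 5e-6,
                      sample_rate_hz = fs, duration_ms = 2000, seed = 4)
  expect_equal(stats::sd(trn$samples), 5e-6, tolerance = 0.05)
  expect_error(render_trace(list(u), list(list(waveform = rep(0, 1e5),
                                               channel = 1, gain = 1)),
                            0, fs, duration_ms = 30), "parameter error")
})

test_that("synthetic ABR sweeps carry the designed wave amplitudes", {
  sp0 <- abr_spec(noise_sd_uv = 0, n_sweeps = 100)
  sw <- simulate_abr(sp0, 64)
  avg <- colMeans(sw$sweeps)
  t <- sw$t_ms
  # local max nearest 5.7 ms, peak minus antecedent trough = map value
  band <- which(t >= 4.5 & t <= 7)
  pk <- band[which.max(avg[band])]
  expect_lt(abs(t[pk] - 5.7), 0.05)
  amp <- avg[pk] - min(avg[(pk - 20):pk])
  expect_equal(amp, sp0$waveV_amp_vs_freq[["64"]], tolerance = 0.02)
  # all-zero amplitude maps: the average is statistically zero
  spz <- abr_spec(waveI_amp_vs_freq = c("8" = 0),
                  waveV_amp_vs_freq = c("8" = 0),
                  mid_wave_amps_uv = c(0, 0, 0), noise_sd_uv = 2)
  swz <- simulate_abr(spz, 8, seed = 5)
  se <- 2 / sqrt(500)
  expect_lt(abs(mean(swz$sweeps)), 3 * se)
  # averaging n sweeps shrinks noise SD by sqrt(n)
  resid <- colMeans(swz$sweeps)
  expect_equal(stats::sd(resid), 2 / sqrt(500), tolerance = 0.1)
  expect_error(simulate_abr(sp0, 12), "parameter error")
})

# CF distribution of a station profile (drawn, responses not needed)
station_cf_draw <- function(n, station, seed) {
  spec <- if (station == "AN")
    population_spec(n, "AN", cf_log_mean_khz = 25, cf_log_sd_oct = 0.45,
                    fraction_high_f = 7 / 94, n_animals = 5, seed = seed)
  else
    population_spec(n, "ICC", cf_log_mean_khz = 30, cf_log_sd_oct = 0.6,
                    fraction_high_f = 409 / 696, n_animals = 5,
                    seed = seed)
  sc <- call_schedule(n_trials = 1)
  simulate_population(spec, sc)$truth$cf_khz
}

test_that("simulated populations honor their ground-truth construction", {
  cs <- call_schedule(n_trials = 2)
  # no high-frequency units: nobody responds to calls
  p0 <- simulate_population(
    population_spec(20, "AN", fraction_high_f = 0, n_animals = 4,
                    seed = 31), cs)
  expect_false(any(p0$truth$responds_to_calls))
  # ICC CF distribution sits above the AN one
  cf_an <- station_cf_draw(200, "AN", 41)
  cf_icc <- station_cf_draw(200, "ICC", 42)
  expect_gt(stats::median(cf_icc), stats::median(cf_an))
  # fixed seed: byte-identical ground truth on rerun
  p1 <- simulate_population(
    population_spec(10, "AN", n_animals = 2, seed = 7), cs)
  p2 <- simulate_population(
    population_spec(10, "AN", n_animals = 2, seed = 7), cs)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$units$AN_u003$spike_times_ms,
                   p2$units$AN_u003$spike_times_ms)
  # the responds_to_calls flag re-derives from the response-area predicate
  for (i in seq_len(nrow(p1$truth))) {
    nd <- sum(vapply(default_calls(), function(cc)
      call_drives(p1$neurons[[i]], cc), logical(1)))
    expect_identical(p1$truth$responds_to_calls[i], nd >= 3)
  }
})
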