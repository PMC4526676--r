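test_that("PSTHs are trial-averaged rates with exact count conservation", {
  ev <- tone_burst_schedule(10)
  # one spike at +5 ms on every trial: single 1000 spikes/s bin
  u <- unit_spikes("u", "a", "AN", ev$onset_ms + 5, "simulated")
  p <- compute_psth(u, ev, window_ms = 50, bin_width_ms = 1)
  expect_equal(p$rate_hz[6], 1000)
  expect_equal(sum(p$rate_hz > 0), 1)
  # conservation: sum(rate * width * trials) = total spikes in window
  expect_equal(sum(p$rate_hz) * 0.001 * p$n_trials, 10)
  # silent unit: all-zero PSTH
  u0 <- unit_spikes("u0", "a", "AN", 1e6, "simulated")
  expect_true(all(compute_psth(u0, ev, 50, 1)$rate_hz == 0))
  expect_error(compute_psth(u, ev[0, ], 50, 1), "insufficient data")
  expect_error(compute_psth(u, ev, 50, 0.7), "parameter error")
  # homogeneous Poisson at 50 Hz, 500 trials: bins fluctuate like Poisson
  # counts around 50 (chi-square over bins at a 1e-4 familywise level,
  # no bin beyond 6 SE, grand mean within 4 SE)
  ev5 <- tone_burst_schedule(500)
  up <- constant_rate_unit(50, max(ev5$onset_ms) + 200, seed = 51)
  pp <- compute_psth(up, ev5, window_ms = 100, bin_width_ms = 1)
  cnt <- pp$rate_hz * 0.5  # counts per bin, expectation 25
  expect_lt(sum((cnt - 25)^2 / 25), stats::qchisq(1 - 1e-4, 100))
  se <- sqrt(50 / (500 * 0.001))  # Poisson rate SE per bin
  expect_true(all(abs(pp$rate_hz - 50) < 6 * se))
  expect_lt(abs(mean(pp$rate_hz) - 50), 4 * se / sqrt(100))
  # conservation on the stochastic case too
  rel <- unlist(lapply(ev5$onset_ms, function(on) {
    s <- up$spike_times_ms
    s[s >= on & s < on + 100]
  }))
  expect_equal(sum(pp$rate_hz) * 0.001 * 500, length(rel))
})

test_that("ISI CV pools within-trial intervals with the n-1 convention", {
  ev <- tone_burst_schedule(1, duration_ms = 100)
  # perfectly periodic: CV 0
  u <- unit_spikes("u", "a", "AN", ev$onset_ms + seq(5, 95, by = 10),
                   "simulated")
  expect_equal(isi_cv(u, ev, 100), 0)
  # ISIs {5, 15, 10} ms: sample SD 5 (n-1 denominator), mean 10, CV 0.5
  ev2 <- tone_burst_schedule(1, duration_ms = 100)
  u2 <- unit_spikes("u2", "a", "AN", ev2$onset_ms[1] + c(10, 15, 30, 40),
                    "simulated")
  expect_equal(isi_cv(u2, ev2, 100), 0.5, tolerance = 1e-12)
  # long exponential train: CV near 1
  ev3 <- tone_burst_schedule(1, duration_ms = 100)
  long <- constant_rate_unit(200, 60000, seed = 52)
  ev_long <- schedule(data.frame(onset_ms = 0, kind = "tone",
                                 freq_khz = 20, level_db_spl = 60,
                                 duration_ms = 50000,
                                 call_id = NA_character_))
  expect_equal(isi_cv(long, ev_long, 50000), 1, tolerance = 0.05)
  u3 <- unit_spikes("u3", "a", "AN", ev3$onset_ms + c(5, 10), "simulated")
  expect_error(isi_cv(u3, ev3, 100), "insufficient data")
})

test_that("first-spike latency mode uses 0.5 ms bins with earliest-bin ties", {
  ev <- tone_burst_schedule(12)
  u <- unit_spikes("u", "a", "AN", ev$onset_ms + 4.0, "simulated")
  expect_equal(first_spike_latency_mode(u, ev), 4.25)
  # counts 2 vs 1: mode in [3.0, 3.5)
  ev3 <- tone_burst_schedule(30)
  lat <- rep(c(3.1, 3.2, 8.0), 10)
  u3 <- unit_spikes("u3", "a", "AN", sort(ev3$onset_ms + lat), "simulated")
  expect_equal(first_spike_latency_mode(u3, ev3), 3.25)
  # bimodal tie resolves to the earlier bin
  lat_t <- rep(c(2.2, 6.2), 15)
  u4 <- unit_spikes("u4", "a", "AN", sort(ev3$onset_ms + lat_t),
                    "simulated")
  expect_equal(first_spike_latency_mode(u4, ev3), 2.25)
  expect_error(first_spike_latency_mode(u, ev[1:5, ]),
               "insufficient data")
})

test_that("PSTH classification separates the canonical response shapes", {
  mk <- function(rate) structure(list(bin_edges_ms = 0:50, rate_hz = rate,
                                      n_trials = 500, bin_width_ms = 1),
                                 class = "psth")
  tt <- 0:49
  # exponential decay to a plateau: primary
  expect_equal(classify_psth(mk(120 + 180 * exp(-tt / 8))), "primary")
  # brief transient, then silence: onset
  expect_equal(classify_psth(mk(c(300, 150, 20, rep(0, 47)))), "onset")
  # five evenly spaced peaks at a 5 ms period: chopper
  chop <- 150 * (1 + 0.9 * cos(2 * pi * tt / 5)) *
    (0.5 + 0.5 * exp(-tt / 15))
  expect_equal(classify_psth(mk(chop)), "chopper")
  # primary with a deep notch a few ms after the peak: pri-N
  prin <- (120 + 180 * exp(-tt / 8)) * (1 - 0.9 * exp(-((tt - 4) / 1)^2))
  expect_equal(classify_psth(mk(prin)), "pri-N")
  expect_equal(classify_psth(mk(rep(0, 50))), "unclassified")
})

test_that("the fiber gate applies inclusive CV/FSL bounds and the class rule", {
  m <- function(cv, fsl, cls) list(unit_id = "u", cv_isi = cv,
                                   fsl_mode_ms = fsl, psth_class = cls)
  expect_true(an_fiber_gate(m(0.5, 5.0, "primary")))
  expect_false(an_fiber_gate(m(0.49, 3, "primary")))
  expect_false(an_fiber_gate(m(0.9, 5.1, "primary")))
  expect_false(an_fiber_gate(m(0.9, 3, "chopper")))
  expect_false(quiet(an_fiber_gate(m(NA, 3, "primary"))))
})

test_that("the gate separates fiber-like from non-fiber units in simulation", {
  tab <- gate_validation_table(n = 40, n_reps = 200, seed = 42)
  sens <- sum(tab$gate & tab$truth) / sum(tab$truth)
  spec <- sum(!tab$gate & !tab$truth) / sum(!tab$truth)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})
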