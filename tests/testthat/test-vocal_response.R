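test_that("driven and spontaneous windows count spikes exactly", {
  ev <- single_call_schedule(20)
  # silent unit: all zeros
  u0 <- unit_spikes("u0", "a", "AN", 1e9, "simulated")
  cw0 <- count_windows(u0, ev)
  expect_true(all(cw0$driven_counts == 0) && all(cw0$spont_counts == 0))
  # generator-driven unit: 100 Hz in the driven window, 5 Hz elsewhere
  ev256 <- single_call_schedule(256)
  span <- max(ev256$onset_ms) + 200
  rate <- rep(5, span * 2)
  for (on in ev256$onset_ms) {
    bins <- (round((on + 5) / 0.5) + 1):(round((on + 45) / 0.5))
    rate[bins] <- 100
  }
  st <- simulate_spike_train(rate, 0.5, seed = 71)
  u <- unit_spikes("u", "a", "AN", st, "simulated")
  cw <- count_windows(u, ev256)
  expect_equal(mean(cw$driven_counts), 4,
               tolerance = 3 * sqrt(4 / 256) / 4)
  expect_lt(abs(mean(cw$spont_counts) - 0.2), 3 * sqrt(0.2 / 256))
  # bookkeeping: the counts are exactly the spikes in the windows
  total <- sum(vapply(seq_len(nrow(ev256)), function(i) {
    lo <- ev256$onset_ms[i] + 5
    sum(st >= lo & st < lo + 40)
  }, numeric(1)))
  expect_equal(sum(cw$driven_counts), total)
})

test_that("the rank-sum test is exact for small samples and calibrated under the null", {
  # fully separated n=3 vs n=3: exact two-sided p = 0.100
  expect_equal(rank_sum_test(c(5, 6, 7), c(0, 1, 2)), 0.1,
               tolerance = 1e-12)
  # identical samples: p = 1
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2)), 1)
  # agreement with the reference implementation on clean small samples
  set.seed(72)
  for (r in 1:20) {
    x <- sample(seq(1, 200), 8)
    y <- sample(seq(201, 400), 6) / 2.3
    expect_equal(rank_sum_test(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # type-I error near nominal for tied count data
  rej <- with_seed(73, {
    mean(vapply(seq_len(2000), function(r) {
      x <- stats::rpois(256, 2)
      y <- stats::rpois(256, 2)
      rank_sum_test(x, y) < 0.05
    }, logical(1)))
  })
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("the response SNR is the PSTH variance over trial deviation variance", {
  expect_equal(response_snr(rbind(c(0, 2), c(2, 0))), 0)
  expect_equal(response_snr(rbind(c(0, 4), c(2, 2))), 1)
  # additive model: recovered ratio near sigma_s^2 / sigma_n^2
  set.seed(74)
  n_trials <- 500
  signal <- stats::rnorm(30, sd = 2)
  trials <- matrix(rep(signal, each = n_trials), n_trials, 30) +
    matrix(stats::rnorm(n_trials * 30, sd = 1.5), n_trials, 30)
  sig_var <- mean((signal - mean(signal))^2)
  expect_equal(response_snr(trials), sig_var / 1.5^2, tolerance = 0.1)
  # invariances of the variance ratio
  base <- response_snr(trials)
  expect_equal(response_snr(trials + 7), base, tolerance = 1e-12)
  expect_equal(response_snr(trials * 3), base, tolerance = 1e-12)
  # degenerate cases
  expect_identical(response_snr(rbind(c(1, 5), c(1, 5))), Inf)
  expect_identical(response_snr(rbind(c(3, 3), c(3, 3))), 0)
  expect_error(response_snr(matrix(1, 1, 5)), "insufficient data")
})

test_that("responsiveness requires 3 of 9 significant calls", {
  mk <- function(p, snr = 0.5)
    structure(data.frame(unit_id = "u", call_id = paste0("c", 1:9),
                         n_trials = 30, p_value = p, snr = snr,
                         mean_driven = 1, mean_spont = 1),
              class = c("call_response_set", "data.frame"))
  r3 <- summarize_responsiveness(mk(c(0.01, 0.02, 0.04, rep(0.6, 6))))
  expect_true(r3$responsive)
  expect_equal(r3$n_significant_calls, 3)
  r2 <- summarize_responsiveness(mk(c(0.01, 0.02, rep(0.6, 7))))
  expect_false(r2$responsive)
  rn <- summarize_responsiveness(mk(rep(1, 9), snr = 0))
  expect_false(rn$responsive)
  expect_equal(rn$mean_snr, 0)
  # p = 0.05 exactly is not significant (strict inequality)
  expect_false(summarize_responsiveness(
    mk(c(0.05, 0.05, 0.05, rep(0.6, 6))))$responsive)
  # infinite SNRs are excluded from the mean
  ri <- quiet(summarize_responsiveness(mk(rep(1, 9),
                                          snr = c(Inf, rep(0.4, 8)))))
  expect_equal(ri$mean_snr, 0.4)
  # fewer than 9 calls: scaled criterion with a warning
  short <- mk(c(0.01, rep(0.6, 8)))[1:3, ]
  expect_warning(rs <- summarize_responsiveness(short), "fewer than 9")
  expect_true(rs$responsive)  # 1 of 3 meets ceiling(3/3) = 1
})

test_that("driven units separate from non-driven units end to end", {
  cs <- call_schedule(n_trials = 30)
  hi <- simulate_unit_response(neuron_spec(cf_khz = 72, threshold_db = 35),
                               cs, seed = 75)
  lo <- simulate_unit_response(neuron_spec(cf_khz = 20, threshold_db = 30),
                               cs, seed = 76)
  rh <- summarize_responsiveness(test_call_responses(hi, cs))
  rl <- summarize_responsiveness(test_call_responses(lo, cs))
  expect_true(rh$responsive)
  expect_false(rl$responsive)
  expect_gt(rh$mean_snr, rl$mean_snr)
})
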