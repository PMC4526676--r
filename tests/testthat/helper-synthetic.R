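# Shared fixture builders; everything is generated in code at test time.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# n repeated tone presentations at one frequency/level
tone_burst_schedule <- function(n, freq_khz = 20, level_db = 60,
                                duration_ms = 50, period_ms = 150,
                                t0 = 200) {
  schedule(data.frame(onset_ms = t0 + (seq_len(n) - 1) * period_ms,
                      kind = "tone", freq_khz = freq_khz,
                      level_db_spl = level_db, duration_ms = duration_ms,
                      call_id = NA_character_))
}

# n repeated presentations of a single synthetic call
single_call_schedule <- function(n, duration_ms = 40, level_db = 80,
                                 period_ms = 150, t0 = 200) {
  schedule(data.frame(onset_ms = t0 + (seq_len(n) - 1) * period_ms,
                      kind = "call", freq_khz = NA_real_,
                      level_db_spl = level_db, duration_ms = duration_ms,
                      call_id = "c"))
}

# a unit firing at a constant rate over the whole session span
constant_rate_unit <- function(rate_hz, span_ms, seed, gamma_order = 1,
                               refractory_ms = 0) {
  st <- simulate_spike_train(rep(rate_hz, span_ms * 2), 0.5,
                             gamma_order = gamma_order,
                             refractory_ms = refractory_ms, seed = seed)
  unit_spikes("u_const", "a1", "AN", st, source = "simulated")
}

# two distinct units rendered into one extracellular trace, with truth
two_unit_recording <- function(rate_hz = 8, span_ms = 80000,
                               gains = c(120e-6, 100e-6),
                               noise_sd = 10e-6, fs = 24414,
                               seeds = c(1, 2, 3)) {
  tpl1 <- spike_template(fs, pos_frac = 0.45, neg_width_ms = 0.10)
  tpl2 <- -spike_template(fs, pos_frac = 0.25, neg_width_ms = 0.16)
  st1 <- simulate_spike_train(rep(rate_hz, span_ms), 1, gamma_order = 2,
                              refractory_ms = 2, seed = seeds[1])
  st2 <- simulate_spike_train(rep(rate_hz, span_ms), 1, gamma_order = 2,
                              refractory_ms = 2, seed = seeds[2])
  units <- list(unit_spikes("u1", "a1", "AN", st1, "simulated"),
                unit_spikes("u2", "a1", "AN", st2, "simulated"))
  tr <- render_trace(units,
                     list(list(waveform = tpl1, channel = 1,
                               gain = gains[1]),
                          list(waveform = tpl2, channel = 1,
                               gain = gains[2])),
                     noise_sd = noise_sd, sample_rate_hz = fs,
                     seed = seeds[3])
  list(trace = tr, st1 = st1, st2 = st2, fs = fs)
}

# FFT peak frequency (kHz) of a Hann-windowed segment of a waveform
segment_peak_freq_khz <- function(x, fs, t_lo_ms, t_hi_ms, nfft = 2^15) {
  i0 <- max(1, round(t_lo_ms / 1000 * fs))
  i1 <- min(length(x), round(t_hi_ms / 1000 * fs))
  seg <- x[i0:i1]
  n <- length(seg)
  seg <- seg * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  sp <- abs(fft(c(seg, rep(0, nfft - n))))[seq_len(nfft / 2)]
  (which.max(sp) - 1) * fs / nfft / 1000
}

# mixed-class population responding to its CF tone: metrics vs truth
gate_validation_table <- function(n = 40, n_reps = 200, seed = 42) {
  with_seed(seed, {
    classes <- sample(c("primary", "chopper", "pri-N", "onset"), n,
                      replace = TRUE)
    out <- data.frame(cls = classes, truth = NA, gate = NA)
    for (i in seq_len(n)) {
      cl <- classes[i]
      ord <- switch(cl, primary = sample(1:2, 1),
                    `pri-N` = sample(1:2, 1),
                    chopper = sample(9:16, 1), onset = 2)
      fsl <- if (cl %in% c("primary", "pri-N")) stats::runif(1, 2.5, 4.2)
             else stats::runif(1, 4.5, 8)
      nn <- neuron_spec(cf_khz = 20, threshold_db = 30, psth_class = cl,
                        gamma_order = ord, fsl_ms = fsl,
                        max_rate_hz = 250, spont_rate_hz = 10)
      sc <- tone_burst_schedule(n_reps)
      u <- simulate_unit_response(nn, sc, seed = 1000 + i)
      m <- quiet(unit_metrics(u, sc, window_ms = 50))
      out$truth[i] <- (cl == "primary") && (1 / sqrt(ord) >= 0.5) &&
        (fsl <= 5)
      out$gate[i] <- m$is_an_fiber
    }
    out
  })
}
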