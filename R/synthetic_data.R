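#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulations are reproducible without clobbering the
#' session's stream. With `seed = NULL` the expression runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Full-scale amplitude reference: 94 dB SPL == amplitude 1.0
.db_to_amp <- function(level_db_spl) 10^((level_db_spl - 94) / 20)

#' Synthesize a tone pip
#'
#' A gated sinusoid with raised-cosine on/off ramps, the probe stimulus used
#' to map frequency response areas. Amplitude follows a fixed full-scale
#' reference of 94 dB SPL == 1.0.
#'
#' @param freq_khz tone frequency in kHz.
#' @param level_db_spl presentation level in dB SPL.
#' @param duration_ms total duration (default 50 ms).
#' @param ramp_ms rise/fall time of the raised-cosine gates (default 2 ms).
#' @param sample_rate_hz audio sampling rate; must exceed 2.2x the tone
#'   frequency.
#' @return numeric waveform vector.
#' @export
make_tone_pip <- function(freq_khz, level_db_spl, duration_ms = 50,
                          ramp_ms = 2, sample_rate_hz = 192000) {
  if (sample_rate_hz < 2.2 * freq_khz * 1000)
    stop("parameter error: sample rate ", sample_rate_hz,
         " Hz too low for ", freq_khz, " kHz (need >= 2.2x)")
  if (2 * ramp_ms > duration_ms)
    stop("parameter error: ramps longer than the pip")
  n <- round(duration_ms / 1000 * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  x <- .db_to_amp(level_db_spl) * sin(2 * pi * freq_khz * 1000 * t)
  n_ramp <- round(ramp_ms / 1000 * sample_rate_hz)
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[n:(n - n_ramp + 1)] <- x[n:(n - n_ramp + 1)] * ramp
  }
  x
}

#' Specify a synthetic ultrasonic vocalization
#'
#' Mouse communication calls carry a single frequency component confined to
#' 60-90 kHz; the synthetic stand-in is a frequency sweep, linear in
#' log-frequency, with optional amplitude modulation.
#'
#' @param call_id label.
#' @param duration_ms duration in \[30, 60\] ms.
#' @param f_start_khz,f_end_khz sweep endpoints, both within \[60, 90\] kHz.
#' @param level_db_spl presentation level, 80 or 90 dB SPL.
#' @param am_depth amplitude-modulation depth in \[0, 1\].
#' @return object of class `call_spec`.
#' @export
call_spec <- function(call_id, duration_ms, f_start_khz, f_end_khz,
                      level_db_spl = 80, am_depth = 0) {
  if (duration_ms < 30 || duration_ms > 60)
    stop("parameter error: call duration must be in [30, 60] ms")
  if (f_start_khz < 60 || f_start_khz > 90 ||
      f_end_khz < 60 || f_end_khz > 90)
    stop("parameter error: call frequencies must stay within [60, 90] kHz")
  if (!level_db_spl %in% c(80, 90))
    stop("parameter error: call level must be 80 or 90 dB SPL")
  if (am_depth < 0 || am_depth > 1)
    stop("parameter error: am_depth must be in [0, 1]")
  structure(list(call_id = as.character(call_id),
                 duration_ms = duration_ms, f_start_khz = f_start_khz,
                 f_end_khz = f_end_khz, level_db_spl = level_db_spl,
                 am_depth = am_depth),
            class = "call_spec")
}

#' The default battery of nine synthetic vocalizations
#'
#' Nine single-component calls spanning 60-90 kHz with durations of
#' 30-60 ms, presented at 80 or 90 dB SPL — upward and downward sweeps,
#' near-constant whistles, and amplitude-modulated variants.
#'
#' @return named list of nine `call_spec` objects.
#' @export
default_calls <- function() {
  specs <- list(
    call_spec("c1", 40, 62, 80, 80, 0.0),
    call_spec("c2", 55, 85, 65, 80, 0.0),
    call_spec("c3", 30, 70, 70, 80, 0.0),
    call_spec("c4", 45, 60, 90, 90, 0.0),
    call_spec("c5", 60, 75, 62, 90, 0.2),
    call_spec("c6", 35, 68, 82, 80, 0.3),
    call_spec("c7", 50, 88, 72, 90, 0.0),
    call_spec("c8", 42, 64, 76, 80, 0.1),
    call_spec("c9", 38, 80, 88, 90, 0.0))
  names(specs) <- vapply(specs, `[[`, "", "call_id")
  specs
}

#' Synthesize a vocalization waveform from its specification
#'
#' @param spec a `call_spec`.
#' @param sample_rate_hz audio sampling rate (>= 2.2x the highest sweep
#'   frequency).
#' @param ramp_ms raised-cosine gate duration at both ends.
#' @return numeric waveform vector.
#' @export
make_call <- function(spec, sample_rate_hz = 192000, ramp_ms = 2) {
  stopifnot(inherits(spec, "call_spec"))
  f_hi <- max(spec$f_start_khz, spec$f_end_khz)
  if (sample_rate_hz < 2.2 * f_hi * 1000)
    stop("parameter error: sample rate too low for ", f_hi, " kHz")
  n <- round(spec$duration_ms / 1000 * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  dur_s <- spec$duration_ms / 1000
  # instantaneous frequency, log-linear between the endpoints
  f_inst <- spec$f_start_khz * 1000 *
    (spec$f_end_khz / spec$f_start_khz)^(t / dur_s)
  phase <- 2 * pi * cumsum(f_inst) / sample_rate_hz
  x <- .db_to_amp(spec$level_db_spl) * sin(phase)
  if (spec$am_depth > 0)
    x <- x * (1 - spec$am_depth / 2 * (1 - cos(2 * pi * 100 * t)))
  n_ramp <- round(ramp_ms / 1000 * sample_rate_hz)
  if (n_ramp > 0 && 2 * n_ramp < n) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
    x[n:(n - n_ramp + 1)] <- x[n:(n - n_ramp + 1)] * ramp
  }
  x
}

#' Frequency trajectory of a synthetic call
#'
#' @param spec a `call_spec`.
#' @param t_ms times since call onset, ms.
#' @return instantaneous frequency in kHz at each time.
#' @export
call_freq_khz <- function(spec, t_ms) {
  frac <- pmin(pmax(t_ms / spec$duration_ms, 0), 1)
  spec$f_start_khz * (spec$f_end_khz / spec$f_start_khz)^frac
}

#' Specify a model auditory neuron
#'
#' The response model is a V-shaped excitatory frequency response area in
#' log-frequency: at level L dB SPL the neuron responds to frequencies
#' within `w(L) = min(q_sharpness * (L - threshold_db) / 10, w_max_oct)`
#' octaves of its characteristic frequency (CF). Spiking is a time-rescaled
#' gamma renewal process whose order sets the interspike-interval CV
#' (asymptotically `1/sqrt(gamma_order)`), and the peristimulus time course
#' follows the named PSTH class.
#'
#' @param cf_khz characteristic frequency, kHz.
#' @param threshold_db level at CF evoking a criterion rate increase.
#' @param q_sharpness octaves of half-width gained per 10 dB above
#'   threshold (smaller = sharper tuning).
#' @param w_max_oct cap on the half-width: the response area never extends
#'   beyond this many octaves from CF at any level.
#' @param max_rate_hz peak driven rate at CF at high level.
#' @param spont_rate_hz spontaneous rate.
#' @param psth_class `"primary"`, `"chopper"`, `"pri-N"` or `"onset"`.
#' @param adaptation_tau_ms exponential adaptation time constant of the
#'   sustained response.
#' @param gamma_order renewal-process shape; ISI CV = 1/sqrt(order).
#' @param refractory_ms absolute refractory dead time.
#' @param fsl_ms mean first-spike latency.
#' @param responds_to_calls optional ground-truth flag; if `NA` it is
#'   derived from the response-area predicate when a population is built.
#' @return object of class `neuron_spec`.
#' @export
neuron_spec <- function(cf_khz, threshold_db = 30, q_sharpness = 0.12,
                        w_max_oct = 0.5, max_rate_hz = 250,
                        spont_rate_hz = 10, psth_class = "primary",
                        adaptation_tau_ms = 10, gamma_order = 1,
                        refractory_ms = 0.75, fsl_ms = 3.5,
                        responds_to_calls = NA) {
  psth_class <- match.arg(psth_class, c("primary", "chopper", "pri-N",
                                        "onset"))
  stopifnot(cf_khz > 0, q_sharpness > 0, w_max_oct > 0, max_rate_hz > 0,
            spont_rate_hz >= 0, adaptation_tau_ms > 0, gamma_order > 0,
            refractory_ms >= 0, fsl_ms > 0)
  if (spont_rate_hz > max_rate_hz)
    stop("parameter error: spont_rate_hz must not exceed max_rate_hz")
  structure(list(cf_khz = cf_khz, threshold_db = threshold_db,
                 q_sharpness = q_sharpness, w_max_oct = w_max_oct,
                 max_rate_hz = max_rate_hz, spont_rate_hz = spont_rate_hz,
                 psth_class = psth_class,
                 adaptation_tau_ms = adaptation_tau_ms,
                 gamma_order = gamma_order, refractory_ms = refractory_ms,
                 fsl_ms = fsl_ms, responds_to_calls = responds_to_calls),
            class = "neuron_spec")
}

# Driven-rate scale factor in [0, 1] for a tone at (freq, level).
.tuning_strength <- function(neuron, freq_khz, level_db_spl) {
  d <- abs(log2(freq_khz / neuron$cf_khz))
  excess_db <- level_db_spl - neuron$threshold_db
  w <- pmin(neuron$q_sharpness * pmax(excess_db, 0) / 10, neuron$w_max_oct)
  strength <- ifelse(w > 0 & d < w,
                     (1 - d / w) * pmin(1, excess_db / 30), 0)
  pmax(strength, 0)
}

# PSTH-class temporal envelope; t_ms since response onset, dur_ms = stimulus
# duration. Zero outside (0, dur]. Primary-like envelopes carry a strong
# onset transient (peak ~2.5x the adapted excess, i.e. several hundred Hz
# at typical max rates): without it the renewal process waits 1-2 ms for
# its first spike and the first-spike-latency mode drifts off the
# generator's nominal value.
.class_envelope <- function(neuron, t_ms, dur_ms) {
  inside <- t_ms >= 0 & t_ms <= dur_ms
  t <- pmax(t_ms, 0)
  prim <- 0.35 + 0.65 * exp(-t / neuron$adaptation_tau_ms) +
    1.5 * exp(-t / 1.5)
  env <- switch(neuron$psth_class,
    primary = prim,
    `pri-N` = prim * (1 - 0.9 * exp(-((t - 4) / 1)^2)),
    chopper = 0.55 * (1 + 0.9 * cos(2 * pi * t / 4)) *
      (0.6 + 0.4 * exp(-t / neuron$adaptation_tau_ms)),
    onset = exp(-t / 1.5))
  env * inside
}

#' Firing-rate profile of a model neuron for one stimulus
#'
#' Evaluates the inhomogeneous rate (Hz) on a regular time grid around a
#' stimulus: spontaneous rate plus, inside the neuron's V-shaped response
#' area, a class-specific driven excess. For calls the excess follows the
#' instantaneous sweep frequency through the response area. The response is
#' delayed by the neuron's first-spike latency.
#'
#' @param neuron a `neuron_spec`.
#' @param stim either a one-row tone description
#'   (`list(kind = "tone", freq_khz =, level_db_spl =, duration_ms =)`) or a
#'   `call_spec`.
#' @param span_ms time span after stimulus onset to evaluate, ms.
#' @param bin_ms grid resolution, ms.
#' @return list with `t_ms` (grid, relative to stimulus onset), `rate_hz`,
#'   and `bin_ms`.
#' @export
rate_function <- function(neuron, stim, span_ms = 150, bin_ms = 0.5) {
  t <- seq(0, span_ms - bin_ms, by = bin_ms) + bin_ms / 2
  lat <- neuron$fsl_ms - 0.5
  if (inherits(stim, "call_spec")) {
    dur <- stim$duration_ms
    tt <- t - lat
    f_inst <- call_freq_khz(stim, tt)
    s <- .tuning_strength(neuron, f_inst, stim$level_db_spl)
    env <- .class_envelope(neuron, tt, dur)
    rate <- neuron$spont_rate_hz + neuron$max_rate_hz * s * env
  } else {
    dur <- stim$duration_ms
    s <- .tuning_strength(neuron, stim$freq_khz, stim$level_db_spl)
    env <- .class_envelope(neuron, t - lat, dur)
    rate <- neuron$spont_rate_hz + neuron$max_rate_hz * s * env
  }
  list(t_ms = t, rate_hz = rate, bin_ms = bin_ms)
}

#' Simulate a spike train from an inhomogeneous rate profile
#'
#' Time-rescaled gamma renewal process: interspike intervals are gamma with
#' shape `gamma_order` and unit mean in rescaled (integrated-rate) time, so
#' a long stationary train has ISI CV `1/sqrt(gamma_order)`. An absolute
#' refractory period is enforced as a hard dead time (later spikes inside
#' it are dropped).
#'
#' @param rate_hz non-negative rate per bin (Hz).
#' @param bin_ms bin width of the rate grid, ms.
#' @param gamma_order renewal shape parameter (1 = Poisson).
#' @param refractory_ms dead time, ms.
#' @param seed optional RNG seed.
#' @param t0_ms time of the start of the first bin, ms.
#' @return numeric vector of spike times, ms, strictly increasing.
#' @export
simulate_spike_train <- function(rate_hz, bin_ms, gamma_order = 1,
                                 refractory_ms = 0, seed = NULL,
                                 t0_ms = 0) {
  if (any(rate_hz < 0)) stop("parameter error: negative rates")
  with_seed(seed, {
    lam_total <- sum(rate_hz) * bin_ms / 1000
    if (lam_total <= 0) return(numeric(0))
    # cumulative expected count at bin edges
    cum <- c(0, cumsum(rate_hz) * bin_ms / 1000)
    edges <- t0_ms + seq(0, length(rate_hz)) * bin_ms
    n_draw <- ceiling(lam_total + 4 * sqrt(lam_total / gamma_order) + 10)
    s <- cumsum(stats::rgamma(n_draw, shape = gamma_order,
                              rate = gamma_order))
    while (s[length(s)] < lam_total) {
      extra <- cumsum(stats::rgamma(n_draw, shape = gamma_order,
                                    rate = gamma_order))
      s <- c(s, s[length(s)] + extra)
    }
    s <- s[s < lam_total]
    if (!length(s)) return(numeric(0))
    times <- stats::approx(cum, edges, xout = s, ties = "ordered")$y
    if (refractory_ms > 0 && length(times) > 1) {
      keep <- logical(length(times))
      keep[1] <- TRUE
      last <- times[1]
      for (i in 2:length(times)) {
        if (times[i] - last >= refractory_ms) {
          keep[i] <- TRUE
          last <- times[i]
        }
      }
      times <- times[keep]
    }
    unique(times)
  })
}

#' A biphasic extracellular spike template
#'
#' Difference of two Gaussian lobes (sharp negative deflection followed by a
#' slower positive rebound), about 1 ms long, normalized to unit peak
#' magnitude.
#'
#' @param sample_rate_hz trace sampling rate.
#' @param width_ms total template duration.
#' @param pos_frac amplitude of the positive rebound relative to the
#'   negative peak.
#' @param neg_width_ms width (SD) of the negative lobe, ms.
#' @return numeric vector (unit peak magnitude, negative-going).
#' @export
spike_template <- function(sample_rate_hz, width_ms = 1.2, pos_frac = 0.45,
                           neg_width_ms = 0.1) {
  n <- round(width_ms / 1000 * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz * 1000
  w <- -exp(-((t - 0.35) / neg_width_ms)^2 / 2) +
    pos_frac * exp(-((t - 0.65) / (2.2 * neg_width_ms))^2 / 2)
  w / max(abs(w))
}

#' Render an extracellular voltage trace from spike trains
#'
#' The trace is the sum over units of the unit's spike train convolved with
#' its template (scaled by a per-unit gain and assigned to one channel),
#' plus white Gaussian noise.
#'
#' @param units list of `unit_spikes`.
#' @param templates list, one element per unit:
#'   `list(waveform =, channel =, gain =)`; `channel` indexes rows of the
#'   output.
#' @param noise_sd white-noise SD in volts.
#' @param sample_rate_hz output sampling rate.
#' @param duration_ms trace length; defaults to covering the last spike.
#' @param n_channels number of channels.
#' @param seed optional RNG seed for the noise.
#' @return a `trace`.
#' @export
render_trace <- function(units, templates, noise_sd, sample_rate_hz,
                         duration_ms = NULL, n_channels = 1, seed = NULL) {
  if (inherits(units, "unit_spikes")) units <- list(units)
  stopifnot(length(units) == length(templates))
  last_spike <- if (length(units))
    max(c(0, unlist(lapply(units, `[[`, "spike_times_ms")))) else 0
  if (is.null(duration_ms)) duration_ms <- last_spike + 5
  n <- round(duration_ms / 1000 * sample_rate_hz)
  x <- matrix(0, nrow = n_channels, ncol = n)
  for (i in seq_along(units)) {
    tpl <- templates[[i]]
    wf <- tpl$waveform * tpl$gain
    if (length(wf) > n)
      stop("parameter error: template longer than the trace")
    ch <- tpl$channel
    idx0 <- round(units[[i]]$spike_times_ms / 1000 * sample_rate_hz) + 1
    for (k in idx0) {
      if (k < 1 || k + length(wf) - 1 > n) next
      seg <- k:(k + length(wf) - 1)
      x[ch, seg] <- x[ch, seg] + wf
    }
  }
  if (noise_sd > 0)
    x <- x + with_seed(seed,
      matrix(stats::rnorm(length(x), sd = noise_sd), nrow = n_channels))
  trace(x, sample_rate_hz)
}

#' Specify a synthetic ABR preparation
#'
#' Each averaged auditory brainstem response is modeled as five biphasic
#' bumps (a trough immediately preceding each peak) at the wave I-V
#' latencies, scaled per stimulus frequency by the wave-I and wave-V
#' amplitude maps; waves II-IV have fixed mid-range amplitudes. The default
#' maps encode the characteristic pattern of the mouse: wave I (auditory
#' nerve) shrinks and wave V (midbrain) grows as tone frequency increases.
#'
#' @param wave_latencies_ms latencies of waves I-V, ms (strictly
#'   increasing, all within 0-10 ms; wave V near 5.7 ms).
#' @param waveI_amp_vs_freq,waveV_amp_vs_freq named numeric vectors mapping
#'   stimulus frequency (kHz, names) to peak-minus-antecedent-trough
#'   amplitude in microvolts.
#' @param mid_wave_amps_uv amplitudes of waves II-IV, microvolts.
#' @param noise_sd_uv per-sweep white noise SD, microvolts.
#' @param n_sweeps sweeps per stimulus.
#' @param sample_rate_hz ABR sampling rate (25 kHz).
#' @return object of class `abr_spec`.
#' @export
abr_spec <- function(wave_latencies_ms = c(1.2, 2.1, 3.0, 4.2, 5.7),
                     waveI_amp_vs_freq = c("8" = 1.2, "16" = 1.0,
                                           "32" = 0.7, "64" = 0.45,
                                           "80" = 0.3),
                     waveV_amp_vs_freq = c("8" = 0.3, "16" = 0.45,
                                           "32" = 0.7, "64" = 1.0,
                                           "80" = 1.2),
                     mid_wave_amps_uv = c(0.4, 0.3, 0.35),
                     noise_sd_uv = 2, n_sweeps = 500,
                     sample_rate_hz = 25000) {
  if (is.unsorted(wave_latencies_ms, strictly = TRUE))
    stop("parameter error: wave latencies must be strictly increasing")
  if (any(wave_latencies_ms <= 0) || any(wave_latencies_ms >= 10))
    stop("parameter error: wave latencies must lie within 0-10 ms")
  stopifnot(length(wave_latencies_ms) == 5, length(mid_wave_amps_uv) == 3,
            noise_sd_uv >= 0, n_sweeps >= 1)
  structure(list(wave_latencies_ms = wave_latencies_ms,
                 waveI_amp_vs_freq = waveI_amp_vs_freq,
                 waveV_amp_vs_freq = waveV_amp_vs_freq,
                 mid_wave_amps_uv = mid_wave_amps_uv,
                 noise_sd_uv = noise_sd_uv, n_sweeps = n_sweeps,
                 sample_rate_hz = sample_rate_hz),
            class = "abr_spec")
}

# Biphasic bump (trough ~0.5 ms before peak), normalized so that
# peak minus antecedent trough equals exactly 1.
.abr_bump <- function(t_ms, peak_ms, sigma_ms = 0.22, sep_ms = 0.5) {
  w <- exp(-((t_ms - peak_ms) / sigma_ms)^2 / 2) -
    exp(-((t_ms - (peak_ms - sep_ms)) / sigma_ms)^2 / 2)
  before <- t_ms <= peak_ms
  w / (max(w) - min(w[before]))
}

#' Simulate a set of ABR sweeps for one tone frequency
#'
#' @param spec an `abr_spec`.
#' @param stim_freq_khz stimulus frequency; must be a key of the amplitude
#'   maps.
#' @param seed optional RNG seed.
#' @param span_ms sweep length after stimulus onset.
#' @return list with `sweeps` (matrix, n_sweeps x n_samples, microvolts),
#'   `t_ms`, `sample_rate_hz`, `stim_freq_khz`.
#' @export
simulate_abr <- function(spec, stim_freq_khz, seed = NULL, span_ms = 10) {
  stopifnot(inherits(spec, "abr_spec"))
  key <- as.character(stim_freq_khz)
  if (!key %in% names(spec$waveI_amp_vs_freq) ||
      !key %in% names(spec$waveV_amp_vs_freq))
    stop("parameter error: no amplitude map entry for ", stim_freq_khz,
         " kHz")
  n <- round(span_ms / 1000 * spec$sample_rate_hz)
  t_ms <- (seq_len(n) - 1) / spec$sample_rate_hz * 1000
  amps <- c(spec$waveI_amp_vs_freq[[key]], spec$mid_wave_amps_uv,
            spec$waveV_amp_vs_freq[[key]])
  clean <- rep(0, n)
  for (w in 1:5)
    clean <- clean + amps[w] * .abr_bump(t_ms, spec$wave_latencies_ms[w])
  sweeps <- matrix(rep(clean, each = spec$n_sweeps),
                   nrow = spec$n_sweeps)
  if (spec$noise_sd_uv > 0)
    sweeps <- sweeps + with_seed(seed,
      matrix(stats::rnorm(length(sweeps), sd = spec$noise_sd_uv),
             nrow = spec$n_sweeps))
  list(sweeps = sweeps, t_ms = t_ms, sample_rate_hz = spec$sample_rate_hz,
       stim_freq_khz = stim_freq_khz)
}

#' Build the standard tone-pip schedule for frequency response areas
#'
#' Tone frequencies run from 2 to 90 kHz in fixed octave steps and levels
#' from 15 to 100 dB SPL in 5 dB steps; 50 ms pips presented once every
#' 150 ms. The grid is swept cell by cell, `n_reps` times.
#'
#' @param step_oct frequency step, 0.2 (default) or 0.15 octaves.
#' @param levels_db level grid, dB SPL.
#' @param n_reps repetitions of each frequency x level cell.
#' @param duration_ms,period_ms pip duration and onset-to-onset interval.
#' @param f_lo_khz,f_hi_khz frequency range.
#' @param t0_ms onset of the first pip.
#' @return a `schedule` of tone events.
#' @export
tone_schedule <- function(step_oct = 0.2, levels_db = seq(15, 100, by = 5),
                          n_reps = 2, duration_ms = 50, period_ms = 150,
                          f_lo_khz = 2, f_hi_khz = 90, t0_ms = 200) {
  freqs <- fra_freq_grid(step_oct, f_lo_khz, f_hi_khz)
  grid <- expand.grid(freq_khz = freqs, level_db_spl = levels_db)
  grid <- grid[rep(seq_len(nrow(grid)), n_reps), ]
  n <- nrow(grid)
  schedule(data.frame(onset_ms = t0_ms + (seq_len(n) - 1) * period_ms,
                      kind = "tone", freq_khz = grid$freq_khz,
                      level_db_spl = grid$level_db_spl,
                      duration_ms = duration_ms,
                      call_id = NA_character_))
}

#' Log-spaced tone frequency grid
#'
#' @param step_oct octave step (0.2 or 0.15 in the standard protocol).
#' @param f_lo_khz,f_hi_khz range, kHz.
#' @return ascending numeric vector of frequencies, kHz.
#' @export
fra_freq_grid <- function(step_oct = 0.2, f_lo_khz = 2, f_hi_khz = 90) {
  f_lo_khz * 2^seq(0, log2(f_hi_khz / f_lo_khz), by = step_oct)
}

#' Build a vocalization playback schedule
#'
#' The calls are cycled in order, `n_trials` presentations each, one onset
#' every `period_ms`. The default of 256 presentations per call matches
#' the recording protocol; brief onset-type responses add well under one
#' spike per trial, so substantially fewer trials leave them undetectable
#' by the rank-sum criterion.
#'
#' @param calls list of `call_spec` (default: the nine standard calls).
#' @param n_trials presentations per call.
#' @param period_ms onset-to-onset interval.
#' @param t0_ms onset of the first call.
#' @return a `schedule` of call events.
#' @export
call_schedule <- function(calls = default_calls(), n_trials = 256,
                          period_ms = 150, t0_ms = 200) {
  ids <- vapply(calls, `[[`, "", "call_id")
  durs <- vapply(calls, `[[`, 0, "duration_ms")
  lvls <- vapply(calls, `[[`, 0, "level_db_spl")
  idx <- rep(seq_along(calls), times = n_trials)
  n <- length(idx)
  schedule(data.frame(onset_ms = t0_ms + (seq_len(n) - 1) * period_ms,
                      kind = "call", freq_khz = NA_real_,
                      level_db_spl = lvls[idx], duration_ms = durs[idx],
                      call_id = ids[idx]))
}

#' Simulate one unit's spike train across a whole stimulus session
#'
#' Builds the session-long inhomogeneous rate (spontaneous baseline plus
#' the driven excess of every schedule event under the neuron's response
#' model) and draws a single gamma-renewal spike train over it.
#'
#' @param neuron a `neuron_spec`.
#' @param sched a `schedule`.
#' @param calls named list of `call_spec` resolving the schedule's call
#'   ids.
#' @param seed optional RNG seed.
#' @param bin_ms rate-grid resolution.
#' @param unit_id,animal_id,station labels for the returned `unit_spikes`.
#' @return a `unit_spikes` (source `"simulated"`).
#' @export
simulate_unit_response <- function(neuron, sched, calls = default_calls(),
                                   seed = NULL, bin_ms = 0.5,
                                   unit_id = "u1", animal_id = "animal1",
                                   station = "AN") {
  stopifnot(inherits(sched, "schedule"))
  t_end <- max(sched$onset_ms + sched$duration_ms) + 100
  n_bins <- ceiling(t_end / bin_ms)
  rate <- rep(neuron$spont_rate_hz, n_bins)
  lat <- neuron$fsl_ms - 0.5
  for (i in seq_len(nrow(sched))) {
    ev <- sched[i, ]
    dur <- ev$duration_ms
    # driven excess occupies [onset + lat, onset + lat + dur]
    i0 <- floor((ev$onset_ms + lat) / bin_ms)
    i1 <- min(ceiling((ev$onset_ms + lat + dur) / bin_ms) + 1, n_bins)
    if (i1 <= i0) next
    bins <- (i0 + 1):i1
    t_rel <- (bins - 0.5) * bin_ms - ev$onset_ms - lat
    env <- .class_envelope(neuron, t_rel, dur)
    if (ev$kind == "tone") {
      s <- .tuning_strength(neuron, ev$freq_khz, ev$level_db_spl)
    } else if (ev$kind == "call") {
      cs <- calls[[ev$call_id]]
      if (is.null(cs)) stop("unknown call id: ", ev$call_id)
      f_inst <- call_freq_khz(cs, t_rel)
      s <- .tuning_strength(neuron, f_inst, ev$level_db_spl)
    } else {
      s <- 0.5  # clicks: broadband, mid-strength
    }
    rate[bins] <- rate[bins] + neuron$max_rate_hz * s * env
  }
  st <- simulate_spike_train(rate, bin_ms, neuron$gamma_order,
                             neuron$refractory_ms, seed = seed)
  unit_spikes(unit_id, animal_id, station, st, source = "simulated")
}

#' Specify a synthetic recording population
#'
#' Characteristic frequencies are drawn from a two-part mixture: a fraction
#' `fraction_high_f` of units sit inside the 60-90 kHz call band (uniform
#' in log-frequency over 62-88 kHz), the remainder follow a log-normal
#' truncated to 2-42 kHz, whose mode matches the station (20-30 kHz for
#' AN/DCN, higher for ICC). Units are assigned round-robin to animals.
#'
#' @param n_units number of units/sites.
#' @param station `"AN"`, `"DCN"` or `"ICC"`.
#' @param cf_log_mean_khz geometric mean CF of the low-frequency part.
#' @param cf_log_sd_oct SD of log2 CF, octaves.
#' @param fraction_high_f fraction of units with CF inside the call band.
#' @param n_animals number of animals.
#' @param seed RNG seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_units, station = c("AN", "DCN", "ICC"),
                            cf_log_mean_khz = 25, cf_log_sd_oct = 0.5,
                            fraction_high_f = 0.075, n_animals = 5,
                            seed = 1) {
  station <- match.arg(station)
  if (fraction_high_f < 0 || fraction_high_f > 1)
    stop("parameter error: fraction_high_f must be in [0, 1]")
  if (n_units < n_animals || n_animals < 1)
    stop("parameter error: need n_units >= n_animals >= 1")
  structure(list(n_units = n_units, station = station,
                 cf_log_mean_khz = cf_log_mean_khz,
                 cf_log_sd_oct = cf_log_sd_oct,
                 fraction_high_f = fraction_high_f,
                 n_animals = n_animals, seed = seed),
            class = "population_spec")
}

#' Station profiles matching the recorded populations
#'
#' Default population specifications per station: the auditory nerve
#' (94 fibers from 23 animals, CF mode 20-30 kHz, 7/94 call-band units),
#' the dorsal cochlear nucleus (1248 sites from 8 animals, 118/1248), and
#' the central nucleus of the inferior colliculus (696 sites from 5
#' animals, CF mode above 40 kHz, 409/696).
#'
#' @param station `"AN"`, `"DCN"` or `"ICC"`.
#' @param seed RNG seed stored in the spec.
#' @return a `population_spec`.
#' @export
station_profile <- function(station = c("AN", "DCN", "ICC"), seed = 1) {
  station <- match.arg(station)
  switch(station,
    AN = population_spec(94, "AN", cf_log_mean_khz = 25,
                         cf_log_sd_oct = 0.45, fraction_high_f = 7 / 94,
                         n_animals = 23, seed = seed),
    DCN = population_spec(1248, "DCN", cf_log_mean_khz = 25,
                          cf_log_sd_oct = 0.5,
                          fraction_high_f = 118 / 1248, n_animals = 8,
                          seed = seed),
    ICC = population_spec(696, "ICC", cf_log_mean_khz = 30,
                          cf_log_sd_oct = 0.6, fraction_high_f = 409 / 696,
                          n_animals = 5, seed = seed))
}

# Draw neuron specs for a population; returns list(neurons, truth) without
# simulating responses.
.draw_population <- function(spec, calls = default_calls()) {
  with_seed(spec$seed, {
    n <- spec$n_units
    high <- stats::runif(n) < spec$fraction_high_f
    cf <- numeric(n)
    cf[high] <- 2^stats::runif(sum(high), log2(62), log2(88))
    n_low <- sum(!high)
    if (n_low) {
      draw <- function(m) 2^stats::rnorm(m, log2(spec$cf_log_mean_khz),
                                         spec$cf_log_sd_oct)
      x <- draw(n_low)
      while (any(bad <- x < 2 | x > 42)) x[bad] <- draw(sum(bad))
      cf[!high] <- x
    }
    thr <- pmin(pmax(stats::rnorm(n, 30, 7), 15), 50)
    classes <- if (spec$station == "AN") rep("primary", n)
      else sample(c("primary", "chopper", "pri-N", "onset"), n,
                  replace = TRUE, prob = c(0.4, 0.3, 0.15, 0.15))
    order_of <- function(cl) switch(cl, primary = sample(1:2, 1),
                                    `pri-N` = sample(1:2, 1),
                                    chopper = sample(9:16, 1), onset = 2)
    # class FSL distributions sit clear of the 5 ms boundary, mirroring
    # the bimodal separation the fiber criterion relies on
    fsl_of <- function(cl) if (cl %in% c("primary", "pri-N"))
      stats::runif(1, 2.5, 4.2) else stats::runif(1, 4.5, 8)
    neurons <- vector("list", n)
    for (i in seq_len(n)) {
      neurons[[i]] <- neuron_spec(
        cf_khz = cf[i], threshold_db = thr[i],
        max_rate_hz = stats::runif(1, 180, 320),
        spont_rate_hz = stats::runif(1, 4, 18),
        psth_class = classes[i], gamma_order = order_of(classes[i]),
        fsl_ms = fsl_of(classes[i]))
    }
    animal <- paste0("a", (seq_len(n) - 1) %% spec$n_animals + 1)
    truth <- data.frame(
      unit_id = sprintf("%s_u%03d", spec$station, seq_len(n)),
      animal_id = animal, station = spec$station, cf_khz = cf,
      threshold_db = thr, psth_class = classes,
      gamma_order = vapply(neurons, `[[`, 0, "gamma_order"),
      fsl_ms = vapply(neurons, `[[`, 0, "fsl_ms"),
      stringsAsFactors = FALSE)
    truth$fmax_true_khz <- vapply(neurons, fmax_by_construction, 0)
    nd <- vapply(neurons, function(nn)
      sum(vapply(calls, function(cs) call_drives(nn, cs), FALSE)), 0L)
    truth$n_driven_calls <- nd
    truth$responds_to_calls <- nd >= 3
    for (i in seq_len(n))
      neurons[[i]]$responds_to_calls <- truth$responds_to_calls[i]
    list(neurons = neurons, truth = truth)
  })
}

#' Does a call's frequency trajectory enter a neuron's response area?
#'
#' The ground-truth predicate behind `responds_to_calls`: the sweep enters
#' the V-shaped response area iff the closest octave distance between the
#' trajectory and CF is below the (capped) half-width at the call level.
#'
#' @param neuron a `neuron_spec`.
#' @param call a `call_spec`.
#' @return logical.
#' @export
call_drives <- function(neuron, call) {
  f_lo <- min(call$f_start_khz, call$f_end_khz)
  f_hi <- max(call$f_start_khz, call$f_end_khz)
  d_min <- if (neuron$cf_khz >= f_lo && neuron$cf_khz <= f_hi) 0
    else min(abs(log2(f_lo / neuron$cf_khz)),
             abs(log2(f_hi / neuron$cf_khz)))
  w <- min(neuron$q_sharpness *
             max(call$level_db_spl - neuron$threshold_db, 0) / 10,
           neuron$w_max_oct)
  d_min < w
}

#' Ground-truth F_max of a model neuron
#'
#' The highest frequency at which the neuron can respond at the loudest
#' probe level (100 dB SPL), clipped to the 90 kHz top of the probe range.
#'
#' @param neuron a `neuron_spec`.
#' @param max_level_db loudest probe level.
#' @param f_top_khz top of the probe frequency range.
#' @return frequency in kHz.
#' @export
fmax_by_construction <- function(neuron, max_level_db = 100,
                                 f_top_khz = 90) {
  w <- min(neuron$q_sharpness *
             max(max_level_db - neuron$threshold_db, 0) / 10,
           neuron$w_max_oct)
  min(f_top_khz, neuron$cf_khz * 2^w)
}

#' Simulate a whole recording population against a stimulus schedule
#'
#' Draws `n_units` model neurons from the station profile, simulates each
#' one's spike train over the full schedule, and returns the spike trains
#' with the generating ground truth (CF, threshold, PSTH class, F_max by
#' construction, and the call-responsiveness flag re-derived from the
#' response-area predicate). Deterministic given `(spec, seed)`.
#'
#' @param spec a `population_spec`.
#' @param sched a `schedule` of stimuli.
#' @param calls named list of `call_spec` resolving call ids.
#' @return list with `units` (list of `unit_spikes`), `truth` (data.frame)
#'   and `neurons` (list of `neuron_spec`).
#' @export
simulate_population <- function(spec, sched, calls = default_calls()) {
  stopifnot(inherits(spec, "population_spec"))
  pop <- .draw_population(spec, calls)
  units <- vector("list", spec$n_units)
  for (i in seq_len(spec$n_units)) {
    units[[i]] <- simulate_unit_response(
      pop$neurons[[i]], sched, calls, seed = spec$seed + 7919L + i,
      unit_id = pop$truth$unit_id[i], animal_id = pop$truth$animal_id[i],
      station = spec$station)
  }
  names(units) <- pop$truth$unit_id
  list(units = units, truth = pop$truth, neurons = pop$neurons)
}
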