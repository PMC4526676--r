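# Spike times of one unit relative to each event onset, within [0, win).
.aligned_spikes <- function(unit, events, window_ms) {
  lapply(events$onset_ms, function(on) {
    s <- unit$spike_times_ms
    s[s >= on & s < on + window_ms] - on
  })
}

#' Peri-stimulus time histogram
#'
#' Trial-averaged firing rate on a regular grid after stimulus onset. The
#' bookkeeping identity `sum(rate * bin_width_s * n_trials) == total spike
#' count` holds exactly.
#'
#' @param unit a `unit_spikes`.
#' @param events a `schedule` (or subset) of repeated presentations.
#' @param window_ms analysis window after onset, ms.
#' @param bin_width_ms bin width; must divide the window length.
#' @return object of class `psth`: list with `bin_edges_ms`, `rate_hz`
#'   (spikes/s per bin), `n_trials`, `bin_width_ms`.
#' @export
compute_psth <- function(unit, events, window_ms = 100, bin_width_ms = 1) {
  if (nrow(events) == 0) stop("insufficient data: no events")
  if (abs(window_ms / bin_width_ms - round(window_ms / bin_width_ms)) >
      1e-9)
    stop("parameter error: bin width must divide the window length")
  edges <- seq(0, window_ms, by = bin_width_ms)
  n_trials <- nrow(events)
  rel <- unlist(.aligned_spikes(unit, events, window_ms))
  counts <- if (length(rel))
    tabulate(findInterval(rel, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  else rep(0L, length(edges) - 1)
  structure(list(bin_edges_ms = edges,
                 rate_hz = counts / (n_trials * bin_width_ms / 1000),
                 n_trials = n_trials, bin_width_ms = bin_width_ms),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("psth: %d bins x %g ms, %d trials, peak %.0f spikes/s\n",
              length(x$rate_hz), x$bin_width_ms, x$n_trials,
              max(x$rate_hz)))
  invisible(x)
}

#' Coefficient of variation of interspike intervals
#'
#' ISIs are pooled within trials only (an interval spanning two trials is
#' not an interspike interval); CV = sample SD (n-1 denominator) divided by
#' the mean. High CV (>= 0.5, near-Poisson irregularity) is one of the
#' marks of auditory-nerve fibers.
#'
#' @param unit a `unit_spikes`.
#' @param events repeated presentations (`schedule` subset).
#' @param window_ms response window after onset, ms.
#' @return scalar CV.
#' @export
isi_cv <- function(unit, events, window_ms = 100) {
  isis <- unlist(lapply(.aligned_spikes(unit, events, window_ms), diff))
  if (length(isis) < 3)
    stop("insufficient data: need at least 3 interspike intervals")
  stats::sd(isis) / mean(isis)
}

#' Mode of the first-spike latency
#'
#' First-spike latencies across trials are histogrammed in `bin_ms` bins
#' over (0, `max_latency_ms`]; the center of the fullest bin is returned,
#' ties resolved toward the earliest bin. Short FSL (<= 5 ms) marks
#' peripheral units.
#'
#' @param unit a `unit_spikes`.
#' @param events repeated presentations.
#' @param max_latency_ms latest latency considered.
#' @param bin_ms histogram bin width.
#' @return latency of the modal bin center, ms.
#' @export
first_spike_latency_mode <- function(unit, events, max_latency_ms = 30,
                                     bin_ms = 0.5) {
  fsl <- vapply(.aligned_spikes(unit, events, max_latency_ms),
                function(s) if (length(s)) s[1] else NA_real_, 0)
  fsl <- fsl[!is.na(fsl) & fsl > 0]
  if (length(fsl) < 10)
    stop("insufficient data: first spikes on fewer than 10 trials")
  edges <- seq(0, max_latency_ms, by = bin_ms)
  counts <- tabulate(findInterval(fsl, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  k <- which.max(counts)  # which.max returns the earliest maximal bin
  edges[k] + bin_ms / 2
}

#' Classify a PSTH into the canonical response shapes
#'
#' Deterministic surrogate for the visual typing of tone-evoked PSTHs
#' (50 ms tone, 1 ms bins):
#' * `onset` — sustained rate (mean over the last 25 ms of the tone) below
#'   `onset_frac` of the peak (the default 0.1 accommodates the several-fold
#'   onset/sustained ratio of primary-like responses);
#' * `chopper` — at least three regularly spaced peaks in the first 25 ms
#'   (dominant non-zero lag in the autocorrelation);
#' * `pri-N` — primary-shaped with a >= `notch_frac` dip within 2-6 ms
#'   after the peak bin, judged against the rate 2-4 ms *after* the dip:
#'   recovery after the dip is what distinguishes a notch from the
#'   monotone decay of an adapting onset transient;
#' * `primary` — peak within the first 10 ms and sustained rate at least
#'   `onset_frac` of the peak;
#' * `unclassified` otherwise.
#'
#' @param psth a `psth` over a 50 ms tone response, 1 ms bins.
#' @param tone_dur_ms tone duration.
#' @param onset_frac sustained/peak ratio separating onset responses.
#' @param notch_frac dip depth (relative to the surrounding envelope)
#'   defining a pri-N notch.
#' @param chop_min_corr autocorrelation at the dominant lag required to
#'   call regular chopping.
#' @return one of `"primary"`, `"chopper"`, `"pri-N"`, `"onset"`,
#'   `"unclassified"`.
#' @export
classify_psth <- function(psth, tone_dur_ms = 50, onset_frac = 0.1,
                          notch_frac = 0.5, chop_min_corr = 0.25) {
  r <- psth$rate_hz
  bw <- psth$bin_width_ms
  n_tone <- min(round(tone_dur_ms / bw), length(r))
  r <- r[seq_len(n_tone)]
  peak_bin <- which.max(r)
  peak <- r[peak_bin]
  if (peak <= 0) return("unclassified")
  sustained <- mean(r[(n_tone - round(25 / bw) + 1):n_tone])
  if (sustained < onset_frac * peak) return("onset")
  # regular chopping: the autocorrelation of the early response must dip
  # and then rebound to a local peak (a smooth monotone decay also has
  # high low-lag autocorrelation, but never rebounds)
  early <- r[seq_len(round(25 / bw))]
  early <- early - mean(early)
  if (stats::sd(early) > 0) {
    ac <- stats::acf(early, lag.max = round(12 / bw), plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    mins <- .local_min(ac)
    if (length(mins)) {
      after <- seq(min(mins) + 1, length(ac))
      if (length(after) > 1) {
        rebound <- after[which.max(ac[after])]
        period_ms <- (rebound - 1) * bw
        n_peaks_possible <- floor(25 / period_ms) + 1
        if (ac[rebound] > chop_min_corr && rebound %in% .local_max(ac) &&
            n_peaks_possible >= 3)
          return("chopper")
      }
    }
  }
  # pri-N: deep notch 2-6 ms after the peak that recovers afterwards
  lo <- peak_bin + round(2 / bw)
  hi <- min(peak_bin + round(6 / bw), n_tone)
  if (lo < hi) {
    j <- (lo:hi)[which.min(r[lo:hi])]
    after <- (j + round(2 / bw)):min(j + round(4 / bw), n_tone)
    if (length(after) && all(after <= n_tone)) {
      recovery <- mean(r[after])
      if (r[j] < (1 - notch_frac) * recovery &&
          peak_bin <= round(10 / bw))
        return("pri-N")
    }
  }
  if (peak_bin <= round(10 / bw) && sustained >= onset_frac * peak)
    return("primary")
  "unclassified"
}

#' Compute the per-unit classification metrics
#'
#' Convenience wrapper computing ISI CV, first-spike-latency mode, PSTH
#' class and the fiber gate for one unit over repeated presentations of
#' its CF tone.
#'
#' @param unit a `unit_spikes`.
#' @param events repeated CF-tone presentations.
#' @param window_ms response window for CV and the PSTH.
#' @param fsl_bin_ms FSL histogram bin.
#' @return object of class `unit_metrics`: list with `unit_id`, `cv_isi`,
#'   `fsl_mode_ms`, `psth_class`, `is_an_fiber`.
#' @export
unit_metrics <- function(unit, events, window_ms = 50, fsl_bin_ms = 0.5) {
  cv <- tryCatch(isi_cv(unit, events, window_ms), error = function(e) NA)
  fsl <- tryCatch(first_spike_latency_mode(unit, events,
                                           bin_ms = fsl_bin_ms),
                  error = function(e) NA)
  cls <- tryCatch(classify_psth(compute_psth(unit, events, window_ms, 1)),
                  error = function(e) "unclassified")
  m <- structure(list(unit_id = unit$unit_id, cv_isi = cv,
                      fsl_mode_ms = fsl, psth_class = cls,
                      is_an_fiber = FALSE),
                 class = "unit_metrics")
  m$is_an_fiber <- an_fiber_gate(m)
  m
}

#' Auditory-nerve fiber gate
#'
#' A unit is treated as an auditory-nerve fiber only when all three hold:
#' ISI CV >= 0.5 (inclusive), first-spike-latency mode <= 5 ms (inclusive),
#' and a primary-like PSTH. Units with any undefined metric fail the gate.
#'
#' @param metrics a `unit_metrics` (or list with `cv_isi`, `fsl_mode_ms`,
#'   `psth_class`).
#' @param cv_min,fsl_max_ms gate boundaries (both inclusive).
#' @return logical.
#' @export
an_fiber_gate <- function(metrics, cv_min = 0.5, fsl_max_ms = 5) {
  if (is.na(metrics$cv_isi) || is.na(metrics$fsl_mode_ms) ||
      is.na(metrics$psth_class)) {
    message("fiber gate: undefined metric for unit ",
            metrics$unit_id %||% "?", "; gate fails")
    return(FALSE)
  }
  metrics$cv_isi >= cv_min && metrics$fsl_mode_ms <= fsl_max_ms &&
    metrics$psth_class == "primary"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
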