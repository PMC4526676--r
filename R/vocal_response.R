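#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The test behind the driven-versus-spontaneous comparison. The p-value is
#' exact (from the null permutation distribution of the rank sum) whenever
#' both samples have at most 10 observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Identical samples yield p = 1.
#'
#' @param x,y numeric samples (e.g. driven and spontaneous spike counts).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends
#'   larger) or `"less"`.
#' @return p-value in \[0, 1\].
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U for x
  ties <- any(duplicated(c(x, y)))
  if (n1 <= 10 && n2 <= 10 && !ties) {
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(p)
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                            (n * (n - 1)))
  if (sig2 <= 0) return(1)
  sig <- sqrt(sig2)
  z <- switch(alternative,
              two.sided = (abs(u - mu) - 0.5) / sig,
              greater = (u - mu - 0.5) / sig,
              less = -(u - mu + 0.5) / sig)
  if (alternative == "two.sided") min(1, 2 * stats::pnorm(-max(z, 0)))
  else stats::pnorm(-z)
}

#' Per-trial driven and spontaneous spike counts for one call
#'
#' For each presentation the driven window is
#' `[onset + latency_offset, onset + latency_offset + duration]` and the
#' spontaneous window is the equal-duration interval immediately before
#' onset, so the two count distributions are directly comparable.
#'
#' @param unit a `unit_spikes`.
#' @param events presentations of one call (`schedule` subset).
#' @param latency_offset_ms neural latency added to the driven window.
#' @return list with `driven_counts` and `spont_counts` (one per trial)
#'   and `window_ms` (the common window duration).
#' @export
count_windows <- function(unit, events, latency_offset_ms = 5) {
  stopifnot(nrow(events) >= 1)
  dur <- events$duration_ms
  d_lo <- events$onset_ms + latency_offset_ms
  d_hi <- d_lo + dur
  s_lo <- events$onset_ms - dur
  s_hi <- events$onset_ms
  if (nrow(events) > 1 &&
      any(d_hi[-nrow(events)] > s_lo[-1] + 1e-9))
    stop("validation error: driven and spontaneous windows overlap ",
         "across events")
  count_in <- function(lo, hi) {
    s <- unit$spike_times_ms
    findInterval(hi, s) - findInterval(lo, s)
  }
  list(driven_counts = mapply(count_in, d_lo, d_hi),
       spont_counts = mapply(count_in, s_lo, s_hi),
       window_ms = dur[1])
}

#' Response signal-to-noise ratio
#'
#' The responsiveness statistic: the variance across time bins of the PSTH
#' (the trial mean) divided by the average over trials of the variance of
#' each trial's deviation from the PSTH. Both variances use the population
#' convention (divide by the number of bins). A perfectly repeatable
#' response has infinite SNR (flagged as `Inf`); a flat, trial-symmetric
#' response has SNR 0.
#'
#' @param trials numeric matrix n_trials x n_bins of binned rates or
#'   counts.
#' @return non-negative scalar, possibly `Inf`.
#' @export
response_snr <- function(trials) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 2)
    stop("insufficient data: SNR needs at least 2 trials")
  if (ncol(trials) < 2)
    stop("insufficient data: SNR needs at least 2 bins")
  popvar <- function(v) mean((v - mean(v))^2)
  psth <- colMeans(trials)
  num <- popvar(psth)
  dev <- sweep(trials, 2, psth)
  den <- mean(apply(dev, 1, popvar))
  if (den == 0) return(if (num > 0) Inf else 0)
  num / den
}

#' Binned single-trial responses for one call
#'
#' Helper building the n_trials x n_bins count matrix over the driven
#' window, the input to [response_snr()].
#'
#' @param unit a `unit_spikes`.
#' @param events presentations of one call.
#' @param latency_offset_ms driven-window latency offset.
#' @param bin_ms SNR bin width.
#' @return integer matrix n_trials x n_bins.
#' @export
trial_response_matrix <- function(unit, events, latency_offset_ms = 5,
                                  bin_ms = 2) {
  dur <- events$duration_ms[1]
  n_bins <- max(floor(dur / bin_ms), 2)
  t(vapply(seq_len(nrow(events)), function(i) {
    lo <- events$onset_ms[i] + latency_offset_ms
    s <- unit$spike_times_ms
    rel <- s[s >= lo & s < lo + n_bins * bin_ms] - lo
    tabulate(floor(rel / bin_ms) + 1L, nbins = n_bins)
  }, integer(n_bins)))
}

#' Test one unit's response to each vocalization
#'
#' For every call: per-trial driven and spontaneous counts, a two-sided
#' rank-sum p-value, and the response SNR over the driven window.
#'
#' @param unit a `unit_spikes`.
#' @param sched a `schedule` containing the call presentations.
#' @param latency_offset_ms driven-window latency offset.
#' @param snr_bin_ms bin width for the SNR response matrix.
#' @return data.frame of class `call_response_set`, one row per call:
#'   `unit_id, call_id, n_trials, p_value, snr, mean_driven, mean_spont`.
#' @export
test_call_responses <- function(unit, sched, latency_offset_ms = 5,
                                snr_bin_ms = 2) {
  ev <- sched[sched$kind == "call", , drop = FALSE]
  if (!nrow(ev)) stop("insufficient data: no call events in schedule")
  ids <- unique(ev$call_id)
  rows <- lapply(ids, function(cid) {
    e <- ev[ev$call_id == cid, , drop = FALSE]
    cw <- count_windows(unit, e, latency_offset_ms)
    p <- rank_sum_test(cw$driven_counts, cw$spont_counts)
    snr <- response_snr(trial_response_matrix(unit, e, latency_offset_ms,
                                              snr_bin_ms))
    data.frame(unit_id = unit$unit_id, call_id = cid, n_trials = nrow(e),
               p_value = p, snr = snr,
               mean_driven = mean(cw$driven_counts),
               mean_spont = mean(cw$spont_counts))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("call_response_set", "data.frame")
  out
}

#' Summarize a unit's vocalization responsiveness
#'
#' A unit is responsive when at least 3 of the 9 tested calls evoke a
#' significant response (rank-sum p < 0.05, strict). The unit's SNR is the
#' arithmetic mean across calls; infinite per-call SNRs are excluded from
#' the mean with a logged count. If fewer than 9 calls were tested the
#' criterion scales as `ceiling(n/3)` with a warning.
#'
#' @param responses a `call_response_set` for one unit (from
#'   [test_call_responses()]).
#' @param alpha per-call significance level.
#' @return object of class `responsiveness_summary`: list with `unit_id`,
#'   `n_significant_calls`, `responsive`, `mean_snr`, `n_calls`.
#' @export
summarize_responsiveness <- function(responses, alpha = 0.05) {
  n_calls <- nrow(responses)
  need <- if (n_calls < 9) {
    warning("fewer than 9 calls tested; scaling the criterion to ",
            ceiling(n_calls / 3), " of ", n_calls)
    ceiling(n_calls / 3)
  } else 3
  n_sig <- sum(responses$p_value < alpha)
  finite_snr <- responses$snr[is.finite(responses$snr)]
  if (length(finite_snr) < n_calls)
    message(n_calls - length(finite_snr),
            " call(s) with infinite SNR excluded from the mean")
  structure(list(unit_id = responses$unit_id[1],
                 n_significant_calls = n_sig,
                 responsive = n_sig >= need,
                 mean_snr = if (length(finite_snr)) mean(finite_snr) else 0,
                 n_calls = n_calls),
            class = "responsiveness_summary")
}

#' @export
print.responsiveness_summary <- function(x, ...) {
  cat(sprintf("unit %s: %d/%d calls significant -> %sresponsive (mean SNR %.2f)\n",
              x$unit_id, x$n_significant_calls, x$n_calls,
              if (x$responsive) "" else "not ", x$mean_snr))
  invisible(x)
}
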