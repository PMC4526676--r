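#' Build a frequency response area from sorted spikes
#'
#' For every tone event the evoked rate is counted over
#' `(0, duration + 10]` ms from onset and the expected baseline is the
#' rate in the 50 ms immediately preceding onset; a cell of the FRA is the
#' mean of (evoked - baseline) over that cell's repetitions. Cells with no
#' repetitions are flagged missing (`NA`).
#'
#' @param unit a `unit_spikes`.
#' @param sched a `schedule`; only tone events are used.
#' @param count_window_ms response window after onset; default
#'   `duration + 10`.
#' @param baseline_ms baseline window before onset.
#' @return object of class `fra`: list with `freqs_khz`, `levels_db`,
#'   `response` (n_freq x n_level mean excess rate, spikes/s), `resp_var`
#'   (per-cell sample variance), `n_reps`, `spont` (mean baseline rate),
#'   `spont_sd` (SD of per-window baseline rates), `window_ms`.
#' @export
build_fra <- function(unit, sched, count_window_ms = NULL,
                      baseline_ms = 50) {
  ev <- sched[sched$kind == "tone", , drop = FALSE]
  if (!nrow(ev)) stop("insufficient data: no tone events")
  win <- if (is.null(count_window_ms)) ev$duration_ms + 10
         else rep(count_window_ms, nrow(ev))
  s <- unit$spike_times_ms
  count_in <- function(lo, hi) findInterval(hi, s) - findInterval(lo, s)
  evoked <- count_in(ev$onset_ms, ev$onset_ms + win) / (win / 1000)
  base <- count_in(ev$onset_ms - baseline_ms, ev$onset_ms) /
    (baseline_ms / 1000)
  excess <- evoked - base
  freqs <- sort(unique(ev$freq_khz))
  levels <- sort(unique(ev$level_db_spl))
  fi <- match(ev$freq_khz, freqs)
  li <- match(ev$level_db_spl, levels)
  cell <- (li - 1) * length(freqs) + fi
  n_cells <- length(freqs) * length(levels)
  n <- tabulate(cell, n_cells)
  mean_x <- rep(NA_real_, n_cells)
  var_x <- rep(NA_real_, n_cells)
  sums <- vapply(split(excess, factor(cell, levels = seq_len(n_cells))),
                 sum, 0)
  mean_x[n > 0] <- sums[n > 0] / n[n > 0]
  ssq <- vapply(split(excess^2, factor(cell, levels = seq_len(n_cells))),
                sum, 0)
  var_x[n > 1] <- (ssq[n > 1] - n[n > 1] * mean_x[n > 1]^2) /
    (n[n > 1] - 1)
  structure(list(freqs_khz = freqs, levels_db = levels,
                 response = matrix(mean_x, nrow = length(freqs)),
                 resp_var = matrix(var_x, nrow = length(freqs)),
                 n_reps = matrix(n, nrow = length(freqs)),
                 spont = mean(base), spont_sd = stats::sd(base),
                 window_ms = win[1]),
            class = "fra")
}

#' Build a frequency response area from an aMUA envelope
#'
#' Multi-electrode analog of [build_fra()]: each cell is the mean, over
#' repetitions, of the z-scored envelope (relative to the pre-onset
#' baseline distribution) averaged over the response window.
#'
#' @param amua an `amua_trace`.
#' @param sched a `schedule`; only tone events are used.
#' @param channel row of the envelope to analyze.
#' @param count_window_ms response window after onset; default
#'   `duration + 10`.
#' @param baseline_ms baseline window before onset.
#' @return an `fra` whose `response` is in baseline SD units.
#' @export
build_fra_amua <- function(amua, sched, channel = 1,
                           count_window_ms = NULL, baseline_ms = 50) {
  stopifnot(inherits(amua, "amua_trace"))
  ev <- sched[sched$kind == "tone", , drop = FALSE]
  if (!nrow(ev)) stop("insufficient data: no tone events")
  fs <- amua$sample_rate_hz
  sig <- amua$samples[channel, ]
  t0 <- amua$start_time_ms
  win <- if (is.null(count_window_ms)) ev$duration_ms + 10
         else rep(count_window_ms, nrow(ev))
  seg_mean <- function(lo_ms, hi_ms) {
    i0 <- pmax(floor((lo_ms - t0) / 1000 * fs) + 1, 1)
    i1 <- pmin(ceiling((hi_ms - t0) / 1000 * fs), length(sig))
    mapply(function(a, b) mean(sig[a:b]), i0, i1)
  }
  evoked <- seg_mean(ev$onset_ms, ev$onset_ms + win)
  base <- seg_mean(ev$onset_ms - baseline_ms, ev$onset_ms)
  mu <- mean(base)
  sd0 <- stats::sd(base)
  if (sd0 == 0) sd0 <- 1
  z <- (evoked - mu) / sd0
  freqs <- sort(unique(ev$freq_khz))
  levels <- sort(unique(ev$level_db_spl))
  cell <- (match(ev$level_db_spl, levels) - 1) * length(freqs) +
    match(ev$freq_khz, freqs)
  n_cells <- length(freqs) * length(levels)
  n <- tabulate(cell, n_cells)
  f <- factor(cell, levels = seq_len(n_cells))
  mean_z <- rep(NA_real_, n_cells)
  mean_z[n > 0] <- vapply(split(z, f), sum, 0)[n > 0] / n[n > 0]
  var_z <- rep(NA_real_, n_cells)
  ssq <- vapply(split(z^2, f), sum, 0)
  var_z[n > 1] <- (ssq[n > 1] - n[n > 1] * mean_z[n > 1]^2) / (n[n > 1] - 1)
  structure(list(freqs_khz = freqs, levels_db = levels,
                 response = matrix(mean_z, nrow = length(freqs)),
                 resp_var = matrix(var_z, nrow = length(freqs)),
                 n_reps = matrix(n, nrow = length(freqs)),
                 spont = 0, spont_sd = 1, window_ms = win[1],
                 units = "z"),
            class = "fra")
}

#' @export
print.fra <- function(x, ...) {
  cat(sprintf("fra: %d freqs (%.1f-%.1f kHz) x %d levels (%g-%g dB), %g rep(s)/cell\n",
              length(x$freqs_khz), min(x$freqs_khz), max(x$freqs_khz),
              length(x$levels_db), min(x$levels_db), max(x$levels_db),
              stats::median(x$n_reps)))
  invisible(x)
}

# Per-cell significance of excess response over baseline.
# reps >= 5: one-sided one-sample t test of the cell's excess values;
# reps < 5: mean above 2 x the null SE (Poisson-based null variance when
# spike-derived, else the baseline z-scale).
.fra_significant <- function(fra, alpha = 0.05) {
  n <- fra$n_reps
  m <- fra$response
  sig <- matrix(FALSE, nrow = nrow(m), ncol = ncol(m))
  small <- n > 0 & n < 5
  if (any(small)) {
    var_null <- if (is.null(fra$units))
      fra$spont * (1000 / fra$window_ms + 1000 / 50)
    else 2  # z-scored aMUA: var(evoked z) + var(baseline z) under null
    if (!is.finite(var_null) || var_null <= 0)
      var_null <- max(fra$spont_sd^2, 1e-12)
    sig[small] <- m[small] > 2 * sqrt(var_null / n[small])
  }
  big <- n >= 5 & !is.na(m)
  if (any(big)) {
    se <- sqrt(fra$resp_var[big] / n[big])
    tcrit <- stats::qt(1 - alpha, df = n[big] - 1)
    sig[big] <- se > 0 & m[big] / se > tcrit
  }
  sig[is.na(m)] <- FALSE
  sig
}

#' Estimate characteristic frequency and threshold from an FRA
#'
#' For each frequency the threshold is the lowest level whose cell is
#' significantly above baseline and remains significant at the two next
#' levels above (as many as exist at the top of the grid); the CF is the
#' frequency with the minimal threshold. Ties are broken by the geometric
#' mean of the tied frequencies, snapped to the nearest grid frequency.
#'
#' @param fra an `fra`.
#' @param alpha per-cell significance level.
#' @return object of class `tuning_summary`: list with `cf_khz`,
#'   `threshold_db` (both `NA` when no cell is significant) and
#'   `fmax_khz` (`NA`; filled by [estimate_fmax()]).
#' @export
estimate_cf <- function(fra, alpha = 0.05) {
  sig <- .fra_significant(fra, alpha)
  n_lev <- length(fra$levels_db)
  thr <- rep(NA_real_, length(fra$freqs_khz))
  for (i in seq_along(fra$freqs_khz)) {
    for (j in seq_len(n_lev)) {
      above <- j + seq_len(min(2, n_lev - j))
      if (sig[i, j] && all(sig[i, above])) {
        thr[i] <- fra$levels_db[j]
        break
      }
    }
  }
  if (all(is.na(thr)))
    return(structure(list(cf_khz = NA_real_, threshold_db = NA_real_,
                          fmax_khz = NA_real_), class = "tuning_summary"))
  tmin <- min(thr, na.rm = TRUE)
  tied <- which(!is.na(thr) & thr == tmin)
  cf <- if (length(tied) == 1) fra$freqs_khz[tied]
  else {
    gm <- 2^mean(log2(fra$freqs_khz[tied]))
    fra$freqs_khz[which.min(abs(log2(fra$freqs_khz / gm)))]
  }
  structure(list(cf_khz = cf, threshold_db = tmin, fmax_khz = NA_real_),
            class = "tuning_summary")
}

#' @export
print.tuning_summary <- function(x, ...) {
  cat(sprintf("tuning: CF %s kHz, threshold %s dB SPL, F_max %s kHz\n",
              format(x$cf_khz, digits = 3), format(x$threshold_db),
              format(x$fmax_khz, digits = 3)))
  invisible(x)
}

#' Estimate F_max: the highest frequency with a significant tone response
#'
#' For each grid frequency the driven spike counts are pooled across all
#' levels and repetitions and compared to the pooled spontaneous counts
#' (equal-duration windows immediately before each onset) with a one-sided
#' Wilcoxon rank-sum test; F_max is the highest frequency significant at
#' `alpha`, or `NA` when none is. Because F_max is the highest of a few
#' dozen per-frequency tests, the p-values are Holm-corrected across the
#' grid first — without familywise control nearly every silent unit would
#' receive a (spurious) F_max on a 28-frequency grid.
#'
#' @param unit a `unit_spikes`.
#' @param sched a `schedule`; only tone events are used.
#' @param alpha significance level.
#' @param count_window_ms response window after onset; default
#'   `duration + 10`.
#' @return F_max in kHz, or `NA_real_`.
#' @export
estimate_fmax <- function(unit, sched, alpha = 0.05,
                          count_window_ms = NULL) {
  ev <- sched[sched$kind == "tone", , drop = FALSE]
  if (!nrow(ev)) stop("insufficient data: no tone events")
  win <- if (is.null(count_window_ms)) ev$duration_ms + 10
         else rep(count_window_ms, nrow(ev))
  s <- unit$spike_times_ms
  count_in <- function(lo, hi) findInterval(hi, s) - findInterval(lo, s)
  driven <- count_in(ev$onset_ms, ev$onset_ms + win)
  spont <- count_in(ev$onset_ms - win, ev$onset_ms)
  freqs <- sort(unique(ev$freq_khz))
  p <- vapply(freqs, function(f) {
    x <- driven[ev$freq_khz == f]
    rank_sum_test(x, spont, alternative = "greater")
  }, numeric(1))
  sig <- stats::p.adjust(p, method = "holm") < alpha
  if (!any(sig)) return(NA_real_)
  max(freqs[sig])
}

#' Full tuning summary for one unit
#'
#' @param unit a `unit_spikes`.
#' @param sched a `schedule` with the tone grid.
#' @param alpha significance level for both the CF and F_max criteria.
#' @return a `tuning_summary` with `cf_khz`, `threshold_db`, `fmax_khz`.
#' @export
summarize_tuning <- function(unit, sched, alpha = 0.05) {
  ts <- estimate_cf(build_fra(unit, sched), alpha)
  ts$fmax_khz <- estimate_fmax(unit, sched, alpha)
  ts
}
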