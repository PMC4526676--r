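#' Fraction of responsive units with a bootstrap confidence interval
#'
#' Point estimate `n_responsive / n_total` with a percentile bootstrap CI
#' (2.5th and 97.5th percentiles, linear interpolation between order
#' statistics). Unit-level resampling draws units with replacement;
#' animal-level resampling draws animals with replacement and takes all of
#' each animal's units, which respects the clustering of multi-site
#' recordings.
#'
#' @param flags logical vector, one responsiveness flag per unit/site.
#' @param animal_ids animal labels (required for animal-level resampling).
#' @param resampling `"unit"` or `"animal"`.
#' @param n_boot bootstrap resamples.
#' @param seed optional RNG seed.
#' @param conf confidence level.
#' @return object of class `population_summary`: list with `n_total`,
#'   `n_responsive`, `fraction`, `ci95` (length-2), `resampling`,
#'   `n_boot`, `percent` (rounded to the nearest integer), `percent_ci`.
#' @export
fraction_responsive <- function(flags, animal_ids = NULL,
                                resampling = c("unit", "animal"),
                                n_boot = 10000, seed = NULL, conf = 0.95) {
  resampling <- match.arg(resampling)
  flags <- as.logical(flags)
  n <- length(flags)
  if (n < 1) stop("insufficient data: no units")
  frac <- mean(flags)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  boot <- with_seed(seed, {
    if (resampling == "unit") {
      colMeans(matrix(sample(flags, n * n_boot, replace = TRUE), nrow = n))
    } else {
      if (is.null(animal_ids))
        stop("animal_ids required for animal-level resampling")
      by_animal <- split(flags, animal_ids)
      if (length(by_animal) < 2)
        stop("animal-level resampling needs at least 2 animals")
      k <- length(by_animal)
      vapply(seq_len(n_boot), function(b) {
        pick <- sample.int(k, k, replace = TRUE)
        mean(unlist(by_animal[pick]))
      }, numeric(1))
    }
  })
  ci <- unname(stats::quantile(boot, probs, type = 7))
  structure(list(n_total = n, n_responsive = sum(flags), fraction = frac,
                 ci95 = ci, resampling = resampling, n_boot = n_boot,
                 percent = round(100 * frac),
                 percent_ci = round(100 * ci)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("%d of %d responsive = %d%% (95%% CI [%d%% %d%%], %s-level bootstrap, %d resamples)\n",
              x$n_responsive, x$n_total, x$percent, x$percent_ci[1],
              x$percent_ci[2], x$resampling, x$n_boot))
  invisible(x)
}

#' Histogram of characteristic frequencies in octave bins
#'
#' @param cfs_khz characteristic frequencies, kHz; `NA` (undefined) values
#'   are excluded with a logged count.
#' @param bin_oct bin width in octaves.
#' @param f_lo_khz,f_hi_khz histogram span.
#' @return object of class `cf_histogram`: list with `breaks_khz`,
#'   `counts`, `mids_khz`, `n_excluded`.
#' @export
cf_histogram <- function(cfs_khz, bin_oct = 1 / 3, f_lo_khz = 2,
                         f_hi_khz = 90) {
  n_excluded <- sum(is.na(cfs_khz))
  if (n_excluded > 0)
    message(n_excluded, " undefined CF(s) excluded from the histogram")
  cfs <- cfs_khz[!is.na(cfs_khz)]
  if (!length(cfs)) stop("insufficient data: no defined CFs")
  n_bins <- ceiling(log2(f_hi_khz / f_lo_khz) / bin_oct)
  breaks <- f_lo_khz * 2^(seq(0, n_bins) * bin_oct)
  counts <- tabulate(findInterval(cfs, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  structure(list(breaks_khz = breaks, counts = counts,
                 mids_khz = sqrt(breaks[-1] * breaks[-length(breaks)]),
                 n_excluded = n_excluded),
            class = "cf_histogram")
}

#' @export
print.cf_histogram <- function(x, ...) {
  cat(sprintf("cf_histogram: %d CFs in %d bins (modal bin %.1f-%.1f kHz)\n",
              sum(x$counts), length(x$counts),
              x$breaks_khz[which.max(x$counts)],
              x$breaks_khz[which.max(x$counts) + 1]))
  invisible(x)
}

#' One-way fixed-effects ANOVA across groups
#'
#' Used for across-animal comparisons of CF distributions (on log2 CF) and
#' of ABR wave amplitudes across frequencies. Groups with fewer than two
#' values are dropped with a warning.
#'
#' @param values numeric response values.
#' @param groups grouping labels (e.g. animal ids).
#' @param log2_transform take log2 of the values first (for CFs).
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
anova_across_groups <- function(values, groups, log2_transform = FALSE) {
  if (log2_transform) values <- log2(values)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(as.character(groups)[keep])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning(sum(sizes < 2), " group(s) with fewer than 2 values dropped")
    ok <- groups %in% names(sizes)[sizes >= 2]
    values <- values[ok]
    groups <- droplevels(groups[ok])
  }
  if (nlevels(groups) < 2)
    stop("insufficient data: need at least 2 groups with 2+ values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df1 = tab[["Df"]][1], df2 = tab[["Df"]][2])
}

#' Vocalization responsiveness across a population
#'
#' Runs the per-unit call-response test and responsiveness criterion over
#' every unit and collects the flags into one table.
#'
#' @param units list of `unit_spikes`.
#' @param sched a `schedule` with the call presentations.
#' @param latency_offset_ms driven-window latency offset.
#' @param alpha per-call significance level.
#' @return data.frame with one row per unit: `unit_id, animal_id, station,
#'   n_significant_calls, responsive, mean_snr`.
#' @export
population_responsiveness <- function(units, sched, latency_offset_ms = 5,
                                      alpha = 0.05) {
  rows <- lapply(units, function(u) {
    rs <- summarize_responsiveness(
      test_call_responses(u, sched, latency_offset_ms), alpha)
    data.frame(unit_id = u$unit_id, animal_id = u$animal_id,
               station = u$station,
               n_significant_calls = rs$n_significant_calls,
               responsive = rs$responsive, mean_snr = rs$mean_snr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
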