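#' Construct a multi-channel voltage trace
#'
#' A trace is the raw substrate for all extracellular processing: a uniformly
#' sampled voltage record with one row per electrode channel, in volts.
#' Times are milliseconds on a single session clock; `start_time_ms` is the
#' session time of the first sample.
#'
#' @param samples numeric matrix, channels x time, in volts.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param channel_ids character vector of channel labels, one per row.
#' @param start_time_ms session time of sample 1, in ms.
#' @return An object of class `trace`.
#' @export
trace <- function(samples, sample_rate_hz, channel_ids = NULL,
                  start_time_ms = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix [channels x time]")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0)
    stop("sample_rate_hz must be a positive scalar")
  if (any(!is.finite(samples)))
    stop("data error: trace contains non-finite samples")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_ids) != nrow(samples))
    stop("channel_ids length must match the number of channels")
  structure(list(samples = samples,
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 channel_ids = as.character(channel_ids),
                 start_time_ms = as.numeric(start_time_ms)),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("trace: %d channel(s) x %d samples @ %g Hz (%.1f ms)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
              ncol(x$samples) / x$sample_rate_hz * 1000))
  invisible(x)
}

#' Time axis of a trace
#'
#' @param x a `trace`.
#' @return numeric vector of session times (ms), one per sample.
#' @export
trace_times_ms <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$start_time_ms + (seq_len(ncol(x$samples)) - 1) / x$sample_rate_hz * 1000
}

#' Write a trace as float32 binary plus JSON sidecar
#'
#' Samples are stored channel-major (all of channel 1, then channel 2, ...)
#' as little-endian IEEE float32. The sidecar records `sample_rate_hz`,
#' `channel_ids` and `start_time_ms`.
#'
#' @param x a `trace`.
#' @param path output path for the binary samples (conventionally `.f32`).
#' @param sidecar output path for the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(x, "trace"))
  con <- file(path, "wb")
  on.exit(close(con))
  # channel-major: row i of the matrix is contiguous on disk
  writeBin(as.numeric(t(x$samples)), con, size = 4, endian = "little")
  jsonlite::write_json(list(sample_rate_hz = x$sample_rate_hz,
                            channel_ids = x$channel_ids,
                            start_time_ms = x$start_time_ms),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a float32 binary trace with its JSON sidecar
#'
#' @param path binary file of little-endian float32 samples, channel-major.
#' @param sidecar JSON sidecar with `sample_rate_hz`, `channel_ids`,
#'   `start_time_ms`.
#' @return a `trace`.
#' @export
read_trace <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) stop("config error: sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("sample_rate_hz", "channel_ids", "start_time_ms"))
    if (is.null(meta[[key]]))
      stop("config error: sidecar missing key '", key, "'")
  n_ch <- length(meta$channel_ids)
  n_bytes <- file.info(path)$size
  if (is.na(n_bytes)) stop("format error: cannot stat ", path)
  if (n_bytes %% (4 * n_ch) != 0)
    stop("format error: file size ", n_bytes,
         " is not a multiple of 4 x ", n_ch, " channels")
  n_samp <- n_bytes / (4 * n_ch)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n_ch * n_samp, size = 4,
                 endian = "little")
  if (any(!is.finite(raw))) stop("data error: non-finite samples in ", path)
  samples <- matrix(raw, nrow = n_ch, byrow = TRUE)
  trace(samples, meta$sample_rate_hz, meta$channel_ids, meta$start_time_ms)
}

.schedule_cols <- c("onset_ms", "kind", "freq_khz", "level_db_spl",
                    "duration_ms", "call_id")

#' Construct a stimulus schedule
#'
#' A schedule is the ordered list of stimulus events (tone pips, clicks, or
#' vocalization playbacks) that aligns neural data to stimulation. Events
#' are sorted by onset and must not overlap in time.
#'
#' @param events data.frame with columns `onset_ms`, `kind` (one of
#'   `"tone"`, `"click"`, `"call"`), `freq_khz` (tones only, else `NA`),
#'   `level_db_spl`, `duration_ms`, `call_id` (calls only, else `NA`).
#' @param session_id,animal_id labels carried through to results.
#' @return data.frame of class `schedule` with attributes `session_id` and
#'   `animal_id`.
#' @export
schedule <- function(events, session_id = "session1", animal_id = "animal1") {
  stopifnot(is.data.frame(events))
  missing <- setdiff(.schedule_cols, names(events))
  if (length(missing))
    stop("format error: schedule missing column(s): ",
         paste(missing, collapse = ", "))
  events <- events[, .schedule_cols]
  events$kind <- as.character(events$kind)
  events$call_id <- as.character(events$call_id)
  if (!all(events$kind %in% c("tone", "click", "call")))
    stop("format error: kind must be tone, click or call")
  bad_tone <- events$kind == "tone" &
    (!is.finite(events$freq_khz) | !is.na(events$call_id))
  if (any(bad_tone))
    stop("format error: tone events need freq_khz and no call_id")
  bad_call <- events$kind == "call" &
    (is.na(events$call_id) | is.finite(events$freq_khz))
  if (any(bad_call))
    stop("format error: call events need call_id and no freq_khz")
  if (is.unsorted(events$onset_ms)) {
    warning("schedule events were out of time order; sorting by onset")
    events <- events[order(events$onset_ms), ]
  }
  if (nrow(events) > 1) {
    offsets <- events$onset_ms + events$duration_ms
    if (any(offsets[-nrow(events)] > events$onset_ms[-1] + 1e-9))
      stop("validation error: overlapping stimulus events")
  }
  rownames(events) <- NULL
  structure(events, class = c("schedule", "data.frame"),
            session_id = session_id, animal_id = animal_id)
}

#' Read a stimulus schedule from CSV
#'
#' Expects the header `onset_ms,kind,freq_khz,level_db_spl,duration_ms,call_id`
#' with empty cells where a field does not apply (e.g. `freq_khz` for calls).
#'
#' @param path CSV path.
#' @param session_id,animal_id labels for the returned schedule.
#' @return a `schedule`.
#' @export
read_schedule <- function(path, session_id = "session1",
                          animal_id = "animal1") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(onset_ms = "numeric",
                                       kind = "character",
                                       freq_khz = "numeric",
                                       level_db_spl = "numeric",
                                       duration_ms = "numeric",
                                       call_id = "character"))
  df$call_id[!is.na(df$call_id) & df$call_id == ""] <- NA_character_
  schedule(df, session_id = session_id, animal_id = animal_id)
}

#' Write a stimulus schedule to CSV
#'
#' @param x a `schedule`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(x, path) {
  stopifnot(inherits(x, "schedule"))
  utils::write.csv(as.data.frame(x)[, .schedule_cols], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Construct a sorted-unit spike record
#'
#' @param unit_id,animal_id labels.
#' @param station recording station: `"AN"` (auditory nerve), `"DCN"`
#'   (dorsal cochlear nucleus) or `"ICC"` (central nucleus of the inferior
#'   colliculus).
#' @param spike_times_ms strictly increasing spike times on the session
#'   clock, ms.
#' @param source `"sorted"` (from recordings) or `"simulated"`.
#' @return object of class `unit_spikes`.
#' @export
unit_spikes <- function(unit_id, animal_id, station, spike_times_ms,
                        source = c("sorted", "simulated")) {
  source <- match.arg(source)
  station <- match.arg(station, c("AN", "DCN", "ICC"))
  spike_times_ms <- as.numeric(spike_times_ms)
  if (any(!is.finite(spike_times_ms)))
    stop("data error: non-finite spike times")
  if (is.unsorted(spike_times_ms, strictly = TRUE))
    stop("data error: spike times must be strictly increasing")
  structure(list(unit_id = as.character(unit_id),
                 animal_id = as.character(animal_id),
                 station = station,
                 spike_times_ms = spike_times_ms,
                 source = source),
            class = "unit_spikes")
}

#' @export
print.unit_spikes <- function(x, ...) {
  cat(sprintf("unit_spikes %s (%s, %s): %d spikes, %s\n", x$unit_id,
              x$station, x$animal_id, length(x$spike_times_ms), x$source))
  invisible(x)
}

#' Write unit spike times to a long-format CSV
#'
#' Columns: `unit_id,animal_id,station,spike_time_ms`, one row per spike.
#'
#' @param units list of `unit_spikes`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(units, path) {
  if (inherits(units, "unit_spikes")) units <- list(units)
  rows <- lapply(units, function(u)
    data.frame(unit_id = u$unit_id, animal_id = u$animal_id,
               station = u$station, spike_time_ms = u$spike_times_ms))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read unit spike times from a long-format CSV
#'
#' @param path CSV with columns `unit_id,animal_id,station,spike_time_ms`.
#' @param source provenance label for the returned units.
#' @return named list of `unit_spikes`, one per distinct `unit_id`.
#' @export
read_spikes <- function(path, source = "sorted") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "animal_id", "station", "spike_time_ms")
  if (!all(need %in% names(df)))
    stop("format error: spike CSV needs columns ",
         paste(need, collapse = ", "))
  out <- lapply(split(df, df$unit_id), function(d)
    unit_spikes(d$unit_id[1], d$animal_id[1], d$station[1],
                sort(d$spike_time_ms), source = source))
  out[order(names(out))]
}

#' Write a mono waveform as a float32 WAV file
#'
#' Minimal RIFF writer (IEEE float, format code 3) for stimulus audio at
#' ultrasonic sample rates.
#'
#' @param samples numeric vector in [-1, 1] full scale.
#' @param sample_rate_hz sampling rate in Hz (>= 2.2x the highest stimulus
#'   frequency; stimuli here use 192 kHz or above).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path) {
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + 4 * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(3); w16(1)                       # IEEE float, mono
  w32(round(sample_rate_hz)); w32(round(sample_rate_hz) * 4)
  w16(4); w16(32)
  writeChar("data", con, eos = NULL); w32(4 * n)
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a float32 WAV file written by [write_wav()]
#'
#' @param path WAV path (mono, IEEE float32).
#' @return list with `samples` and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("format error: not a RIFF file")
  r32()
  if (readChar(con, 4) != "WAVE") stop("format error: not a WAVE file")
  if (readChar(con, 4) != "fmt ") stop("format error: missing fmt chunk")
  r32()
  fmt <- r16(); n_ch <- r16(); rate <- r32(); r32(); r16(); bits <- r16()
  if (fmt != 3 || n_ch != 1 || bits != 32)
    stop("format error: only mono float32 WAV supported")
  if (readChar(con, 4) != "data") stop("format error: missing data chunk")
  n_bytes <- r32()
  samples <- readBin(con, "numeric", n = n_bytes / 4, size = 4,
                     endian = "little")
  list(samples = samples, sample_rate_hz = rate)
}
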