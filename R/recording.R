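#' Construct a telemetry recording
#'
#' Container for a multi-channel telemetry session: EEG/EMG in mV, activity
#' in counts, body temperature in degrees C, each with its own sampling rate
#' and a per-sample validity mask. Wall-clock start and the local lights-on
#' time anchor the recording to Zeitgeber time (ZT).
#'
#' @param channels Named list; each element a list with `data` (numeric
#'   vector), `rate` (samples/s, > 0), and optionally `mask` (logical vector,
#'   TRUE = valid; defaults to all valid).
#' @param start Wall-clock start, a `POSIXct` (or anything `as.POSIXct`
#'   accepts).
#' @param lights_on Local clock time of lights-on as `"HH:MM"` (default
#'   `"07:00"`, ZT 0).
#' @param subject Subject identifier.
#' @param meta Optional named list of session metadata.
#'
#' @return An object of class `telemetry_recording`.
#' @export
telemetry_recording <- function(channels, start, lights_on = "07:00",
                                subject = "s1", meta = list()) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("`channels` must be a non-empty named list")
  channels <- lapply(channels, function(ch) {
    if (is.null(ch$data) || is.null(ch$rate))
      stop("each channel needs `data` and `rate`")
    if (!is.numeric(ch$rate) || length(ch$rate) != 1L || ch$rate <= 0)
      stop("channel rate must be a single positive number")
    if (is.null(ch$mask)) ch$mask <- rep(TRUE, length(ch$data))
    if (length(ch$mask) != length(ch$data))
      stop("mask length must equal sample length")
    ch[c("data", "rate", "mask")]
  })
  start <- as.POSIXct(start, tz = "UTC")
  if (length(start) != 1L || is.na(start)) stop("`start` must be a single timestamp")
  parse_clock(lights_on)  # validates
  structure(list(channels = channels, start = start, lights_on = lights_on,
                 subject = subject, meta = meta),
            class = "telemetry_recording")
}

#' @export
print.telemetry_recording <- function(x, ...) {
  cat("<telemetry_recording> subject:", x$subject,
      " start:", format(x$start, "%Y-%m-%d %H:%M:%S"),
      " lights_on:", x$lights_on, "\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-12s %9d samples @ %g/s (%.1f s, %.1f%% valid)\n",
                nm, length(ch$data), ch$rate, length(ch$data) / ch$rate,
                100 * mean(ch$mask)))
  }
  invisible(x)
}

#' Recording duration in seconds
#'
#' The duration implied by the longest channel (samples / rate). Sample i of
#' a channel covers the half-open interval `[i/rate, (i+1)/rate)` seconds
#' from `start`.
#'
#' @param rec A [telemetry_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "telemetry_recording"))
  max(vapply(rec$channels, function(ch) length(ch$data) / ch$rate, 0))
}

# "HH:MM" -> fractional hours
parse_clock <- function(x) {
  if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    return(lt$hour + lt$min / 60 + lt$sec / 3600)
  }
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) stop("clock time must be 'HH:MM', got: ", x)
  h <- as.numeric(m[2]); mi <- as.numeric(m[3])
  if (h >= 24 || mi >= 60) stop("invalid clock time: ", x)
  h + mi / 60
}

# local clock hours of `start + t_s seconds`
clock_hours_at <- function(start, t_s) {
  lt <- as.POSIXlt(start)
  h0 <- lt$hour + lt$min / 60 + lt$sec / 3600
  (h0 + t_s / 3600) %% 24
}

#' Align recording times to Zeitgeber time
#'
#' ZT is hours since lights-on: `zt(t) = ((clock(t) - lights_on) mod 24)`.
#' ZT 0--12 is the light (resting) phase for mice, ZT 12--24 the dark
#' (active) phase.
#'
#' @param rec A [telemetry_recording()], or a `POSIXct` start if `t_s` is
#'   given with an explicit `lights_on`.
#' @param t_s Offsets in seconds from the recording start for which to
#'   compute ZT. Defaults to one value per second of the recording.
#' @return A data.frame with columns `t_s`, `zt` (hours in `[0, 24)`) and
#'   `day` (logical; TRUE iff `zt < 12`).
#' @export
zt_align <- function(rec, t_s = NULL) {
  stopifnot(inherits(rec, "telemetry_recording"))
  if (is.null(t_s)) t_s <- seq(0, floor(recording_duration(rec)) - 1)
  zt <- zt_of(rec$start, rec$lights_on, t_s)
  data.frame(t_s = t_s, zt = zt, day = zt < 12)
}

zt_of <- function(start, lights_on, t_s) {
  (clock_hours_at(start, t_s) - parse_clock(lights_on)) %% 24
}
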