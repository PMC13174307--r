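#' Mask out-of-range artifact samples
#'
#' Samples outside physiological range are masked invalid but never
#' deleted, so downstream bin averages can use valid samples only. EEG/EMG
#' samples with |x| > 2 mV, activity samples below 0 counts, and
#' temperature samples at or below 25 degrees C are masked, matching the
#' telemetry noise thresholds. Channels are matched by name (`EEG*`/`EMG*`,
#' `activity`, `temperature`); a missing channel is skipped with a message.
#'
#' @param rec A [telemetry_recording()].
#' @param eeg_emg_limit Absolute EEG/EMG limit, mV (default 2).
#' @param activity_floor Activity floor, counts; values strictly below are
#'   masked (default 0).
#' @param temp_floor Temperature floor, degrees C; values at or below are
#'   masked (default 25).
#' @return A list: `recording` (with updated masks) and `masked`, a named
#'   integer vector of newly masked sample counts per channel.
#' @export
clip_artifacts <- function(rec, eeg_emg_limit = 2, activity_floor = 0,
                           temp_floor = 25) {
  stopifnot(inherits(rec, "telemetry_recording"))
  masked <- integer(0)
  for (nm in names(rec$channels)) {
    ch <- rec$channels[[nm]]
    bad <- if (grepl("^(EEG|EMG)", nm, ignore.case = TRUE)) {
      abs(ch$data) > eeg_emg_limit
    } else if (grepl("^activity", nm, ignore.case = TRUE)) {
      ch$data < activity_floor
    } else if (grepl("^temp", nm, ignore.case = TRUE)) {
      ch$data <= temp_floor
    } else {
      message("clip_artifacts: no rule for channel '", nm, "'; skipped")
      next
    }
    newly <- bad & ch$mask
    masked[nm] <- sum(newly)
    rec$channels[[nm]]$mask <- ch$mask & !bad
  }
  list(recording = rec, masked = masked)
}

#' Merge recordings from the same subject
#'
#' Concatenates recordings separated by stops (e.g. days split by a
#' treatment) on a common wall-clock axis. Inter-part gaps are filled with
#' masked-invalid zero samples, so the total valid duration equals the sum
#' of the parts' valid durations. Parts must share subject and channel
#' schema (names and rates) and must not overlap in wall-clock time.
#'
#' @param parts List of [telemetry_recording()]s (any order; sorted by
#'   start).
#' @return A single merged [telemetry_recording()].
#' @export
merge_recordings <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  if (length(parts) == 1L) return(parts[[1]])
  ord <- order(vapply(parts, function(p) as.numeric(p$start), 0))
  parts <- parts[ord]
  p1 <- parts[[1]]
  schema <- lapply(p1$channels, `[[`, "rate")
  for (p in parts[-1]) {
    if (!identical(p$subject, p1$subject))
      stop("cannot merge recordings from different subjects")
    if (!identical(lapply(p$channels, `[[`, "rate"), schema))
      stop("channel schema mismatch between parts")
  }
  starts <- vapply(parts, function(p) as.numeric(p$start), 0)
  ends <- starts + vapply(parts, recording_duration, 0)
  if (any(starts[-1] < ends[-length(ends)] - 1e-9))
    stop("parts overlap in wall-clock time; cannot merge")

  total_s <- ends[length(ends)] - starts[1]
  channels <- list()
  for (nm in names(p1$channels)) {
    rate <- schema[[nm]]
    n_total <- round(total_s * rate)
    data <- numeric(n_total)
    mask <- logical(n_total)
    for (p in parts) {
      off <- round((as.numeric(p$start) - starts[1]) * rate)
      ch <- p$channels[[nm]]
      idx <- off + seq_along(ch$data)
      data[idx] <- ch$data
      mask[idx] <- ch$mask
    }
    channels[[nm]] <- list(data = data, rate = rate, mask = mask)
  }
  telemetry_recording(channels, start = p1$start, lights_on = p1$lights_on,
                      subject = p1$subject,
                      meta = list(merged_parts = length(parts)))
}
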