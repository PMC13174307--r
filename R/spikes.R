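#' High-pass filter EEG for spike detection
#'
#' Linear-phase FIR high-pass with passband edge 6.3 Hz and a 5.0-Hz-wide
#' transition band (stopband edge 1.3 Hz), Kaiser-window design with at
#' least 60 dB stopband attenuation. The filter is applied zero-phase
#' (centered convolution), so events keep their timestamps; the first and
#' last half-filter-length samples are zeroed.
#'
#' @param x EEG samples (mV).
#' @param fs Sampling rate, samples/s.
#' @param passband Passband edge, Hz (default 6.3).
#' @param transition Transition band width, Hz (default 5.0).
#' @return Filtered samples, same length as `x`.
#' @name highpass_eeg
NULL

# Kaiser-window FIR design shared by the filter and the spike generator
highpass_kernel <- function(fs, passband = 6.3, transition = 5.0) {
  atten <- 60
  beta <- 0.1102 * (atten - 8.7)
  dw <- 2 * pi * transition / fs
  n <- ceiling((atten - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1  # even order -> odd-length type-I filter
  cutoff <- passband - transition / 2
  signal::fir1(n, cutoff / (fs / 2), type = "high",
               window = signal::kaiser(n + 1, beta))
}

#' @rdname highpass_eeg
#' @export
highpass_eeg <- function(x, fs, passband = 6.3, transition = 5.0) {
  h <- highpass_kernel(fs, passband, transition)
  y <- stats::filter(x, h, method = "convolution", sides = 2)
  y[is.na(y)] <- 0
  as.numeric(y)
}

#' Estimate the baseline SD for spike detection
#'
#' The recording is split into thirds; within each third the candidate
#' 2-min window minimizing the 99th percentile of |signal| is chosen
#' (automating the manual "little to no spikes" selection), and the
#' baseline SD is the mean of the three window SDs.
#'
#' @param x High-passed EEG samples (mV).
#' @param fs Sampling rate, samples/s.
#' @param mask Optional validity mask; windows with under 99% valid
#'   samples are not candidates.
#' @param window_s Window length, s (default 120).
#' @param step_s Candidate window step, s (default 30).
#' @return A list of class `baseline_estimate`: `sd` (mV), and `windows`,
#'   a data.frame of the three chosen windows (`third`, `start_s`, `sd`,
#'   `p99`).
#' @export
estimate_baseline_sd <- function(x, fs, mask = NULL, window_s = 120,
                                 step_s = 30) {
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  if (sum(mask) < 3 * window_s * fs)
    stop("need at least ", 3 * window_s, " s of valid signal")
  n <- length(x)
  wn <- round(window_s * fs)
  thirds <- floor(seq(0, n, length.out = 4))
  rows <- list()
  for (th in 1:3) {
    lo <- thirds[th] + 1L; hi <- thirds[th + 1]
    starts <- seq(lo, hi - wn + 1L, by = round(step_s * fs))
    best <- NULL
    for (s0 in starts) {
      idx <- s0:(s0 + wn - 1L)
      if (mean(mask[idx]) < 0.99) next
      p99 <- stats::quantile(abs(x[idx]), 0.99, names = FALSE)
      if (is.null(best) || p99 < best$p99)
        best <- list(start_s = (s0 - 1) / fs, p99 = p99,
                     sd = stats::sd(x[idx][mask[idx]]))
    }
    if (is.null(best))
      stop("third ", th, " has no 2-min window with enough valid signal")
    rows[[th]] <- data.frame(third = th, start_s = best$start_s,
                             sd = best$sd, p99 = best$p99)
  }
  windows <- do.call(rbind, rows)
  sd_hat <- mean(windows$sd)
  if (sd_hat == 0) stop("degenerate (constant) signal: baseline SD is 0")
  structure(list(sd = sd_hat, windows = windows),
            class = "baseline_estimate")
}

#' Detect epileptiform spikes
#'
#' Candidate events are maximal runs where the high-passed signal exceeds
#' `k` times the baseline SD in absolute value; runs separated by less
#' than `merge_gap_ms` are merged. Event duration is measured between the
#' crossings of `k/2` times the SD around the peak, and events outside the
#' 5--80 ms duration gate are rejected. A sharpness gate (|peak| / duration
#' above `slope_floor`) stands in for template/shape matching. Events
#' overlapping masked-invalid samples are rejected, and an event starting
#' within `refractory_ms` of an accepted event is treated as a rebound
#' lobe of the same discharge (the high-pass filter turns a slow transient
#' into an oscillatory one) and dropped. The detector has no randomness
#' and is translation-equivariant.
#'
#' @param x High-passed EEG samples (mV), e.g. from [highpass_eeg()].
#' @param fs Sampling rate, samples/s.
#' @param baseline A [estimate_baseline_sd()] result (or a single SD in
#'   mV).
#' @param k Detection threshold in baseline SDs (default 10).
#' @param dur_range Accepted event duration range, ms (default 5--80).
#' @param merge_gap_ms Runs closer than this are merged, ms (default 5).
#' @param slope_floor Minimum |peak| / duration sharpness, mV/ms
#'   (default 0, i.e. disabled).
#' @param refractory_ms Events starting within this window after an
#'   accepted event are dropped as rebounds, ms (default 100).
#' @param mask Optional validity mask.
#' @return A data.frame of events sorted by onset: `onset_s`, `duration_ms`,
#'   `peak_mV` (signed), `threshold_mV`.
#' @export
detect_spikes <- function(x, fs, baseline, k = 10, dur_range = c(5, 80),
                          merge_gap_ms = 5, slope_floor = 0,
                          refractory_ms = 100, mask = NULL) {
  sd_b <- if (inherits(baseline, "baseline_estimate")) baseline$sd
          else as.numeric(baseline)
  if (sd_b <= 0) stop("baseline SD must be > 0")
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  thr <- k * sd_b
  half <- thr / 2
  empty <- data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                      peak_mV = numeric(0), threshold_mV = numeric(0))
  above <- abs(x) > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < merge_gap_ms
  gap_n <- merge_gap_ms / 1000 * fs
  if (nrow(runs) > 1L) {
    keep_start <- c(TRUE, runs[-1, "start"] - runs[-nrow(runs), "end"] >= gap_n)
    grp <- cumsum(keep_start)
    runs <- cbind(start = tapply(runs[, "start"], grp, min),
                  end = tapply(runs[, "end"], grp, max))
  }
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, "start"]; b <- runs[i, "end"]
    pk <- a - 1L + which.max(abs(x[a:b]))
    # expand to the half-threshold crossings around the peak
    L <- pk; while (L > 1L && abs(x[L - 1L]) > half) L <- L - 1L
    R <- pk; while (R < length(x) && abs(x[R + 1L]) > half) R <- R + 1L
    dur_ms <- (R - L + 1L) / fs * 1000
    if (dur_ms < dur_range[1] || dur_ms > dur_range[2]) next
    if (abs(x[pk]) / dur_ms < slope_floor) next
    if (any(!mask[L:R])) next
    out[[i]] <- data.frame(onset_s = (L - 1L) / fs, duration_ms = dur_ms,
                           peak_mV = x[pk], threshold_mV = thr)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty)
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  if (refractory_ms > 0 && nrow(ev) > 1L) {
    # cluster events closer than the refractory window and keep the
    # largest-amplitude member (the main lobe; the rest are ringing)
    cl <- cumsum(c(TRUE, diff(ev$onset_s) >= refractory_ms / 1000))
    keep <- vapply(split(seq_len(nrow(ev)), cl),
                   function(ii) ii[which.max(abs(ev$peak_mV[ii]))],
                   integer(1))
    ev <- ev[sort(keep), , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Spike counts per 1-min and 15-min bins
#'
#' Integer event counts per 1-min bin over the recording span; 15-min bins
#' are the mean of their 1-min bins (multi-day circadian averaging is done
#' by [circadian_profile()]).
#'
#' @param events Event data.frame with an `onset_s` column, sorted.
#' @param duration_s Recording duration, s.
#' @return A list: `minute` (data.frame `t_s`, `count`) and `quarter`
#'   (data.frame `t_s`, `mean_count`, mean of the 15 one-min bins).
#' @export
spike_rate_series <- function(events, duration_s) {
  n_min <- ceiling(duration_s / 60)
  counts <- tabulate(pmin(floor(events$onset_s / 60), n_min - 1) + 1L, n_min)
  minute <- data.frame(t_s = (seq_len(n_min) - 1) * 60, count = counts)
  q <- floor(minute$t_s / 900)
  quarter <- data.frame(t_s = sort(unique(q)) * 900,
                        mean_count = as.numeric(
                          tapply(minute$count, q, mean)))
  list(minute = minute, quarter = quarter)
}
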