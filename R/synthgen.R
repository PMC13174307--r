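#' Generate a synthetic hypnogram
#'
#' Simulates a Markov chain over (Wake, NREM, REM) at the 5-s staging epoch.
#' The transition matrix is selected per epoch by the Zeitgeber time of the
#' epoch start: the day matrix while lights are on (ZT < 12), the night
#' matrix otherwise. Deterministic given `cfg$seed`.
#'
#' @param cfg A [gen_config()].
#' @return A data.frame with one row per 5-s epoch: `epoch`, `t_s` (epoch
#'   start, s from recording start), `zt`, `day`, `state`.
#' @export
generate_hypnogram <- function(cfg) {
  validate_gen_config(cfg)
  n <- cfg$duration / EPOCH_S
  t_s <- (seq_len(n) - 1) * EPOCH_S
  zt <- zt_of(cfg$start, cfg$lights_on, t_s)
  day <- zt < 12
  set.seed(cfg$seed)
  u <- stats::runif(n)
  state <- integer(n)
  state[1] <- 1L  # start awake
  Pd <- cfg$sleep_transition_day
  Pn <- cfg$sleep_transition_night
  cd <- t(apply(Pd, 1, cumsum))
  cn <- t(apply(Pn, 1, cumsum))
  for (i in seq_len(n - 1L)) {
    cm <- if (day[i]) cd else cn
    state[i + 1L] <- findInterval(u[i], cm[state[i], ], left.open = TRUE) + 1L
  }
  data.frame(epoch = seq_len(n), t_s = t_s, zt = zt, day = day,
             state = factor(STATES[state], levels = STATES))
}

# 1/f^chi colored noise by spectral shaping of white noise. The amplitude
# response follows f^(-chi/2) over [1, 100] Hz and is held flat below 1 Hz
# (avoids low-frequency divergence) and above 100 Hz; output scaled to
# `rms`.
colored_noise <- function(n, fs, chi, rms) {
  if (n == 0L) return(numeric(0))
  w <- stats::rnorm(n)
  if (rms == 0) return(numeric(n))
  X <- stats::fft(w)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  fa <- pmin(pmax(abs(f), 1), 100)
  X <- X * fa^(-chi / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (rms / s)
}

#' Synthesize EEG and EMG signals from a hypnogram
#'
#' EEG per state = 1/f^chi colored-noise background (state-dependent
#' exponent and RMS) plus sinusoidal band components at the delta (3.25 Hz),
#' theta (9 Hz), and gamma (55 Hz) band centers with state-dependent
#' amplitudes and random phase per state run. EMG = white noise scaled so
#' its rectified mean equals the state's configured level. REM defaults put
#' the theta:delta epoch amplitude ratio well above 1 with EMG below the REM
#' threshold. Deterministic given `cfg$seed`.
#'
#' @param hypnogram Output of [generate_hypnogram()].
#' @param cfg A [gen_config()].
#' @return A [telemetry_recording()] with `EEG` and `EMG` channels (mV).
#' @export
synthesize_signals <- function(hypnogram, cfg) {
  validate_gen_config(cfg)
  if (nrow(hypnogram) == 0L) stop("hypnogram is empty; refusing to synthesize")
  if (!all(as.character(hypnogram$state) %in% STATES))
    stop("unknown state label in hypnogram")
  fs <- cfg$eeg_fs
  spe <- EPOCH_S * fs  # samples per epoch
  n_total <- nrow(hypnogram) * spe
  eeg <- numeric(n_total)
  emg <- numeric(n_total)
  set.seed(cfg$seed + 1L)
  st <- as.character(hypnogram$state)
  runs <- rle(st)
  pos <- 0L
  for (r in seq_along(runs$lengths)) {
    state <- runs$values[r]
    n <- runs$lengths[r] * spe
    idx <- pos + seq_len(n)
    bg <- colored_noise(n, fs, cfg$aperiodic_exponent_by_state[[state]],
                        cfg$background_rms_by_state[[state]])
    x <- bg
    amps <- cfg$band_amplitudes_by_state[[state]]
    tt <- (pos + seq_len(n) - 1) / fs
    for (b in names(amps)) {
      if (amps[[b]] > 0)
        x <- x + amps[[b]] *
          sin(2 * pi * BAND_CENTERS[[b]] * tt + stats::runif(1, 0, 2 * pi))
    }
    eeg[idx] <- x
    lvl <- cfg$emg_level_by_state[[state]]
    emg[idx] <- stats::rnorm(n, sd = lvl * sqrt(pi / 2))  # E|X| = lvl
    pos <- pos + n
  }
  telemetry_recording(
    channels = list(EEG = list(data = eeg, rate = fs),
                    EMG = list(data = emg, rate = fs)),
    start = cfg$start, lights_on = cfg$lights_on,
    meta = list(generator = "synthetic", seed = cfg$seed))
}

# Biphasic difference-of-Gaussians spike template: a dominant sharp
# deflection preceded by a smaller (0.3x) opposite-polarity wave, as in
# interictal discharges. Peak-normalized; the width of the main lobe above
# 0.4 x peak (the detector's half-threshold for a 12x-SD spike against a
# 10x-SD threshold) is calibrated to equal `dur_ms`.
.dog_shape <- function(tt, sigma) {
  exp(-(tt - sigma)^2 / (2 * sigma^2)) -
    0.3 * exp(-(tt + sigma)^2 / (2 * sigma^2))
}

.dog_calib <- local({
  val <- NULL
  function() {
    if (!is.null(val)) return(val)
    tt <- seq(-8, 8, by = 0.001)
    s <- .dog_shape(tt, 1)
    s <- s / max(abs(s))
    pk <- which.max(abs(s))
    L <- pk; while (L > 1L && abs(s[L - 1L]) > 0.4) L <- L - 1L
    R <- pk; while (R < length(s) && abs(s[R + 1L]) > 0.4) R <- R + 1L
    # main-lobe width and left crossing, in sigma units from the center
    val <<- list(width = tt[R] - tt[L], left = tt[L])
    val
  }
})

# template sampled on [-4 sigma, 4 sigma]; `onset_offset_s` is the time of
# the main lobe's left half-threshold crossing relative to the first sample
spike_template <- function(dur_ms, fs) {
  cal <- .dog_calib()
  sigma_s <- (dur_ms / 1000) / cal$width
  half <- 4 * sigma_s
  tt <- seq(-half, half, by = 1 / fs)
  s <- .dog_shape(tt, sigma_s)
  list(shape = s / max(abs(s)),
       onset_offset_s = half + cal$left * sigma_s)
}

#' Inject epileptiform spikes into a synthetic recording
#'
#' Spikes are drawn as an inhomogeneous Poisson process with a
#' state-dependent rate. Each spike is a biphasic difference-of-Gaussians
#' transient with random polarity and duration uniform in
#' `cfg$spike_duration_range`. Amplitude is defined on the scale the
#' detector operates on: each template is scaled so that its high-passed
#' (6.3 Hz) peak equals `cfg$spike_amplitude_multiple` times the SD of the
#' high-passed background EEG (the filter attenuates slow transients, so
#' the compensation keeps the multiple uniform across durations). Events
#' are thinned to a minimum separation of 250 ms so
#' that ground truth remains unambiguous. Deterministic given `cfg$seed`.
#'
#' @param rec A [telemetry_recording()] with an `EEG` channel.
#' @param hypnogram Matching [generate_hypnogram()] output.
#' @param cfg A [gen_config()].
#' @return A list: `recording` (spikes added to EEG) and `truth`, a
#'   data.frame of ground-truth events (`onset_s`, `duration_ms`,
#'   `amplitude_mV` signed, `state`).
#' @export
inject_spikes <- function(rec, hypnogram, cfg) {
  validate_gen_config(cfg)
  if (is.null(rec$channels$EEG)) stop("recording has no EEG channel")
  if (any(cfg$spike_rate_by_state < 0)) stop("negative spike rate")
  fs <- rec$channels$EEG$rate
  eeg <- rec$channels$EEG$data
  truth0 <- data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                       amplitude_mV = numeric(0),
                       state = character(0))
  if (all(cfg$spike_rate_by_state == 0))
    return(list(recording = rec, truth = truth0))
  sd_bg <- stats::sd(highpass_eeg(eeg, fs))
  amp <- cfg$spike_amplitude_multiple * sd_bg

  set.seed(cfg$seed + 2L)
  st <- as.character(hypnogram$state)
  lambda <- cfg$spike_rate_by_state[st] / 60 * EPOCH_S  # expected per epoch
  counts <- stats::rpois(length(lambda), lambda)
  onsets <- numeric(0); states <- character(0)
  has <- which(counts > 0)
  for (i in has) {
    o <- hypnogram$t_s[i] + sort(stats::runif(counts[i], 0, EPOCH_S))
    onsets <- c(onsets, o)
    states <- c(states, rep(st[i], counts[i]))
  }
  if (length(onsets)) {
    keep <- c(TRUE, diff(onsets) > 0.25)  # thin to >= 250 ms separation
    onsets <- onsets[keep]; states <- states[keep]
  }
  n_ev <- length(onsets)
  if (n_ev == 0L) return(list(recording = rec, truth = truth0))
  durs <- stats::runif(n_ev, cfg$spike_duration_range[1],
                       cfg$spike_duration_range[2])
  pol <- sample(c(-1, 1), n_ev, replace = TRUE)
  hk <- highpass_kernel(fs)
  for (j in seq_len(n_ev)) {
    tp <- spike_template(durs[j], fs)
    # the amplitude multiple is defined on the detection scale (the
    # high-passed channel): compensate the filter's attenuation of the
    # template so the filtered peak equals multiple x background SD
    att <- max(abs(stats::convolve(tp$shape, rev(hk), type = "open")))
    tpl <- tp$shape * (amp / att) * pol[j]
    # place so the main lobe's half-threshold crossing sits at the onset
    i0 <- round((onsets[j] - tp$onset_offset_s) * fs) + 1L
    idx <- i0 + seq_along(tpl) - 1L
    ok <- idx >= 1L & idx <= length(eeg)
    eeg[idx[ok]] <- eeg[idx[ok]] + tpl[ok]
  }
  rec$channels$EEG$data <- eeg
  truth <- data.frame(onset_s = onsets, duration_ms = durs,
                      amplitude_mV = amp * pol, state = states)
  list(recording = rec, truth = truth[order(truth$onset_s), ])
}

#' Generate activity and temperature channels
#'
#' Activity is a non-negative Poisson count channel at the EEG rate whose
#' per-minute mean is the configured day/night Wake rate, scaled by 0.05 in
#' sleep states (Wake >> sleep). Temperature at `temp_fs` is the configured
#' mean plus a circadian sinusoid peaking in the dark phase (ZT 18) plus
#' Gaussian noise. Deterministic given `cfg$seed`.
#'
#' @inheritParams inject_spikes
#' @return A list of two channels (`activity`, `temperature`) in the
#'   [telemetry_recording()] channel format.
#' @export
generate_activity_temperature <- function(hypnogram, cfg) {
  validate_gen_config(cfg)
  fs <- cfg$eeg_fs
  set.seed(cfg$seed + 3L)
  st <- as.character(hypnogram$state)
  state_fac <- c(Wake = 1, NREM = 0.05, REM = 0.05)[st]
  per_min <- ifelse(hypnogram$day, cfg$locomotion_day_mean,
                    cfg$locomotion_night_mean) * state_fac
  lam_per_sample <- rep(per_min / (60 * fs), each = EPOCH_S * fs)
  activity <- stats::rpois(length(lam_per_sample), lam_per_sample)

  n_temp <- cfg$duration * cfg$temp_fs
  tt <- (seq_len(n_temp) - 1) / cfg$temp_fs
  ztt <- zt_of(cfg$start, cfg$lights_on, tt)
  temperature <- cfg$temperature_mean +
    cfg$temperature_circadian_amplitude * cos(2 * pi * (ztt - 18) / 24) +
    stats::rnorm(n_temp, sd = cfg$temperature_noise_sd)
  list(activity = list(data = as.numeric(activity), rate = fs,
                       mask = rep(TRUE, length(activity))),
       temperature = list(data = temperature, rate = cfg$temp_fs,
                          mask = rep(TRUE, n_temp)))
}

#' Simulate a full telemetry recording with ground truth
#'
#' Convenience wrapper chaining [generate_hypnogram()],
#' [synthesize_signals()], [generate_activity_temperature()] and
#' [inject_spikes()].
#'
#' @param cfg A [gen_config()].
#' @return A list: `recording` (EEG, EMG, activity, temperature channels)
#'   and `truth` (list with `hypnogram` and `spikes`).
#' @export
simulate_recording <- function(cfg) {
  hyp <- generate_hypnogram(cfg)
  rec <- synthesize_signals(hyp, cfg)
  at <- generate_activity_temperature(hyp, cfg)
  rec$channels$activity <- at$activity
  rec$channels$temperature <- at$temperature
  inj <- inject_spikes(rec, hyp, cfg)
  list(recording = inj$recording,
       truth = list(hypnogram = hyp, spikes = inj$truth))
}
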