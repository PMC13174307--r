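#' Rule-based staging thresholds
#'
#' Threshold set for Wake/NREM/REM staging at 5-s epochs, in mV on the
#' epoch feature scale (RMS amplitudes for EEG/delta/theta, rectified mean
#' for EMG): REM if theta:delta > `rem_td_min` and EMG < `rem_emg_max`;
#' else NREM if EEG RMS > `nrem_eeg_min`, delta RMS > `nrem_delta_min` and
#' EMG < `nrem_emg_max`; else Wake.
#'
#' @param rem_td_min REM theta:delta ratio threshold (default 1.0).
#' @param rem_emg_max REM EMG ceiling, mV (default 0.011).
#' @param nrem_eeg_min NREM EEG RMS floor, mV (default 0.035).
#' @param nrem_delta_min NREM delta RMS floor, mV (default 0.022).
#' @param nrem_emg_max NREM EMG ceiling, mV (default 0.007).
#' @param epoch_s Epoch length, s (default 5).
#' @return A list of class `staging_thresholds`.
#' @export
staging_thresholds <- function(rem_td_min = 1.0, rem_emg_max = 0.011,
                               nrem_eeg_min = 0.035, nrem_delta_min = 0.022,
                               nrem_emg_max = 0.007, epoch_s = 5) {
  th <- list(rem_td_min = rem_td_min, rem_emg_max = rem_emg_max,
             nrem_eeg_min = nrem_eeg_min, nrem_delta_min = nrem_delta_min,
             nrem_emg_max = nrem_emg_max, epoch_s = epoch_s)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive")
  if (th$rem_emg_max <= th$nrem_emg_max)
    stop("rem_emg_max must exceed nrem_emg_max")
  structure(th, class = "staging_thresholds")
}

#' Per-epoch staging features
#'
#' Computes, per 5-s epoch: EEG RMS; delta (1.5--5 Hz) and theta (6--12 Hz)
#' component RMS amplitudes from zero-phase band-pass filtering;
#' theta:delta ratio; rectified-mean EMG; and the valid-sample fraction.
#' Epochs with under 50% valid samples get `NA` features and
#' `valid = FALSE`.
#'
#' @param rec A [telemetry_recording()] with `EEG` and `EMG` channels, or
#'   an EEG vector (then `emg` and `fs` are required).
#' @param emg EMG samples (mV) when `rec` is a vector.
#' @param fs Sampling rate when `rec` is a vector.
#' @param epoch_s Epoch length, s (default 5).
#' @return A data.frame, one row per epoch: `epoch`, `t_s`, `eeg_rms`,
#'   `delta_amp`, `theta_amp`, `td_ratio`, `emg_rect_mean`, `valid_frac`,
#'   `valid`.
#' @export
epoch_features <- function(rec, emg = NULL, fs = NULL, epoch_s = 5) {
  if (inherits(rec, "telemetry_recording")) {
    if (is.null(rec$channels$EEG) || is.null(rec$channels$EMG))
      stop("recording needs EEG and EMG channels")
    fs <- rec$channels$EEG$rate
    eeg <- rec$channels$EEG$data
    emg_x <- rec$channels$EMG$data
    m_eeg <- rec$channels$EEG$mask
    m_emg <- rec$channels$EMG$mask
  } else {
    eeg <- rec; emg_x <- emg
    if (is.null(emg_x) || is.null(fs)) stop("need `emg` and `fs`")
    m_eeg <- rep(TRUE, length(eeg)); m_emg <- rep(TRUE, length(emg_x))
  }
  spe <- round(epoch_s * fs)
  n_ep <- floor(length(eeg) / spe)
  if (n_ep < 1L) stop("signal shorter than one epoch")
  bp <- function(x, lo, hi) {
    bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
    signal::filtfilt(bf, x)
  }
  delta <- bp(eeg, 1.5, 5)
  theta <- bp(eeg, 6, 12)
  ep_fun <- function(x, f) {
    apply(matrix(x[seq_len(n_ep * spe)], nrow = spe), 2, f)
  }
  rms_valid <- function(x) sqrt(mean(x^2))
  eeg_rms <- ep_fun(eeg, rms_valid)
  delta_amp <- ep_fun(delta, rms_valid)
  theta_amp <- ep_fun(theta, rms_valid)
  emg_rect <- ep_fun(emg_x[seq_len(n_ep * spe)], function(x) mean(abs(x)))
  vf <- pmin(ep_fun(as.numeric(m_eeg), mean), ep_fun(as.numeric(m_emg), mean))
  valid <- vf >= 0.5
  out <- data.frame(epoch = seq_len(n_ep), t_s = (seq_len(n_ep) - 1) * epoch_s,
                    eeg_rms = eeg_rms, delta_amp = delta_amp,
                    theta_amp = theta_amp,
                    td_ratio = ifelse(delta_amp > 0, theta_amp / delta_amp, NA),
                    emg_rect_mean = emg_rect, valid_frac = vf, valid = valid)
  out[!valid, c("eeg_rms", "delta_amp", "theta_amp", "td_ratio",
                "emg_rect_mean")] <- NA
  out
}

#' Stage epochs into Wake/NREM/REM
#'
#' Deterministic rule cascade per epoch: REM if `td_ratio > rem_td_min` and
#' `emg < rem_emg_max`; else NREM if `eeg_rms > nrem_eeg_min`,
#' `delta_amp > nrem_delta_min` and `emg < nrem_emg_max`; else Wake.
#' Invalid-feature epochs copy the previous label (the first epoch
#' defaults to Wake).
#'
#' @param features Output of [epoch_features()].
#' @param thresholds A [staging_thresholds()].
#' @param start,lights_on Optional wall-clock start and lights-on time; if
#'   given, `zt` and `day` columns are attached.
#' @return A hypnogram data.frame: `epoch`, `t_s`, `state` (factor
#'   Wake/NREM/REM), and optionally `zt`, `day`.
#' @export
stage_epochs <- function(features, thresholds = staging_thresholds(),
                         start = NULL, lights_on = "07:00") {
  n <- nrow(features)
  state <- character(n)
  for (i in seq_len(n)) {
    f <- features[i, ]
    if (!isTRUE(f$valid) || is.na(f$emg_rect_mean)) {
      state[i] <- if (i == 1L) "Wake" else state[i - 1L]
    } else if (!is.na(f$td_ratio) && f$td_ratio > thresholds$rem_td_min &&
               f$emg_rect_mean < thresholds$rem_emg_max) {
      state[i] <- "REM"
    } else if (f$eeg_rms > thresholds$nrem_eeg_min &&
               f$delta_amp > thresholds$nrem_delta_min &&
               f$emg_rect_mean < thresholds$nrem_emg_max) {
      state[i] <- "NREM"
    } else {
      state[i] <- "Wake"
    }
  }
  out <- data.frame(epoch = features$epoch, t_s = features$t_s,
                    state = factor(state, levels = STATES))
  if (!is.null(start)) {
    out$zt <- zt_of(as.POSIXct(start, tz = "UTC"), lights_on, out$t_s)
    out$day <- out$zt < 12
  }
  out
}

transition_types <- function(from, to) {
  lab <- rep(NA_character_, length(from))
  lab[from == "Wake" & to %in% c("NREM", "REM")] <- "Wake->Sleep"
  lab[from %in% c("NREM", "REM") & to == "Wake"] <- "Sleep->Wake"
  lab2 <- paste0(from, "->", to)
  list(pooled = lab, specific = ifelse(from == to, NA, lab2))
}

#' Count sleep-stage transitions by day and night
#'
#' A transition is any change of label between consecutive epochs.
#' `Wake->Sleep` pools entries into REM and NREM, `Sleep->Wake` pools exits
#' from both; specific pairs (REM->NREM, NREM->REM, Wake->REM, REM->Wake,
#' ...) are counted separately. Transitions are attributed to the phase
#' (day/night) of their first epoch, counted per recording day, and
#' averaged across days.
#'
#' @param hyp Hypnogram data.frame with `t_s`, `state`, and `day` columns
#'   (see [stage_epochs()] with `start`, or [generate_hypnogram()]).
#' @return A data.frame: `phase` (day/night), `transition`, `total`,
#'   `mean_per_day`.
#' @export
count_transitions <- function(hyp) {
  if (nrow(hyp) == 0L) stop("hypnogram is empty")
  if (is.null(hyp$day)) stop("hypnogram needs a `day` column")
  n <- nrow(hyp)
  if (n < 2L)
    return(data.frame(phase = character(0), transition = character(0),
                      total = integer(0), mean_per_day = numeric(0)))
  from <- as.character(hyp$state[-n]); to <- as.character(hyp$state[-1])
  phase <- ifelse(hyp$day[-n], "day", "night")
  rec_day <- floor(hyp$t_s[-n] / 86400)
  tt <- transition_types(from, to)
  labs <- c("Wake->Sleep", "Sleep->Wake", "NREM->REM", "REM->NREM",
            "Wake->REM", "REM->Wake", "Wake->NREM", "NREM->Wake")
  n_days <- length(unique(rec_day))
  rows <- list()
  for (ph in c("day", "night")) {
    for (lb in labs) {
      hits <- phase == ph &
        (if (lb %in% c("Wake->Sleep", "Sleep->Wake")) !is.na(tt$pooled) & tt$pooled == lb
         else !is.na(tt$specific) & tt$specific == lb)
      rows[[paste(ph, lb)]] <- data.frame(
        phase = ph, transition = lb, total = sum(hits),
        mean_per_day = sum(hits) / n_days)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-stage bout metrics
#'
#' A bout is a maximal run of one label; its duration is the run length
#' times the epoch length. Metrics are reported overall (`phase = "all"`)
#' and per day/night phase when the hypnogram carries a `day` column
#' (bouts attributed to the phase of their first epoch).
#'
#' @param hyp Hypnogram data.frame with `state` (and optionally `day`).
#' @param epoch_s Epoch length, s (default 5).
#' @return A data.frame: `phase`, `stage`, `n_bouts`, `mean_bout_s`,
#'   `total_s`.
#' @export
bout_metrics <- function(hyp, epoch_s = 5) {
  if (nrow(hyp) == 0L) stop("hypnogram is empty")
  st <- as.character(hyp$state)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bouts <- data.frame(stage = r$values, dur_s = r$lengths * epoch_s,
                      start_epoch = starts)
  mk <- function(b, phase) {
    if (nrow(b) == 0L)
      return(data.frame(phase = character(0), stage = character(0),
                        n_bouts = integer(0), mean_bout_s = numeric(0),
                        total_s = numeric(0)))
    agg <- lapply(split(b, b$stage), function(d)
      data.frame(phase = phase, stage = d$stage[1], n_bouts = nrow(d),
                 mean_bout_s = mean(d$dur_s), total_s = sum(d$dur_s)))
    do.call(rbind, agg)
  }
  out <- mk(bouts, "all")
  if (!is.null(hyp$day)) {
    ph <- ifelse(hyp$day[bouts$start_epoch], "day", "night")
    out <- rbind(out, mk(bouts[ph == "day", ], "day"),
                 mk(bouts[ph == "night", ], "night"))
  }
  rownames(out) <- NULL
  out
}

#' Epileptiform spikes per sleep stage
#'
#' Each event is assigned to the stage of the epoch containing its onset;
#' counts are reported per stage (Wake, and Sleep split into REM and NREM)
#' and phase (day/night), with per-day averages. Events outside the
#' hypnogram span are dropped with a warning.
#'
#' @param events Spike event data.frame with `onset_s`.
#' @param hyp Hypnogram data.frame with `t_s`, `state`, `day`.
#' @param epoch_s Epoch length, s (default 5).
#' @return A data.frame: `phase`, `stage`, `total`, `mean_per_day`.
#' @export
spikes_by_stage <- function(events, hyp, epoch_s = 5) {
  if (is.null(hyp$day)) stop("hypnogram needs a `day` column")
  span <- nrow(hyp) * epoch_s
  out_of <- events$onset_s < 0 | events$onset_s >= span
  if (any(out_of)) {
    warning(sum(out_of), " event(s) outside the hypnogram span dropped")
    events <- events[!out_of, , drop = FALSE]
  }
  ep <- floor(events$onset_s / epoch_s) + 1L
  st <- as.character(hyp$state[ep])
  ph <- ifelse(hyp$day[ep], "day", "night")
  n_days <- length(unique(floor(hyp$t_s / 86400)))
  grid <- expand.grid(phase = c("day", "night"), stage = STATES,
                      stringsAsFactors = FALSE)
  grid$total <- mapply(function(p, s) sum(ph == p & st == s),
                       grid$phase, grid$stage)
  grid$mean_per_day <- grid$total / n_days
  grid
}
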