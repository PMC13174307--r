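#' Synthetic telemetry generator configuration
#'
#' Holds every knob of the synthetic-data generator: state-dependent EEG
#' spectra (1/f background exponent plus narrowband oscillations), EMG tone
#' per vigilance state, state-dependent Poisson epileptiform spike rates,
#' day/night Markov sleep dynamics, light/dark-modulated locomotion and
#' body temperature, and the sampling rates of the emulated transmitter
#' (EEG/EMG/activity at 500 samples/s, temperature at 10 samples/s).
#'
#' Defaults are calibrated so that state-conditional epoch features straddle
#' the staging thresholds (see [staging_thresholds()]) with a margin, and so
#' that injected spikes exceed the detector threshold: amplitudes are
#' `spike_amplitude_multiple` times the SD of the high-passed background EEG.
#'
#' @param duration Recording duration in seconds; must be a positive
#'   multiple of the 5-s staging epoch.
#' @param eeg_fs EEG/EMG/activity sampling rate, samples/s. 500 matches the
#'   transmitter; 250 is a reduced-rate mode for fast simulation (all
#'   downstream parameters are in physical units, so rate-independent).
#' @param temp_fs Temperature sampling rate, samples/s.
#' @param start Wall-clock start of the recording.
#' @param lights_on Lights-on local clock time, `"HH:MM"`.
#' @param aperiodic_exponent_by_state Named numeric: 1/f exponent chi of the
#'   EEG background per state (`Wake`, `NREM`, `REM`).
#' @param background_rms_by_state Named numeric: RMS (mV) of the 1/f
#'   background per state.
#' @param band_amplitudes_by_state Named list of named numerics: sinusoidal
#'   band component amplitudes (mV) per state; band names among
#'   `delta`, `theta`, `gamma` (centers 3.25, 9, 55 Hz).
#' @param emg_level_by_state Named numeric: target rectified-mean EMG level
#'   (mV) per state.
#' @param spike_rate_by_state Named numeric: epileptiform spike rate
#'   (events/min) per state.
#' @param spike_amplitude_multiple Spike peak amplitude as a multiple of the
#'   high-passed background EEG SD (default 12).
#' @param spike_duration_range Spike duration range in ms (default 5--80).
#' @param sleep_transition_day,sleep_transition_night 3x3 row-stochastic
#'   Markov matrices over (Wake, NREM, REM) applied per 5-s epoch during the
#'   light and dark phase respectively.
#' @param locomotion_day_mean,locomotion_night_mean Wake-state locomotor
#'   activity rate, counts/min, during the light and dark phase. Sleep
#'   states emit 5% of the Wake rate.
#' @param temperature_mean Mean body temperature, degrees C.
#' @param temperature_circadian_amplitude Amplitude (degrees C) of the
#'   circadian temperature sinusoid, peaking in the dark phase (ZT 18).
#' @param temperature_noise_sd Gaussian noise SD on temperature, degrees C.
#' @param seed Integer seed; every generator operation is deterministic
#'   given the seed and config.
#'
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(duration = 7200,
                       eeg_fs = 500,
                       temp_fs = 10,
                       start = "2024-01-01 07:00:00",
                       lights_on = "07:00",
                       aperiodic_exponent_by_state =
                         c(Wake = 1, NREM = 2.5, REM = 2),
                       background_rms_by_state =
                         c(Wake = 0.025, NREM = 0.035, REM = 0.015),
                       band_amplitudes_by_state = list(
                         Wake = c(delta = 0.005, theta = 0.010, gamma = 0.008),
                         NREM = c(delta = 0.040, theta = 0.005, gamma = 0.002),
                         REM  = c(delta = 0.005, theta = 0.040, gamma = 0.006)),
                       emg_level_by_state =
                         c(Wake = 0.020, NREM = 0.003, REM = 0.004),
                       spike_rate_by_state =
                         c(Wake = 0.5, NREM = 2, REM = 1),
                       spike_amplitude_multiple = 12,
                       spike_duration_range = c(5, 80),
                       sleep_transition_day = rbind(
                         Wake = c(0.90, 0.095, 0.005),
                         NREM = c(0.05, 0.90, 0.05),
                         REM  = c(0.10, 0.10, 0.80)),
                       sleep_transition_night = rbind(
                         Wake = c(0.97, 0.028, 0.002),
                         NREM = c(0.07, 0.88, 0.05),
                         REM  = c(0.12, 0.08, 0.80)),
                       locomotion_day_mean = 10,
                       locomotion_night_mean = 40,
                       temperature_mean = 36.5,
                       temperature_circadian_amplitude = 0.5,
                       temperature_noise_sd = 0.05,
                       seed = 1L) {
  cfg <- list(duration = duration, eeg_fs = eeg_fs, temp_fs = temp_fs,
              start = as.POSIXct(start, tz = "UTC"), lights_on = lights_on,
              aperiodic_exponent_by_state = aperiodic_exponent_by_state,
              background_rms_by_state = background_rms_by_state,
              band_amplitudes_by_state = band_amplitudes_by_state,
              emg_level_by_state = emg_level_by_state,
              spike_rate_by_state = spike_rate_by_state,
              spike_amplitude_multiple = spike_amplitude_multiple,
              spike_duration_range = spike_duration_range,
              sleep_transition_day = sleep_transition_day,
              sleep_transition_night = sleep_transition_night,
              locomotion_day_mean = locomotion_day_mean,
              locomotion_night_mean = locomotion_night_mean,
              temperature_mean = temperature_mean,
              temperature_circadian_amplitude = temperature_circadian_amplitude,
              temperature_noise_sd = temperature_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "gen_config"
  validate_gen_config(cfg)
  cfg
}

STATES <- c("Wake", "NREM", "REM")
EPOCH_S <- 5
BAND_CENTERS <- c(delta = 3.25, theta = 9, gamma = 55)

validate_gen_config <- function(cfg) {
  if (!is.numeric(cfg$duration) || cfg$duration <= 0 ||
      cfg$duration %% EPOCH_S != 0)
    stop("`duration` must be a positive multiple of the ", EPOCH_S, "-s epoch")
  if (cfg$eeg_fs <= 0 || cfg$temp_fs <= 0) stop("sampling rates must be > 0")
  for (nm in c("aperiodic_exponent_by_state", "background_rms_by_state",
               "emg_level_by_state", "spike_rate_by_state")) {
    v <- cfg[[nm]]
    if (!all(STATES %in% names(v))) stop(nm, " must name all of ",
                                         paste(STATES, collapse = ", "))
    if (any(v < 0)) stop(nm, " must be non-negative")
  }
  for (nm in c("sleep_transition_day", "sleep_transition_night")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)))
      stop(nm, " must be a 3x3 matrix over (Wake, NREM, REM)")
    if (any(m < 0)) stop(nm, " has negative entries")
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stop(nm, " rows must each sum to 1 (non-stochastic row found)")
  }
  if (cfg$spike_amplitude_multiple < 0) stop("spike_amplitude_multiple must be >= 0")
  dr <- cfg$spike_duration_range
  if (length(dr) != 2L || dr[1] <= 0 || dr[2] < dr[1])
    stop("spike_duration_range must be an increasing positive pair (ms)")
  invisible(cfg)
}
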