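# Shared fixtures, built once per test run and memoized.

STATES_LEVELS <- function() c("Wake", "NREM", "REM")

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a config whose Markov chain stays in one state forever
single_state_cfg <- function(state = "Wake", chi = 2, rms = 0.03,
                             duration = 600, fs = 250, seed = 1,
                             bands = c(delta = 0)) {
  row <- c(Wake = 0, NREM = 0, REM = 0); row[state] <- 1
  P <- rbind(Wake = row, NREM = row, REM = row)
  gen_config(duration = duration, eeg_fs = fs, seed = seed,
             aperiodic_exponent_by_state = c(Wake = chi, NREM = chi, REM = chi),
             background_rms_by_state = c(Wake = rms, NREM = rms, REM = rms),
             band_amplitudes_by_state = list(Wake = bands, NREM = bands,
                                             REM = bands),
             spike_rate_by_state = c(Wake = 0, NREM = 0, REM = 0),
             sleep_transition_day = P, sleep_transition_night = P)
}

# 2-h synthetic recording at 250 samples/s with injected spikes, plus the
# detection chain run on it; shared by spike and acceptance tests
spike_fixture <- function() memo("spike_fixture", function() {
  cfg <- gen_config(duration = 7200, eeg_fs = 250, seed = 42)
  sim <- simulate_recording(cfg)
  eeg <- sim$recording$channels$EEG
  filt <- highpass_eeg(eeg$data, eeg$rate)
  base <- estimate_baseline_sd(filt, eeg$rate)
  events <- detect_spikes(filt, eeg$rate, base)
  list(cfg = cfg, sim = sim, filt = filt, fs = eeg$rate,
       base = base, events = events)
})

# precision/recall of detections against ground truth, +-25 ms onsets
match_events <- function(events, truth, tol_s = 0.025) {
  recall <- mean(vapply(truth$onset_s, function(o)
    any(abs(events$onset_s - o) < tol_s), TRUE))
  precision <- mean(vapply(events$onset_s, function(o)
    any(abs(truth$onset_s - o) < tol_s), TRUE))
  list(recall = recall, precision = precision)
}

# brute-force hypnogram metrics oracle: plain loops, no vectorization
brute_transitions <- function(states) {
  counts <- c("Wake->Sleep" = 0, "Sleep->Wake" = 0, "NREM->REM" = 0,
              "REM->NREM" = 0, "Wake->REM" = 0, "REM->Wake" = 0,
              "Wake->NREM" = 0, "NREM->Wake" = 0)
  for (i in seq_len(length(states) - 1)) {
    a <- states[i]; b <- states[i + 1]
    if (a == b) next
    counts[paste0(a, "->", b)] <- counts[paste0(a, "->", b)] + 1
    if (a == "Wake") counts["Wake->Sleep"] <- counts["Wake->Sleep"] + 1
    if (b == "Wake") counts["Sleep->Wake"] <- counts["Sleep->Wake"] + 1
  }
  counts
}

brute_bouts <- function(states, epoch_s = 5) {
  out <- list()
  i <- 1
  while (i <= length(states)) {
    j <- i
    while (j < length(states) && states[j + 1] == states[i]) j <- j + 1
    out[[length(out) + 1]] <- data.frame(stage = states[i],
                                         dur_s = (j - i + 1) * epoch_s)
    i <- j + 1
  }
  do.call(rbind, out)
}

random_hypnogram <- function(n, day = TRUE) {
  data.frame(epoch = seq_len(n), t_s = (seq_len(n) - 1) * 5,
             state = factor(sample(c("Wake", "NREM", "REM"), n,
                                   replace = TRUE),
                            levels = c("Wake", "NREM", "REM")),
             day = day)
}
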