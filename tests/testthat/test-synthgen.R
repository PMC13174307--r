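test_that("hypnogram epoching, absorbing states, and validation", {
  cfg <- single_state_cfg(duration = 60)
  hyp <- generate_hypnogram(cfg)
  expect_equal(nrow(hyp), 12)  # 60 s at the 5-s epoch
  expect_true(all(hyp$state == "Wake"))  # absorbing Wake row

  bad <- cfg
  bad$sleep_transition_day[1, ] <- c(0.5, 0.2, 0.2)  # row sums to 0.9
  expect_error(generate_hypnogram(bad), "sum to 1")
  expect_error(gen_config(duration = 7), "multiple")
})

test_that("long-run state fractions match the stationary distribution and
           dwell times are geometric", {
  P <- rbind(Wake = c(0.90, 0.08, 0.02),
             NREM = c(0.10, 0.85, 0.05),
             REM  = c(0.15, 0.05, 0.80))
  cfg <- gen_config(duration = 1e5 * 5, eeg_fs = 250, seed = 11,
                    sleep_transition_day = P, sleep_transition_night = P)
  hyp <- generate_hypnogram(cfg)
  # stationary eigenvector oracle
  e <- eigen(t(P))
  pi_hat <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_hat <- pi_hat / sum(pi_hat)
  emp <- as.numeric(prop.table(table(hyp$state)))
  expect_true(all(abs(emp - pi_hat) < 0.02))

  # Wake dwell times geometric(1 - p_ww): chi-square GOF at alpha = 0.01
  r <- rle(as.character(hyp$state))
  dwell <- r$lengths[r$values == "Wake"]
  p_stay <- P["Wake", 1]
  kmax <- 25
  obs <- tabulate(pmin(dwell, kmax), kmax)
  expp <- (1 - p_stay) * p_stay^(0:(kmax - 2))
  expp <- c(expp, p_stay^(kmax - 1))  # pooled tail
  chisq <- sum((obs - length(dwell) * expp)^2 / (length(dwell) * expp))
  expect_lt(chisq, qchisq(0.99, df = kmax - 1))
})

test_that("EEG background has the configured 1/f slope and REM epochs are
           theta-dominant", {
  cfg <- single_state_cfg(chi = 2, duration = 300, seed = 3)
  hyp <- generate_hypnogram(cfg)
  rec <- synthesize_signals(hyp, cfg)
  x <- rec$channels$EEG$data
  # log-log periodogram slope over 15-70 Hz
  sp <- stats::spec.pgram(stats::ts(x, frequency = 250), spans = 31,
                          plot = FALSE, taper = 0)
  sel <- sp$freq >= 15 & sp$freq <= 70
  slope <- coef(lm(log10(sp$spec[sel]) ~ log10(sp$freq[sel])))[2]
  expect_lt(abs(-slope - 2), 0.15)

  cfg_rem <- gen_config(duration = 300, eeg_fs = 250, seed = 4)
  hyp_r <- generate_hypnogram(cfg_rem)
  hyp_r$state <- factor("REM", levels = levels(hyp_r$state))  # all-REM run
  rec_r <- synthesize_signals(hyp_r, cfg_rem)
  f <- epoch_features(rec_r)
  expect_gte(mean(f$td_ratio > 1), 0.95)

  expect_error(synthesize_signals(hyp_r[0, ], cfg_rem), "empty")
})

test_that("spike injection follows the state-dependent Poisson model", {
  # no rates -> identity
  cfg0 <- single_state_cfg(duration = 600, seed = 6)
  hyp0 <- generate_hypnogram(cfg0)
  rec0 <- synthesize_signals(hyp0, cfg0)
  out0 <- inject_spikes(rec0, hyp0, cfg0)
  expect_identical(out0$recording$channels$EEG$data,
                   rec0$channels$EEG$data)
  expect_equal(nrow(out0$truth), 0)

  # 2/min in NREM only over 100 min of NREM: Poisson CI oracle
  cfg <- single_state_cfg("NREM", duration = 6000, seed = 8)
  cfg$spike_rate_by_state <- c(Wake = 0, NREM = 2, REM = 0)
  hyp <- generate_hypnogram(cfg)
  hyp$state <- factor("NREM", levels = levels(hyp$state))
  rec <- synthesize_signals(hyp, cfg)
  out <- inject_spikes(rec, hyp, cfg)
  expect_lt(abs(nrow(out$truth) - 200), 3 * sqrt(200))
  # durations inside the configured 5-80 ms range, onsets sorted in-span
  expect_true(all(out$truth$duration_ms >= 5 & out$truth$duration_ms <= 80))
  expect_true(all(diff(out$truth$onset_s) > 0))
  expect_true(all(out$truth$onset_s >= 0 & out$truth$onset_s <= 6000))
  expect_error({
    bad <- cfg; bad$spike_rate_by_state["NREM"] <- -1
    inject_spikes(rec, hyp, bad)
  }, "non-negative|negative")
})

test_that("activity and temperature channels have the configured circadian
           structure and rates", {
  cfg <- gen_config(duration = 86400, eeg_fs = 10, seed = 9)
  hyp <- generate_hypnogram(cfg)
  at <- generate_activity_temperature(hyp, cfg)
  expect_equal(length(at$activity$data), 86400 * 10)   # EEG rate
  expect_equal(length(at$temperature$data), 86400 * 10)  # 10 samples/s
  expect_equal(at$temperature$rate, 10)

  zt <- zt_of(cfg$start, cfg$lights_on,
              (seq_along(at$activity$data) - 1) / 10)
  day_mean <- mean(at$activity$data[zt < 12])
  night_mean <- mean(at$activity$data[zt >= 12])
  expect_gt(night_mean, day_mean)  # nocturnal locomotion

  cfg_flat <- gen_config(duration = 86400, eeg_fs = 10, seed = 9,
                         temperature_circadian_amplitude = 0,
                         temperature_noise_sd = 0.05)
  at2 <- generate_activity_temperature(hyp, cfg_flat)
  hrs <- floor((seq_along(at2$temperature$data) - 1) / 10 / 3600)
  hourly <- tapply(at2$temperature$data, hrs, mean)
  expect_lt(max(hourly) - min(hourly), 0.02)  # flat up to noise
})

test_that("generator output is deterministic given seed and sized exactly", {
  cfg <- gen_config(duration = 120, eeg_fs = 250, seed = 77)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$channels$EEG$data,
                   b$recording$channels$EEG$data)
  expect_identical(a$truth$spikes, b$truth$spikes)
  expect_identical(a$truth$hypnogram, b$truth$hypnogram)
  for (ch in a$recording$channels)
    expect_equal(length(ch$data), 120 * ch$rate)
})

test_that("open-field walk matches the uniform-disk area ratio without
           anxiety, habituates with decay, and labels zones consistently", {
  of <- generate_openfield(duration = 3600, step_sd = 2, seed = 5)
  geom <- arena_geometry()
  expect_equal(geom$radius, 12 * 2.54 / 2)  # 12-inch diameter arena
  z <- assign_zones(of$trajectory, geom)
  # long-run occupancy of the 0.6-radius center approximates the 0.36 area
  # ratio for an anxiety-free reflected walk
  expect_lt(abs(mean(z$zone == "center") - 0.36), 0.04)

  # habituation_decay 0: per-10-min expected distance constant
  dm <- distance_moved(of$trajectory, fps = 30)
  expect_lt(max(dm$per_bin$distance) / min(dm$per_bin$distance), 1.05)

  of_dec <- generate_openfield(duration = 3600, habituation_decay = 0.03,
                               step_sd = 2, seed = 5)
  dm2 <- distance_moved(of_dec$trajectory, fps = 30)
  expect_gt(habituation_index(dm2$per_bin), 1.5)

  # anxiety drives center avoidance
  of_anx <- generate_openfield(anxiety = 0.5, duration = 1800, step_sd = 2,
                               seed = 6)
  z_anx <- assign_zones(of_anx$trajectory, geom)
  expect_lt(mean(z_anx$zone == "center"), mean(z$zone == "center"))

  # motif track aligned, ids in range, community mapping fixed
  expect_equal(nrow(of$motifs), nrow(of$trajectory))
  expect_true(all(of$motifs$motif %in% 0:29))
  expect_true(all(of$motifs$community %in% 0:8))
  expect_identical(of$motifs$community, motif_community(of$motifs$motif))
  expect_error(generate_openfield(fps = 0), "fps")
})

test_that("the ground-truth sidecar echoes hypnogram, spikes, and seed", {
  cfg <- gen_config(duration = 60, eeg_fs = 100, seed = 12)
  sim <- simulate_recording(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_sidecar(sim, cfg, f)
  side <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(side$seed, 12)
  expect_equal(side$hypnogram, as.character(sim$truth$hypnogram$state))
  expect_equal(nrow(side$spikes), nrow(sim$truth$spikes))
  expect_equal(side$config$eeg_fs, 100)
})

test_that("pose CSV round-trips the trajectory", {
  of <- generate_openfield(duration = 10, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(of$trajectory, f)
  back <- read_pose_csv(f)
  expect_equal(back$x, of$trajectory$x)
  expect_equal(back$y, of$trajectory$y)
  expect_equal(back$frame, of$trajectory$frame)
})
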