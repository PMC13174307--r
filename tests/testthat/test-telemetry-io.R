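test_that("EDF write/read round-trips channels, rates, start time, and
           values to within one quantization step", {
  cfg <- gen_config(duration = 10, eeg_fs = 500, seed = 5)
  sim <- simulate_recording(cfg)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(sim$recording, f)
  back <- read_edf(f)
  expect_identical(names(back$channels), names(sim$recording$channels))
  expect_equal(back$channels$EEG$rate, 500)  # collected at 500 Hz
  expect_equal(back$channels$temperature$rate, 10)
  expect_identical(back$start, sim$recording$start)
  for (nm in names(back$channels)) {
    orig <- sim$recording$channels[[nm]]$data
    step <- diff(range(orig)) / 65535
    expect_lte(max(abs(back$channels[[nm]]$data - orig)), step)
  }
})

test_that("EDF writer and reader reject degenerate inputs", {
  expect_error(telemetry_recording(list(), start = "2024-01-01"),
               "non-empty")
  expect_error(read_edf(tempfile()), "no such file")
  # malformed header: corrupt the number-of-signals field
  cfg <- gen_config(duration = 5, eeg_fs = 100, seed = 1)
  sim <- simulate_recording(cfg)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(sim$recording, f)
  raw <- readBin(f, "raw", file.size(f))
  raw[253:256] <- charToRaw("abcd")
  writeBin(raw, f)
  expect_error(read_edf(f), "number of signals")
})

test_that("written EDF is readable by an independent implementation", {
  cfg <- gen_config(duration = 10, eeg_fs = 250, seed = 13)
  sim <- simulate_recording(cfg)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(sim$recording, f)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, mne, numpy as np",
    sprintf("raw = mne.io.read_raw_edf(%s, preload=True, verbose='error')",
            deparse(f)),
    "print(','.join(raw.ch_names))",
    "print(raw.info['sfreq'])",
    "x = raw.get_data(picks=['EEG'])[0]",
    "print(float(np.sqrt(np.mean(x**2))))"), script)
  out <- system2("python", script, stdout = TRUE)
  expect_equal(strsplit(out[1], ",")[[1]],
               names(sim$recording$channels))
  expect_equal(as.numeric(out[2]), 250)
  rms_r <- sqrt(mean(sim$recording$channels$EEG$data^2))
  expect_lt(abs(as.numeric(out[3]) - rms_r) / rms_r, 0.01)
})

test_that("clip_artifacts masks exactly the out-of-range samples and is
           idempotent", {
  cfg <- gen_config(duration = 10, eeg_fs = 100, seed = 2)
  sim <- simulate_recording(cfg)
  rec <- sim$recording
  # inject known artifacts
  rec$channels$EEG$data[c(3, 50, 100)] <- c(2.5, -3, 2.0001)
  rec$channels$EMG$data[10] <- -2.2
  rec$channels$activity$data[c(5, 6)] <- -1
  rec$channels$temperature$data[7] <- 25  # <= 25 masked
  out <- clip_artifacts(rec)
  expect_equal(unname(out$masked[c("EEG", "EMG", "activity", "temperature")]),
               c(3L, 1L, 2L, 1L))
  expect_false(out$recording$channels$EEG$mask[3])
  # values untouched
  expect_equal(out$recording$channels$EEG$data[3], 2.5)
  # second pass masks nothing
  out2 <- clip_artifacts(out$recording)
  expect_true(all(out2$masked == 0))
  expect_identical(out2$recording$channels, out$recording$channels)
  # clean signal: nothing masked
  clean <- clip_artifacts(sim$recording)
  expect_equal(sum(clean$masked[c("EEG", "EMG")]), 0L)
})

test_that("merge concatenates on the wall clock, masks gaps, and conserves
           valid samples", {
  mk <- function(start, dur, fs = 10, subject = "m1") {
    n <- dur * fs
    telemetry_recording(
      list(EEG = list(data = stats::rnorm(n, sd = 0.1), rate = fs)),
      start = start, subject = subject)
  }
  a <- mk("2024-01-01 08:00:00", 3600)
  expect_identical(merge_recordings(list(a)), a)

  b <- mk("2024-01-01 09:10:00", 3600)
  m <- merge_recordings(list(a, b))
  expect_equal(recording_duration(m), 2 * 3600 + 600)
  expect_equal(sum(m$channels$EEG$mask),
               sum(a$channels$EEG$mask) + sum(b$channels$EEG$mask))
  gap <- m$channels$EEG$mask[(3600 * 10 + 1):(4200 * 10)]
  expect_true(all(!gap))
  # split at the part boundary recovers the originals exactly
  expect_identical(m$channels$EEG$data[1:36000], a$channels$EEG$data)
  expect_identical(m$channels$EEG$data[42001:78000], b$channels$EEG$data)

  overl <- mk("2024-01-01 08:30:00", 3600)
  expect_error(merge_recordings(list(a, overl)), "overlap")
  other <- mk("2024-01-01 10:30:00", 60, subject = "m2")
  expect_error(merge_recordings(list(a, other)), "subject")
  schema <- mk("2024-01-01 10:30:00", 60, fs = 20)
  expect_error(merge_recordings(list(a, schema)), "schema")
})

test_that("ZT alignment anchors lights-on at 7 am and is 24-h periodic", {
  rec <- telemetry_recording(
    list(EEG = list(data = numeric(10), rate = 1)),
    start = "2024-01-01 07:00:00")
  z <- zt_align(rec, t_s = c(0, 12 * 3600, 23.5 * 3600, 24 * 3600))
  expect_equal(z$zt, c(0, 12, 23.5, 0))        # 07:00 -> ZT 0
  expect_equal(z$day, c(TRUE, FALSE, FALSE, TRUE))

  rec2 <- telemetry_recording(
    list(EEG = list(data = numeric(10), rate = 1)),
    start = "2024-01-01 06:30:00")
  expect_equal(zt_align(rec2, t_s = 0)$zt, 23.5)  # 06:30 -> ZT 23.5
  expect_equal(zt_align(rec2, t_s = 0.5 * 3600)$zt, 0)
  # periodicity: zt(t + 24 h) == zt(t)
  tt <- runif(20, 0, 86400)
  expect_equal(zt_align(rec2, t_s = tt)$zt,
               zt_align(rec2, t_s = tt + 86400)$zt)
})
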