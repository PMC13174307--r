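#' Frequency band schemes
#'
#' Two named schemes are used and never mixed within one analysis:
#' `"canonical"` for band-power time series (delta 1.5--5, theta 6--12,
#' beta_low 11--15, beta_high 15--25, gamma 30--80, plus the gamma_low
#' 30--60 and gamma_high 60--80 sub-bands), and `"periodic"` for the
#' peak metrics of the spectral parameterization (theta 6--12, beta_low
#' 11--15, beta_high 15--25, low_gamma 25--40, high_gamma 40--70). Bands
#' may overlap by design (beta_low overlaps theta).
#'
#' @param name `"canonical"` or `"periodic"`.
#' @return Named list of `c(low, high)` pairs in Hz, class `band_scheme`.
#' @export
band_scheme <- function(name = c("canonical", "periodic")) {
  name <- match.arg(name)
  bands <- switch(name,
    canonical = list(delta = c(1.5, 5), theta = c(6, 12),
                     beta_low = c(11, 15), beta_high = c(15, 25),
                     gamma = c(30, 80), gamma_low = c(30, 60),
                     gamma_high = c(60, 80)),
    periodic = list(theta = c(6, 12), beta_low = c(11, 15),
                    beta_high = c(15, 25), low_gamma = c(25, 40),
                    high_gamma = c(40, 70)))
  structure(bands, class = "band_scheme", scheme_name = name)
}

#' Band-power time series
#'
#' Welch-style short-time band power: Hann-tapered segments of `nfft`
#' samples with 50% overlap, band power as the sum of spectral bins whose
#' centers fall inside each band, aggregated to 1-min bins (mean over the
#' bin's segments). At the transmitter rate of 500 samples/s the default
#' `nfft` of 1024 points gives the nominal 0.5 Hz resolution (numerically
#' 500/1024 = 0.488 Hz per bin); at other rates `nfft` is scaled to keep
#' approximately 0.5 Hz resolution. Segments containing masked-invalid
#' samples are excluded; bins with under 50% valid samples are flagged by
#' their `valid_frac`.
#'
#' @param x EEG samples (mV) or a [telemetry_recording()] (its `EEG`
#'   channel is used).
#' @param fs Sampling rate, samples/s (ignored when `x` is a recording).
#' @param scheme A [band_scheme()] (default canonical).
#' @param nfft FFT length; default `2^round(log2(fs / 0.5))`.
#' @param bin_s Aggregation bin length, s (default 60).
#' @param mask Optional logical validity mask.
#' @return A long data.frame: `bin`, `t_s` (bin start), `band`, `power`
#'   (mV^2), `valid_frac`.
#' @export
bandpower_series <- function(x, fs = NULL, scheme = band_scheme("canonical"),
                             nfft = NULL, bin_s = 60, mask = NULL) {
  if (inherits(x, "telemetry_recording")) {
    ch <- x$channels$EEG
    if (is.null(ch)) stop("recording has no EEG channel")
    mask <- ch$mask; fs <- ch$rate; x <- ch$data
  }
  if (is.null(fs)) stop("`fs` is required for a bare sample vector")
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  if (is.null(nfft)) nfft <- 2^round(log2(fs / 0.5))
  hi <- max(vapply(scheme, `[`, 0, 2))
  if (hi > fs / 2) stop("band edge ", hi, " Hz is above Nyquist (", fs / 2, ")")

  step <- nfft / 2
  starts <- seq(1, length(x) - nfft + 1, by = step)
  if (length(starts) == 0L) stop("signal shorter than one FFT window")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)  # Hann
  seg <- matrix(x[outer(seq_len(nfft) - 1L, starts, "+")], nrow = nfft)
  seg_ok <- colSums(!matrix(mask[outer(seq_len(nfft) - 1L, starts, "+")],
                            nrow = nfft)) == 0
  seg <- seg * win
  X <- stats::mvfft(seg)
  nf <- nfft %/% 2 + 1
  psd <- (Mod(X[seq_len(nf), , drop = FALSE])^2) / (fs * sum(win^2))
  psd[2:(nf - 1), ] <- 2 * psd[2:(nf - 1), ]
  freq <- (seq_len(nf) - 1) * fs / nfft
  df <- fs / nfft

  bin <- floor((starts - 1) / (bin_s * fs))
  bins <- sort(unique(bin))
  nbin <- length(bins)
  bandpow <- matrix(NA_real_, nbin, length(scheme),
                    dimnames = list(NULL, names(scheme)))
  valid_frac <- vapply(bins, function(b) {
    idx <- seq(b * bin_s * fs + 1, min((b + 1) * bin_s * fs, length(x)))
    mean(mask[idx])
  }, 0)
  for (j in seq_along(scheme)) {
    sel <- freq >= scheme[[j]][1] & freq <= scheme[[j]][2]
    segpow <- colSums(psd[sel, , drop = FALSE]) * df
    for (bi in seq_along(bins)) {
      use <- bin == bins[bi] & seg_ok
      if (any(use)) bandpow[bi, j] <- mean(segpow[use])
    }
  }
  data.frame(bin = rep(bins, times = length(scheme)),
             t_s = rep(bins * bin_s, times = length(scheme)),
             band = rep(names(scheme), each = nbin),
             power = as.vector(bandpow),
             valid_frac = rep(valid_frac, times = length(scheme)))
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed via the standard symmetric tridiagonal eigenproblem; tapers
#' are unit-energy, returned in decreasing eigenvalue (concentration)
#' order.
#'
#' @param n Taper length, samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @return An `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (k > 2 * nw) warning("k > 2*nw - 1 tapers are poorly concentrated")
  w <- nw / n
  i <- seq_len(n) - 1
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  M[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' Multitaper mean spectra over 10-s bins
#'
#' Multitaper power spectral density (5 Slepian tapers, time-bandwidth
#' NW = 3, which yields 2 NW - 1 = 5 well-concentrated tapers) on 0.5-s
#' non-overlapping windows, averaged within each 10-s bin.
#'
#' @param x Signal segment (mV).
#' @param fs Sampling rate, samples/s.
#' @param win_s Window length, s (default 0.5, non-overlapping).
#' @param bin_s Averaging bin, s (default 10).
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default 5).
#' @return A list: `freq` (Hz), `spectra` (matrix, one row per 10-s bin,
#'   one-sided PSD in mV^2/Hz), `bin_t_s` (bin starts).
#' @export
multitaper_mean_spectra <- function(x, fs, win_s = 0.5, bin_s = 10,
                                    nw = 3, k = 5) {
  win_n <- round(win_s * fs)
  if (length(x) < win_n) stop("segment shorter than one ", win_s, "-s window")
  nwin <- floor(length(x) / win_n)
  W <- matrix(x[seq_len(nwin * win_n)], nrow = win_n)
  W <- W - rep(colMeans(W), each = win_n)
  tapers <- dpss_tapers(win_n, nw, k)
  nf <- win_n %/% 2 + 1
  acc <- matrix(0, nf, nwin)
  for (j in seq_len(k)) {
    X <- stats::mvfft(W * tapers[, j])
    acc <- acc + Mod(X[seq_len(nf), , drop = FALSE])^2
  }
  psd <- acc / (k * fs)
  psd[2:(nf - 1), ] <- 2 * psd[2:(nf - 1), ]
  freq <- (seq_len(nf) - 1) * fs / win_n
  wins_per_bin <- round(bin_s / win_s)
  nbin <- floor(nwin / wins_per_bin)
  if (nbin == 0L) { nbin <- 1L; wins_per_bin <- nwin }
  spectra <- t(vapply(seq_len(nbin), function(b) {
    cols <- ((b - 1) * wins_per_bin + 1):(b * wins_per_bin)
    rowMeans(psd[, cols, drop = FALSE])
  }, numeric(nf)))
  list(freq = freq, spectra = spectra,
       bin_t_s = (seq_len(nbin) - 1) * bin_s)
}

#' Select the day and night hours used for aperiodic analysis
#'
#' One hour of EEG from the light and one from the dark phase of recording
#' day 2, starting at local clock 10:00 and 22:00.
#'
#' @param rec A [telemetry_recording()] with an `EEG` channel spanning
#'   those times.
#' @return A list with `day` and `night` elements, each a list of `data`
#'   (1 h of EEG samples), `fs`, and `t_offset_s` (offset from recording
#'   start).
#' @export
select_aperiodic_hours <- function(rec) {
  stopifnot(inherits(rec, "telemetry_recording"))
  ch <- rec$channels$EEG
  if (is.null(ch)) stop("recording has no EEG channel")
  dur <- recording_duration(rec)
  day2 <- as.POSIXct(format(rec$start + 86400, "%Y-%m-%d"), tz = "UTC")
  grab <- function(clock_h) {
    t0 <- as.numeric(day2) + clock_h * 3600 - as.numeric(rec$start)
    if (t0 < 0 || t0 + 3600 > dur)
      stop(sprintf(paste0("recording does not span day-2 %02d:00 + 1 h ",
                          "(available: 0-%.0f s from start)"), clock_h, dur))
    idx <- round(t0 * ch$rate) + seq_len(3600 * ch$rate)
    list(data = ch$data[idx], fs = ch$rate, t_offset_s = t0)
  }
  list(day = grab(10), night = grab(22))
}
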