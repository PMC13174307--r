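#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Fits a fixed-mode aperiodic model `log10 P(f) = offset - chi * log10(f)`
#' over the aperiodic range (15--70 Hz) by iterative robust regression
#' (fit, mask bins more than 1 SD above the fit, refit), then fits Gaussian
#' peaks to the flattened spectrum over the periodic range (4--70 Hz):
#' peak bandwidth limited to 3--30 Hz, unlimited peak count (capped at 12
#' for safety), minimum peak height 0, relative stopping threshold 1 SD of
#' the flattened residual. After peak extraction the aperiodic component is
#' re-fit on the peak-removed spectrum, so the exponent chi is the slope
#' magnitude of the 1/f background. The fit is fully deterministic.
#'
#' @param freq Frequencies, Hz.
#' @param power One-sided power spectral density (linear units), strictly
#'   positive over the fit ranges.
#' @param periodic_range,aperiodic_range Fit ranges, Hz.
#' @param peak_width_limits Gaussian bandwidth (2 SD) limits, Hz.
#' @param max_n_peaks Maximum number of peaks (default `Inf`, capped at 12).
#' @param min_peak_height Minimum peak height, log10 power over the
#'   aperiodic curve.
#' @param peak_threshold Stopping threshold in SDs of the flattened
#'   spectrum.
#' @return An object of class `spectrum_fit`: `offset`, `exponent`,
#'   `peaks` (data.frame `cf`, `height`, `bw`), the fit ranges, and the
#'   input spectrum restricted to the periodic range.
#' @export
fit_spectrum <- function(freq, power,
                         periodic_range = c(4, 70),
                         aperiodic_range = c(15, 70),
                         peak_width_limits = c(3, 30),
                         max_n_peaks = Inf,
                         min_peak_height = 0,
                         peak_threshold = 1) {
  stopifnot(length(freq) == length(power))
  sel_p <- freq >= periodic_range[1] & freq <= periodic_range[2]
  sel_a <- freq >= aperiodic_range[1] & freq <= aperiodic_range[2]
  if (sum(sel_a) < 3L) stop("too few bins inside the aperiodic range")
  if (any(power[sel_p | sel_a] <= 0))
    stop("spectrum has non-positive values inside the fit range")
  fp <- freq[sel_p]; lp <- log10(power[sel_p])
  fa <- freq[sel_a]; la <- log10(power[sel_a])

  ap_fit <- function(f, l) {
    co <- stats::coef(stats::lm(l ~ log10(f)))
    c(offset = unname(co[1]), exponent = unname(-co[2]))
  }
  # robust initial aperiodic fit: mask bins > 1 SD above the first fit
  ap <- ap_fit(fa, la)
  res <- la - (ap["offset"] - ap["exponent"] * log10(fa))
  keep <- res <= stats::sd(res)
  if (sum(keep) >= 3L) ap <- ap_fit(fa[keep], la[keep])

  ap_curve <- function(f) ap[["offset"]] - ap[["exponent"]] * log10(f)
  flat <- lp - ap_curve(fp)

  sd_lim <- peak_width_limits / 2
  gauss <- function(f, cf, h, s) h * exp(-(f - cf)^2 / (2 * s^2))
  guesses <- NULL
  work <- flat
  n_max <- min(max_n_peaks, 12)
  while (is.null(guesses) || nrow(guesses) < n_max) {
    i <- which.max(work)
    h <- work[i]
    if (h <= min_peak_height || h <= peak_threshold * stats::sd(work)) break
    cf <- fp[i]
    half <- h / 2  # half-height width -> SD guess
    li <- i; while (li > 1L && work[li] > half) li <- li - 1L
    ri <- i; while (ri < length(work) && work[ri] > half) ri <- ri + 1L
    fwhm <- max(fp[ri] - fp[li], diff(fp[1:2]))
    s <- min(max(fwhm / 2.355, sd_lim[1]), sd_lim[2])
    guesses <- rbind(guesses, c(cf, h, s))
    work <- work - gauss(fp, cf, h, s)
  }

  peaks <- data.frame(cf = numeric(0), height = numeric(0), bw = numeric(0))
  if (!is.null(guesses)) {
    npk <- nrow(guesses)
    par0 <- as.vector(t(guesses))
    obj <- function(p) {
      m <- matrix(p, ncol = 3, byrow = TRUE)
      pred <- rowSums(vapply(seq_len(nrow(m)), function(j)
        gauss(fp, m[j, 1], m[j, 2], m[j, 3]), numeric(length(fp))))
      sum((flat - pred)^2)
    }
    lower <- rep(c(periodic_range[1], 0, sd_lim[1]), npk)
    upper <- rep(c(periodic_range[2], Inf, sd_lim[2]), npk)
    fit <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    m <- matrix(fit$par, ncol = 3, byrow = TRUE)
    ok <- m[, 2] > min_peak_height & m[, 2] > 0
    m <- m[ok, , drop = FALSE]
    if (nrow(m)) {
      m <- m[order(m[, 1]), , drop = FALSE]
      peaks <- data.frame(cf = m[, 1], height = m[, 2], bw = 2 * m[, 3])
    }
  }

  # re-fit the aperiodic component on the peak-removed spectrum
  if (nrow(peaks)) {
    pk_a <- peak_model(peaks, fa)
    ap <- ap_fit(fa, la - pk_a)
  }

  structure(list(offset = ap[["offset"]], exponent = ap[["exponent"]],
                 peaks = peaks,
                 periodic_range = periodic_range,
                 aperiodic_range = aperiodic_range,
                 freq = fp, power = power[sel_p]),
            class = "spectrum_fit")
}

# summed Gaussian peak model in log10 power units
peak_model <- function(peaks, f) {
  if (nrow(peaks) == 0L) return(numeric(length(f)))
  rowSums(vapply(seq_len(nrow(peaks)), function(j)
    peaks$height[j] * exp(-(f - peaks$cf[j])^2 / (2 * (peaks$bw[j] / 2)^2)),
    numeric(length(f))))
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("<spectrum_fit> offset %.3f, exponent %.3f, %d peak(s)\n",
              x$offset, x$exponent, nrow(x$peaks)))
  if (nrow(x$peaks)) print(round(x$peaks, 3))
  invisible(x)
}

#' Per-band peak metrics of a spectrum fit
#'
#' For each band of the periodic scheme containing at least one fitted
#' peak center, reports the largest peak's log power (height in log10
#' units over the aperiodic curve) and the area under the curve between
#' the full model and the aperiodic curve over the band, in linear power
#' units (trapezoid rule on a fine grid). Bands without a peak get `NA`.
#'
#' @param fit A [fit_spectrum()] result.
#' @param scheme A [band_scheme()] (default the periodic-fit scheme).
#' @param grid_df Integration grid step, Hz.
#' @return A data.frame: `band`, `peak_cf`, `peak_log_power`, `auc`.
#' @export
band_peak_metrics <- function(fit, scheme = band_scheme("periodic"),
                              grid_df = 0.05) {
  stopifnot(inherits(fit, "spectrum_fit"))
  out <- data.frame(band = names(scheme), peak_cf = NA_real_,
                    peak_log_power = NA_real_, auc = NA_real_)
  ap <- function(f) fit$offset - fit$exponent * log10(f)
  for (j in seq_along(scheme)) {
    lo <- scheme[[j]][1]; hi <- scheme[[j]][2]
    inb <- fit$peaks$cf >= lo & fit$peaks$cf <= hi
    if (!any(inb)) next
    pk <- fit$peaks[inb, , drop = FALSE]
    best <- pk[which.max(pk$height), ]
    out$peak_cf[j] <- best$cf
    out$peak_log_power[j] <- best$height
    f <- seq(lo, hi, by = grid_df)
    diffpow <- 10^(ap(f) + peak_model(fit$peaks, f)) - 10^ap(f)
    out$auc[j] <- sum((diffpow[-1] + diffpow[-length(f)]) / 2) * grid_df
  }
  out
}
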