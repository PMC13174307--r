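#' Average a sampled channel into 1-min values
#'
#' Mean of valid samples per 1-min bin; bins with under 50% valid samples
#' are set `NA` (excluded from downstream averages).
#'
#' @param x Samples.
#' @param fs Sampling rate, samples/s.
#' @param mask Optional validity mask.
#' @param fun Aggregator (default mean; use `sum` for counts).
#' @return A data.frame: `t_s` (bin start), `value`, `valid_frac`.
#' @export
aggregate_minutes <- function(x, fs, mask = NULL, fun = mean) {
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  spb <- round(60 * fs)
  n_bin <- floor(length(x) / spb)
  idx <- seq_len(n_bin * spb)
  bin <- rep(seq_len(n_bin), each = spb)
  vf <- as.numeric(tapply(mask[idx], bin, mean))
  val <- vapply(seq_len(n_bin), function(b) {
    sel <- idx[bin == b]
    sel <- sel[mask[sel]]
    if (length(sel) == 0L) return(NA_real_)
    fun(x[sel])
  }, 0)
  val[vf < 0.5] <- NA
  data.frame(t_s = (seq_len(n_bin) - 1) * 60, value = val, valid_frac = vf)
}

#' Circadian 15-min profile across the ZT cycle
#'
#' Averages a 1-min series into the 96 15-min Zeitgeber-time slots of the
#' 24-h cycle: each slot is the mean over its 1-min bins within a day,
#' then averaged across recording days, with the SEM across days. Day
#' slots are those with ZT < 12.
#'
#' @param minutes A 1-min series data.frame (`t_s`, `value`), e.g. from
#'   [aggregate_minutes()] or [spike_rate_series()] (rename `count` to
#'   `value`).
#' @param start Wall-clock start of the series.
#' @param lights_on Lights-on clock time (default `"07:00"`).
#' @return A data.frame of class `circadian_profile` with 96 rows: `slot`
#'   (0--95), `zt` (slot start, h), `day`, `mean`, `sem`, `n_days`; the
#'   day/night grand means are attached as attributes `day_mean` and
#'   `night_mean`.
#' @export
circadian_profile <- function(minutes, start, lights_on = "07:00") {
  if (nrow(minutes) == 0L) stop("empty series")
  v <- minutes$value
  zt <- zt_of(as.POSIXct(start, tz = "UTC"), lights_on, minutes$t_s)
  slot <- floor(zt * 4) %% 96
  rec_day <- floor(minutes$t_s / 86400)
  ok <- !is.na(v)
  per_day <- tapply(v[ok], list(slot[ok], rec_day[ok]), mean)
  out <- data.frame(slot = 0:95, zt = (0:95) / 4, day = (0:95) / 4 < 12,
                    mean = NA_real_, sem = NA_real_, n_days = 0L)
  present <- as.integer(rownames(per_day))
  m <- rowMeans(per_day, na.rm = TRUE)
  nn <- rowSums(!is.na(per_day))
  sdv <- apply(per_day, 1, stats::sd, na.rm = TRUE)
  out$mean[out$slot %in% present] <- m
  out$n_days[out$slot %in% present] <- nn
  out$sem[out$slot %in% present] <- ifelse(nn > 1, sdv / sqrt(nn), NA)
  attr(out, "day_mean") <- mean(out$mean[out$day], na.rm = TRUE)
  attr(out, "night_mean") <- mean(out$mean[!out$day], na.rm = TRUE)
  class(out) <- c("circadian_profile", "data.frame")
  out
}

#' Equal-frequency (quantile) bins
#'
#' Rank-orders observations (stable on ties by original index) and splits
#' them into `k` contiguous rank blocks whose sizes differ by at most one
#' observation; bin 1 holds the lowest values ("rest"), bin `k` the
#' highest ("active"). With `n` divisible by `k` each bin holds exactly
#' `n/k` observations (20% each for quintiles).
#'
#' @param values Numeric observations.
#' @param k Number of bins (default 5).
#' @return A list of class `bin_assignment`: `bin` (per-observation index
#'   1..k, in input order), `sizes`, `boundaries` (value at each block
#'   edge), `k`.
#' @export
equal_frequency_bins <- function(values, k = 5) {
  n <- length(values)
  if (n < k) stop("need at least k = ", k, " observations, got ", n)
  ord <- order(values, seq_len(n))  # stable tie-break by original index
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  bin_sorted <- rep(seq_len(k), times = sizes)
  bin <- integer(n)
  bin[ord] <- bin_sorted
  edges <- cumsum(sizes)
  structure(list(bin = bin, sizes = sizes,
                 boundaries = values[ord][edges], k = k),
            class = "bin_assignment")
}

#' Mean and SEM of a target variable per quantile bin
#'
#' Groups a target series (e.g. spike counts per 15-min bin) by the
#' equal-frequency bin of a conditioning variable (locomotor activity, or
#' a band's oscillatory power) on the same timebase.
#'
#' @param target Numeric target series.
#' @param bins A [equal_frequency_bins()] result on the conditioning
#'   series (same length, same timebase).
#' @return A data.frame: `bin`, `n`, `mean`, `sem`.
#' @export
association_by_bin <- function(target, bins) {
  stopifnot(inherits(bins, "bin_assignment"))
  if (length(target) != length(bins$bin))
    stop("timebase mismatch: target and binned series differ in length")
  out <- lapply(seq_len(bins$k), function(b) {
    v <- target[bins$bin == b]
    v <- v[!is.na(v)]
    data.frame(bin = b, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA)
  })
  do.call(rbind, out)
}

#' Normalize a longitudinal series to its baseline week
#'
#' Each value is divided by the subject's baseline-week mean, so the
#' baseline week normalizes to 1 by construction (the design used for
#' saline-baseline treatment comparisons).
#'
#' @param values Numeric series.
#' @param week Integer week label per value.
#' @param baseline_week Week used as baseline (default 1).
#' @return Normalized values; errors if the baseline mean is not positive.
#' @export
normalize_to_baseline <- function(values, week, baseline_week = 1) {
  stopifnot(length(values) == length(week))
  base <- mean(values[week == baseline_week], na.rm = TRUE)
  if (!is.finite(base) || base <= 0)
    stop("baseline week mean is zero or undefined; subject excluded")
  values / base
}

#' Temperature by locomotor activity level
#'
#' Temperature means per rest-to-active quintile of the activity series on
#' the shared 15-min timebase, split by day/night phase.
#'
#' @param temperature Temperature series (15-min bins), degrees C.
#' @param activity Activity series on the same timebase.
#' @param day Logical phase flag per bin (TRUE = day).
#' @param k Number of activity bins (default 5).
#' @return A data.frame: `phase`, `bin`, `n`, `mean`, `sem`.
#' @export
temperature_by_activity <- function(temperature, activity, day, k = 5) {
  stopifnot(length(temperature) == length(activity),
            length(day) == length(activity))
  out <- lapply(c(day = TRUE, night = FALSE), function(d) {
    sel <- day == d
    if (sum(sel) < k) return(NULL)
    a <- association_by_bin(temperature[sel],
                            equal_frequency_bins(activity[sel], k))
    cbind(phase = if (d) "day" else "night", a)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
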