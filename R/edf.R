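#' Write a telemetry recording to an EDF file
#'
#' European Data Format (EDF): ASCII header plus 16-bit little-endian
#' samples, one data record per second. Each channel becomes one EDF signal
#' with `rate` samples per record, so every channel rate must be a positive
#' integer and the recording duration a whole number of seconds. Physical
#' calibration is taken from each channel's data range, so the round-trip
#' error is at most one 16-bit quantization step. Validity masks are not
#' part of EDF and are not persisted; [read_edf()] returns all-valid masks.
#'
#' @param rec A [telemetry_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "telemetry_recording"))
  chs <- rec$channels
  if (length(chs) == 0L) stop("empty channel set; refusing to write")
  rates <- vapply(chs, `[[`, 0, "rate")
  if (any(rates != round(rates) | rates < 1))
    stop("EDF export requires integer channel rates (samples per 1-s record)")
  durs <- vapply(chs, function(ch) length(ch$data) / ch$rate, 0)
  nrec <- max(durs)
  if (any(durs != durs[1]) || nrec != round(nrec))
    stop("EDF export requires equal whole-second channel durations")
  nrec <- as.integer(nrec)
  ns <- length(chs)

  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = w, flag = "-")
  }
  # widest numeric representation fitting the 8-char header field
  fmt8 <- function(x) {
    for (d in 7:1) {
      s <- formatC(x, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    stop("cannot represent ", x, " in an 8-character EDF field")
  }
  num <- function(x, w) pad(fmt8(x), w)

  cal <- lapply(chs, function(ch) {
    pmin <- min(ch$data); pmax <- max(ch$data)
    if (pmin == pmax) { pmin <- pmin - 1; pmax <- pmax + 1 }
    # digitize against the 8-char header representation, not the full
    # double, so write -> read stays within one quantization step;
    # widen outward until the rounded bounds still cover the data
    span <- pmax - pmin
    lo <- as.numeric(fmt8(pmin)); eps <- span * 1e-6
    while (lo > pmin) { lo <- as.numeric(fmt8(pmin - eps)); eps <- eps * 10 }
    hi <- as.numeric(fmt8(pmax)); eps <- span * 1e-6
    while (hi < pmax) { hi <- as.numeric(fmt8(pmax + eps)); eps <- eps * 10 }
    list(pmin = lo, pmax = hi)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(rec$subject, 80), pad("telemetry", 80),
    format(rec$start, "%d.%m.%y"), format(rec$start, "%H.%M.%S"),
    pad(256 * (1 + ns), 8), pad("", 44), pad(nrec, 8), pad(1, 8), pad(ns, 4))
  field <- function(f, w) paste0(vapply(seq_len(ns), f, ""), collapse = "")
  hdr <- paste0(
    hdr,
    field(function(i) pad(names(chs)[i], 16), 16),
    field(function(i) pad("", 80), 80),
    field(function(i) pad("", 8), 8),
    field(function(i) num(cal[[i]]$pmin, 8), 8),
    field(function(i) num(cal[[i]]$pmax, 8), 8),
    field(function(i) pad(-32768, 8), 8),
    field(function(i) pad(32767, 8), 8),
    field(function(i) pad("", 80), 80),
    field(function(i) pad(chs[[i]]$rate, 8), 8),
    field(function(i) pad("", 32), 32))
  writeChar(hdr, con, eos = NULL)

  blocks <- lapply(seq_len(ns), function(i) {
    ch <- chs[[i]]; cc <- cal[[i]]
    d <- round((ch$data - cc$pmin) / (cc$pmax - cc$pmin) * 65535) - 32768
    matrix(as.integer(pmin(pmax(d, -32768), 32767)),
           nrow = ch$rate, ncol = nrec)
  })
  samples <- as.vector(do.call(rbind, blocks))  # record-major interleave
  writeBin(samples, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file into a telemetry recording
#'
#' Supports the plain EDF layout written by [write_edf()] (and standard
#' continuous EDF exports with integer samples-per-record). Channel names,
#' rates and the start timestamp round-trip exactly; sample values
#' round-trip to within one quantization step of the physical range.
#'
#' @param path EDF file path.
#' @param lights_on Lights-on clock time to attach (EDF has no field for
#'   it), default `"07:00"`.
#' @return A [telemetry_recording()].
#' @export
read_edf <- function(path, lights_on = "07:00") {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    x <- readChar(con, w, useBytes = TRUE)
    if (nchar(x, type = "bytes") < w) stop("EDF header truncated")
    trimws(x)
  }
  rdnum <- function(w, fieldname) {
    x <- rd(w)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("malformed EDF header field '", fieldname, "': ", x)
    v
  }
  rd(8)                     # version
  subject <- rd(80)
  rd(80)                    # recording id
  date <- rd(8); time <- rd(8)
  rdnum(8, "header bytes")
  rd(44)
  nrec <- rdnum(8, "number of records")
  recdur <- rdnum(8, "record duration")
  ns <- as.integer(rdnum(4, "number of signals"))
  if (ns < 1) stop("malformed EDF header field 'number of signals': ", ns)

  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  if (any(is.na(pmin) | is.na(pmax)))
    stop("malformed EDF header field 'physical min/max'")
  if (any(is.na(dmin) | is.na(dmax) | dmax == dmin))
    stop("malformed EDF header field 'digital min/max'")
  rdv(80)
  spr <- as.integer(rdv(8))
  if (any(is.na(spr) | spr < 1))
    stop("malformed EDF header field 'samples per record'")
  rdv(32)

  total <- nrec * sum(spr)
  raw <- readBin(con, "integer", n = total, size = 2L, endian = "little")
  if (length(raw) < total) stop("EDF data section truncated")
  m <- matrix(raw, nrow = sum(spr))
  ends <- cumsum(spr); starts <- ends - spr + 1L
  channels <- list()
  for (i in seq_len(ns)) {
    d <- as.vector(m[starts[i]:ends[i], , drop = FALSE])
    x <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    channels[[labels[i]]] <- list(data = x, rate = spr[i] / recdur)
  }
  dd <- as.integer(strsplit(date, ".", fixed = TRUE)[[1]])
  tt <- as.integer(strsplit(time, ".", fixed = TRUE)[[1]])
  if (length(dd) != 3L || any(is.na(dd)))
    stop("malformed EDF header field 'start date': ", date)
  if (length(tt) != 3L || any(is.na(tt)))
    stop("malformed EDF header field 'start time': ", time)
  year <- ifelse(dd[3] >= 85, 1900 + dd[3], 2000 + dd[3])
  start <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:%02d",
                              year, dd[2], dd[1], tt[1], tt[2], tt[3]),
                      tz = "UTC")
  telemetry_recording(channels, start = start, lights_on = lights_on,
                      subject = if (nzchar(subject)) subject else "unknown")
}
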