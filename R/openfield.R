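#' Assign trajectory frames to arena zones
#'
#' The center zone is the disk of 0.6 times the arena radius (boundary
#' inclusive); the periphery is the annulus out to the wall; frames beyond
#' the nominal radius (tracking noise) are zoned `"out"` and excluded from
#' center/periphery denominators. Frames with pose likelihood below
#' `likelihood_min` or non-finite coordinates are invalid (`NA` zone).
#'
#' @param traj Trajectory data.frame (`x`, `y`, optionally `likelihood`).
#' @param geometry An [arena_geometry()].
#' @param likelihood_min Pose-likelihood validity threshold (default 0.9).
#' @return A data.frame: `frame`, `r` (distance from center), `zone`
#'   (factor center/periphery/out, `NA` when invalid), `valid`.
#' @export
assign_zones <- function(traj, geometry, likelihood_min = 0.9) {
  stopifnot(inherits(geometry, "arena_geometry"))
  lik <- if (is.null(traj$likelihood)) rep(1, nrow(traj)) else traj$likelihood
  valid <- is.finite(traj$x) & is.finite(traj$y) & lik >= likelihood_min
  r <- sqrt((traj$x - geometry$center[1])^2 + (traj$y - geometry$center[2])^2)
  zone <- rep(NA_character_, nrow(traj))
  rc <- geometry$center_ratio * geometry$radius
  zone[valid & r <= rc] <- "center"
  zone[valid & r > rc & r <= geometry$radius] <- "periphery"
  zone[valid & r > geometry$radius] <- "out"
  data.frame(frame = if (is.null(traj$frame)) seq_len(nrow(traj)) else traj$frame,
             r = r, zone = factor(zone, levels = c("center", "periphery", "out")),
             valid = valid)
}

#' Distance moved per 10-min bin
#'
#' Sum of Euclidean steps between consecutive valid frames per bin (steps
#' spanning invalid frames are skipped, without interpolation); each step
#' is attributed to the bin of its first frame.
#'
#' @param traj Trajectory data.frame (`x`, `y`, optionally `likelihood`).
#' @param fps Frames per second.
#' @param bin_s Bin length, s (default 600, i.e. 10 min).
#' @param likelihood_min Pose-likelihood validity threshold.
#' @return A list: `per_bin` (data.frame `bin`, `t_s`, `distance`) and
#'   `total`.
#' @export
distance_moved <- function(traj, fps, bin_s = 600, likelihood_min = 0.9) {
  n <- nrow(traj)
  lik <- if (is.null(traj$likelihood)) rep(1, n) else traj$likelihood
  valid <- is.finite(traj$x) & is.finite(traj$y) & lik >= likelihood_min
  # motion support is [0, (n-1)/fps): the last frame starts no step
  n_bins <- max(1L, ceiling((n - 1) / (bin_s * fps)))
  per_bin <- data.frame(bin = seq_len(n_bins),
                        t_s = (seq_len(n_bins) - 1) * bin_s,
                        distance = 0)
  if (sum(valid) < 2L) {
    warning("fewer than 2 valid frames; distance is 0")
    return(list(per_bin = per_bin, total = 0))
  }
  i <- which(valid[-n] & valid[-1])  # consecutive valid pairs
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)[i]
  bin <- floor((i - 1) / (bin_s * fps)) + 1L
  agg <- tapply(step, bin, sum)
  per_bin$distance[as.integer(names(agg))] <- as.numeric(agg)
  list(per_bin = per_bin, total = sum(step))
}

#' Habituation index of an open-field session
#'
#' Ratio of the distance traveled in the first 10-min interval to the
#' last (0--10 min / 50--60 min for a 60-min session). 1 means no
#' habituation; values above 1 indicate habituation (exploration decays).
#' Scale-invariant: units of distance cancel.
#'
#' @param per_bin_distances Numeric per-bin distances (first to last), or
#'   the `per_bin` data.frame from [distance_moved()].
#' @return The index, or `NA` (with a warning) when the last-bin distance
#'   is zero.
#' @export
habituation_index <- function(per_bin_distances) {
  d <- if (is.data.frame(per_bin_distances)) per_bin_distances$distance
       else as.numeric(per_bin_distances)
  if (length(d) < 2L) stop("need at least two bins")
  last <- d[length(d)]
  if (last == 0) {
    warning("last-bin distance is zero; habituation index undefined")
    return(NA_real_)
  }
  d[1] / last
}

#' Percent time in the arena center per motif or community
#'
#' For each label, 100 times the number of labeled frames in the center
#' zone divided by the label's total in-arena frames (center + periphery;
#' `out` and invalid frames are excluded from denominators), at the
#' session level or per 10-min bin. Labels with zero frames in a window
#' are absent from the output.
#'
#' @param labels Per-frame motif (or community) labels, aligned with
#'   `zones`.
#' @param zones [assign_zones()] output of the same session.
#' @param fps Frames per second (needed for binning).
#' @param bin_s Bin length, s; `NULL` (default) for session-level.
#' @return A data.frame: `label`, `bin` (0 for session level), `t_s`,
#'   `n_frames`, `pct_center`.
#' @export
motif_center_time <- function(labels, zones, fps = NULL, bin_s = NULL) {
  if (length(labels) != nrow(zones))
    stop("labels and zones are misaligned (", length(labels), " vs ",
         nrow(zones), " frames)")
  zn <- as.character(zones$zone)
  use <- !is.na(zn) & zn %in% c("center", "periphery")
  bin <- if (is.null(bin_s)) rep(0L, length(labels)) else {
    if (is.null(fps)) stop("fps is required for binning")
    floor((seq_along(labels) - 1) / (bin_s * fps))
  }
  d <- data.frame(label = labels[use], bin = bin[use],
                  center = zn[use] == "center")
  agg <- lapply(split(d, list(d$label, d$bin), drop = TRUE), function(g)
    data.frame(label = g$label[1], bin = g$bin[1],
               t_s = g$bin[1] * if (is.null(bin_s)) 0 else bin_s,
               n_frames = nrow(g), pct_center = 100 * mean(g$center)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$bin, out$label), , drop = FALSE]
}

#' Kernel-density heatmap of spatial usage
#'
#' Gaussian kernel density estimate (Scott's bandwidth rule,
#' sd * n^(-1/6) per axis) of a point cloud, evaluated on a 200 x 200
#' grid over the arena extent, normalized by its maximum and masked below
#' 10% of the maximum. A common maximum can be supplied via `norm_max` to
#' keep probability scaling consistent when comparing groups.
#'
#' @param x,y Point coordinates (at least 3 points, non-degenerate in
#'   both axes).
#' @param extent `c(xmin, xmax, ymin, ymax)`, or an [arena_geometry()]
#'   (center +- radius); defaults to the point range.
#' @param gridsize Grid bins per axis (default 200).
#' @param mask_frac Mask cells below this fraction of the maximum
#'   (default 0.1).
#' @param norm_max Optional external maximum (raw density units) for
#'   common scaling across groups.
#' @return A list of class `heatmap_grid`: `x`, `y` (grid axes), `z`
#'   (normalized density in `[0, 1]`), `mask` (TRUE where below
#'   `mask_frac`), `raw_max`, `extent`.
#' @export
kde_heatmap <- function(x, y, extent = NULL, gridsize = 200,
                        mask_frac = 0.1, norm_max = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for a KDE")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate point cloud (singular covariance); skipped")
  if (inherits(extent, "arena_geometry"))
    extent <- c(extent$center[1] - extent$radius,
                extent$center[1] + extent$radius,
                extent$center[2] - extent$radius,
                extent$center[2] + extent$radius)
  if (is.null(extent)) extent <- c(range(x), range(y))
  scott <- n^(-1 / 6)
  # kde2d uses h/4 as the Gaussian kernel SD
  h <- 4 * scott * c(stats::sd(x), stats::sd(y))
  k <- MASS::kde2d(x, y, h = h, n = gridsize, lims = extent)
  raw_max <- max(k$z)
  z <- k$z / (if (is.null(norm_max)) raw_max else norm_max)
  structure(list(x = k$x, y = k$y, z = z, mask = z < mask_frac,
                 raw_max = raw_max, extent = extent),
            class = "heatmap_grid")
}

#' Remove pre-identified outlier sessions
#'
#' Drops sessions listed in a configuration-supplied exclusion list;
#' exclusions are logged. Idempotent; an unknown session id is an error.
#'
#' @param sessions Session table with a `session` column.
#' @param exclude Character vector of session ids to drop (from config).
#' @param reason Logged reason (default `"pre-identified outlier"`).
#' @return The filtered table.
#' @export
exclude_sessions <- function(sessions, exclude,
                             reason = "pre-identified outlier") {
  if (length(exclude) == 0L) return(sessions)
  unknown <- setdiff(exclude, sessions$session)
  if (length(unknown))
    stop("unknown session id(s) in exclusion list: ",
         paste(unknown, collapse = ", "))
  message("excluding ", length(unique(exclude)), " session(s): ",
          paste(unique(exclude), collapse = ", "), " (", reason, ")")
  sessions[!(sessions$session %in% exclude), , drop = FALSE]
}
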