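#' Arena geometry for the open field
#'
#' Circular arena geometry. The study arena is a 12-inch inner-diameter
#' circle, i.e. radius 15.24 cm; the center zone is the disk of
#' `center_ratio` (default 0.6) times the radius.
#'
#' @param center Numeric length-2, arena center (x, y).
#' @param radius Arena radius (same units as coordinates).
#' @param center_ratio Center-zone boundary as a fraction of the radius.
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(center = c(0, 0), radius = 12 * 2.54 / 2,
                           center_ratio = 0.6) {
  if (radius <= 0) stop("radius must be > 0")
  if (center_ratio <= 0 || center_ratio >= 1)
    stop("center_ratio must be in (0, 1)")
  structure(list(center = unname(as.numeric(center)),
                 radius = unname(as.numeric(radius)),
                 center_ratio = center_ratio), class = "arena_geometry")
}

#' Estimate arena geometry from a trajectory
#'
#' Fallback when the arena geometry is not supplied by configuration: the
#' minimum enclosing circle of the full-session trajectory (Welzl's
#' algorithm on the convex hull), optionally inflated by a margin for
#' wall clearance the animal never crosses.
#'
#' @param traj Trajectory data.frame (`x`, `y`).
#' @param margin Multiplicative radius inflation (default 1, none).
#' @param center_ratio Center-zone boundary fraction (default 0.6).
#' @return An [arena_geometry()].
#' @export
arena_from_trajectory <- function(traj, margin = 1, center_ratio = 0.6) {
  ok <- is.finite(traj$x) & is.finite(traj$y)
  pts <- unique(cbind(traj$x[ok], traj$y[ok]))
  if (nrow(pts) < 2L) stop("need at least 2 distinct valid points")
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  mec <- welzl_mec(hull)  # hull order; deterministic, hull is small
  arena_geometry(center = mec$center, radius = mec$radius * margin,
                 center_ratio = center_ratio)
}

# minimum enclosing circle, Welzl's randomized incremental algorithm
welzl_mec <- function(P, R = matrix(numeric(0), 0, 2)) {
  circ_from <- function(R) {
    n <- nrow(R)
    if (n == 0L) return(list(center = c(0, 0), radius = -Inf))
    if (n == 1L) return(list(center = R[1, ], radius = 0))
    if (n == 2L) return(list(center = (R[1, ] + R[2, ]) / 2,
                             radius = sqrt(sum((R[1, ] - R[2, ])^2)) / 2))
    ax <- R[1, 1]; ay <- R[1, 2]; bx <- R[2, 1]; by <- R[2, 2]
    cx <- R[3, 1]; cy <- R[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(list(center = c(NA, NA), radius = Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(c, p) is.finite(c$radius) &&
    sqrt(sum((p - c$center)^2)) <= c$radius * (1 + 1e-10)
  if (nrow(P) == 0L || nrow(R) == 3L) return(circ_from(R))
  p <- P[nrow(P), ]
  d <- welzl_mec(P[-nrow(P), , drop = FALSE], R)
  if (inside(d, p)) return(d)
  welzl_mec(P[-nrow(P), , drop = FALSE], rbind(R, p))
}

#' Simulate an open-field session with motif labels
#'
#' Generates a reflected Gaussian random walk for the belly point inside a
#' circular arena. A radial drift toward the wall proportional to `anxiety`
#' produces center avoidance (anxiety 0 gives near-uniform long-run
#' occupancy, so the center-zone fraction approaches the area ratio 0.36).
#' The expected step length decays as `exp(-habituation_decay * t)`
#' (t in minutes), emulating within-session habituation. Per-frame motif
#' labels (0--29) and community labels (0--8) are drawn from a
#' zone-conditional categorical distribution (center vs periphery), so
#' zone-conditional motif frequencies are known exactly.
#'
#' @param arena An [arena_geometry()].
#' @param anxiety Non-negative drift strength toward the wall (units of
#'   step SD per frame at the wall).
#' @param habituation_decay Decay rate of expected step length, 1/min.
#' @param fps Frames per second (> 0).
#' @param duration Session duration, s.
#' @param step_sd Initial per-frame step SD per axis (same units as arena).
#' @param seed Integer seed.
#' @return A list: `trajectory` (data.frame `frame`, `t_s`, `x`, `y`,
#'   `likelihood`), `motifs` (data.frame `frame`, `motif`, `community`),
#'   and `motif_probs` (2 x 30 matrix of zone-conditional motif
#'   probabilities, rows `center` and `periphery`).
#' @export
generate_openfield <- function(arena = arena_geometry(), anxiety = 0,
                               habituation_decay = 0, fps = 30,
                               duration = 3600, step_sd = 1, seed = 1L) {
  if (fps <= 0) stop("fps must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (anxiety < 0) stop("anxiety must be >= 0")
  n <- floor(fps * duration)
  set.seed(as.integer(seed))
  R <- arena$radius
  xy <- matrix(0, n, 2)
  p <- arena$center  # start at center
  sig <- step_sd * exp(-habituation_decay * ((seq_len(n) - 1) / fps / 60))
  dx <- stats::rnorm(n); dy <- stats::rnorm(n)
  for (i in seq_len(n)) {
    v <- p - arena$center
    r <- sqrt(sum(v^2))
    drift <- if (r > 0) anxiety * sig[i] * (v / r) * (r / R) else c(0, 0)
    p <- p + sig[i] * c(dx[i], dy[i]) + drift
    # reflect off the circular wall
    v <- p - arena$center
    r <- sqrt(sum(v^2))
    if (r > R) p <- arena$center + v * (2 * R - r) / r
    xy[i, ] <- p
  }
  traj <- data.frame(frame = seq_len(n), t_s = (seq_len(n) - 1) / fps,
                     x = xy[, 1], y = xy[, 2], likelihood = 1)
  # zone-conditional motif emission: center favors low motif ids,
  # periphery high ids; 30 motifs grouped into 9 communities
  w_center <- 30:1; w_periph <- 1:30
  probs <- rbind(center = w_center / sum(w_center),
                 periphery = w_periph / sum(w_periph))
  colnames(probs) <- as.character(0:29)
  zone <- assign_zones(traj, arena)$zone
  motif <- integer(n)
  in_center <- zone == "center"
  motif[in_center] <- sample(0:29, sum(in_center), replace = TRUE,
                             prob = probs["center", ])
  motif[!in_center] <- sample(0:29, sum(!in_center), replace = TRUE,
                              prob = probs["periphery", ])
  motifs <- data.frame(frame = seq_len(n), motif = motif,
                       community = motif_community(motif))
  list(trajectory = traj, motifs = motifs, motif_probs = probs)
}

#' Map behavioral motifs to communities
#'
#' Fixed assignment of the 30 motif ids (0--29) onto 9 behavioral
#' communities (0--8).
#'
#' @param motif Integer vector of motif ids in 0--29.
#' @return Integer community ids in 0--8.
#' @export
motif_community <- function(motif) {
  if (any(motif < 0 | motif > 29)) stop("motif ids must be in 0..29")
  as.integer(floor(motif * 9 / 30))
}

#' Write a pose table in pose-estimation export convention
#'
#' Long-format CSV: `frame`, `bodypart`, `x`, `y`, `likelihood`.
#'
#' @param traj Trajectory data.frame from [generate_openfield()].
#' @param path Output CSV path.
#' @param bodypart Body-part label (default `"belly"`).
#' @export
write_pose_csv <- function(traj, path, bodypart = "belly") {
  out <- data.frame(frame = traj$frame, bodypart = bodypart,
                    x = traj$x, y = traj$y, likelihood = traj$likelihood)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a pose table written by [write_pose_csv()]
#'
#' @param path CSV path.
#' @param bodypart Body part to extract.
#' @param fps Frames per second of the video (attached as metadata).
#' @return Trajectory data.frame (`frame`, `t_s`, `x`, `y`, `likelihood`).
#' @export
read_pose_csv <- function(path, bodypart = "belly", fps = 30) {
  d <- utils::read.csv(path)
  d <- d[d$bodypart == bodypart, ]
  data.frame(frame = d$frame, t_s = (d$frame - 1) / fps,
             x = d$x, y = d$y, likelihood = d$likelihood)
}
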