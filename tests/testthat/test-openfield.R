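test_that("zone assignment matches the 0.6-radius area-ratio oracle", {
  geom <- arena_geometry(radius = 10)
  # exact center and inclusive 0.6 boundary
  traj <- data.frame(x = c(0, 6, 6.0001, 10, 11), y = 0)
  z <- assign_zones(traj, geom)
  expect_equal(as.character(z$zone),
               c("center", "center", "periphery", "periphery", "out"))

  # 1e5 uniform disk points: center fraction 0.36 +- 0.01 (0.6^2 = 0.36)
  set.seed(71)
  n <- 1e5
  r <- 10 * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  zu <- assign_zones(data.frame(x = r * cos(th), y = r * sin(th)), geom)
  expect_lt(abs(mean(zu$zone == "center") - 0.36), 0.01)

  # invalid frames get NA zones
  zi <- assign_zones(data.frame(x = c(0, NA, 1), y = c(0, 1, 1),
                                likelihood = c(1, 1, 0.5)), geom)
  expect_equal(is.na(zi$zone), c(FALSE, TRUE, TRUE))
})

test_that("distance is summed over valid steps per 10-min bin", {
  # square of side 10 traversed once -> 40
  sq <- data.frame(x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0))
  expect_equal(distance_moved(sq, fps = 1)$total, 40)
  # stationary -> 0
  expect_equal(distance_moved(data.frame(x = rep(1, 50), y = 1),
                              fps = 1)$total, 0)
  # 60-min session at 30 fps -> six 10-min bins
  of <- generate_openfield(duration = 3600, seed = 4)
  dm <- distance_moved(of$trajectory, fps = 30)
  expect_equal(nrow(dm$per_bin), 6)
  expect_equal(sum(dm$per_bin$distance), dm$total)
  # a gap of invalid frames contributes no distance
  g <- data.frame(x = c(0, 1, NA, 100, 101), y = 0)
  expect_equal(distance_moved(g, fps = 1)$total, 2)
  expect_warning(d0 <- distance_moved(data.frame(x = 1, y = 1), fps = 1),
                 "valid frames")
  expect_equal(d0$total, 0)
})

test_that("habituation index is early/late distance, flagged when
           undefined, and scale-invariant", {
  expect_equal(habituation_index(rep(123, 6)), 1)  # constant-rate walker
  expect_equal(habituation_index(c(100, 90, 80, 70, 60, 50)), 2)
  expect_warning(hi <- habituation_index(c(10, 0)), "undefined")
  expect_true(is.na(hi))
  d <- c(80, 70, 60, 50, 45, 40)
  expect_equal(habituation_index(d), habituation_index(d * 3.7))
})

test_that("motif center time matches zone-conditional construction", {
  geom <- arena_geometry(radius = 10)
  # motif 1 only in center, motif 2 mixed half/half
  traj <- data.frame(x = c(0, 1, 2, 0, 9, 9.5), y = 0)
  zones <- assign_zones(traj, geom)
  labels <- c(1, 1, 1, 2, 2, 2)
  mc <- motif_center_time(labels, zones)
  expect_equal(mc$pct_center[mc$label == 1], 100)
  expect_equal(mc$pct_center[mc$label == 2], 100 / 3)
  expect_error(motif_center_time(labels[-1], zones), "misaligned")

  # synthetic session: zone-conditional frequencies known from the
  # generator; empirical center% matches the closed-form expectation
  of <- generate_openfield(duration = 3600, step_sd = 2, seed = 9)
  z <- assign_zones(of$trajectory, arena_geometry())
  mcs <- motif_center_time(of$motifs$motif, z)
  p_c <- of$motif_probs["center", ]
  p_p <- of$motif_probs["periphery", ]
  n_c <- sum(z$zone == "center"); n_p <- sum(z$zone == "periphery")
  expected <- 100 * (n_c * p_c) / (n_c * p_c + n_p * p_p)
  got <- mcs$pct_center[match(as.character(0:29), mcs$label)]
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) /
                     (n_c * p_c + n_p * p_p))
  expect_true(all(abs(got - expected) < pmax(4 * se, 1)))

  # aggregation invariant: frame-weighted mean over motifs equals the
  # whole-session center time
  overall <- 100 * n_c / (n_c + n_p)
  expect_equal(sum(mcs$pct_center * mcs$n_frames) / sum(mcs$n_frames),
               overall)

  # 10-min bins: labels absent from a window are absent from the output
  mcb <- motif_center_time(of$motifs$community, z, fps = 30, bin_s = 600)
  expect_true(all(mcb$bin %in% 0:5))
  expect_true(all(mcb$n_frames > 0))
})

test_that("KDE heatmaps are 200x200, max-normalized, and masked below 10%", {
  set.seed(81)
  x <- stats::rnorm(2000, 0, 0.5); y <- stats::rnorm(2000, 0, 0.5)
  hm <- kde_heatmap(x, y, extent = c(-10, 10, -10, 10))
  expect_equal(dim(hm$z), c(200, 200))
  expect_equal(max(hm$z), 1)
  pk <- which(hm$z == 1, arr.ind = TRUE)
  expect_lt(abs(hm$x[pk[1]]), 1)  # maximum at the cluster
  expect_lt(abs(hm$y[pk[2]]), 1)
  expect_true(all(hm$z[hm$mask] < 0.1))

  # two equal clusters far apart: two unmasked blobs, peaks within 5%
  x2 <- c(stats::rnorm(1500, -5, 0.4), stats::rnorm(1500, 5, 0.4))
  y2 <- stats::rnorm(3000, 0, 0.4)
  hm2 <- kde_heatmap(x2, y2, extent = c(-10, 10, -10, 10))
  left <- max(hm2$z[hm2$x < 0, ]); right <- max(hm2$z[hm2$x > 0, ])
  expect_lt(abs(left - right) / max(left, right), 0.05)
  expect_gt(min(left, right), 0.9)

  # group-consistent scaling via a common maximum
  hm3 <- kde_heatmap(x, y, extent = c(-10, 10, -10, 10),
                     norm_max = 2 * hm$raw_max)
  expect_equal(max(hm3$z), 0.5)

  expect_error(kde_heatmap(1:2, 1:2), "at least 3")
  expect_error(kde_heatmap(rep(1, 10), stats::rnorm(10)), "degenerate")
})

test_that("arena geometry fallback recovers the enclosing circle", {
  # points on a known circle: MEC center/radius recovered
  th <- seq(0, 2 * pi, length.out = 50)[-50]
  traj <- data.frame(x = 3 + 7 * cos(th), y = -2 + 7 * sin(th))
  g <- arena_from_trajectory(traj)
  expect_equal(g$center, c(3, -2), tolerance = 1e-8)
  expect_equal(g$radius, 7, tolerance = 1e-8)
  # a walk confined to the arena yields a radius <= the true radius
  of <- generate_openfield(duration = 600, step_sd = 2, seed = 3)
  g2 <- arena_from_trajectory(of$trajectory)
  expect_lte(g2$radius, arena_geometry()$radius + 1e-9)
  expect_gt(g2$radius, 0.8 * arena_geometry()$radius)
})

test_that("session exclusion is config-driven, logged, and idempotent", {
  tab <- data.frame(session = c("s1", "s2", "s3"), value = 1:3)
  expect_identical(exclude_sessions(tab, character(0)), tab)
  expect_message(out <- exclude_sessions(tab, "s2"), "excluding 1 session")
  expect_equal(out$session, c("s1", "s3"))
  # idempotent: re-running with the same list gives the same table
  expect_identical(suppressMessages(exclude_sessions(tab, "s2")), out)
  expect_error(exclude_sessions(tab, "nope"), "unknown session")
})
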