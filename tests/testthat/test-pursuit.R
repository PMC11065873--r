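annulus <- function() arena_geometry("annulus", outer = 70, inner = 50)

# Frames of two mice at fixed track angles (degrees), radius 30 cm.
on_track <- function(theta_self_deg, theta_other_deg) {
  ts <- theta_self_deg * pi / 180; to <- theta_other_deg * pi / 180
  list(self = cbind(30 * cos(ts), 30 * sin(ts)),
       other = cbind(30 * cos(to), 30 * sin(to)))
}

test_that("alpha follows the signed along-track convention", {
  p <- on_track(0, 90)
  expect_equal(compute_alpha(p$self, p$other, "ccw", annulus())$alpha_deg, 90)
  p <- on_track(0, -90)   # 90 degrees ahead for a cw traveller
  expect_equal(compute_alpha(p$self, p$other, "cw", annulus())$alpha_deg, -90)
  p <- on_track(0, -10)   # 10 degrees behind a ccw traveller
  expect_equal(compute_alpha(p$self, p$other, "ccw", annulus())$alpha_deg, 350)
  # off-track frames are invalid
  bad <- compute_alpha(cbind(5, 0), cbind(30, 0), "ccw", annulus())
  expect_false(bad$valid)
  expect_true(is.na(bad$alpha_deg))
})

test_that("alpha is rotation invariant and flips sign with travel direction", {
  set.seed(6)
  for (i in 1:20) {
    t1 <- runif(1, -180, 180); t2 <- runif(1, -180, 180); rot <- runif(1, 0, 360)
    p <- on_track(t1, t2); pr <- on_track(t1 + rot, t2 + rot)
    a1 <- compute_alpha(p$self, p$other, "ccw", annulus())$alpha_deg
    a2 <- compute_alpha(pr$self, pr$other, "ccw", annulus())$alpha_deg
    expect_equal(a1, a2, tolerance = 1e-9)
    acw <- compute_alpha(p$self, p$other, "cw", annulus())$alpha_deg
    # ccw angle a ahead <-> cw angle -(360 - a): same physical bearing
    expect_equal((a1 + (-acw)) %% 360, 0, tolerance = 1e-9)
  }
})

test_that("travel direction tracks angular velocity with a dead band", {
  fr <- 30
  th <- seq(0, 4 * pi, length.out = 600)
  tr_ccw <- trajectory(30 * cos(th), 30 * sin(th), frame_rate = fr)
  expect_true(all(travel_direction(tr_ccw) == "ccw"))
  tr_cw <- trajectory(30 * cos(-th), 30 * sin(-th), frame_rate = fr)
  expect_true(all(travel_direction(tr_cw) == "cw"))
  # a single mid-session reversal is detected within the smoothing window
  th2 <- c(th[1:300], th[300] - (th[2] - th[1]) * seq_len(300))
  tr_rev <- trajectory(30 * cos(th2), 30 * sin(th2), frame_rate = fr)
  d <- travel_direction(tr_rev)
  switches <- which(d[-1] != d[-length(d)])
  expect_equal(length(switches), 1)
  expect_lt(abs(switches - 300), 16)
})

test_that("angle maps localise tuning and flatten constants", {
  fr <- 30
  n <- 6000
  set.seed(12)
  alpha <- data.frame(alpha_deg = runif(n, 0, 360),
                      travel_dir = "ccw", valid = TRUE)
  ev <- generate_angle_events(alpha$alpha_deg, alpha$travel_dir, 45, 20,
                              "ccw", peak_rate = 3, baseline_rate = 0,
                              frame_rate = fr, seed = 3)
  m <- build_angle_map(alpha, ev, fr)
  pk <- peak_metrics(m)
  expect_equal(pk$half, "ccw")
  expect_lt(abs(pk$peak_deg - 45), 22.5)   # within 1.5 bins
  # the cw half never happened: flagged unvisited
  expect_true(all(is.na(m$cw$smoothed)))
  # constant-rate cell gives a flat map
  ev2 <- with(alpha, as.integer(seq_len(n) %% 10 == 0))
  m2 <- build_angle_map(alpha, ev2, fr)
  expect_lt(diff(range(m2$ccw$smoothed)) / mean(m2$ccw$smoothed), 0.6)
  # events conserved per half
  expect_equal(sum(m$ccw$counts), sum(ev))
})

test_that("sharper tuning raises angle-map information", {
  fr <- 30; n <- 9000
  set.seed(15)
  alpha <- data.frame(alpha_deg = runif(n, 0, 360),
                      travel_dir = sample(c("ccw", "cw"), n, TRUE),
                      valid = TRUE)
  info_at <- function(sigma) {
    mean(vapply(1:5, function(s) {
      ev <- generate_angle_events(alpha$alpha_deg, alpha$travel_dir,
                                  runif(1, 0, 360), sigma, "ccw",
                                  peak_rate = 2, frame_rate = fr, seed = s)
      angle_map_information(build_angle_map(alpha, ev, fr))
    }, numeric(1)))
  }
  expect_gt(info_at(15), info_at(60))
})

test_that("peak metrics follow the half-decay signal-region rule", {
  # single active bin: minimal width, all activity in the signal region
  m <- list(ccw = list(occupancy = rep(1, 24), counts = rep(0, 24),
                       rate = rep(0, 24),
                       smoothed = c(2, rep(0, 23)), visited = rep(TRUE, 24)),
            cw = list(occupancy = rep(1, 24), counts = rep(0, 24),
                      rate = rep(0, 24),
                      smoothed = rep(0, 24), visited = rep(TRUE, 24)),
            bin_deg = 15,
            centers_deg = list(ccw = (1:24 - 0.5) * 15,
                               cw = -(1:24 - 0.5) * 15))
  class(m) <- "angle_map"
  pk <- peak_metrics(m)
  expect_equal(pk$half_width_deg, 15)
  expect_equal(pk$signal_fraction, 1)
  expect_false(pk$untuned)
  # flat map: the signal region spans everything and is flagged untuned
  m$ccw$smoothed <- rep(1, 24); m$cw$smoothed <- rep(1, 24)
  pk2 <- peak_metrics(m)
  expect_true(pk2$untuned)
  expect_equal(pk2$half_width_deg, 360)
})

test_that("population autocorrelogram is 1 at zero shift and decays for narrow maps", {
  set.seed(18)
  mk_map <- function(width) {
    mu <- runif(1, 0, 360)
    d <- abs((1:24 - 0.5) * 15 - mu) %% 360; d <- pmin(d, 360 - d)
    c(exp(-d^2 / (2 * width^2)), rep(NA, 24))
  }
  mat <- do.call(rbind, replicate(30, mk_map(15), simplify = FALSE))
  acg <- population_autocorrelogram(mat)
  expect_equal(acg$r[acg$shift_deg == 0], 1, tolerance = 1e-12)
  expect_true(all(abs(acg$r[abs(acg$shift_deg) > 90]) < 0.3))
  # symmetric population: symmetric autocorrelogram
  expect_equal(acg$r, rev(acg$r), tolerance = 0.2)
  # single-bin maps decorrelate by the first shift
  one <- matrix(NA_real_, 20, 48)
  for (i in 1:20) one[i, sample(1:24, 1)] <- 1
  one[is.na(one[, 1:24])] <- 0
  one[, 25:48] <- NA
  acg1 <- population_autocorrelogram(one)
  expect_lt(acg1$r[acg1$shift_deg == 15], 0.2)
})

test_that("session labelling applies the 30%-of-previous-max rule", {
  # previous-day max 100 s, today's median 25 s -> trained
  lab <- label_sessions(list(c(80, 100, 90), c(20, 25, 30)))
  expect_equal(lab$label, c("naive", "trained"))
  # 35 s median does not cross the threshold
  lab <- label_sessions(list(c(80, 100, 90), c(30, 35, 40)))
  expect_equal(lab$label, c("naive", "naive"))
  # the very first session is always naive; trained is absorbing
  lab <- label_sessions(list(c(10, 12), c(100, 90), c(20, 22), c(80, 90)))
  expect_equal(lab$label[1], "naive")
  expect_equal(lab$label[3], "trained")
  expect_equal(lab$label[4], "trained")
})

test_that("experience grouping partitions sessions and detects narrowing", {
  set.seed(20)
  mk_map <- function(width) {
    mu <- runif(1, 0, 360)
    d <- abs((1:24 - 0.5) * 15 - mu) %% 360; d <- pmin(d, 360 - d)
    m <- list(ccw = list(smoothed = exp(-d^2 / (2 * width^2)),
                         occupancy = rep(1, 24)),
              cw = list(smoothed = rep(0, 24), occupancy = rep(1, 24)),
              bin_deg = 15,
              centers_deg = list(ccw = (1:24 - 0.5) * 15,
                                 cw = -(1:24 - 0.5) * 15))
    class(m) <- "angle_map"
    m
  }
  widths <- seq(60, 15, length.out = 6)   # narrowing across 6 groups
  maps <- list(); sess <- integer(0)
  for (g in 1:6) for (k in 1:12) {
    maps[[length(maps) + 1]] <- mk_map(widths[g])
    sess <- c(sess, (g - 1) * 5 + ((k - 1) %% 5) + 1)
  }
  ec <- experience_curve(maps, sess, group_size = 5)
  expect_equal(sum(ec$auc$n_maps), length(maps))   # partition covers all
  expect_lt(ec$r, -0.8)                            # monotone narrowing
})
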