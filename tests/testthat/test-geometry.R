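test_that("relative-position transform is plain vector subtraction", {
  expect_equal(as.numeric(to_relative(c(0, 0), c(10, 0))), c(10, 0))
  expect_equal(as.numeric(to_relative(c(5, 5), c(5, 5))), c(0, 0))
  expect_equal(as.numeric(to_relative(c(-10, 20), c(30, -20))), c(40, -40))
})

test_that("egocentric transform rotates by minus head direction", {
  expect_equal(as.numeric(to_egocentric(c(0, 0), c(10, 0), 0)), c(10, 0))
  # a partner due east of a north-facing mouse is on its right: ego (0, -10)
  expect_equal(as.numeric(to_egocentric(c(0, 0), c(10, 0), pi / 2)),
               c(0, -10))
  expect_equal(as.numeric(to_egocentric(c(0, 0), c(0, 0), 1.3)), c(0, 0))
  # partner straight ahead maps to +x
  hd <- 0.7
  ahead <- c(5 * cos(hd), 5 * sin(hd))
  expect_equal(as.numeric(to_egocentric(c(0, 0), ahead, hd)), c(5, 0))
})

test_that("ego transform properties: identity at hd 0, rotation invariance, norm", {
  set.seed(7)
  for (rep in 1:25) {
    s <- runif(2, -30, 30); o <- runif(2, -30, 30); hd <- runif(1, -pi, pi)
    expect_equal(to_egocentric(s, o, 0), to_relative(s, o))
    # rotating the whole scene leaves ego coordinates unchanged
    phi <- runif(1, -pi, pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    e1 <- to_egocentric(s, o, hd)
    e2 <- to_egocentric(as.numeric(R %*% s), as.numeric(R %*% o),
                        hd + phi)
    expect_equal(e1, e2, tolerance = 1e-12)
    # and rotates rel_allo coordinates by that angle
    r2 <- to_relative(as.numeric(R %*% s), as.numeric(R %*% o))
    expect_equal(as.numeric(R %*% as.numeric(to_relative(s, o))),
                 as.numeric(r2), tolerance = 1e-12)
    # both relative vectors preserve inter-animal distance
    d <- sqrt(sum((o - s)^2))
    expect_equal(sqrt(sum(e1^2)), d, tolerance = 1e-12)
  }
})

test_that("effective arena doubles the linear extent and the bin size", {
  ea <- effective_arena(arena_geometry("circle", diameter = 70))
  expect_equal(ea$half_extent, 70)   # grid [-70, 70]^2
  expect_equal(ea$bin_size, 4)
  ea <- effective_arena(arena_geometry("square", side = 50))
  expect_equal(ea$half_extent, 50)
  expect_equal(ea$bin_size, 4)
  ea <- effective_arena(arena_geometry("annulus", outer = 70, inner = 50))
  expect_equal(ea$half_extent, 70)
  expect_equal(ea$bin_size, 4)
})

test_that("arena geometry validates its size parameters", {
  expect_error(arena_geometry("circle", diameter = -1))
  expect_error(arena_geometry("annulus", outer = 50, inner = 70))
  a <- arena_geometry("annulus", outer = 70, inner = 50)
  expect_true(arena_contains(a, c(30, 0)))
  expect_false(arena_contains(a, c(10, 0)))  # inside the hole
  expect_false(arena_contains(a, c(40, 0)))
})

test_that("trajectory cleaning fixes invalid points before the mean filter", {
  a <- std_arena()
  # constant position is a fixed point of the filter
  tr <- trajectory(rep(10, 100), rep(10, 100))
  out <- clean_trajectory(tr, a)
  expect_equal(out$x_cm, rep(10, 100))
  expect_equal(out$y_cm, rep(10, 100))
  # a single out-of-arena spike is removed, not smeared
  x <- rep(0, 100); x[50] <- 500
  out <- clean_trajectory(trajectory(x, rep(0, 100)), a)
  expect_equal(out$x_cm, rep(0, 100))
  expect_false(out$valid[50])
  # the mean filter preserves linear signals away from the edges
  n <- 60
  ramp <- seq(-15, 15, length.out = n)
  out <- clean_trajectory(trajectory(ramp, rep(0, n)), a)
  expect_equal(out$x_cm[8:(n - 7)], ramp[8:(n - 7)], tolerance = 1e-10)
  # an all-invalid trajectory is an unrecoverable input
  expect_error(clean_trajectory(trajectory(rep(999, 20), rep(0, 20)), a),
               "no valid")
})

test_that("head direction is smoothed circularly across the wrap", {
  a <- std_arena()
  # angles jittering around +pi would average to ~0 linearly; circularly
  # they stay near +pi
  n <- 45
  hd <- rep(c(pi - 0.05, -pi + 0.05), length.out = n)
  out <- clean_trajectory(trajectory(rep(1, n), rep(1, n), head_dir = hd), a)
  expect_true(all(abs(abs(out$head_dir_rad[8:(n - 7)]) - pi) < 0.06))
})

test_that("frame_coordinates assembles each reference frame correctly", {
  n <- 30
  t1 <- trajectory(seq(0, 5, length.out = n), rep(0, n),
                   head_dir = rep(pi / 2, n))
  t2 <- trajectory(rep(10, n), rep(3, n))
  trajs <- list(m1 = t1, p1 = t2)
  self <- frame_coordinates(trajs, frame_spec("self_allo"))
  expect_equal(self$xy[, 1], t1$x_cm)
  rel <- frame_coordinates(trajs, frame_spec("rel_allo", "p1"))
  expect_equal(rel$xy[, 1], 10 - t1$x_cm)
  expect_equal(rel$xy[, 2], rep(3, n))
  ego <- frame_coordinates(trajs, frame_spec("rel_ego", "p1"))
  # facing +y: arena-frame offset (dx, dy) becomes ego (dy, -dx)
  expect_equal(ego$xy[, 1], rep(3, n), tolerance = 1e-12)
  expect_equal(ego$xy[, 2], -(10 - t1$x_cm), tolerance = 1e-12)
  expect_error(frame_spec("self_allo", referent = "p1"))
  expect_error(frame_spec("rel_ego"))
})
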