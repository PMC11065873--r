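test_that("raw rates follow the count/occupancy definition", {
  tr <- sweep_trajectory(side = 20, bin = 2, reps = 3)
  n <- nrow(tr)
  # all events in the first visited bin: its occupancy is 3 frames = 0.1 s
  ev <- rep(0L, n); ev[c(1, 101, 201)] <- 1L
  m <- rate_map(cbind(tr$x_cm, tr$y_cm), tr$valid, ev, half_extent = 10,
                bin_size = 2, frame_rate = 30)
  expect_equal(sum(m$counts), sum(ev))     # events conserved
  expect_equal(sum(m$occupancy), n / 30)   # occupancy = total valid time
  b <- m$counts == 3
  expect_equal(sum(b), 1)
  expect_equal(m$rate[b], 3 / 0.1)
  # uniform occupancy everywhere
  expect_true(all(m$occupancy == 3 / 30))
})

test_that("smoothing preserves constants and reproduces the kernel", {
  tr <- sweep_trajectory(side = 60, bin = 2, reps = 2)
  n <- nrow(tr)
  # one event per bin per two frames: constant 15 ev/s everywhere
  ev <- c(rep(1L, n / 2), rep(0L, n / 2))
  m <- rate_map(cbind(tr$x_cm, tr$y_cm), tr$valid, ev, 30, 2, 30)
  expect_true(all(abs(m$smoothed - 15) < 1e-9))
  # an impulse smooths to a Gaussian profile with sd 2 bins: interior
  # ratios between neighbouring bins follow exp(-d^2/8)
  ev <- rep(0L, n); ev[which(tr$x_cm == 1 & tr$y_cm == 1)[1]] <- 1L
  m <- rate_map(cbind(tr$x_cm, tr$y_cm), tr$valid, ev, 30, 2, 30)
  pk <- which(m$rate == max(m$rate, na.rm = TRUE), arr.ind = TRUE)
  i <- pk[1, 1]; j <- pk[1, 2]
  prof <- m$smoothed[i + 0:3, j] / m$smoothed[i, j]
  expect_equal(prof, exp(-(0:3)^2 / (2 * 2^2)), tolerance = 1e-9)
})

test_that("smoothing with holes and uneven occupancy equals the oracle", {
  set.seed(11)
  for (rep in 1:5) {
    nb <- 12
    visits <- matrix(sample(0:4, nb * nb, replace = TRUE,
                            prob = c(0.25, 0.3, 0.2, 0.15, 0.1)), nb, nb)
    # trajectory revisiting each bin `visits` times
    ctr <- seq(-nb + 1, nb - 1, by = 2) / 2
    g <- expand.grid(x = ctr, y = ctr)
    xy <- cbind(rep(g$x, times = as.numeric(visits)),
                rep(g$y, times = as.numeric(visits)))
    bf <- socialvec:::bin_frames(xy, rep(TRUE, nrow(xy)), nb / 2, 1, 30)
    counts <- matrix(0, nb, nb)
    counts[visits > 0] <- rpois(sum(visits > 0), 1)
    sm <- socialvec:::smooth_flat(bf, matrix(as.numeric(counts), ncol = 1))
    oracle <- smooth_oracle(counts, visits / 30, sd = 2)
    visited <- visits > 0
    expect_equal(matrix(sm, nb, nb)[visited], oracle[visited],
                 tolerance = 1e-10)
    expect_true(all(is.na(matrix(sm, nb, nb)[!visited])))
  }
})

test_that("spatial information matches closed forms and stays non-negative", {
  # uniform rate: zero information
  occ <- matrix(1, 5, 5); rate <- matrix(2, 5, 5)
  expect_equal(spatial_information(manual_map(occ, rate)), 0)
  # two bins, p = (1/2, 1/2), rates (2, 0) -> exactly 1 bit/event
  occ <- matrix(c(1, 1), 1, 2); rate <- matrix(c(2, 0), 1, 2)
  expect_equal(spatial_information(manual_map(occ, rate)), 1)
  # random maps match the direct-summation oracle and are >= 0
  set.seed(5)
  for (rep in 1:100) {
    occ <- matrix(rexp(100), 10, 10)
    rate <- matrix(rexp(100) * rbinom(100, 1, 0.8), 10, 10)
    m <- manual_map(occ, rate)
    i_pkg <- spatial_information(m)
    i_orc <- info_oracle(as.numeric(occ), as.numeric(rate))
    expect_equal(i_pkg, i_orc, tolerance = 1e-12)
    expect_gte(i_pkg, 0)
  }
  # no events: undefined information signal
  expect_true(is.na(spatial_information(manual_map(matrix(1, 2, 2),
                                                   matrix(0, 2, 2)))))
})

test_that("field detection applies the peak and 60% contour rules", {
  mk <- function(rate) {
    occ <- matrix(1, nrow(rate), ncol(rate))
    manual_map(occ, rate)
  }
  # flat sub-threshold map: no fields
  expect_equal(nrow(detect_fields(mk(matrix(0.3, 15, 15)))), 0)
  # one Gaussian bump with peak 1.0: one field, area = bins above 0.6
  ctr <- seq(-14, 14, by = 2)
  g <- outer(ctr, ctr, function(x, y) exp(-(x^2 + y^2) / (2 * 4^2)))
  f <- detect_fields(mk(g))
  expect_equal(nrow(f), 1)
  expect_equal(f$peak_rate, 1)
  expect_equal(f$n_bins, sum(g > 0.6))
  # two bumps with a deep trough: two fields with disjoint areas
  g2 <- outer(ctr, ctr, function(x, y) {
    0.9 * exp(-((x + 8)^2 + y^2) / 8) + 1.0 * exp(-((x - 8)^2 + y^2) / 8)
  })
  f2 <- detect_fields(mk(g2))
  expect_equal(nrow(f2), 2)
  expect_equal(sum(f2$n_bins), sum(g2 > 0.6 * 0.9))
})

test_that("split-half stability behaves at its limits", {
  tr <- sweep_trajectory(side = 60, bin = 2, reps = 2)  # halves identical
  n <- nrow(tr)
  set.seed(3)
  ev_half <- rbinom(n / 2, 1, 0.2)
  ev <- c(ev_half, ev_half)                 # duplicated halves
  r <- split_half_stability(cbind(tr$x_cm, tr$y_cm), tr$valid, ev, 30, 2, 30)
  expect_equal(r, 1, tolerance = 1e-12)
  # independent noise: near-zero stability on average
  rs <- vapply(1:10, function(s) {
    set.seed(s)
    split_half_stability(cbind(tr$x_cm, tr$y_cm), tr$valid,
                         rbinom(n, 1, 0.2), 30, 2, 30)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
  # a strong planted field in a long session clears the 0.3 cutoff
  s <- simulate_session(std_arena(), duration = 600, seed = 8,
                        truth = list(ground_truth_cell("self_allo",
                                                       c(10, 5))))
  fc <- frame_coordinates(s$trajectories, frame_spec("self_allo"))
  r <- split_half_stability(fc$xy, fc$valid, s$raster[1, ], 35, 2, 30)
  expect_gt(r, 0.3)
})

test_that("radial field density is flat for uniform peaks and zero beyond range", {
  s <- simulate_session(std_arena(), duration = 120, seed = 5)
  fc <- frame_coordinates(s$trajectories, frame_spec("rel_allo", "p1"))
  occ <- rate_map(fc$xy, fc$valid, integer(0), 70, 4, 30)
  # no peaks: zero density everywhere
  rd0 <- radial_field_density(data.frame(peak_x = numeric(0),
                                         peak_y = numeric(0)), occ)
  expect_true(all(rd0$density == 0))
  # rings near the maximum inter-animal distance are barely coverable
  expect_lt(max(rd0$coverage[rd0$r_inner >= 60]), 0.25)
  # uniform peaks on a disc: interior ring density is flat
  set.seed(2)
  th <- runif(4000, 0, 2 * pi); rr <- 30 * sqrt(runif(4000))
  rd <- radial_field_density(data.frame(peak_x = rr * cos(th),
                                        peak_y = rr * sin(th)), occ)
  inner <- rd$density[rd$r_outer <= 30]
  expect_lt(max(inner) / min(inner), 1.8)
})

test_that("maps in ego and rel_allo frames coincide when head direction is zero", {
  a <- std_arena()
  n <- 600
  set.seed(14)
  t1 <- trajectory(runif(n, -20, 20), runif(n, -20, 20),
                   head_dir = rep(0, n))
  t2 <- trajectory(runif(n, -20, 20), runif(n, -20, 20))
  trajs <- list(m1 = t1, p1 = t2)
  ev <- rbinom(n, 1, 0.1)
  rel <- frame_coordinates(trajs, frame_spec("rel_allo", "p1"))
  ego <- frame_coordinates(trajs, frame_spec("rel_ego", "p1"))
  m1 <- rate_map(rel$xy, rel$valid, ev, 70, 4, 30)
  m2 <- rate_map(ego$xy, ego$valid, ev, 70, 4, 30)
  expect_equal(m1$smoothed, m2$smoothed)
})
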