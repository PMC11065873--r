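# Synthetic sessions with known ground truth: smooth confined foraging
# trajectories, head direction aligned to motion, and Bernoulli-thinned
# calcium events driven by Gaussian tuning fields in any reference frame.

#' Simulate a confined foraging trajectory
#'
#' A smooth correlated random walk: heading diffuses with Gaussian turning
#' noise, speed relaxes toward a target with jitter, and proposed steps that
#' would leave the arena are deflected toward the arena center.  Head
#' direction equals the motion heading plus Gaussian noise, emulating a
#' head-mounted LED estimate.
#'
#' @param arena an [arena_geometry()].
#' @param duration session length in seconds (default 600, a 10-min session).
#' @param frame_rate frames per second (default 30).
#' @param speed_target mean running speed in cm/s (default 8).
#' @param turning_sd stationary scale of the angular velocity in rad/s
#'   (default 1.5); the angular velocity itself follows an
#'   Ornstein-Uhlenbeck process, so the heading is smooth.
#' @param head_noise_sd sd of head-direction noise around motion heading, rad
#'   (default 0.2).
#' @param seed integer seed; the same seed reproduces the same trajectory.
#' @return a [trajectory()] whose positions all lie inside the arena.
#' @export
simulate_trajectory <- function(arena, duration = 600, frame_rate = 30,
                                speed_target = 8, turning_sd = 1.5,
                                head_noise_sd = 0.2, seed = 1) {
  stopifnot(duration > 0)
  if (speed_target <= 0) stop("speed_target must be positive")
  with_seed(seed, {
    sim_walk(arena, duration, frame_rate, speed_target, turning_sd,
             head_noise_sd)
  })
}

# Single-animal stepper (RNG state managed by the caller).  `target_xy`, when
# a function of frame index, pulls the heading toward that point with gain
# `attraction` (dimensionless in [0, 1]).
sim_walk <- function(arena, duration, frame_rate, speed_target, turning_sd,
                     head_noise_sd, target_xy = NULL, attraction = 0) {
  dt <- 1 / frame_rate
  n <- round(duration * frame_rate)
  x <- numeric(n); y <- numeric(n)
  half <- arena_half_extent(arena)
  # start at a uniform random point inside the arena
  repeat {
    p0 <- stats::runif(2, -half, half)
    if (arena_contains(arena, p0)) break
  }
  x[1] <- p0[1]; y[1] <- p0[2]
  h <- stats::runif(1, -pi, pi)
  sp <- speed_target
  heading <- numeric(n); heading[1] <- h
  # angular velocity is Ornstein-Uhlenbeck (time constant tau_w, stationary
  # sd turning_sd), giving a smooth, differentiable heading
  tau_w <- 0.7
  omega <- 0
  wj <- stats::rnorm(n, 0, turning_sd * sqrt(2 * dt / tau_w))
  spj <- stats::rnorm(n, 0, speed_target * 0.5 * sqrt(dt))
  for (i in 2:n) {
    omega <- omega - omega * dt / tau_w + wj[i]
    h <- h + omega * dt
    if (attraction > 0) {
      tg <- target_xy[i - 1, ]
      bearing <- atan2(tg[2] - y[i - 1], tg[1] - x[i - 1])
      h <- h + attraction * 4 * dt * wrap_angle(bearing - h)
    }
    sp <- sp + (speed_target - sp) * dt * 2 + spj[i]
    sp <- max(sp, 0)
    px <- x[i - 1] + sp * dt * cos(h)
    py <- y[i - 1] + sp * dt * sin(h)
    if (!arena_contains(arena, c(px, py))) {
      # deflect toward the arena's "safe" direction and retake the step
      h <- safe_heading(arena, x[i - 1], y[i - 1])
      omega <- 0
      px <- x[i - 1] + sp * dt * cos(h)
      py <- y[i - 1] + sp * dt * sin(h)
      if (!arena_contains(arena, c(px, py))) { px <- x[i - 1]; py <- y[i - 1] }
    }
    x[i] <- px; y[i] <- py; heading[i] <- wrap_angle(h)
  }
  hd <- wrap_angle(heading + stats::rnorm(n, 0, head_noise_sd))
  out <- trajectory(x, y, frame_rate = frame_rate, head_dir = hd)
  # the noiseless motion heading, kept for ground-truth event generation
  attr(out, "true_heading") <- wrap_angle(heading)
  out
}

# Heading pointing back into the arena interior from (x, y).
safe_heading <- function(arena, x, y) {
  if (arena$shape == "annulus") {
    r <- sqrt(x^2 + y^2)
    mid <- (arena$outer + arena$inner) / 4
    th <- atan2(y, x)
    # aim tangentially, nudged toward the track mid-line
    tangent <- th + sample(c(-1, 1), 1) * pi / 2
    radial <- if (r > mid) th + pi else th
    return(wrap_angle(atan2(0.7 * sin(tangent) + 0.3 * sin(radial),
                            0.7 * cos(tangent) + 0.3 * cos(radial))))
  }
  wrap_angle(atan2(-y, -x) + stats::runif(1, -pi / 3, pi / 3))
}

#' Simulate a pair of interacting trajectories
#'
#' The first animal forages independently; the second receives a heading bias
#' toward the first with dimensionless gain `attraction`.  `attraction = 0`
#' gives two independent walks.
#'
#' @inheritParams simulate_trajectory
#' @param attraction pursuit/approach gain in `[0, 1]`.
#' @return list of two [trajectory()] objects.
#' @export
simulate_pair <- function(arena, duration = 600, frame_rate = 30,
                          speed_target = 8, turning_sd = 1.5,
                          attraction = 0, seed = 1) {
  stopifnot(attraction >= 0, attraction <= 1)
  t1 <- with_seed(derive_seed(seed, 1), {
    sim_walk(arena, duration, frame_rate, speed_target, turning_sd, 0.2)
  })
  t2 <- with_seed(derive_seed(seed, 2), {
    sim_walk(arena, duration, frame_rate, speed_target, turning_sd, 0.2,
             target_xy = cbind(t1$x_cm, t1$y_cm), attraction = attraction)
  })
  list(t1, t2)
}

#' Simulate an annular-track pursuit session
#'
#' Each trial has the task's two phases.  During an initial free period the
#' leader runs along the track mid-line at a fixed angular speed (sign
#' varying across trials) while the imaged follower moves independently in
#' its own direction, so the relative angle sweeps the whole circle.  During
#' the chase the follower closes the angular gap exponentially, catching up
#' at the trial's prescribed latency.  The leader starts each trial at a
#' random track position.  Head direction of the follower is tangent to its
#' motion plus noise.
#'
#' @param arena an annulus [arena_geometry()].
#' @param latency_profile numeric vector, seconds per trial (one trial per
#'   element).
#' @param frame_rate frames per second (default 30).
#' @param leader_speed_deg leader angular speed, degrees/s (default 45).
#' @param seed integer seed.
#' @return list with `trajectories` (follower = imaged animal first, then
#'   leader), `trials` (data.frame trial/start_s/end_s/latency_s/direction)
#'   and `frame_rate`.
#' @export
simulate_annular_pursuit <- function(arena, latency_profile,
                                     frame_rate = 30, leader_speed_deg = 45,
                                     seed = 1) {
  if (arena$shape != "annulus") stop("pursuit sessions need an annulus arena")
  r_out <- arena$outer / 2; r_in <- arena$inner / 2
  r_mid <- (r_out + r_in) / 2
  with_seed(seed, {
    dt <- 1 / frame_rate
    xs <- ys <- hs <- xl <- yl <- numeric(0)
    trials <- data.frame(trial = integer(0), start_s = numeric(0),
                         end_s = numeric(0), latency_s = numeric(0),
                         direction = character(0))
    t0 <- 0
    for (k in seq_along(latency_profile)) {
      lat <- latency_profile[k]
      nf <- max(round(lat * frame_rate), 4L)
      dirn <- sample(c(1, -1), 1)  # +1 ccw, -1 cw
      w_l <- dirn * (leader_speed_deg * pi / 180)
      th_l <- stats::runif(1, -pi, pi) + w_l * dt * (seq_len(nf) - 1)
      # the trial latency is the time until close following begins: the
      # follower explores freely at its own angular velocity for most of the
      # trial, and the chase itself is brief (<= 4 s)
      nf_free <- nf - round(min(4, 0.3 * lat) * frame_rate)
      nf_free <- min(max(nf_free, 2L), nf - 2L)
      w_f <- sample(c(1, -1), 1) * (leader_speed_deg * pi / 180) *
        stats::runif(1, 0.5, 1.5)
      w_f <- w_f + cumsum(stats::rnorm(nf_free, 0, 0.1)) * dt
      th_f_free <- stats::runif(1, -pi, pi) + cumsum(c(0, w_f[-1]) * dt)
      # chase phase: close the remaining gap exponentially
      nf_chase <- nf - nf_free
      gap0 <- (dirn * (th_l[nf_free] - th_f_free[nf_free])) %% (2 * pi)
      gap <- gap0 * exp(-4 * (seq_len(nf_chase) - 1) / nf_chase) + 0.05
      th_f <- c(th_f_free, (th_l[(nf_free + 1):nf] - dirn * gap))
      rr_f <- pmin(pmax(r_mid + cumsum(stats::rnorm(nf, 0, 0.3)) * 0.1,
                        r_in + 1), r_out - 1)
      rr_l <- pmin(pmax(r_mid + cumsum(stats::rnorm(nf, 0, 0.3)) * 0.1,
                        r_in + 1), r_out - 1)
      xs <- c(xs, rr_f * cos(th_f)); ys <- c(ys, rr_f * sin(th_f))
      # heading tangent to the follower's own travel direction
      dth <- diff(th_f); dir_f <- sign(c(dth[1], dth)); dir_f[dir_f == 0] <- dirn
      hs <- c(hs, wrap_angle(th_f + dir_f * pi / 2 + stats::rnorm(nf, 0, 0.15)))
      xl <- c(xl, rr_l * cos(th_l)); yl <- c(yl, rr_l * sin(th_l))
      trials <- rbind(trials, data.frame(
        trial = k, start_s = t0, end_s = t0 + nf * dt, latency_s = lat,
        direction = if (dirn > 0) "ccw" else "cw"))
      t0 <- t0 + nf * dt
    }
    follower <- trajectory(xs, ys, frame_rate = frame_rate, head_dir = hs)
    leader <- trajectory(xl, yl, frame_rate = frame_rate)
    list(trajectories = list(m1 = follower, p1 = leader), trials = trials,
         frame_rate = frame_rate)
  })
}

#' Ground-truth tuned cell
#'
#' Describes a cell with Gaussian tuning fields planted in one of the four
#' reference frames, used by [generate_events()] to drive synthetic calcium
#' events.
#'
#' @param frame one of `"self_allo"`, `"other_allo"`, `"rel_allo"`,
#'   `"rel_ego"`.
#' @param centers two-column matrix (or length-2 vector) of field centers, cm,
#'   in that frame's coordinates.
#' @param field_sd Gaussian field standard deviation, cm (default 8).
#' @param peak_rate event rate at the field center, events/s (default 1).
#' @param baseline_rate floor event rate, events/s (default 0.05, the sparse
#'   out-of-field rate typical of deconvolved CA1 calcium event trains).
#' @param referent_gains named numeric vector of per-partner gains in
#'   `[0, 1]`; for social frames, which partner(s) drive the cell.  Ignored
#'   for `self_allo`.
#' @return an object of class `ground_truth_cell`.
#' @export
ground_truth_cell <- function(frame, centers, field_sd = 8, peak_rate = 1,
                              baseline_rate = 0.05, referent_gains = NULL) {
  stopifnot(peak_rate >= baseline_rate, baseline_rate >= 0, field_sd > 0)
  centers <- rbind(centers)
  if (frame != "self_allo" && is.null(referent_gains))
    stop("social-frame cells need referent_gains")
  structure(list(frame = frame, centers = centers, field_sd = field_sd,
                 peak_rate = peak_rate, baseline_rate = baseline_rate,
                 referent_gains = referent_gains),
            class = "ground_truth_cell")
}

# Instantaneous rate (events/s) of one ground-truth cell along the session.
cell_rate_series <- function(cell, trajectories, subject = 1L) {
  n <- nrow(trajectories[[subject]])
  amp <- cell$peak_rate - cell$baseline_rate
  rate <- rep(cell$baseline_rate, n)
  bump <- function(xy) {
    d2 <- rep(0, nrow(xy)) * NA_real_
    g <- rep(0, nrow(xy))
    for (j in seq_len(nrow(cell$centers))) {
      d2 <- (xy[, 1] - cell$centers[j, 1])^2 + (xy[, 2] - cell$centers[j, 2])^2
      g <- pmax(g, exp(-d2 / (2 * cell$field_sd^2)), na.rm = FALSE)
    }
    g[!is.finite(xy[, 1])] <- 0
    g
  }
  if (cell$frame == "self_allo") {
    fc <- frame_coordinates(trajectories, frame_spec("self_allo"), subject)
    xy <- fc$xy; xy[!fc$valid, ] <- NA_real_
    rate <- rate + amp * bump(xy)
  } else {
    for (ref in names(cell$referent_gains)) {
      gain <- cell$referent_gains[[ref]]
      if (gain <= 0) next
      if (is.null(trajectories[[ref]]))
        stop(sprintf("cell needs partner '%s' absent from session", ref))
      fc <- frame_coordinates(trajectories, frame_spec(cell$frame, ref),
                              subject)
      xy <- fc$xy; xy[!fc$valid, ] <- NA_real_
      rate <- rate + gain * amp * bump(xy)
    }
  }
  rate
}

#' Generate a binary event raster from ground-truth cells
#'
#' Per frame, each cell's instantaneous rate is its baseline plus Gaussian
#' field bumps evaluated at the session's position in the cell's reference
#' frame; an event is emitted as Bernoulli(rate * dt), clipped at 1.  This
#' matches the binarised suprathreshold-frame raster the analysis consumes.
#'
#' @param truth list of [ground_truth_cell()] objects.
#' @param trajectories named list of [trajectory()] objects (imaged animal
#'   first).
#' @param seed integer seed; per-cell streams are derived so adding cells
#'   never perturbs existing rows.
#' @param subject imaged animal (default first).
#' @return binary matrix, cells x frames.
#' @export
generate_events <- function(truth, trajectories, seed = 1, subject = 1L) {
  n <- nrow(trajectories[[subject]])
  dt <- 1 / attr(trajectories[[subject]], "frame_rate")
  raster <- matrix(0L, nrow = length(truth), ncol = n)
  for (i in seq_along(truth)) {
    rate <- cell_rate_series(truth[[i]], trajectories, subject)
    p <- pmin(rate * dt, 1)
    u <- with_seed(derive_seed(seed, 100 + i), stats::runif(n))
    raster[i, ] <- as.integer(u < p)
  }
  raster
}

#' Generate events tuned to the pursuit angle
#'
#' Drives a cell from the one-dimensional signed track angle `alpha` rather
#' than a two-dimensional field: the rate is the baseline plus a circular
#' Gaussian bump at `mu_deg` (sd `sigma_deg`), active only on frames whose
#' travel direction matches `dir_pref`.
#'
#' @param alpha_deg signed track angle per frame, degrees (see
#'   [compute_alpha()]).
#' @param travel_dir per-frame `"cw"`/`"ccw"` labels.
#' @param mu_deg preferred angle(s), degrees, in the signed convention of
#'   `dir_pref`'s half; a vector plants a multi-field cell (envelope of the
#'   bumps).
#' @param sigma_deg tuning width, degrees.
#' @param dir_pref `"cw"` or `"ccw"`.
#' @param peak_rate,baseline_rate events/s.
#' @param frame_rate Hz.
#' @param seed integer seed.
#' @return integer 0/1 event vector, one per frame.
#' @export
generate_angle_events <- function(alpha_deg, travel_dir, mu_deg, sigma_deg,
                                  dir_pref = "ccw", peak_rate = 1,
                                  baseline_rate = 0.05, frame_rate = 30,
                                  seed = 1) {
  n <- length(alpha_deg)
  g <- rep(0, n)
  for (mu in mu_deg) {
    d <- abs(alpha_deg - mu) %% 360
    d <- pmin(d, 360 - d)
    g <- pmax(g, exp(-d^2 / (2 * sigma_deg^2)))
  }
  rate <- rep(baseline_rate, n)
  on <- travel_dir == dir_pref & is.finite(alpha_deg)
  rate[on] <- baseline_rate + (peak_rate - baseline_rate) * g[on]
  p <- pmin(rate / frame_rate, 1)
  u <- with_seed(seed, stats::runif(n))
  as.integer(u < p)
}

#' Simulate a full session with planted cells
#'
#' Convenience wrapper: simulates the imaged animal plus `n_partners`
#' conspecifics, generates the event raster from `truth`, and bundles
#' everything into a session object consumed by the classification, decoding
#' and remapping stages.
#'
#' @inheritParams simulate_trajectory
#' @param n_partners number of conspecifics (1 or 2).
#' @param truth list of [ground_truth_cell()]; may be empty.
#' @param attraction heading bias of partners toward the imaged animal.
#' @return an object of class `social_session`: list with `arena`,
#'   `frame_rate`, `trajectories` (named `m1`, `p1`, `p2`, imaged animal
#'   first), `raster`, `truth`, `seed`.
#'
#' @details Events are generated from the animal's true state (noiseless
#'   motion heading), while the session exposes the observed channels: head
#'   direction with tracking noise, passed through the standard cleaning and
#'   15-point smoothing that real trajectories receive.  Classification and
#'   decoding therefore face realistic observation noise.
#' @export
simulate_session <- function(arena, duration = 600, frame_rate = 30,
                             n_partners = 1, truth = list(),
                             speed_target = 8, turning_sd = 1.5,
                             attraction = 0, seed = 1) {
  stopifnot(n_partners >= 1, n_partners <= 2)
  trajs <- list()
  trajs$m1 <- with_seed(derive_seed(seed, 1), {
    sim_walk(arena, duration, frame_rate, speed_target, turning_sd, 0.2)
  })
  for (p in seq_len(n_partners)) {
    trajs[[paste0("p", p)]] <- with_seed(derive_seed(seed, 1 + p), {
      sim_walk(arena, duration, frame_rate, speed_target, turning_sd, 0.2,
               target_xy = cbind(trajs$m1$x_cm, trajs$m1$y_cm),
               attraction = attraction)
    })
  }
  # ground truth sees the true heading; the analysis sees cleaned tracking
  true_trajs <- lapply(trajs, function(tr) {
    trajectory(tr$x_cm, tr$y_cm, frame_rate = frame_rate,
               head_dir = attr(tr, "true_heading"), valid = tr$valid)
  })
  raster <- generate_events(truth, true_trajs, seed = seed)
  observed <- lapply(trajs, clean_trajectory, arena = arena)
  structure(list(arena = arena, frame_rate = frame_rate,
                 trajectories = observed, raster = raster, truth = truth,
                 seed = seed),
            class = "social_session")
}

#' @export
print.social_session <- function(x, ...) {
  cat(sprintf(
    "<social_session> %s arena, %d animals, %d cells x %d frames @ %g Hz\n",
    x$arena$shape, length(x$trajectories), nrow(x$raster),
    nrow(x$trajectories[[1]]), x$frame_rate))
  invisible(x)
}
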