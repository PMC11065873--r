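# Shared fixture builders: everything is generated in code at test time.

std_arena <- function() arena_geometry("circle", diameter = 70)

# A short session with one planted cell per reference frame plus a silent
# cell, used by several module tests.
quick_session <- function(duration = 120, seed = 42, baseline = 0.05) {
  truth <- list(
    ground_truth_cell("self_allo", c(10, 5), baseline_rate = baseline),
    ground_truth_cell("rel_ego", c(15, 0), baseline_rate = baseline,
                      referent_gains = c(p1 = 1)),
    ground_truth_cell("other_allo", c(-8, 12), baseline_rate = baseline,
                      referent_gains = c(p1 = 1)),
    ground_truth_cell("self_allo", c(0, 0), peak_rate = 0, baseline_rate = 0))
  simulate_session(std_arena(), duration = duration, seed = seed,
                   truth = truth)
}

# Deterministic square-arena trajectory that sweeps every bin uniformly:
# one frame per (x, y) grid point, repeated `reps` times.
sweep_trajectory <- function(side = 20, bin = 2, reps = 2, frame_rate = 30) {
  ctr <- seq(-side / 2 + bin / 2, side / 2 - bin / 2, by = bin)
  g <- expand.grid(x = ctr, y = ctr)
  x <- rep(g$x, reps); y <- rep(g$y, reps)
  trajectory(x, y, frame_rate = frame_rate)
}

# Brute-force spatial information oracle: direct summation over bins.
info_oracle <- function(p, lam) {
  p <- p / sum(p)
  L <- sum(p * lam)
  tot <- 0
  for (i in seq_along(p)) {
    if (lam[i] > 0) tot <- tot + p[i] * (lam[i] / L) * log2(lam[i] / L)
  }
  tot
}

# Brute-force occupancy-normalised Gaussian smoothing oracle: at each
# visited bin, kernel-weighted event counts divided by kernel-weighted
# occupancy, summed directly over the truncated window.
smooth_oracle <- function(counts, occupancy, sd = 2,
                          radius = ceiling(3 * sd)) {
  nb1 <- nrow(counts); nb2 <- ncol(counts)
  out <- matrix(NA_real_, nb1, nb2)
  for (i in seq_len(nb1)) for (j in seq_len(nb2)) {
    if (occupancy[i, j] <= 0) next
    num <- 0; den <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nb1 || jj < 1 || jj > nb2) next
      w <- exp(-di^2 / (2 * sd^2)) * exp(-dj^2 / (2 * sd^2))
      num <- num + w * counts[ii, jj]; den <- den + w * occupancy[ii, jj]
    }
    out[i, j] <- num / den
  }
  out
}

# Construct a rate_map object directly from matrices (for closed-form tests).
manual_map <- function(occupancy, rate, bin_size = 2) {
  nb <- nrow(occupancy)
  visited <- occupancy > 0
  half <- nb * bin_size / 2
  structure(list(
    frame = NULL, nb = nb, bin_size = bin_size, half_extent = half,
    centers = -half + (seq_len(nb) - 0.5) * bin_size,
    occupancy = occupancy, counts = rate * occupancy, rate = rate,
    smoothed = rate, visited = visited,
    overall_rate = sum(rate * occupancy, na.rm = TRUE) / sum(occupancy),
    total_time = sum(occupancy)), class = "rate_map")
}
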