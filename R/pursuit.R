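# Annular-track pursuit analysis: signed track angle alpha, 1-D angle maps,
# peak metrics, population autocorrelograms, learning-curve summaries and
# naive/trained session labelling.

#' Per-frame travel direction on the annular track
#'
#' Sign of the imaged animal's angular velocity about the track center,
#' smoothed over `smooth_s` seconds.  Frames with angular speed inside the
#' dead band inherit the last confident direction (frames before the first
#' confident one inherit it backwards).
#'
#' @param traj a [trajectory()] on the annulus.
#' @param smooth_s smoothing window in seconds (default 0.5).
#' @param dead_band_deg_s angular-speed dead band in degrees/s (default 3).
#' @return character vector of `"cw"` / `"ccw"`, one per frame.
#' @export
travel_direction <- function(traj, smooth_s = 0.5, dead_band_deg_s = 3) {
  fr <- attr(traj, "frame_rate")
  th <- atan2(traj$y_cm, traj$x_cm)
  dth <- wrap_angle(diff(th))
  omega <- c(dth[1], dth) * fr            # rad/s
  w <- max(1L, round(smooth_s * fr))
  omega <- moving_average(omega, w)
  dead <- dead_band_deg_s * pi / 180
  dirn <- ifelse(omega > dead, 1L, ifelse(omega < -dead, -1L, 0L))
  # carry last confident direction through the dead band
  conf <- which(dirn != 0L)
  if (length(conf) == 0) return(rep("ccw", nrow(traj)))
  filled <- dirn
  last <- dirn[conf[1]]
  for (i in seq_along(dirn)) {
    if (filled[i] == 0L) filled[i] <- last else last <- filled[i]
  }
  if (conf[1] > 1) filled[seq_len(conf[1] - 1)] <- dirn[conf[1]]
  ifelse(filled > 0, "ccw", "cw")
}

#' Signed along-track angle between two mice
#'
#' The angle from the imaged animal to the conspecific measured along the
#' track in the direction of travel, unwrapped to `[0, 360)` degrees and
#' negated for clockwise travel (so clockwise frames span `(-360, 0]`).
#' Values near 0 mean the conspecific is just ahead; absolute values near 360
#' mean it is just behind.
#'
#' @param self_xy,other_xy n x 2 position matrices, cm, arena-centered.
#' @param travel_dir per-frame `"cw"`/`"ccw"` (see [travel_direction()]).
#' @param arena the annulus [arena_geometry()]; frames with either animal
#'   off the track are marked invalid.
#' @param track_tol radial tolerance in cm beyond the track walls (default
#'   1).
#' @return data.frame with `alpha_deg`, `travel_dir`, `valid`.
#' @export
compute_alpha <- function(self_xy, other_xy, travel_dir, arena,
                          track_tol = 1) {
  stopifnot(arena$shape == "annulus")
  r_in <- arena$inner / 2 - track_tol
  r_out <- arena$outer / 2 + track_tol
  rs <- sqrt(self_xy[, 1]^2 + self_xy[, 2]^2)
  ro <- sqrt(other_xy[, 1]^2 + other_xy[, 2]^2)
  valid <- is.finite(rs) & is.finite(ro) &
    rs >= r_in & rs <= r_out & ro >= r_in & ro <= r_out
  ths <- atan2(self_xy[, 2], self_xy[, 1])
  tho <- atan2(other_xy[, 2], other_xy[, 1])
  ahead_ccw <- ((tho - ths) * 180 / pi) %% 360
  ahead_cw <- ((ths - tho) * 180 / pi) %% 360
  alpha <- ifelse(travel_dir == "ccw", ahead_ccw, -ahead_cw)
  alpha[!valid] <- NA_real_
  data.frame(alpha_deg = alpha, travel_dir = travel_dir, valid = valid)
}

# Circular (wrapping) banded Gaussian kernel, n bins.
gauss_band_circular <- function(n, sd) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  d <- pmin(d, n - d)
  exp(-d^2 / (2 * sd^2))
}

#' One-dimensional angle map of a cell
#'
#' Event rate as a function of the signed track angle, in 15-degree bins:
#' 24 bins for the counter-clockwise half (`[0, 360)`) and 24 for the
#' clockwise half (`(-360, 0]`).  Rates are events divided by time spent per
#' bin; each half is smoothed circularly and independently with a Gaussian
#' kernel (sd = 1 bin), renormalised over visited bins.
#'
#' @param alpha data.frame from [compute_alpha()].
#' @param events binary event vector, one per frame.
#' @param frame_rate Hz.
#' @param bin_deg bin width, degrees (default 15).
#' @param smooth_sd kernel sd in bins (default 1).
#' @return object of class `angle_map`: per half (`ccw`, `cw`) the
#'   `occupancy` (s), `counts`, `rate` and `smoothed` vectors, plus signed
#'   bin `centers_deg`.
#' @export
build_angle_map <- function(alpha, events, frame_rate, bin_deg = 15,
                            smooth_sd = 1) {
  nb <- round(360 / bin_deg)
  dt <- 1 / frame_rate
  ev <- events == 1
  half <- function(sel, a) {
    # a in [0, 360) within the half
    bin <- pmin(floor(a / bin_deg) + 1L, nb)
    occ <- tabulate(bin[sel], nbins = nb) * dt
    cnt <- tabulate(bin[sel & ev], nbins = nb)
    visited <- occ > 0
    rate <- ifelse(visited, cnt / ifelse(occ > 0, occ, 1), NA_real_)
    K <- gauss_band_circular(nb, smooth_sd)
    num <- K %*% ifelse(visited, rate, 0)
    den <- K %*% as.numeric(visited)
    smoothed <- ifelse(visited, num / den, NA_real_)
    list(occupancy = occ, counts = cnt, rate = rate,
         smoothed = as.numeric(smoothed), visited = visited)
  }
  ccw_sel <- alpha$valid & alpha$travel_dir == "ccw"
  cw_sel <- alpha$valid & alpha$travel_dir == "cw"
  a_ccw <- alpha$alpha_deg %% 360
  a_cw <- (-alpha$alpha_deg) %% 360
  structure(list(
    ccw = half(ccw_sel, a_ccw),
    cw = half(cw_sel, a_cw),
    bin_deg = bin_deg,
    centers_deg = list(ccw = (seq_len(nb) - 0.5) * bin_deg,
                       cw = -(seq_len(nb) - 0.5) * bin_deg)),
    class = "angle_map")
}

#' Information content of an angle map
#'
#' The bits-per-event information score applied to the one-dimensional map,
#' with occupancy pooled over both travel-direction halves.
#'
#' @param map an `angle_map`.
#' @param use_smoothed use the smoothed rates (default).
#' @return bits/event, `NA` if no events.
#' @export
angle_map_information <- function(map, use_smoothed = TRUE) {
  get <- function(h) if (use_smoothed) h$smoothed else h$rate
  occ <- c(map$ccw$occupancy, map$cw$occupancy)
  lam <- c(get(map$ccw), get(map$cw))
  v <- occ > 0 & is.finite(lam)
  if (!any(v)) return(NA_real_)
  information_from_pl(occ[v] / sum(occ[v]), lam[v])
}

#' Peak metrics of an angle map
#'
#' Finds the global peak of the smoothed map, grows the signal region as the
#' contiguous (circular, within the peak's half) run of bins with rate at
#' least half the peak, and reports its angular half-width, the fraction of
#' total map activity inside the region, and the signal-to-noise activity
#' ratio: the mean rate inside the signal region divided by the mean rate
#' over the complementary noise region (both halves).  Normalising per bin
#' rather than per total makes the ratio comparable between narrow and broad
#' signal regions.
#'
#' @param map an `angle_map`.
#' @return list: `peak_deg` (signed), `peak_rate`, `half` (`"ccw"`/`"cw"`),
#'   `half_width_deg`, `signal_fraction`, `activity_ratio`, `untuned`
#'   (TRUE when the half-decay region spans the entire map).
#' @export
peak_metrics <- function(map) {
  nb <- length(map$ccw$smoothed)
  all_sm <- c(map$ccw$smoothed, map$cw$smoothed)
  if (all(!is.finite(all_sm)) || max(all_sm, na.rm = TRUE) <= 0)
    return(list(peak_deg = NA_real_, peak_rate = NA_real_, half = NA,
                half_width_deg = NA_real_, signal_fraction = NA_real_,
                activity_ratio = NA_real_, untuned = NA))
  k <- which.max(ifelse(is.finite(all_sm), all_sm, -Inf))
  half_name <- if (k <= nb) "ccw" else "cw"
  h <- map[[half_name]]
  pk <- if (k <= nb) k else k - nb
  peak <- h$smoothed[pk]
  thr <- peak / 2
  inreg <- rep(FALSE, nb)
  inreg[pk] <- TRUE
  # grow clockwise and counter-clockwise around the circular half
  for (dirn in c(1L, -1L)) {
    i <- pk
    repeat {
      i <- ((i - 1 + dirn) %% nb) + 1
      if (i == pk || inreg[i]) break
      if (is.finite(h$smoothed[i]) && h$smoothed[i] >= thr) {
        inreg[i] <- TRUE
      } else break
    }
  }
  total <- sum(all_sm[is.finite(all_sm)])
  sig_vals <- h$smoothed[inreg]
  other <- setdiff(c("ccw", "cw"), half_name)
  noise_vals <- c(h$smoothed[!inreg], map[[other]]$smoothed)
  sig <- sum(sig_vals[is.finite(sig_vals)])
  sf <- if (total > 0) sig / total else NA_real_
  sig_mean <- mean(sig_vals, na.rm = TRUE)
  noise_mean <- mean(noise_vals, na.rm = TRUE)
  ratio <- if (is.finite(noise_mean) && noise_mean > 0) {
    sig_mean / noise_mean
  } else Inf
  list(peak_deg = map$centers_deg[[half_name]][pk],
       peak_rate = peak, half = half_name,
       half_width_deg = sum(inreg) * map$bin_deg,
       signal_fraction = sf,
       activity_ratio = ratio,
       untuned = all(inreg))
}

#' Stack angle maps into a population matrix
#'
#' @param maps list of `angle_map` objects.
#' @param use_smoothed use smoothed rates (default).
#' @return numeric matrix, cells x (2 * bins): columns 1..24 the ccw half,
#'   25..48 the cw half; unvisited bins are `NA`.
#' @export
angle_map_matrix <- function(maps, use_smoothed = TRUE) {
  get <- function(m, h) if (use_smoothed) m[[h]]$smoothed else m[[h]]$rate
  t(vapply(maps, function(m) c(get(m, "ccw"), get(m, "cw")),
           numeric(2 * length(maps[[1]]$ccw$smoothed))))
}

#' Population autocorrelogram of angle maps
#'
#' Correlates the stacked collection of angle maps with circularly shifted
#' versions of themselves, shifting each travel-direction half independently
#' but computing one Pearson correlation from both halves together, for
#' shifts from -180 to +180 degrees.
#'
#' @param mat population matrix from [angle_map_matrix()] (cells x 48).
#' @param bin_deg bin width in degrees (default 15).
#' @param max_shift_deg largest absolute shift (default 180).
#' @return data.frame `shift_deg`, `r`.
#' @export
population_autocorrelogram <- function(mat, bin_deg = 15,
                                       max_shift_deg = 180) {
  nb <- ncol(mat) / 2
  kmax <- round(max_shift_deg / bin_deg)
  shifts <- seq(-kmax, kmax)
  r <- vapply(shifts, function(k) {
    idx <- ((seq_len(nb) - 1 + k) %% nb) + 1
    shifted <- cbind(mat[, idx, drop = FALSE],
                     mat[, nb + idx, drop = FALSE])
    a <- as.numeric(mat); b <- as.numeric(shifted)
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      return(NA_real_)
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  data.frame(shift_deg = shifts * bin_deg, r = r)
}

#' Normalised area under an autocorrelogram
#'
#' Mean correlation over the shift grid, so values are comparable across
#' grids; narrower population tuning gives a smaller area.
#'
#' @param acg data.frame from [population_autocorrelogram()].
#' @return mean correlation.
#' @export
autocorrelogram_auc <- function(acg) {
  mean(acg$r, na.rm = TRUE)
}

#' Label-shuffle test for an autocorrelogram AUC difference
#'
#' Observed difference `auc(A) - auc(B)` between two map populations,
#' compared with the null distribution obtained by shuffling the group tags
#' of the pooled cells.
#'
#' @param mat_a,mat_b population matrices ([angle_map_matrix()]).
#' @param n_shuffles tag permutations (default 1000).
#' @param seed integer seed.
#' @return list: `observed` difference, `null` vector of shuffled
#'   differences, `p_greater` fraction of null at least as large as observed.
#' @export
auc_label_shuffle <- function(mat_a, mat_b, n_shuffles = 1000, seed = 1) {
  pool <- rbind(mat_a, mat_b)
  na <- nrow(mat_a)
  ntot <- nrow(pool)
  auc_of <- function(rows) {
    autocorrelogram_auc(population_autocorrelogram(pool[rows, , drop = FALSE]))
  }
  observed <- auc_of(seq_len(na)) - auc_of(seq(na + 1, ntot))
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      idx <- sample.int(ntot)
      auc_of(idx[seq_len(na)]) - auc_of(idx[seq(na + 1, ntot)])
    }, numeric(1))
  })
  list(observed = observed, null = null,
       p_greater = mean(abs(null) >= abs(observed)))
}

#' Label pursuit sessions as naive or trained
#'
#' A mouse is trained from the first session whose median trial latency falls
#' below 30% of the highest latency observed on the previous day; that and
#' all later sessions are trained, all earlier ones naive.  The first session
#' is always naive.
#'
#' @param latencies list of numeric vectors, trial latencies (s) per session
#'   in chronological order.
#' @param threshold fraction of the previous day's maximum (default 0.3).
#' @return data.frame `session`, `median_latency_s`, `label`.
#' @export
label_sessions <- function(latencies, threshold = 0.3) {
  n <- length(latencies)
  stopifnot(n >= 1)
  med <- vapply(latencies, stats::median, numeric(1))
  label <- rep("naive", n)
  trained <- FALSE
  for (d in seq_len(n)) {
    if (d > 1 && !trained &&
        med[d] < threshold * max(latencies[[d - 1]])) trained <- TRUE
    if (trained) label[d] <- "trained"
  }
  data.frame(session = seq_len(n), median_latency_s = med, label = label)
}

#' Autocorrelogram AUC across experience
#'
#' Pools angle maps over non-overlapping groups of consecutive sessions,
#' computes each group's autocorrelogram AUC, and tests for a linear trend of
#' AUC against group index with a two-tailed Pearson correlation test.
#'
#' @param maps list of `angle_map` objects, pooled across sessions.
#' @param session_index session number of each map's cell.
#' @param group_size sessions per group (default 5).
#' @return list: `auc` data.frame (`group`, `sessions`, `n_maps`, `auc`),
#'   `r` Pearson correlation of AUC vs group index, `p_value`.
#' @export
experience_curve <- function(maps, session_index, group_size = 5) {
  stopifnot(length(maps) == length(session_index))
  grp <- (session_index - min(session_index)) %/% group_size + 1
  groups <- sort(unique(grp))
  if (length(groups) < 2) stop("need at least two session groups")
  auc <- vapply(groups, function(g) {
    autocorrelogram_auc(
      population_autocorrelogram(angle_map_matrix(maps[grp == g])))
  }, numeric(1))
  tab <- data.frame(group = groups,
                    n_maps = as.integer(table(factor(grp, levels = groups))),
                    auc = auc)
  ct <- stats::cor.test(tab$group, tab$auc)
  list(auc = tab, r = unname(ct$estimate), p_value = ct$p.value)
}
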