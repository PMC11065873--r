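# Shuffle-calibrated cell classification: temporal-shuffle null distributions
# of spatial information, the place/social-vector category rules, the overlap
# index, and the shuffling-in-place false-positive control.

# Frame name -> conventional category label.
frame_category <- c(self_allo = "selfPC", other_allo = "socialPC",
                    rel_allo = "alloSVC", rel_ego = "egoSVC")

#' Circularly shift an event train in time
#'
#' Displaces the calcium event train by `shift` frames, wrapping around the
#' session duration; the event count is conserved.
#'
#' @param events binary event vector.
#' @param shift shift in frames, `0 < shift < length(events)`.
#' @return shifted binary vector.
#' @export
temporal_shuffle <- function(events, shift) {
  n <- length(events)
  stopifnot(shift > 0, shift < n)
  events[((seq_len(n) - 1 - shift) %% n) + 1]
}

# Information of a cell's map under many circular time shifts, vectorised:
# per shift, event frames are displaced and re-binned against the fixed
# occupancy, maps are batch-smoothed and Eq.-style information evaluated.
shuffled_information <- function(bf, ev_frames, shifts) {
  n <- length(bf$idx)
  nbin <- bf$nb^2
  S <- length(shifts)
  cnts <- matrix(0, nbin, S)
  for (s in seq_len(S)) {
    f2 <- ((ev_frames - 1 + shifts[s]) %% n) + 1
    b <- bf$idx[f2]
    cnts[, s] <- tabulate(b[!is.na(b)], nbins = nbin)
  }
  sm <- smooth_flat(bf, cnts)
  lam <- sm[bf$visited, , drop = FALSE]
  p <- bf$occupancy[bf$visited] / sum(bf$occupancy[bf$visited])
  # I = (1/L) sum_i p_i l_i log2 l_i - log2 L, with 0 log 0 := 0
  L <- as.numeric(crossprod(lam, p))
  ll <- lam * log(lam)
  ll[lam == 0] <- 0
  num <- as.numeric(crossprod(ll, p)) / log(2)
  out <- num / L - log2(L)
  out[!is.finite(L) | L <= 0] <- NA_real_
  out
}

#' Classify cells against temporal-shuffle null distributions
#'
#' For every cell and reference frame, computes the spatial information of
#' the true map, a null distribution of information from `n_shuffles`
#' circular time shifts of the event train (uniform shifts with a minimum
#' displacement), the 95th-percentile cutoff (linear-interpolation
#' percentile), and split-half stability.  A cell is a member of a frame's
#' category when its information exceeds the cutoff and its stability exceeds
#' `stability_min`; categories are non-exclusive, so one cell can belong to
#' several.
#'
#' @param session a `social_session`.
#' @param specs list of [frame_spec()] objects to test (default: all four
#'   frames against the first partner).
#' @param cells cell indices (default all raster rows).
#' @param n_shuffles shuffles per cell and frame (default 1000).
#' @param percentile cutoff percentile of the null distribution (default 95).
#' @param stability_min split-half stability criterion (default 0.3).
#' @param min_shift_s minimum temporal displacement of a shuffle, seconds
#'   (default 20).
#' @param seed master seed; per-(cell, frame) streams are derived from it, so
#'   results do not depend on cell ordering.
#' @return data.frame, one row per cell x frame: `cell`, `frame`, `referent`,
#'   `category`, `info`, `cutoff`, `stability`, `member`.  Cells with no
#'   events get `NA` information and are members of nothing.
#' @export
classify_cells <- function(session, specs = NULL, cells = NULL,
                           n_shuffles = 1000, percentile = 95,
                           stability_min = 0.3, min_shift_s = 20,
                           seed = session$seed %||% 1) {
  if (is.null(specs)) {
    ref <- names(session$trajectories)[2]
    specs <- list(frame_spec("self_allo"),
                  frame_spec("other_allo", ref),
                  frame_spec("rel_allo", ref),
                  frame_spec("rel_ego", ref))
  }
  if (is.null(cells)) cells <- seq_len(nrow(session$raster))
  n <- ncol(session$raster)
  min_shift <- max(1L, round(min_shift_s * session$frame_rate))
  if (2 * min_shift >= n)
    stop("session too short for the requested minimum shuffle shift")
  out <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    geom <- map_geometry(session$arena, spec)
    fc <- frame_coordinates(session$trajectories, spec)
    bf <- bin_frames(fc$xy, fc$valid, geom$half_extent, geom$bin_size,
                     session$frame_rate)
    for (ci in seq_along(cells)) {
      cell <- cells[ci]
      ev <- which(session$raster[cell, ] == 1)
      if (length(ev) == 0) {
        out[[length(out) + 1]] <- data.frame(
          cell = cell, frame = spec$frame,
          referent = spec$referent %||% NA_character_,
          category = frame_category[[spec$frame]],
          info = NA_real_, cutoff = NA_real_, stability = NA_real_,
          member = FALSE)
        next
      }
      info <- shuffled_information(bf, ev, 0L)  # shift 0 = true map
      shifts <- with_seed(derive_seed(seed, 1000 * si + cell), {
        sample(seq(min_shift, n - min_shift), n_shuffles, replace = TRUE)
      })
      null_info <- shuffled_information(bf, ev, shifts)
      cutoff <- as.numeric(stats::quantile(null_info, percentile / 100,
                                           na.rm = TRUE, type = 7))
      stab <- split_half_stability(fc$xy, fc$valid, ev, geom$half_extent,
                                   geom$bin_size, session$frame_rate)
      member <- is.finite(info) && is.finite(cutoff) && info > cutoff &&
        is.finite(stab) && stab > stability_min
      out[[length(out) + 1]] <- data.frame(
        cell = cell, frame = spec$frame,
        referent = spec$referent %||% NA_character_,
        category = frame_category[[spec$frame]],
        info = info, cutoff = cutoff, stability = stab, member = member)
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap index between two cell categories
#'
#' Observed number of cells in both categories divided by its expectation
#' under independence, `N * (n_A/N) * (n_B/N)`.  Values above 1 indicate more
#' co-membership than chance.  Significance from an exact two-tailed binomial
#' test of `n_AB` successes in `N` trials with probability
#' `P = (n_A/N)(n_B/N)`.
#'
#' @param n_a,n_b category sizes.
#' @param n_ab number of cells in both.
#' @param n_total total number of cells.
#' @return list with `index` and `p_value`; `index` is `NA` if either
#'   category is empty.
#' @export
overlap_index <- function(n_a, n_b, n_ab, n_total) {
  stopifnot(n_ab <= min(n_a, n_b), max(n_a, n_b) <= n_total)
  if (n_a == 0 || n_b == 0)
    return(list(index = NA_real_, p_value = NA_real_))
  p_ind <- (n_a / n_total) * (n_b / n_total)
  expected <- n_total * p_ind
  pv <- stats::binom.test(n_ab, n_total, p = p_ind,
                          alternative = "two.sided")$p.value
  list(index = n_ab / expected, p_value = pv)
}

#' Shuffling-in-place control
#'
#' Permutes a cell's events in a way that preserves its self-place map while
#' destroying tuning to the partner's relative position.  The physical arena
#' is divided into 10-cm bins; for each bin the frames during which the
#' imaged animal occupied it are stitched together, the event sub-train is
#' circularly shifted by a random amount at least `min_shift_s` away from
#' identity (or by the maximum-distance shift where the bin's coverage is too
#' short), and the episodes are re-placed in temporal order.
#'
#' @param session a `social_session`.
#' @param cell raster row to shuffle.
#' @param n_instances number of independent shuffled instances (default 10).
#' @param bin_cm spatial bin width of the in-place partition, cm (default 10).
#' @param min_shift_s minimum temporal distance of the within-bin shift,
#'   seconds (default 5).
#' @param seed integer seed.
#' @return integer matrix `n_instances` x `n_frames` of shuffled event
#'   trains.
#' @export
shuffle_in_place <- function(session, cell, n_instances = 10, bin_cm = 10,
                             min_shift_s = 5, seed = session$seed %||% 1) {
  traj <- session$trajectories[[1]]
  n <- nrow(traj)
  if (n / session$frame_rate < 2 * min_shift_s)
    stop("session too short for shuffling-in-place")
  half <- arena_half_extent(session$arena)
  bf <- bin_frames(cbind(traj$x_cm, traj$y_cm), traj$valid, half, bin_cm,
                   session$frame_rate, smooth_sd = 1)
  ev <- session$raster[cell, ]
  ms <- max(1L, round(min_shift_s * session$frame_rate))
  bins <- sort(unique(bf$idx[!is.na(bf$idx)]))
  frames_by_bin <- lapply(bins, function(b) which(!is.na(bf$idx) & bf$idx == b))
  out <- matrix(rep(as.integer(ev), n_instances), nrow = n_instances,
                byrow = TRUE)
  with_seed(derive_seed(seed, 7000 + cell), {
    for (inst in seq_len(n_instances)) {
      for (fb in frames_by_bin) {
        m <- length(fb)
        if (m < 2) next
        if (m >= 2 * ms) {
          s <- sample(seq(ms, m - ms), 1)
        } else {
          s <- floor(m / 2)    # maximum-distance shift for low-coverage bins
          if (s < 1) next
        }
        sub <- ev[fb]
        out[inst, fb] <- sub[((seq_len(m) - 1 - s) %% m) + 1]
      }
    }
  })
  out
}
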