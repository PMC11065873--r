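# Occupancy and event-rate maps on a square bin grid, with NaN-aware Gaussian
# smoothing, spatial information, field detection, split-half stability and
# radial field-density profiles.

# Precompute everything about a binned trajectory that does not depend on the
# events: per-frame flat bin index, occupancy, visited mask and the smoothing
# operators.  Shared by rate_map(), the shuffle machinery and the decoder.
bin_frames <- function(xy, valid, half_extent, bin_size, frame_rate,
                       smooth_sd = 2) {
  nb <- ceiling(2 * half_extent / bin_size - 1e-9)
  ix <- floor((xy[, 1] + half_extent) / bin_size) + 1
  iy <- floor((xy[, 2] + half_extent) / bin_size) + 1
  ix[ix == nb + 1 & xy[, 1] <= half_extent + 1e-9] <- nb  # boundary inclusive
  iy[iy == nb + 1 & xy[, 2] <= half_extent + 1e-9] <- nb
  ok <- valid & is.finite(ix) & is.finite(iy) &
    ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
  idx <- rep(NA_integer_, nrow(xy))
  idx[ok] <- as.integer(ix[ok] + (iy[ok] - 1) * nb)
  dt <- 1 / frame_rate
  occ_frames <- tabulate(idx[ok], nbins = nb * nb)
  occupancy <- occ_frames * dt
  visited <- occupancy > 0
  K <- gauss_band(nb, smooth_sd)
  # occupancy-weighted smoothing: the smoothed rate is the Gaussian-smoothed
  # count map divided by the Gaussian-smoothed occupancy map
  den <- K %*% matrix(occupancy, nb, nb) %*% K
  centers <- -half_extent + (seq_len(nb) - 0.5) * bin_size
  xg <- rep(seq_len(nb), nb); yg <- rep(seq_len(nb), each = nb)
  tidx <- yg + (xg - 1L) * nb   # flat-index transpose permutation
  list(nb = nb, bin_size = bin_size, half_extent = half_extent,
       centers = centers, idx = idx, valid_frame = ok, dt = dt,
       occupancy = occupancy, visited = visited, K = K, den = den,
       tidx = tidx, smooth_sd = smooth_sd)
}

# Banded 1-D Gaussian kernel as an n x n matrix (unnormalised; normalisation
# happens jointly with the visited mask).
gauss_band <- function(n, sd, radius = NULL) {
  if (is.null(radius)) radius <- ceiling(3 * sd)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sd^2))
  K[d > radius] <- 0
  K
}

# Occupancy-normalised smoothing: columns of `count_flat` are flat nb*nb
# event-count maps; the result column is smooth(counts) / smooth(occupancy),
# with NA at unvisited bins.  The separable kernel is applied as two banded
# multiplies with a transpose permutation (an involution on flat indices) in
# between, avoiding 3-D array copies.
smooth_flat <- function(bf, count_flat) {
  nb <- bf$nb
  S <- ncol(count_flat)
  A <- count_flat
  dim(A) <- c(nb, nb * S)
  A <- bf$K %*% A                             # smooth along x
  dim(A) <- c(nb * nb, S)
  A <- A[bf$tidx, , drop = FALSE]             # transpose each map
  dim(A) <- c(nb, nb * S)
  A <- bf$K %*% A                             # smooth along y
  dim(A) <- c(nb * nb, S)
  A <- A[bf$tidx, , drop = FALSE]
  out <- A / as.numeric(bf$den)
  out[!bf$visited, ] <- NA_real_
  out
}

#' Build an event-rate map
#'
#' Accumulates occupancy and event counts over valid frames on a square grid
#' and divides to get raw rates.  The smoothed rate applies a 2-D Gaussian
#' kernel (sd = 2 bins by default) to the count and occupancy maps separately
#' and divides the results, so sparsely visited bins borrow statistical
#' strength from their neighbourhood instead of contributing single-frame
#' rate outliers.  Bins never visited are flagged `NA`, not zero-filled.
#'
#' @param xy n x 2 matrix of per-frame coordinates (cm) in the map's
#'   reference frame (see [frame_coordinates()]).
#' @param valid logical per frame; invalid frames enter neither occupancy nor
#'   counts.
#' @param events binary event vector (one per frame) or integer vector of
#'   event frame indices.
#' @param half_extent grid spans `[-half_extent, half_extent]` per axis (cm).
#' @param bin_size bin side in cm (2 for allocentric maps, 4 for
#'   relative-position maps on the effective arena).
#' @param frame_rate Hz.
#' @param smooth_sd Gaussian kernel sd in bins (default 2).
#' @return object of class `rate_map`: matrices `occupancy` (s), `counts`,
#'   `rate` and `smoothed` (events/s), logical `visited`, bin `centers`,
#'   scalar `overall_rate`, plus grid metadata.
#' @export
rate_map <- function(xy, valid, events, half_extent, bin_size = 2,
                     frame_rate = 30, smooth_sd = 2) {
  bf <- bin_frames(xy, valid, half_extent, bin_size, frame_rate, smooth_sd)
  if (!any(bf$valid_frame)) stop("no valid frames: cannot build a map")
  finish_map(bf, event_frames(events, length(bf$idx)))
}

# Normalise `events` to a vector of frame indices.
event_frames <- function(events, n_frames) {
  if (length(events) == n_frames && all(events %in% c(0, 1))) {
    which(events == 1)
  } else {
    ev <- as.integer(events)
    stopifnot(all(ev >= 1 & ev <= n_frames))
    ev
  }
}

# Assemble a rate_map object from a binned-frame structure and event frames.
finish_map <- function(bf, ev_frames, frame = NULL) {
  nb <- bf$nb
  bidx <- bf$idx[ev_frames]
  counts <- tabulate(bidx[!is.na(bidx)], nbins = nb * nb)
  rate <- rep(NA_real_, nb * nb)
  rate[bf$visited] <- counts[bf$visited] / bf$occupancy[bf$visited]
  sm <- smooth_flat(bf, matrix(as.numeric(counts), ncol = 1))[, 1]
  total_time <- sum(bf$occupancy)
  structure(list(
    frame = frame,
    nb = nb, bin_size = bf$bin_size, half_extent = bf$half_extent,
    centers = bf$centers,
    occupancy = matrix(bf$occupancy, nb, nb),
    pooled_occ = matrix(bf$den, nb, nb),   # kernel-weighted occupancy, s
    counts = matrix(counts, nb, nb),
    rate = matrix(rate, nb, nb),
    smoothed = matrix(sm, nb, nb),
    visited = matrix(bf$visited, nb, nb),
    overall_rate = sum(counts) / total_time,
    total_time = total_time), class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf(
    "<rate_map> %dx%d bins of %g cm, %.1f s occupancy, %d events, peak %.2f ev/s\n",
    x$nb, x$nb, x$bin_size, x$total_time, sum(x$counts),
    suppressWarnings(max(x$smoothed, na.rm = TRUE))))
  invisible(x)
}

#' Map of a session cell in a reference frame
#'
#' Convenience wrapper: extracts the session coordinates in `spec`'s frame
#' and builds the cell's rate map with the conventional bin sizes (2 cm for
#' allocentric frames, 4 cm on the doubled effective arena for relative
#' frames).
#'
#' @param session a `social_session`.
#' @param cell cell index (row of the raster).
#' @param spec a [frame_spec()].
#' @param bin_size override the default bin size (cm).
#' @param smooth_sd kernel sd in bins.
#' @param frames optional subset of frame indices to restrict to (e.g. one
#'   session half).
#' @return a `rate_map`.
#' @export
session_rate_map <- function(session, cell, spec, bin_size = NULL,
                             smooth_sd = 2, frames = NULL) {
  geom <- map_geometry(session$arena, spec, bin_size)
  fc <- frame_coordinates(session$trajectories, spec)
  valid <- fc$valid
  events <- session$raster[cell, ]
  if (!is.null(frames)) {
    keep <- rep(FALSE, length(valid)); keep[frames] <- TRUE
    valid <- valid & keep
  }
  rate_map(fc$xy, valid, events, geom$half_extent, geom$bin_size,
           session$frame_rate, smooth_sd)
}

# Grid geometry for a frame: physical extent/2-cm bins for allocentric maps,
# doubled extent/4-cm bins for relative maps.
map_geometry <- function(arena, spec, bin_size = NULL) {
  if (spec$frame %in% c("rel_allo", "rel_ego")) {
    ea <- effective_arena(arena)
    list(half_extent = ea$half_extent,
         bin_size = if (is.null(bin_size)) ea$bin_size else bin_size)
  } else {
    list(half_extent = arena_half_extent(arena),
         bin_size = if (is.null(bin_size)) 2 else bin_size)
  }
}

#' Spatial information content of a rate map
#'
#' The Skaggs-type information score in bits per event,
#' `I = sum_i p_i (l_i / L) log2(l_i / L)`, where `p_i` is occupancy
#' normalised to 1, `l_i` the event rate in bin i, and `L = sum_i p_i l_i`
#' the occupancy-weighted mean rate.  Computed on the smoothed map by default.
#' `I` is a weighted Kullback-Leibler divergence, hence non-negative, and zero
#' iff the rate is constant over visited bins.
#'
#' @param map a `rate_map` (or anything with `occupancy`, `smoothed`, `rate`,
#'   `visited` matrices).
#' @param use_smoothed compute on the smoothed map (default) or the raw one.
#' @return information in bits/event; `NA` if the cell emitted no events
#'   (undefined-information signal).
#' @export
spatial_information <- function(map, use_smoothed = TRUE) {
  lam <- if (use_smoothed) map$smoothed else map$rate
  v <- map$visited
  p <- map$occupancy[v] / sum(map$occupancy[v])
  l <- lam[v]
  information_from_pl(p, l)
}

# Core of the information score shared with the batch shuffle path.
information_from_pl <- function(p, l) {
  L <- sum(p * l)
  if (!is.finite(L) || L <= 0) return(NA_real_)
  nz <- l > 0
  sum(p[nz] * (l[nz] / L) * log2(l[nz] / L))
}

#' Detect firing fields in a smoothed rate map
#'
#' Fields are local maxima of the smoothed map above `peak_min` events/s; the
#' field area is the 4-connected region around the peak with rate above
#' `area_fraction` of the peak.  Candidate peaks falling inside the area of a
#' larger field are merged into it.
#'
#' @param map a `rate_map`.
#' @param peak_min minimum peak rate, events/s (default 0.5).
#' @param area_fraction area contour as a fraction of the peak (default 0.6).
#' @param min_occ_s minimum occupancy (s) for a bin to host a peak (default
#'   0.1); rate estimates from shorter visits are dominated by single-frame
#'   noise (one event in one frame reads as `frame_rate` events/s).
#' @param min_support_s minimum kernel-weighted occupancy behind a peak's
#'   smoothed estimate (default 2 s): with less support, a single event can
#'   by itself push the pooled rate past the 0.5 events/s field threshold.
#' @return data.frame with one row per field: `peak_ix`, `peak_iy`,
#'   `peak_x`, `peak_y` (cm), `peak_rate`, `n_bins`, `size_cm2`, and `mass`
#'   (sum of smoothed rates over the field's area; the field with the
#'   largest mass is the cell's dominant field, see [primary_field()]).
#' @export
detect_fields <- function(map, peak_min = 0.5, area_fraction = 0.6,
                          min_occ_s = 0.1, min_support_s = 4) {
  sm <- map$smoothed
  nb <- map$nb
  z <- ifelse(is.na(sm), -Inf, sm)
  # strict-or-equal local maxima over the 8-neighbourhood
  is_peak <- matrix(TRUE, nb, nb)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- shift_matrix(z, dx, dy, fill = -Inf)
    is_peak <- is_peak & (z >= sh)
  }
  is_peak <- is_peak & map$occupancy >= min_occ_s
  if (!is.null(map$pooled_occ)) is_peak <- is_peak & map$pooled_occ >= min_support_s
  cand <- which(is_peak & z > peak_min, arr.ind = TRUE)
  out <- data.frame(peak_ix = integer(0), peak_iy = integer(0),
                    peak_x = numeric(0), peak_y = numeric(0),
                    peak_rate = numeric(0), n_bins = integer(0),
                    size_cm2 = numeric(0), mass = numeric(0))
  if (nrow(cand) == 0) return(out)
  ord <- order(z[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  claimed <- matrix(FALSE, nb, nb)
  for (k in seq_len(nrow(cand))) {
    px <- cand[k, 1]; py <- cand[k, 2]
    if (claimed[px, py]) next   # merged into a previously grown field
    thr <- area_fraction * z[px, py]
    area <- flood_fill(z, px, py, thr)
    claimed[area] <- TRUE
    nbin <- sum(area)
    out <- rbind(out, data.frame(
      peak_ix = px, peak_iy = py,
      peak_x = map$centers[px], peak_y = map$centers[py],
      peak_rate = z[px, py], n_bins = nbin,
      size_cm2 = nbin * map$bin_size^2,
      mass = sum(z[area & is.finite(z)])))
  }
  out
}

#' Dominant field of a rate map
#'
#' The detected field containing the greatest total in-field activity (sum
#' of smoothed rates over its area).  As a field-location estimator this is
#' robust to narrow high-rate spikes in sparsely sampled map regions, which
#' can out-peak a genuine broad field.
#'
#' @inheritParams detect_fields
#' @return one-row data.frame (see [detect_fields()]), or `NULL` when no
#'   field is detected.
#' @export
primary_field <- function(map, peak_min = 0.5, area_fraction = 0.6,
                          min_occ_s = 0.1, min_support_s = 4) {
  f <- detect_fields(map, peak_min, area_fraction, min_occ_s, min_support_s)
  if (nrow(f) == 0) return(NULL)
  f[which.max(f$mass), , drop = FALSE]
}

#' Location of a map's supported peak
#'
#' The maximum of the smoothed map over bins with at least `min_occ_s`
#' seconds of occupancy and `min_support_s` seconds of kernel-weighted
#' occupancy behind the smoothed estimate, guarding the argmax against rate
#' outliers in barely sampled regions.
#'
#' @param map a `rate_map`.
#' @param min_occ_s minimum bin occupancy, seconds (default 0.1).
#' @param min_support_s minimum pooled (kernel-weighted) occupancy, seconds
#'   (default 2; see [detect_fields()]).
#' @return list with `ix`, `iy` (bin indices), `x`, `y` (bin centre, cm) and
#'   `rate` (events/s); `NULL` if no bin qualifies.
#' @export
map_peak <- function(map, min_occ_s = 0.1, min_support_s = 4) {
  z <- map$smoothed
  z[is.na(z) | map$occupancy < min_occ_s] <- -Inf
  if (!is.null(map$pooled_occ)) z[map$pooled_occ < min_support_s] <- -Inf
  if (all(!is.finite(z))) return(NULL)
  k <- which.max(z)
  ix <- ((k - 1) %% map$nb) + 1
  iy <- ((k - 1) %/% map$nb) + 1
  list(ix = ix, iy = iy, x = map$centers[ix], y = map$centers[iy],
       rate = z[k])
}

shift_matrix <- function(m, dx, dy, fill = 0) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  xs <- seq_len(n1) - dx; ys <- seq_len(n2) - dy
  okx <- xs >= 1 & xs <= n1; oky <- ys >= 1 & ys <= n2
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# 4-connected region of bins with value > thr containing (px, py).
flood_fill <- function(z, px, py, thr) {
  nb1 <- nrow(z); nb2 <- ncol(z)
  inreg <- matrix(FALSE, nb1, nb2)
  stack <- list(c(px, py))
  inreg[px, py] <- TRUE
  while (length(stack) > 0) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + d
      if (q[1] < 1 || q[1] > nb1 || q[2] < 1 || q[2] > nb2) next
      if (inreg[q[1], q[2]]) next
      if (is.finite(z[q[1], q[2]]) && z[q[1], q[2]] > thr) {
        inreg[q[1], q[2]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
  }
  inreg
}

#' Split-half stability of a cell's map
#'
#' Pearson correlation between smoothed maps built from the first and second
#' halves of the session, over bins visited in both halves.
#'
#' @inheritParams rate_map
#' @return Pearson r, or `NA` if fewer than 2 bins are visited in both halves
#'   (undefined-stability signal).
#' @export
split_half_stability <- function(xy, valid, events, half_extent,
                                 bin_size = 2, frame_rate = 30,
                                 smooth_sd = 2) {
  n <- nrow(xy)
  h1 <- seq_len(ceiling(n / 2))       # odd counts: first half gets the extra
  h2 <- setdiff(seq_len(n), h1)
  ev <- event_frames(events, n)
  v1 <- valid; v1[h2] <- FALSE
  v2 <- valid; v2[h1] <- FALSE
  m1 <- try(rate_map(xy, v1, ev[ev <= max(h1)], half_extent, bin_size,
                     frame_rate, smooth_sd), silent = TRUE)
  m2 <- try(rate_map(xy, v2, ev[ev > max(h1)], half_extent, bin_size,
                     frame_rate, smooth_sd), silent = TRUE)
  if (inherits(m1, "try-error") || inherits(m2, "try-error"))
    return(NA_real_)
  map_correlation(m1, m2)
}

#' Pearson correlation between two maps over commonly visited bins
#'
#' @param m1,m2 `rate_map` objects on the same grid.
#' @return Pearson r; `NA` with fewer than 2 common bins or zero variance.
#' @export
map_correlation <- function(m1, m2) {
  common <- m1$visited & m2$visited
  if (sum(common) < 2) return(NA_real_)
  a <- m1$smoothed[common]; b <- m2$smoothed[common]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Radial density and coverage of field peaks around the animal
#'
#' For relative-frame fields, counts field peaks inside concentric rings
#' around the origin (the imaged animal), normalised by ring area, and
#' reports each ring's coverage: the fraction of its bins that were visited.
#'
#' @param peaks matrix/data.frame with columns `peak_x`, `peak_y` (cm),
#'   pooled across cells.
#' @param occupancy_map a `rate_map` of the relative frame supplying the grid
#'   and visited mask.
#' @param ring_width radial ring width in cm (default 5).
#' @return data.frame: `r_inner`, `r_outer`, `n_peaks`, `density`
#'   (peaks/cm^2), `coverage` (fraction of ring bins visited).
#' @export
radial_field_density <- function(peaks, occupancy_map, ring_width = 5) {
  rmax <- occupancy_map$half_extent
  edges <- seq(0, rmax, by = ring_width)
  if (edges[length(edges)] < rmax) edges <- c(edges, rmax)
  ctr <- occupancy_map$centers
  br <- sqrt(outer(ctr^2, ctr^2, "+"))
  pr <- if (nrow(rbind(peaks)) > 0) {
    sqrt(as.numeric(peaks$peak_x)^2 + as.numeric(peaks$peak_y)^2)
  } else numeric(0)
  out <- data.frame(r_inner = edges[-length(edges)], r_outer = edges[-1])
  out$n_peaks <- vapply(seq_len(nrow(out)), function(i) {
    sum(pr >= out$r_inner[i] & pr < out$r_outer[i])
  }, integer(1))
  out$density <- out$n_peaks / (pi * (out$r_outer^2 - out$r_inner^2))
  out$coverage <- vapply(seq_len(nrow(out)), function(i) {
    inring <- br >= out$r_inner[i] & br < out$r_outer[i]
    if (!any(inring)) return(0)
    sum(occupancy_map$visited[inring]) / sum(inring)
  }, numeric(1))
  out
}
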