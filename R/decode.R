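# Naive-Bayes population decoding of position in any reference frame, with
# contiguous 5-fold cross-validation, circular-shift shuffled baselines, and
# cross-referent (identity) decoding.

#' Fit a naive-Bayes decoder on a set of training frames
#'
#' Per-cell tuning curves `f_i(X)` are the smoothed training rate maps and
#' the prior `P(X)` is the training occupancy, normalised over visited bins.
#'
#' @param xy n x 2 frame coordinates (cm) in the decoding frame.
#' @param valid logical per frame.
#' @param raster binary cells x frames matrix (the rows to decode with).
#' @param train_frames integer indices of training frames.
#' @param half_extent,bin_size grid geometry (cm).
#' @param frame_rate Hz.
#' @param rate_floor minimum f_i(X), events/s, keeping log-likelihoods finite
#'   in bins where a cell was silent during training (default 1e-4).
#' @param smooth_sd kernel sd in bins.
#' @return object of class `bayes_decoder`: `log_f` (bins x cells), `log_p`
#'   (bins), `sum_f` (bins), bin centres and metadata.
#' @export
fit_decoder <- function(xy, valid, raster, train_frames, half_extent,
                        bin_size, frame_rate, rate_floor = 1e-4,
                        smooth_sd = 2) {
  n <- ncol(raster)
  vtrain <- valid
  keep <- rep(FALSE, n); keep[train_frames] <- TRUE
  vtrain <- vtrain & keep
  bf <- bin_frames(xy, vtrain, half_extent, bin_size, frame_rate, smooth_sd)
  if (!any(bf$visited)) stop("no visited bins in training data")
  ncell <- nrow(raster)
  nbin <- bf$nb^2
  cnts <- matrix(0, nbin, ncell)
  for (i in seq_len(ncell)) {
    b <- bf$idx[raster[i, ] == 1]
    cnts[, i] <- tabulate(b[!is.na(b)], nbins = nbin)
  }
  fmat <- smooth_flat(bf, cnts)       # all cells smoothed in one pass
  fmat[is.na(fmat)] <- 0
  fmat <- pmax(fmat, rate_floor)
  prior <- bf$occupancy / sum(bf$occupancy)
  log_p <- ifelse(bf$visited, log(prior), -Inf)
  vb <- which(bf$visited)
  structure(list(
    log_f = log(fmat[vb, , drop = FALSE]),
    sum_f = rowSums(fmat[vb, , drop = FALSE]),  # sum over cells, per bin
    log_p = log_p[vb], visited_bins = vb,
    nb = bf$nb, bin_size = bin_size, half_extent = half_extent,
    centers = bf$centers, frame_rate = frame_rate,
    rate_floor = rate_floor), class = "bayes_decoder")
}

#' Decode event-count windows with a fitted decoder
#'
#' Maximum a-posteriori position under independent-Poisson likelihoods:
#' `argmax_X log P(X) + sum_i n_i log f_i(X) - tau sum_i f_i(X)` (the
#' normalisation constant is irrelevant to the argmax).  Ties resolve to the
#' lowest bin index (x-fastest order).
#'
#' @param model a `bayes_decoder`.
#' @param n_counts cells x windows matrix of event counts per window.
#' @param tau window length in seconds.
#' @return list with `bin` (flat bin index per window, on the full grid) and
#'   `xy` (windows x 2 matrix of decoded bin centres, cm).
#' @export
decode_window <- function(model, n_counts, tau) {
  n_counts <- rbind(n_counts)
  # log-posterior over visited bins for all windows at once
  lp <- model$log_p - tau * model$sum_f +
    model$log_f %*% n_counts
  best <- max.col(t(lp), ties.method = "first")
  bins <- model$visited_bins[best]
  ix <- ((bins - 1) %% model$nb) + 1
  iy <- ((bins - 1) %/% model$nb) + 1
  list(bin = bins, xy = cbind(model$centers[ix], model$centers[iy]))
}

# Event counts per cell in centred windows of `w` frames at the given window
# centres.  `cs` may pass a precomputed cumulative-sum matrix (cells x n+1).
window_counts <- function(raster, centers, w, cs = NULL) {
  n <- ncol(raster)
  half_lo <- (w - 1) %/% 2
  half_hi <- w - 1 - half_lo
  if (is.null(cs)) cs <- cbind(0, t(apply(raster, 1, cumsum)))
  lo <- pmax(centers - half_lo, 1L)
  hi <- pmin(centers + half_hi, n)
  cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]
}

#' Cross-validated population decoding of position
#'
#' Splits the session into 5 consecutive segments, trains the decoder on four
#' and decodes the held-out one, for every fold.  The error is the mean
#' Euclidean distance (cm) between decoded bin centre and true position over
#' all valid held-out windows.  A shuffled baseline repeats the whole
#' procedure on sessions whose positions were circularly displaced in time.
#'
#' @param session a `social_session`.
#' @param cells raster rows to decode with (e.g. one category's members).
#' @param spec a [frame_spec()] naming the decoded frame.
#' @param tau decoding window, seconds (default 0.5).
#' @param stride frames between successive decoded windows (default 1; larger
#'   strides subsample windows for speed).
#' @param n_folds contiguous cross-validation folds (default 5).
#' @param n_shuffles shuffled-baseline repetitions (default 100; 0 skips the
#'   baseline).
#' @param min_shift_s minimum circular displacement of a shuffle, seconds.
#' @param seed integer seed for the shuffle shifts.
#' @return object of class `decoding_result`: `mae` (cm), `errors` per
#'   window, `decoded_xy`, `true_xy`, `window_center` frame indices, and
#'   `shuffled_mae` (one value per shuffle).  If `cells` is empty, a list
#'   with `status = "skipped"` (sessions without cells of the tested
#'   category are discarded, not errors).
#' @export
cross_validated_decode <- function(session, cells, spec, tau = 0.5,
                                   stride = 1L, n_folds = 5,
                                   n_shuffles = 100, min_shift_s = 20,
                                   seed = session$seed %||% 1) {
  if (length(cells) == 0)
    return(structure(list(status = "skipped",
                          reason = "no cells of the tested category"),
                     class = "decoding_result"))
  geom <- map_geometry(session$arena, spec)
  fc <- frame_coordinates(session$trajectories, spec)
  res <- cv_decode_core(fc$xy, fc$valid,
                        session$raster[cells, , drop = FALSE],
                        geom, session$frame_rate, tau, stride, n_folds)
  shuffled <- numeric(0)
  if (n_shuffles > 0) {
    n <- nrow(fc$xy)
    ms <- max(1L, round(min_shift_s * session$frame_rate))
    shifts <- with_seed(derive_seed(seed, 31), {
      sample(seq(ms, n - ms), n_shuffles, replace = TRUE)
    })
    shuffled <- vapply(shifts, function(s) {
      ord <- ((seq_len(n) - 1 + s) %% n) + 1
      cv_decode_core(fc$xy[ord, , drop = FALSE], fc$valid[ord],
                     session$raster[cells, , drop = FALSE],
                     geom, session$frame_rate, tau, stride, n_folds)$mae
    }, numeric(1))
  }
  structure(c(res, list(shuffled_mae = shuffled, status = "ok",
                        frame = spec$frame)),
            class = "decoding_result")
}

cv_decode_core <- function(xy, valid, raster, geom, frame_rate, tau, stride,
                           n_folds) {
  n <- ncol(raster)
  w <- max(1L, round(tau * frame_rate))
  fold_id <- ceiling(seq_len(n) / (n / n_folds))
  cs <- cbind(0, t(apply(raster, 1, cumsum)))
  err <- numeric(0); dec_xy <- NULL; tru_xy <- NULL; wc_all <- integer(0)
  for (f in seq_len(n_folds)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    model <- tryCatch(
      fit_decoder(xy, valid, raster, train, geom$half_extent, geom$bin_size,
                  frame_rate),
      error = function(e) NULL)
    if (is.null(model)) next
    wc <- test[seq(1, length(test), by = stride)]
    wc <- wc[valid[wc]]
    if (length(wc) == 0) next
    counts <- window_counts(raster, wc, w, cs)
    dec <- decode_window(model, counts, tau)
    e <- sqrt((dec$xy[, 1] - xy[wc, 1])^2 + (dec$xy[, 2] - xy[wc, 2])^2)
    err <- c(err, e)
    dec_xy <- rbind(dec_xy, dec$xy)
    tru_xy <- rbind(tru_xy, xy[wc, , drop = FALSE])
    wc_all <- c(wc_all, wc)
  }
  list(mae = mean(err), errors = err, decoded_xy = dec_xy, true_xy = tru_xy,
       window_center = wc_all)
}

#' @export
print.decoding_result <- function(x, ...) {
  if (identical(x$status, "skipped")) {
    cat("<decoding_result> skipped:", x$reason, "\n")
  } else {
    cat(sprintf("<decoding_result> mae %.2f cm over %d windows", x$mae,
                length(x$errors)))
    if (length(x$shuffled_mae))
      cat(sprintf("; shuffled baseline %.2f cm (n = %d)",
                  mean(x$shuffled_mae), length(x$shuffled_mae)))
    cat("\n")
  }
  invisible(x)
}

#' Cross-referent decoding of relative position
#'
#' Fits a decoder on the relative position of one partner and tests it on the
#' same partner (cross-validated) and on the other partner (full transfer),
#' both against a shuffled baseline.  Used to ask whether social-vector cells
#' carry partner identity.
#'
#' @param session a `social_session` with two partners.
#' @param cells raster rows to use.
#' @param frame `"rel_ego"` or `"rel_allo"`.
#' @param ref_train,ref_test partner names for training and transfer testing.
#' @inheritParams cross_validated_decode
#' @return list with `same` (a `decoding_result` for the trained partner),
#'   `cross_mae` (transfer error, cm) and `shuffled_mae` from `same`.
#' @export
cross_referent_decode <- function(session, cells, frame = "rel_ego",
                                  ref_train, ref_test, tau = 0.5,
                                  stride = 1L, n_shuffles = 100,
                                  seed = session$seed %||% 1) {
  if (is.null(session$trajectories[[ref_train]]) ||
      is.null(session$trajectories[[ref_test]]))
    stop("both partner tracks are required for cross-referent decoding")
  spec_a <- frame_spec(frame, ref_train)
  spec_b <- frame_spec(frame, ref_test)
  same <- cross_validated_decode(session, cells, spec_a, tau = tau,
                                 stride = stride, n_shuffles = n_shuffles,
                                 seed = seed)
  geom <- map_geometry(session$arena, spec_b)
  fa <- frame_coordinates(session$trajectories, spec_a)
  fb <- frame_coordinates(session$trajectories, spec_b)
  raster <- session$raster[cells, , drop = FALSE]
  n <- ncol(raster)
  model <- fit_decoder(fa$xy, fa$valid, raster, seq_len(n),
                       geom$half_extent, geom$bin_size, session$frame_rate)
  w <- max(1L, round(tau * session$frame_rate))
  wc <- seq(1, n, by = stride)
  wc <- wc[fb$valid[wc]]
  counts <- window_counts(raster, wc, w)
  dec <- decode_window(model, counts, tau)
  cross_mae <- mean(sqrt((dec$xy[, 1] - fb$xy[wc, 1])^2 +
                         (dec$xy[, 2] - fb$xy[wc, 2])^2))
  list(same = same, cross_mae = cross_mae, shuffled_mae = same$shuffled_mae)
}
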