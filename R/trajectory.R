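#' Construct a trajectory table
#'
#' A trajectory is a per-frame time series of position (cm) and, for the
#' imaged animal, head direction (radians, counter-clockwise from +x, wrapped
#' to `(-pi, pi]`).
#'
#' @param x,y position coordinates in cm.
#' @param frame_rate sampling rate in Hz (default 30).
#' @param head_dir optional head-direction angle per frame, radians.
#' @param valid optional logical vector marking usable frames; defaults to
#'   frames with finite coordinates.
#' @return a `data.frame` of class `trajectory` with columns `frame` (0-based),
#'   `t_s`, `x_cm`, `y_cm`, `head_dir_rad`, `valid` and attribute `frame_rate`.
#' @export
trajectory <- function(x, y, frame_rate = 30, head_dir = NULL, valid = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, frame_rate > 0)
  if (is.null(head_dir)) head_dir <- rep(NA_real_, n)
  stopifnot(length(head_dir) == n)
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  stopifnot(length(valid) == n)
  hd <- ifelse(is.na(head_dir), NA_real_, wrap_angle(head_dir))
  out <- data.frame(frame = seq_len(n) - 1L,
                    t_s = (seq_len(n) - 1L) / frame_rate,
                    x_cm = as.numeric(x), y_cm = as.numeric(y),
                    head_dir_rad = hd,
                    valid = as.logical(valid))
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Clean and smooth a raw trajectory
#'
#' Out-of-arena or non-finite samples are marked invalid and bridged by linear
#' interpolation, then a 15-point centered mean filter smooths each position
#' axis.  Head direction is smoothed circularly (mean of unit vectors over the
#' same window).  Frames that were invalid in the input stay flagged invalid
#' in the output so they are excluded from every occupancy and event-count
#' accumulation downstream.
#'
#' @param traj a [trajectory()].
#' @param arena an [arena_geometry()]; positions outside it are treated as
#'   tracking errors.
#' @param width filter width in frames (default 15).
#' @return a cleaned `trajectory` of the same length.
#' @export
clean_trajectory <- function(traj, arena, width = 15) {
  n <- nrow(traj)
  if (n < width) stop("trajectory shorter than the smoothing window")
  inside <- arena_contains(arena, cbind(traj$x_cm, traj$y_cm))
  ok <- traj$valid & inside & is.finite(traj$x_cm) & is.finite(traj$y_cm)
  if (!any(ok)) stop("trajectory has no valid in-arena samples")
  x <- traj$x_cm; x[!ok] <- NA_real_
  y <- traj$y_cm; y[!ok] <- NA_real_
  x <- moving_average(interpolate_na(x), width)
  y <- moving_average(interpolate_na(y), width)
  hd <- traj$head_dir_rad
  if (any(is.finite(hd))) {
    c_s <- moving_average(interpolate_na(cos(hd)), width)
    s_s <- moving_average(interpolate_na(sin(hd)), width)
    hd <- atan2(s_s, c_s)
  }
  trajectory(x, y, frame_rate = attr(traj, "frame_rate"),
             head_dir = hd, valid = ok)
}

#' Reference-frame specifier
#'
#' Names one of the four coordinate systems a spatial map can live in:
#' \describe{
#'   \item{`self_allo`}{the imaged animal's own position in arena coordinates
#'     (place-cell frame).}
#'   \item{`other_allo`}{the partner's position in arena coordinates
#'     (social-place frame).}
#'   \item{`rel_allo`}{the partner's position relative to the imaged animal,
#'     axes fixed to the arena (allocentric social-vector frame).}
#'   \item{`rel_ego`}{the same relative position in axes that rotate with the
#'     imaged animal's head (egocentric social-vector frame); "directly
#'     ahead" maps to +x and "left" to +y.}
#' }
#'
#' @param frame one of `"self_allo"`, `"other_allo"`, `"rel_allo"`,
#'   `"rel_ego"`.
#' @param referent partner id (name or index into the session's trajectory
#'   list) for the three social frames; must be absent for `self_allo`.
#' @return an object of class `frame_spec`.
#' @export
frame_spec <- function(frame = c("self_allo", "other_allo", "rel_allo",
                                 "rel_ego"),
                       referent = NULL) {
  frame <- match.arg(frame)
  if (frame == "self_allo" && !is.null(referent))
    stop("self_allo has no referent")
  if (frame != "self_allo" && is.null(referent))
    stop(sprintf("frame '%s' needs a referent partner", frame))
  structure(list(frame = frame, referent = referent), class = "frame_spec")
}

#' Partner position relative to self (allocentric axes)
#'
#' @param self_pos,other_pos two-column matrices (or length-2 vectors) of
#'   positions in cm.
#' @return matrix of `other_pos - self_pos`.
#' @export
to_relative <- function(self_pos, other_pos) {
  rbind(other_pos) - rbind(self_pos)
}

#' Partner position relative to self in head-rotating (egocentric) axes
#'
#' Rotates the relative vector by minus the head direction, so a partner
#' directly ahead of the animal maps to the +x axis and a partner on the
#' animal's left to +y.
#'
#' @inheritParams to_relative
#' @param head_dir head direction in radians (CCW from +x), one per frame.
#' @return matrix of egocentric coordinates; rows with missing `head_dir`
#'   are `NA`.
#' @export
to_egocentric <- function(self_pos, other_pos, head_dir) {
  d <- to_relative(self_pos, other_pos)
  ct <- cos(-head_dir); st <- sin(-head_dir)
  out <- cbind(ct * d[, 1] - st * d[, 2],
               st * d[, 1] + ct * d[, 2])
  out[!is.finite(head_dir), ] <- NA_real_
  out
}

#' Per-frame coordinates of a session in a given reference frame
#'
#' @param trajectories named list of cleaned [trajectory()] objects; the first
#'   (or the one named by `subject`) is the imaged animal.
#' @param spec a [frame_spec()].
#' @param subject name or index of the imaged animal (default first).
#' @return list with `xy` (n x 2 matrix, cm) and `valid` (logical per frame:
#'   all required channels present).
#' @export
frame_coordinates <- function(trajectories, spec, subject = 1L) {
  self <- trajectories[[subject]]
  self_xy <- cbind(self$x_cm, self$y_cm)
  valid <- self$valid
  if (spec$frame == "self_allo") {
    return(list(xy = self_xy, valid = valid & is.finite(self_xy[, 1])))
  }
  other <- trajectories[[spec$referent]]
  if (is.null(other)) stop(sprintf("referent '%s' not in session",
                                   as.character(spec$referent)))
  if (nrow(other) != nrow(self)) stop("trajectory lengths differ")
  other_xy <- cbind(other$x_cm, other$y_cm)
  valid <- valid & other$valid
  xy <- switch(spec$frame,
    other_allo = other_xy,
    rel_allo = to_relative(self_xy, other_xy),
    rel_ego = {
      hd <- self$head_dir_rad
      valid <- valid & is.finite(hd)
      to_egocentric(self_xy, other_xy, hd)
    })
  valid <- valid & is.finite(xy[, 1]) & is.finite(xy[, 2])
  list(xy = xy, valid = valid)
}
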