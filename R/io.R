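# Session bundle I/O (plain-text CSV + JSON manifest), behaviour-annotation
# intake, and the pipeline orchestrator tying classification and decoding
# together.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session bundle to a directory
#'
#' Plain-text layout: `manifest.json` (arena, frame rate, animal ids, raster
#' shape, seed), one `trajectory_<animal>.csv` per animal with columns
#' `frame` (0-based), `t_s`, `x_cm`, `y_cm`, `head_dir_rad`, `valid`, and
#' `events.csv` with one row per calcium event (`cell`, `frame`, both
#' matching the raster's 1-based cell rows and 0-based frames).
#'
#' @param session a `social_session`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arena <- unclass(session$arena)
  manifest <- list(
    arena = arena,
    frame_rate = session$frame_rate,
    animals = names(session$trajectories),
    n_cells = nrow(session$raster),
    n_frames = ncol(session$raster),
    seed = session$seed)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(session$trajectories)) {
    tr <- session$trajectories[[nm]]
    df <- data.frame(frame = tr$frame, t_s = fmt_num(tr$t_s),
                     x_cm = fmt_num(tr$x_cm), y_cm = fmt_num(tr$y_cm),
                     head_dir_rad = ifelse(is.na(tr$head_dir_rad), "NA",
                                           fmt_num(tr$head_dir_rad)),
                     valid = tr$valid)
    utils::write.csv(df, file.path(path, paste0("trajectory_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  ev <- which(session$raster == 1, arr.ind = TRUE)
  ev <- ev[order(ev[, 1], ev[, 2]), , drop = FALSE]
  utils::write.csv(data.frame(cell = ev[, 1], frame = ev[, 2] - 1L),
                   file.path(path, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a session bundle
#'
#' Reads the layout written by [write_session()], validating that every
#' channel has the frame count declared in the manifest; a
#' simulate-write-read round trip reproduces all arrays exactly.
#'
#' @param path bundle directory.
#' @return a `social_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("no manifest.json in '%s'", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$arena$shape)) stop("manifest lacks an arena descriptor")
  ar <- manifest$arena
  arena <- switch(ar$shape,
    circle = arena_geometry("circle", diameter = ar$diameter),
    square = arena_geometry("square", side = ar$side),
    annulus = arena_geometry("annulus", outer = ar$outer, inner = ar$inner),
    stop(sprintf("unknown arena shape '%s'", ar$shape)))
  n_frames <- manifest$n_frames
  trajs <- list()
  for (nm in manifest$animals) {
    f <- file.path(path, paste0("trajectory_", nm, ".csv"))
    if (!file.exists(f)) stop(sprintf("missing trajectory file '%s'", f))
    df <- utils::read.csv(f)
    if (nrow(df) != n_frames)
      stop(sprintf("'%s' has %d frames but manifest declares %d",
                   f, nrow(df), n_frames))
    trajs[[nm]] <- trajectory(df$x_cm, df$y_cm,
                              frame_rate = manifest$frame_rate,
                              head_dir = suppressWarnings(
                                as.numeric(df$head_dir_rad)),
                              valid = df$valid)
  }
  evf <- file.path(path, "events.csv")
  if (!file.exists(evf)) stop(sprintf("missing events file '%s'", evf))
  ev <- utils::read.csv(evf)
  raster <- matrix(0L, manifest$n_cells, n_frames)
  if (nrow(ev) > 0) {
    if (any(ev$frame < 0 | ev$frame >= n_frames))
      stop(sprintf("events.csv has frames outside [0, %d)", n_frames))
    if (any(ev$cell < 1 | ev$cell > manifest$n_cells))
      stop("events.csv names a cell outside the raster")
    raster[cbind(ev$cell, ev$frame + 1L)] <- 1L
  }
  structure(list(arena = arena, frame_rate = manifest$frame_rate,
                 trajectories = trajs, raster = raster, truth = list(),
                 seed = manifest$seed),
            class = "social_session")
}

#' Fraction of session time spent in social interaction
#'
#' Merges overlapping social intervals and reports the fraction of the
#' session they cover, as a percentage.  Intervals are half-open
#' `[onset, offset)` seconds.
#'
#' @param annotations data.frame with columns `onset_s`, `offset_s`,
#'   `category` (`"social"` / `"non-social"`); extra columns (behaviour
#'   labels) are ignored.
#' @param duration session duration in seconds.
#' @return percentage of time in social behaviour.
#' @export
interaction_fraction <- function(annotations, duration) {
  stopifnot(duration > 0)
  soc <- annotations[annotations$category == "social", , drop = FALSE]
  if (nrow(soc) == 0) return(0)
  if (any(soc$offset_s <= soc$onset_s))
    stop("annotation intervals must have offset > onset")
  if (any(soc$onset_s < 0 | soc$offset_s > duration))
    stop("annotation interval extends beyond the session duration")
  o <- order(soc$onset_s)
  on <- soc$onset_s[o]; off <- soc$offset_s[o]
  total <- 0; cur_on <- on[1]; cur_off <- off[1]
  for (i in seq_along(on)[-1]) {
    if (on[i] <= cur_off) {
      cur_off <- max(cur_off, off[i])
    } else {
      total <- total + (cur_off - cur_on)
      cur_on <- on[i]; cur_off <- off[i]
    }
  }
  total <- total + (cur_off - cur_on)
  100 * total / duration
}

#' Run classification and decoding on one session
#'
#' Orchestrates the pipeline: classifies every cell in the four reference
#' frames, decodes each frame's position from its member cells (skipping,
#' with an explicit status, frames with no member cells), and writes the
#' per-cell classification CSV, a category-count JSON summary and a decoding
#' JSON to `out_dir`.  Reruns with the same session and seed produce
#' byte-identical outputs.
#'
#' @param session a `social_session`.
#' @param out_dir output directory (created if needed).
#' @param n_shuffles temporal shuffles per cell and frame.
#' @param decode_shuffles shuffled-baseline repetitions per decoded frame
#'   (0 skips baselines).
#' @param stride decoding window stride, frames.
#' @param seed master seed recorded in every output.
#' @return invisibly, list with `classification` (data.frame), `summary`
#'   (category counts) and `decoding` (per-frame mae or skip status).
#' @export
run_session_analysis <- function(session, out_dir, n_shuffles = 1000,
                                 decode_shuffles = 0, stride = 15L,
                                 seed = session$seed %||% 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- names(session$trajectories)[2]
  specs <- list(frame_spec("self_allo"),
                frame_spec("other_allo", ref),
                frame_spec("rel_allo", ref),
                frame_spec("rel_ego", ref))
  cls <- classify_cells(session, specs, n_shuffles = n_shuffles, seed = seed)
  counts <- stats::aggregate(member ~ category, cls, sum)
  summary <- list(seed = seed, n_cells = nrow(session$raster),
                  n_members = stats::setNames(as.list(counts$member),
                                              counts$category))
  decoding <- list()
  for (spec in specs) {
    members <- cls$cell[cls$frame == spec$frame & cls$member]
    res <- cross_validated_decode(session, members, spec, stride = stride,
                                  n_shuffles = decode_shuffles, seed = seed)
    decoding[[spec$frame]] <- if (identical(res$status, "skipped")) {
      list(status = "skipped", reason = res$reason)
    } else {
      list(status = "ok", n_cells = length(members), mae_cm = res$mae,
           shuffled_mae_cm = if (length(res$shuffled_mae))
             mean(res$shuffled_mae) else NULL)
    }
  }
  utils::write.csv(cls, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "category_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(decoding, file.path(out_dir, "decoding.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(classification = cls, summary = summary,
                 decoding = decoding))
}
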