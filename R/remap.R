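# Identity, familiarity and context comparisons: split-half map correlations
# within/across referents, and the normalised population-vector dot product
# across contexts.

#' Split a session into two contiguous halves
#'
#' All channels (trajectories and raster) are sliced consistently; with an
#' odd frame count the first half receives the extra frame.
#'
#' @param session a `social_session`.
#' @return list of two `social_session` objects.
#' @export
session_halves <- function(session) {
  n <- ncol(session$raster)
  stopifnot(n >= 2)
  h1 <- seq_len(ceiling(n / 2))
  h2 <- setdiff(seq_len(n), h1)
  slice <- function(idx) {
    trajs <- lapply(session$trajectories, function(tr) {
      out <- trajectory(tr$x_cm[idx], tr$y_cm[idx],
                        frame_rate = attr(tr, "frame_rate"),
                        head_dir = tr$head_dir_rad[idx],
                        valid = tr$valid[idx])
      out
    })
    structure(list(arena = session$arena, frame_rate = session$frame_rate,
                   trajectories = trajs,
                   raster = session$raster[, idx, drop = FALSE],
                   truth = session$truth, seed = session$seed),
              class = "social_session")
  }
  list(slice(h1), slice(h2))
}

#' Correlation between half-session maps of one cell
#'
#' Builds a smoothed map of the cell from the first half of the session using
#' the relative position of one partner, and from the second half using the
#' same or a different partner, then correlates them over commonly visited
#' bins.  Comparing same-referent to cross-referent pairings asks whether a
#' social-vector cell distinguishes partner identity.
#'
#' @param session a `social_session` (two partners for cross-referent use).
#' @param cell raster row.
#' @param frame `"rel_ego"` or `"rel_allo"` (allocentric frames also work).
#' @param referent_first,referent_second partner for each half's map.
#' @return Pearson r over commonly visited bins, `NA` if undefined.
#' @export
half_map_correlation <- function(session, cell, frame = "rel_ego",
                                 referent_first, referent_second) {
  halves <- session_halves(session)
  m1 <- try(session_rate_map(halves[[1]], cell,
                             frame_spec(frame, referent_first)),
            silent = TRUE)
  m2 <- try(session_rate_map(halves[[2]], cell,
                             frame_spec(frame, referent_second)),
            silent = TRUE)
  if (inherits(m1, "try-error") || inherits(m2, "try-error"))
    return(NA_real_)
  map_correlation(m1, m2)
}

#' Normalised population activity vector
#'
#' Mean event rate of each cell in one condition, divided per cell by the
#' maximum of that cell's mean rate across all compared conditions, then
#' normalised to unit Euclidean norm.
#'
#' @param rates numeric vector of mean event rates (events/s), one per cell,
#'   for this condition.
#' @param max_rates per-cell maxima across all conditions entering the
#'   comparison (same length).
#' @return unit-norm numeric vector; errors if all activity is zero.
#' @export
population_vector <- function(rates, max_rates) {
  stopifnot(length(rates) == length(max_rates), all(rates >= 0))
  v <- ifelse(max_rates > 0, rates / max_rates, 0)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("zero population vector: no active cells")
  v / nrm
}

#' Cosine similarity of two population vectors
#'
#' Dot product of the normalised vectors, equal to the cosine of the angle
#' between them; lies in `[0, 1]` for non-negative rates.
#'
#' @param vec_a,vec_b unit-norm vectors from [population_vector()] with
#'   matched cell order.
#' @return scalar cosine similarity.
#' @export
population_dot_product <- function(vec_a, vec_b) {
  stopifnot(length(vec_a) == length(vec_b))
  sum(vec_a * vec_b)
}

#' Mean event rate per cell of a session (or session half)
#'
#' @param session a `social_session`.
#' @param cells raster rows (default all).
#' @return events/s per cell, counted over valid frames of the imaged
#'   animal's trajectory.
#' @export
mean_event_rates <- function(session, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(session$raster))
  v <- session$trajectories[[1]]$valid
  tt <- sum(v) / session$frame_rate
  rowSums(session$raster[cells, v, drop = FALSE]) / tt
}

#' Within- vs cross-context population similarity
#'
#' For two sessions (contexts) with registered cells, computes the cosine
#' similarity between the population vectors of the two halves of the same
#' session, and between halves of different sessions.  Per-cell rates are
#' normalised by the cell's maximum across all four halves.
#'
#' @param session_a,session_b `social_session` objects with matched cell
#'   rows (same cells, registered across sessions).
#' @return list with `within` (length 2: each session's half-vs-half
#'   similarity) and `cross` (length 2: first-vs-second half across
#'   sessions).
#' @export
context_similarity <- function(session_a, session_b) {
  stopifnot(nrow(session_a$raster) == nrow(session_b$raster))
  ha <- session_halves(session_a)
  hb <- session_halves(session_b)
  r <- cbind(mean_event_rates(ha[[1]]), mean_event_rates(ha[[2]]),
             mean_event_rates(hb[[1]]), mean_event_rates(hb[[2]]))
  mx <- apply(r, 1, max)
  pv <- lapply(1:4, function(j) population_vector(r[, j], mx))
  list(within = c(population_dot_product(pv[[1]], pv[[2]]),
                  population_dot_product(pv[[3]], pv[[4]])),
       cross = c(population_dot_product(pv[[1]], pv[[4]]),
                 population_dot_product(pv[[2]], pv[[3]])))
}
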