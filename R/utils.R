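# Internal helpers shared across modules.

#' Wrap angles to (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @keywords internal
wrap_angle <- function(theta) {
  w <- theta - 2 * pi * floor((theta + pi) / (2 * pi))
  # floor() maps +pi to -pi; restore the (+pi] convention
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# Deterministic seed fan-out: one stream per component, derived from a master
# seed with a counter so adding components never perturbs earlier streams.
# All arithmetic stays below 2^53 so doubles are exact; result < 2^31.
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- (abs(seed) %% 2147483647)
  for (k in c(counter, 0)) {
    s <- (s * 69069 + k * 12345 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate expr with a local RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Centered moving-average with partial windows at the edges (NA-aware).
moving_average <- function(x, width) {
  n <- length(x)
  half <- (width - 1) %/% 2
  xs <- ifelse(is.na(x), 0, x)
  m <- ifelse(is.na(x), 0, 1)
  cs <- c(0, cumsum(xs))
  cm <- c(0, cumsum(m))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  num <- cs[hi + 1] - cs[lo]
  den <- cm[hi + 1] - cm[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Linear interpolation over NA runs, extending the first/last finite value to
# the ends.  Errors if nothing is finite.
interpolate_na <- function(x) {
  if (all(is.na(x))) stop("cannot interpolate: no finite values")
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}
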