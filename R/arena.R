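#' Arena geometry descriptor
#'
#' Describes the behavioural arena: a circular open field, a square box, or an
#' annular (ring-shaped) track.  The arena center is always at the origin
#' `(0, 0)` and all sizes are in centimetres.
#'
#' @param shape one of `"circle"`, `"square"`, `"annulus"`.
#' @param diameter circle diameter in cm (circle only).
#' @param side square side length in cm (square only).
#' @param outer,inner outer and inner diameters in cm (annulus only).
#'
#' @return An object of class `arena_geometry` with fields `shape` and the
#'   relevant size parameters.
#'
#' @examples
#' arena_geometry("circle", diameter = 70)
#' arena_geometry("square", side = 50)
#' arena_geometry("annulus", outer = 70, inner = 50)
#' @export
arena_geometry <- function(shape = c("circle", "square", "annulus"),
                           diameter = NULL, side = NULL,
                           outer = NULL, inner = NULL) {
  shape <- match.arg(shape)
  g <- switch(shape,
    circle = {
      stopifnot(is.numeric(diameter), diameter > 0)
      list(shape = shape, diameter = diameter)
    },
    square = {
      stopifnot(is.numeric(side), side > 0)
      list(shape = shape, side = side)
    },
    annulus = {
      stopifnot(is.numeric(outer), is.numeric(inner),
                outer > 0, inner > 0, inner < outer)
      list(shape = shape, outer = outer, inner = inner)
    }
  )
  structure(g, class = "arena_geometry")
}

#' @export
print.arena_geometry <- function(x, ...) {
  dims <- switch(x$shape,
    circle = sprintf("diameter %g cm", x$diameter),
    square = sprintf("side %g cm", x$side),
    annulus = sprintf("outer %g cm, inner %g cm", x$outer, x$inner))
  cat(sprintf("<arena_geometry> %s, %s, centered at (0, 0)\n", x$shape, dims))
  invisible(x)
}

#' Test whether positions lie inside the arena
#'
#' @param arena an [arena_geometry()] object.
#' @param xy two-column matrix (or length-2 vector) of positions in cm.
#' @param tol tolerance in cm added to the boundary, so points numerically on
#'   the wall count as inside.
#' @return logical vector, one element per row of `xy`; `NA` positions give
#'   `FALSE`.
#' @export
arena_contains <- function(arena, xy, tol = 1e-9) {
  xy <- rbind(xy)
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  ok <- switch(arena$shape,
    circle = r <= arena$diameter / 2 + tol,
    square = abs(xy[, 1]) <= arena$side / 2 + tol &
             abs(xy[, 2]) <= arena$side / 2 + tol,
    annulus = r <= arena$outer / 2 + tol & r >= arena$inner / 2 - tol)
  ok & !is.na(ok)
}

# Square bounding box [-h, h] per axis of the physical arena.
arena_half_extent <- function(arena) {
  switch(arena$shape,
    circle = arena$diameter / 2,
    square = arena$side / 2,
    annulus = arena$outer / 2)
}

#' Effective arena for relative-position maps
#'
#' The space of all possible partner-relative-to-self positions spans twice
#' the linear extent of the physical arena (four times the area), so relative
#' maps are binned on a square grid of twice the physical extent with bins
#' twice the base size.
#'
#' @param arena an [arena_geometry()] object.
#' @param base_bin base spatial bin size in cm used for allocentric maps
#'   (default 2 cm).
#' @return list with `half_extent` (cm; the grid spans
#'   `[-half_extent, half_extent]` per axis) and `bin_size` (cm, doubled).
#'
#' @examples
#' effective_arena(arena_geometry("circle", diameter = 70))
#' @export
effective_arena <- function(arena, base_bin = 2) {
  stopifnot(base_bin > 0)
  list(half_extent = 2 * arena_half_extent(arena),
       bin_size = 2 * base_bin)
}
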