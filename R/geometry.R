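#' Periodic square field
#'
#' Describes the simulation domain: a square of side `side_length` with
#' periodic boundary conditions on all four sides. All geometric queries in
#' the package (contacts, neighbour counts, displacement) respect the
#' periodicity through the minimal-image convention, which is valid because
#' every interaction range in the model is far below half the field side.
#'
#' @param side_length Side of the square field in micrometres. Must exceed
#'   twice the largest agent extent so that an agent can never interact with
#'   its own periodic image.
#' @return A list of class `field_spec` with elements `side_length` and
#'   `periodic`.
#' @examples
#' field_spec(600)
#' @export
field_spec <- function(side_length = 600) {
  stopifnot(is.numeric(side_length), length(side_length) == 1L,
            is.finite(side_length), side_length > 0)
  structure(list(side_length = side_length, periodic = TRUE),
            class = "field_spec")
}

#' Wrap positions into the periodic field
#'
#' @param position Numeric vector of length 2, or an n-by-2 matrix of
#'   positions (micrometres).
#' @param field A [field_spec()].
#' @return Positions with every coordinate in `[0, side_length)`.
#' @examples
#' wrap_position(c(610, -5), field_spec(600))
#' @export
wrap_position <- function(position, field) {
  s <- field$side_length
  w <- position - s * floor(position / s)
  # floor() can round x/s up to exactly 1 for x slightly below s
  w[w >= s] <- 0
  w
}

#' Minimal-image displacement between two wrapped points
#'
#' Returns the displacement `d` such that `a = b + d` modulo the field, with
#' each component in `[-side/2, side/2]`. Antisymmetric in its arguments.
#'
#' @param a,b Numeric length-2 vectors (wrapped positions, micrometres).
#' @inheritParams wrap_position
#' @return Numeric length-2 displacement in micrometres.
#' @examples
#' minimal_image(c(595, 300), c(5, 300), field_spec(600))
#' @export
minimal_image <- function(a, b, field) {
  s <- field$side_length
  d <- a - b
  d - s * round(d / s)
}

#' Circle-circle contact under periodic boundaries
#'
#' Computes the overlap between two circles using the minimal-image
#' separation of their centres. The contact normal points from circle `b`
#' toward circle `a`.
#'
#' @param center_a,center_b Circle centres (length-2, micrometres).
#' @param radius_a,radius_b Circle radii (micrometres, positive).
#' @inheritParams wrap_position
#' @return A list of class `contact_result` with `overlap` (>= 0, um),
#'   `normal` (unit vector when `overlap > 0`) and `distance`. Coincident
#'   centres are signalled via `degenerate = TRUE` (the caller substitutes a
#'   seeded random direction).
#' @export
circle_circle_contact <- function(center_a, radius_a, center_b, radius_b,
                                  field) {
  stopifnot(radius_a > 0, radius_b > 0)
  d <- minimal_image(center_a, center_b, field)
  dist <- sqrt(sum(d^2))
  overlap <- max(0, radius_a + radius_b - dist)
  if (dist == 0) {
    return(structure(list(overlap = radius_a + radius_b, normal = c(NA, NA),
                          distance = 0, degenerate = TRUE),
                     class = "contact_result"))
  }
  structure(list(overlap = overlap,
                 normal = if (overlap > 0) d / dist else c(0, 0),
                 distance = dist, degenerate = FALSE),
            class = "contact_result")
}

#' Circle-segment contact under periodic boundaries
#'
#' Contact between a circle and a rectangle of half-width `half_width` laid
#' along the segment from `seg_start` to `seg_end` (a neuroblast process).
#' The closest point on the segment is found in the minimal-image frame of
#' the segment start; the returned parameter `s` is 0 at `seg_start` (soma
#' centre) and 1 at `seg_end` (tip centre). The normal points from the
#' closest segment point toward the circle centre.
#'
#' @param center Circle centre (length-2, micrometres).
#' @param radius Circle radius (micrometres).
#' @param seg_start,seg_end Segment endpoints (wrapped positions).
#' @param half_width Half-width of the rectangle (the model's `w`).
#' @inheritParams wrap_position
#' @return A `contact_result` list with `overlap`, `normal`, `distance` and
#'   `segment_param`. A circle centre exactly on the segment axis is
#'   degenerate (normal undefined).
#' @export
circle_segment_contact <- function(center, radius, seg_start, seg_end,
                                   half_width, field) {
  ab <- minimal_image(seg_end, seg_start, field)
  len2 <- sum(ab^2)
  stopifnot(len2 > 0)
  ac <- minimal_image(center, seg_start, field)
  s <- min(1, max(0, sum(ac * ab) / len2))
  closest <- s * ab
  d <- ac - closest
  dist <- sqrt(sum(d^2))
  overlap <- max(0, half_width + radius - dist)
  if (dist == 0) {
    return(structure(list(overlap = half_width + radius, normal = c(NA, NA),
                          distance = 0, segment_param = s, degenerate = TRUE),
                     class = "contact_result"))
  }
  structure(list(overlap = overlap,
                 normal = if (overlap > 0) d / dist else c(0, 0),
                 distance = dist, segment_param = s, degenerate = FALSE),
            class = "contact_result")
}
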