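#' World configuration
#'
#' The simulated environment is a continuous two-dimensional 300 x 300 grid
#' with torus topology (opposite edges identified), so there are no border
#' effects. One grid unit represents 1 m and one time step 1 minute. Only
#' the active part of the day is simulated: a day is 12 hours (720 minutes)
#' and a year 350 days (252000 minutes).
#'
#' @param width,height World extent in grid units.
#' @param day_length Minutes per (active) day.
#' @param year_days Days per year.
#' @return An object of class `emo_world`.
#' @export
world_config <- function(width = 300, height = 300, day_length = 720, year_days = 350) {
  structure(list(
    width = width, height = height,
    day_length = day_length, year_days = year_days,
    year_length = day_length * year_days
  ), class = "emo_world")
}

#' Wrap coordinates onto the torus
#'
#' @param x,y Coordinates (any real values).
#' @param world An [world_config()] object.
#' @return A list with wrapped `x` and `y` in `[0, width)` / `[0, height)`.
#' @export
wrap_position <- function(x, y, world = world_config()) {
  list(x = x %% world$width, y = y %% world$height)
}

#' Torus (minimal-image) distance
#'
#' Euclidean distance between two points under the minimal-image convention:
#' each coordinate difference is reduced modulo the world extent to the
#' representative of smallest magnitude. Vectorized over points.
#'
#' @param x1,y1,x2,y2 Coordinates (wrapped or not; wrapping is implied).
#' @param world An [world_config()] object.
#' @return Distances in grid units.
#' @export
torus_distance <- function(x1, y1, x2, y2, world = world_config()) {
  dx <- (x2 - x1) %% world$width
  dx <- pmin(dx, world$width - dx)
  dy <- (y2 - y1) %% world$height
  dy <- pmin(dy, world$height - dy)
  sqrt(dx^2 + dy^2)
}

torus_delta <- function(a, b, span) {
  d <- (b - a) %% span
  ifelse(d > span / 2, d - span, d)
}

#' Which group members are visible to a focal individual
#'
#' Perception combines a radius and a forward view cone. Others are visible
#' when they lie within `radius` grid units and their bearing is within
#' half the view angle of the focal heading. When a scan event fires
#' (probability `myPscan` per activation, decided by the caller via `scan`)
#' the view angle is treated as 360 degrees. An individual never perceives
#' itself.
#'
#' @param x,y,heading Focal position (grid units) and heading (radians).
#' @param others_x,others_y Candidate positions.
#' @param view_angle View angle in degrees (full width of the cone).
#' @param radius Perception radius in grid units.
#' @param scan If `TRUE`, the view cone is ignored (360-degree scan).
#' @param world An [world_config()] object.
#' @return Logical vector: which candidates are visible.
#' @export
visible_others <- function(x, y, heading, others_x, others_y,
                           view_angle = 120, radius = 50,
                           scan = FALSE, world = world_config()) {
  dx <- torus_delta(x, others_x, world$width)
  dy <- torus_delta(y, others_y, world$height)
  d <- sqrt(dx^2 + dy^2)
  within <- d <= radius & d > 0
  if (!scan && view_angle < 360) {
    bearing <- atan2(dy, dx)
    diff <- abs((bearing - heading + pi) %% (2 * pi) - pi)
    within <- within & diff <= (view_angle * pi / 180) / 2
  }
  within
}
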