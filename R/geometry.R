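# Signed 2D angle and distance primitives in image coordinates.
#
# Coordinate convention used throughout the package: raster standard, origin at
# the top-left corner, x increases rightward (image columns), y increases
# downward (image rows). Continuous coordinates; the pixel with 0-based indices
# (ix, iy) covers [ix, ix+1] x [iy, iy+1] and has center (ix + 0.5, iy + 0.5).
#
# Patient facing is a configuration flag: "+x" means the patient's anterior
# side points toward increasing x (default), "-x" the opposite. All signed
# clinical quantities are defined in the anatomical frame (anterior, superior),
# so left- and right-facing radiographs yield identical parameter values.

.DEG <- 180 / pi

.facing_sign <- function(facing) {
  facing <- match.arg(facing, c("+x", "-x"))
  if (facing == "+x") 1 else -1
}

#' Wrap an angle in degrees into (-180, 180]
#' @noRd
.wrap180 <- function(a) {
  a <- ((a + 180) %% 360) - 180
  ifelse(a == -180, 180, a)
}

# Map an image-frame vector to the anatomical frame (x = anterior, y = superior).
.anat <- function(v, fac) c(fac * v[1], -v[2])

.is_point <- function(p) {
  is.numeric(p) && length(p) == 2 && all(is.finite(p))
}

.stop_geom <- function(msg) {
  stop(errorCondition(msg, class = c("spinalign_degenerate_geometry", "spinalign_error")))
}

#' Create a directed line
#'
#' A directed line is an origin point plus a unit direction vector, the
#' substrate for every construction line used by the parameter definitions
#' (horizontal and vertical reference lines, endplate lines, endplate
#' perpendiculars, and the pelvic line from the femoral-head center to the
#' sacral endplate midpoint).
#'
#' @param origin Numeric length-2 point `c(x, y)` in image coordinates.
#' @param direction Numeric length-2 direction vector; normalized to unit
#'   length internally.
#' @return An object of class `directed_line` with elements `origin` and
#'   `direction` (unit vector).
#' @examples
#' horiz <- directed_line(c(0, 0), c(1, 0))
#' vert  <- directed_line(c(0, 0), c(0, 1))
#' signed_angle_between(horiz, vert)
#' @export
directed_line <- function(origin, direction) {
  if (!.is_point(origin) || !is.numeric(direction) || length(direction) != 2 ||
      !all(is.finite(direction))) {
    .stop_geom("directed_line() requires finite length-2 'origin' and 'direction'")
  }
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) .stop_geom("zero-length direction vector")
  structure(list(origin = as.numeric(origin), direction = as.numeric(direction) / n),
            class = "directed_line")
}

.dir_of <- function(x) {
  if (inherits(x, "directed_line")) return(x$direction)
  if (!is.numeric(x) || length(x) != 2) .stop_geom("expected a directed_line or a length-2 vector")
  n <- sqrt(sum(x^2))
  if (n < 1e-12) .stop_geom("zero-length direction vector")
  x / n
}

#' Signed angle between two directed lines
#'
#' Angle from `a` to `b` in degrees in (-180, 180], measured counterclockwise
#' in the (x, y) basis of the image frame. The operation is antisymmetric and
#' zero for identical directions. Higher-level code maps vectors into the
#' anatomical frame before calling this, so that reported signs follow
#' clinical conventions regardless of patient facing.
#'
#' @param a,b `directed_line` objects (or bare length-2 direction vectors).
#' @return Signed angle in degrees.
#' @export
signed_angle_between <- function(a, b) {
  da <- .dir_of(a)
  db <- .dir_of(b)
  .wrap180(atan2(da[1] * db[2] - da[2] * db[1], sum(da * db)) * .DEG)
}

#' Slope of an endplate line relative to the image horizontal
#'
#' The generic "angle between the horizontal line and an endplate" operation.
#' Positive when the anterior corner is superior (smaller y) to the posterior
#' corner; this makes sacral slope positive for a normally inclined sacral
#' endplate. Invariant under x-mirroring combined with a facing flip.
#'
#' @param anterior,posterior The endplate corner points, `c(x, y)` in image
#'   coordinates.
#' @param facing `"+x"` (anterior toward increasing x, default) or `"-x"`.
#' @return Signed slope in degrees.
#' @examples
#' endplate_slope(c(100, 190), c(50, 200))  # anterior corner raised: positive
#' @export
endplate_slope <- function(anterior, posterior, facing = "+x") {
  if (!.is_point(anterior) || !.is_point(posterior)) {
    .stop_geom("endplate corners must be finite length-2 points")
  }
  v <- anterior - posterior
  if (sqrt(sum(v^2)) < 1e-9) .stop_geom("coincident endplate corner points")
  fac <- .facing_sign(facing)
  va <- .anat(v, fac)
  atan2(va[2], va[1]) * .DEG
}

#' Perpendicular of a directed line
#'
#' Returns the line through the same origin whose direction is the
#' superior-pointing normal of the input (for a horizontal input direction the
#' normal points up the image, i.e. toward smaller y). Used for the
#' "perpendicular to the endplate" constructions of the incidence parameters.
#'
#' @param line A `directed_line`.
#' @return A `directed_line` with the same origin and perpendicular direction.
#' @export
perpendicular <- function(line) {
  if (!inherits(line, "directed_line")) .stop_geom("perpendicular() expects a directed_line")
  d <- line$direction
  directed_line(line$origin, c(d[2], -d[1]))
}

#' Horizontal offset from a plumb line, in millimetres
#'
#' Distance along the image x axis between the vertical plumb line dropped
#' from `from_point` and the landmark `to_point`, converted to millimetres.
#' Positive when the plumb line falls anterior to the landmark under the
#' facing convention, the usual sign for a sagittal vertical axis.
#'
#' @param from_point Point the plumb line is dropped from.
#' @param to_point Reference landmark.
#' @param spacing Isotropic pixel spacing in mm/px (> 0).
#' @param facing `"+x"` or `"-x"`.
#' @return Signed horizontal distance in millimetres.
#' @export
plumbline_horizontal_offset <- function(from_point, to_point, spacing, facing = "+x") {
  if (!.is_point(from_point) || !.is_point(to_point)) {
    .stop_geom("plumb-line endpoints must be finite length-2 points")
  }
  spacing <- as.numeric(spacing)
  if (!is.finite(spacing) || spacing <= 0) {
    stop(errorCondition("pixel spacing must be a positive mm/px value",
                        class = c("spinalign_calibration_missing", "spinalign_error")))
  }
  fac <- .facing_sign(facing)
  fac * (from_point[1] - to_point[1]) * spacing
}
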