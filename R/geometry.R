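#' Morris water maze pool geometry
#'
#' Describes the circular pool, the escape platform and the derived analysis
#' zones in pool-centered Cartesian coordinates (cm, y up). Defaults follow a
#' standard mouse protocol: a 170-cm pool with a 12-cm platform, an 8-cm-wide
#' outer (thigmotaxis) ring at the wall, and a 30-cm focal zone around the
#' platform.
#'
#' @param pool_diameter Pool diameter in cm.
#' @param platform_diameter Escape platform diameter in cm.
#' @param platform_center Numeric length-2, platform center (x, y) in cm.
#'   Defaults to the middle of the north-east quadrant at half the pool
#'   radius from the center.
#' @param outer_ring_width Width in cm of the outer ring measured inward from
#'   the pool wall.
#' @param focal_zone_diameter Diameter in cm of the focal search zone
#'   centered on the platform.
#' @param quadrant_axes Orientation in radians of the two orthogonal axes
#'   splitting the pool into quadrants (0 = axes aligned with x and y).
#' @return An object of class `pool_geometry`.
#' @examples
#' geom <- pool_geometry()
#' geom$pool_radius
#' @export
pool_geometry <- function(pool_diameter = 170,
                          platform_diameter = 12,
                          platform_center = NULL,
                          outer_ring_width = 8,
                          focal_zone_diameter = 30,
                          quadrant_axes = 0) {
  if (pool_diameter <= 0 || platform_diameter <= 0) {
    stop("pool and platform diameters must be positive", call. = FALSE)
  }
  pool_radius <- pool_diameter / 2
  if (is.null(platform_center)) {
    r <- pool_radius / 2
    platform_center <- c(r / sqrt(2), r / sqrt(2))
  }
  platform_center <- as.numeric(platform_center)
  if (length(platform_center) != 2L || anyNA(platform_center)) {
    stop("`platform_center` must be numeric (x, y)", call. = FALSE)
  }
  if (sqrt(sum(platform_center^2)) + platform_diameter / 2 > pool_radius) {
    stop("platform must lie fully inside the pool", call. = FALSE)
  }
  if (outer_ring_width <= 0 || outer_ring_width >= pool_radius) {
    stop("`outer_ring_width` must be in (0, pool radius)", call. = FALSE)
  }
  if (focal_zone_diameter < platform_diameter) {
    stop("`focal_zone_diameter` must be >= platform diameter", call. = FALSE)
  }
  structure(
    list(
      pool_diameter = pool_diameter,
      pool_radius = pool_radius,
      platform_diameter = platform_diameter,
      platform_center = platform_center,
      outer_ring_width = outer_ring_width,
      focal_zone_diameter = focal_zone_diameter,
      quadrant_axes = quadrant_axes
    ),
    class = "pool_geometry"
  )
}

#' @export
print.pool_geometry <- function(x, ...) {
  cat(sprintf(
    "<pool_geometry> pool %.1f cm, platform %.1f cm at (%.1f, %.1f), outer ring %.1f cm\n",
    x$pool_diameter, x$platform_diameter,
    x$platform_center[1], x$platform_center[2], x$outer_ring_width
  ))
  invisible(x)
}

#' Release point for a compass start position
#'
#' @param geometry A [pool_geometry()].
#' @param position One of `"N"`, `"E"`, `"S"`, `"W"`.
#' @param margin Distance in cm from the wall at which the animal is released.
#' @return Numeric length-2 (x, y) in cm.
#' @export
start_point <- function(geometry, position = c("N", "E", "S", "W"),
                        margin = 2) {
  position <- match.arg(position)
  ang <- switch(position, N = pi / 2, E = 0, S = -pi / 2, W = pi)
  r <- geometry$pool_radius - margin
  c(r * cos(ang), r * sin(ang))
}

#' Quadrant index of pool-centered points
#'
#' Quadrants are numbered 1-4 counter-clockwise starting at the first
#' quadrant axis; with the default axis orientation, quadrant 1 is the
#' north-east quadrant. Points on a quadrant boundary belong to the quadrant
#' counter-clockwise of the boundary (left-closed convention), so the
#' assignment is deterministic.
#'
#' @param x,y Numeric vectors of coordinates in cm.
#' @param geometry A [pool_geometry()].
#' @return Integer vector of quadrant indices in 1:4.
#' @export
quadrant_index <- function(x, y, geometry) {
  ang <- atan2(y, x) - geometry$quadrant_axes
  ang <- ang %% (2 * pi)
  idx <- as.integer(floor(ang / (pi / 2))) + 1L
  idx[idx > 4L] <- 1L # guard against floating 2*pi wrap
  idx
}

#' Rectangular arena with named zones
#'
#' Used for open-field and elevated-plus-maze style zone-occupancy analyses.
#' The arena is a rectangle centered on the origin; zones are named polygons
#' (or unions of polygons) that must lie within the arena bounds.
#'
#' @param width,height Arena dimensions in cm.
#' @param zones Named list; each element is a two-column matrix of polygon
#'   vertices (x, y) or a list of such matrices (a union of polygons).
#' @return An object of class `arena_geometry`.
#' @export
arena_geometry <- function(width, height, zones = list()) {
  if (width <= 0 || height <= 0) stop("arena dimensions must be positive", call. = FALSE)
  if (length(zones) && (is.null(names(zones)) || anyDuplicated(names(zones)))) {
    stop("zones must be uniquely named", call. = FALSE)
  }
  zones <- lapply(zones, function(z) {
    if (is.matrix(z)) z <- list(z)
    lapply(z, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || nrow(p) < 3L) {
        stop("each zone polygon needs >= 3 (x, y) vertices", call. = FALSE)
      }
      if (any(abs(p[, 1]) > width / 2 + 1e-9) || any(abs(p[, 2]) > height / 2 + 1e-9)) {
        stop("zone polygon extends beyond the arena", call. = FALSE)
      }
      p
    })
  })
  structure(list(width = width, height = height, zones = zones),
            class = "arena_geometry")
}

rect_poly <- function(cx, cy, w, h) {
  cbind(
    x = cx + c(-w, w, w, -w) / 2,
    y = cy + c(-h, -h, h, h) / 2
  )
}

#' Standard open-field arena (43.2 x 43.2 cm, central 11 x 11 cm zone)
#'
#' @return An [arena_geometry()] with a `"center"` zone.
#' @export
of_arena <- function() {
  arena_geometry(43.2, 43.2, zones = list(center = rect_poly(0, 0, 11, 11)))
}

#' Standard elevated-plus-maze geometry
#'
#' Two open and two closed arms of 50.8 x 10.2 cm around a 10 x 10 cm hub.
#' Open arms run along the x axis, closed arms along y. The bounding box is
#' used as the arena rectangle.
#'
#' @return An [arena_geometry()] with `"open_arms"`, `"closed_arms"` and
#'   `"center"` zones.
#' @export
epm_arena <- function() {
  arm_l <- 50.8
  arm_w <- 10.2
  hub <- 10
  span <- hub + 2 * arm_l
  arena_geometry(
    span, span,
    zones = list(
      open_arms = list(
        rect_poly((hub + arm_l) / 2, 0, arm_l, arm_w),
        rect_poly(-(hub + arm_l) / 2, 0, arm_l, arm_w)
      ),
      closed_arms = list(
        rect_poly(0, (hub + arm_l) / 2, arm_w, arm_l),
        rect_poly(0, -(hub + arm_l) / 2, arm_w, arm_l)
      ),
      center = rect_poly(0, 0, hub, hub)
    )
  )
}
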