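#' Time in the old and new platform quadrants after reversal
#'
#' During reversal learning the platform moves to the opposite quadrant;
#' the percentage of trial time spent in the quadrant that now holds the
#' platform versus the one that used to is the standard readout of
#' behavioral flexibility. Occupancy is time-weighted: each inter-sample
#' interval is attributed to the quadrant containing its start point, with
#' the deterministic boundary convention of [quadrant_index()].
#'
#' @param trial A [swim_trial()].
#' @param geometry A [pool_geometry()].
#' @param old_platform,new_platform Numeric (x, y) of the platform centers;
#'   they must lie in different quadrants.
#' @return Named numeric: `pct_time_new_quadrant`, `pct_time_old_quadrant`.
#' @export
reversal_quadrant_times <- function(trial, geometry = trial$geometry,
                                    old_platform, new_platform) {
  q_old <- quadrant_index(old_platform[1], old_platform[2], geometry)
  q_new <- quadrant_index(new_platform[1], new_platform[2], geometry)
  if (q_old == q_new) {
    stop("old and new platform lie in the same quadrant", call. = FALSE)
  }
  s <- trial$samples
  n <- nrow(s)
  w <- diff(s$t)
  total <- sum(w)
  if (total <= 0) stop("zero-duration trial", call. = FALSE)
  q <- quadrant_index(s$x[-n], s$y[-n], geometry)
  c(
    pct_time_new_quadrant = 100 * sum(w[q == q_new]) / total,
    pct_time_old_quadrant = 100 * sum(w[q == q_old]) / total
  )
}

#' Zone occupancy and average velocity in a rectangular arena
#'
#' Computes, for every named zone of the arena, the percentage of trial
#' time and of traveled distance spent in the zone (interval start-point
#' attribution, as in [zone_fractions()]), plus the average velocity
#' (total distance / total time). Open-field center occupancy and elevated
#'-plus-maze open-arm occupancy are both instances of this readout.
#'
#' @param path A data frame with columns `t`, `x`, `y`, or a [swim_trial()].
#' @param arena An [arena_geometry()].
#' @param tolerance Permitted overshoot beyond the arena bounds, cm.
#' @return A list with `zones` (data frame: `zone`, `pct_time`,
#'   `pct_distance`) and `avg_velocity` (cm/s).
#' @export
zone_occupancy <- function(path, arena, tolerance = 1) {
  s <- if (inherits(path, "swim_trial")) path$samples else as.data.frame(path)
  if (!all(c("t", "x", "y") %in% names(s))) {
    stop("`path` must have columns t, x, y", call. = FALSE)
  }
  if (nrow(s) < 2L) stop("path needs at least 2 samples", call. = FALSE)
  if (any(diff(s$t) <= 0)) stop("non-monotone timestamps", call. = FALSE)
  if (any(abs(s$x) > arena$width / 2 + tolerance) ||
      any(abs(s$y) > arena$height / 2 + tolerance)) {
    stop("path leaves the arena beyond tolerance", call. = FALSE)
  }
  n <- nrow(s)
  w_t <- diff(s$t)
  w_d <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  total_t <- sum(w_t)
  total_d <- sum(w_d)
  if (total_t <= 0) stop("zero-duration path", call. = FALSE)
  sx <- s$x[-n]
  sy <- s$y[-n]
  res <- lapply(names(arena$zones), function(zn) {
    inside <- rep(FALSE, n - 1L)
    for (poly in arena$zones[[zn]]) {
      inside <- inside | pracma::inpolygon(sx, sy, poly[, 1], poly[, 2],
                                           boundary = TRUE)
    }
    data.frame(zone = zn,
               pct_time = 100 * sum(w_t[inside]) / total_t,
               pct_distance = if (total_d > 0) 100 * sum(w_d[inside]) / total_d else 0)
  })
  list(
    zones = do.call(rbind, res),
    avg_velocity = total_d / total_t
  )
}
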