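#' Geometric features of a swim path
#'
#' Attributes each path step's length to the analysis zone containing its
#' start point and returns the feature vector on which strategy
#' classification operates. Fractions are proportions of total swim
#' distance; quadrant occupancy uses the same step-start attribution, so
#' `frac_per_quadrant` sums to 1 and `frac_outer_ring + frac_inner_area = 1`
#' by construction. Points exactly on the outer-ring boundary belong to the
#' inner area (left-closed convention).
#'
#' Additional scalar features:
#' * `heading_efficiency` - net displacement toward the platform divided by
#'   path length, clipped to \[0, 1\]; near 1 for a direct swim.
#' * `circularity` - absolute net angular progression around the pool center
#'   divided by total angular progression (samples closer than 5 cm to the
#'   center are excluded because their bearing is ill-defined); near 1 for
#'   sustained one-directional circling.
#' * `mean_radius` - distance-weighted mean distance from the pool center.
#' * `frac_central` - fraction of swim distance within a central disc of the
#'   focal-zone diameter, used to separate scanning from random swims.
#'
#' Trials sampled coarser than `max_dt` are first resampled at
#' `resample_dt` so that step attribution approximates the continuous path.
#'
#' @param trial A [swim_trial()].
#' @param geometry A [pool_geometry()]; defaults to the trial's own.
#' @param corridor_half_angle Half-angle in degrees of the platform corridor,
#'   the angular sector centered on the release-point-to-platform line.
#' @param max_dt Maximum tolerated sampling interval before resampling, s.
#' @param resample_dt Resampling interval, s.
#' @return An object of class `trial_features`.
#' @export
zone_fractions <- function(trial, geometry = trial$geometry,
                           corridor_half_angle = 20,
                           max_dt = 0.2, resample_dt = 0.1) {
  stopifnot(inherits(trial, "swim_trial"))
  if (max(diff(trial$samples$t)) > max_dt + 1e-9) {
    trial <- resample_path(trial, resample_dt)
  }
  s <- trial$samples
  n <- nrow(s)
  step_len <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  total <- sum(step_len)
  if (total <= 0) stop("stationary trial: zero total path length", call. = FALSE)

  sx <- s$x[-n]
  sy <- s$y[-n]
  r <- sqrt(sx^2 + sy^2)
  ring_r <- geometry$pool_radius - geometry$outer_ring_width
  frac_outer <- sum(step_len[r > ring_r]) / total

  start <- c(s$x[1], s$y[1])
  pc <- geometry$platform_center
  v0 <- pc - start
  v0n <- sqrt(sum(v0^2))
  dx <- sx - start[1]
  dy <- sy - start[2]
  dn <- sqrt(dx^2 + dy^2)
  cosang <- ifelse(dn * v0n == 0, 1,
                   pmax(-1, pmin(1, (dx * v0[1] + dy * v0[2]) / (dn * v0n))))
  in_corr <- cosang >= cos(corridor_half_angle * pi / 180)
  frac_corridor <- sum(step_len[in_corr]) / total

  focal_r <- geometry$focal_zone_diameter / 2
  dplat <- sqrt((sx - pc[1])^2 + (sy - pc[2])^2)
  frac_focal <- sum(step_len[dplat <= focal_r]) / total
  frac_central <- sum(step_len[r <= focal_r]) / total

  q <- quadrant_index(sx, sy, geometry)
  frac_q <- vapply(1:4, function(k) sum(step_len[q == k]), numeric(1)) / total

  d0 <- sqrt(sum((start - pc)^2))
  d1 <- sqrt(sum((c(s$x[n], s$y[n]) - pc)^2))
  heading_eff <- max(0, min(1, (d0 - d1) / total))

  rad <- sqrt(s$x^2 + s$y^2)
  th <- atan2(s$y, s$x)
  dth <- diff(th)
  dth <- (dth + pi) %% (2 * pi) - pi
  ok <- pmin(rad[-n], rad[-1]) >= 5
  denom <- sum(abs(dth[ok]))
  circularity <- if (denom > 0) abs(sum(dth[ok])) / denom else 0

  structure(
    list(
      frac_outer_ring = frac_outer,
      frac_inner_area = 1 - frac_outer,
      frac_corridor = frac_corridor,
      frac_focal_zone = frac_focal,
      frac_central = frac_central,
      frac_per_quadrant = frac_q,
      heading_efficiency = heading_eff,
      circularity = circularity,
      mean_radius = sum(step_len * r) / total,
      path_length = total,
      latency = s$t[n] - s$t[1]
    ),
    class = "trial_features"
  )
}

#' @export
print.trial_features <- function(x, ...) {
  cat(sprintf(
    paste0("<trial_features> path %.1f cm in %.1f s\n",
           "  outer %.2f | corridor %.2f | focal %.2f | central %.2f\n",
           "  efficiency %.2f | circularity %.2f | quadrants %s\n"),
    x$path_length, x$latency, x$frac_outer_ring, x$frac_corridor,
    x$frac_focal_zone, x$frac_central, x$heading_efficiency, x$circularity,
    paste(sprintf("%.2f", x$frac_per_quadrant), collapse = "/")
  ))
  invisible(x)
}

#' @export
as.data.frame.trial_features <- function(x, ...) {
  data.frame(
    frac_outer_ring = x$frac_outer_ring,
    frac_inner_area = x$frac_inner_area,
    frac_corridor = x$frac_corridor,
    frac_focal_zone = x$frac_focal_zone,
    frac_central = x$frac_central,
    frac_q1 = x$frac_per_quadrant[1],
    frac_q2 = x$frac_per_quadrant[2],
    frac_q3 = x$frac_per_quadrant[3],
    frac_q4 = x$frac_per_quadrant[4],
    heading_efficiency = x$heading_efficiency,
    circularity = x$circularity,
    mean_radius = x$mean_radius,
    path_length = x$path_length,
    latency = x$latency
  )
}
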