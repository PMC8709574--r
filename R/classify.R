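#' Thresholds for swim-strategy classification
#'
#' The published rule set gives distance-fraction cutoffs (thigmotaxis
#' >70% in the outer ring, inner-area strategies >80% inside it, directed
#' search >60% and direct swim >80% in the platform corridor) but no
#' arbitration order and only partial definitions for the scanning /
#' random-swim split; the remaining parameters here make the cascade total
#' and deterministic and are documented in the methods vignette.
#'
#' @param thigmotaxis_outer_fraction Minimum outer-ring distance fraction
#'   for thigmotaxis (exclusive).
#' @param inner_area_fraction Minimum inner-area distance fraction for the
#'   inner-area strategies (exclusive).
#' @param corridor_fraction_directed Minimum corridor distance fraction for
#'   directed search (exclusive).
#' @param corridor_fraction_direct Minimum corridor distance fraction for
#'   direct swim (exclusive).
#' @param corridor_half_angle Corridor half-angle, degrees.
#' @param quadrant_balance_max Maximum distance fraction any single quadrant
#'   may hold for exploration to count as balanced (inclusive).
#' @param efficiency_min_direct Minimum heading efficiency for a direct swim
#'   (inclusive); separates direct swims from corridor-confined zigzags.
#' @param efficiency_min_directed Minimum heading efficiency for directed
#'   search (inclusive); "directed" trajectories make net progress toward
#'   the platform, unlike undirected swims that merely cross the corridor
#'   sector.
#' @param focal_fraction_min Minimum focal-zone distance fraction for focal
#'   search (exclusive).
#' @param circularity_min Circularity above which a trajectory counts as
#'   circling (exclusive).
#' @param chaining_radius_tol Relative tolerance on the match between the
#'   mean swim radius and the platform's orbit radius for chaining.
#' @param scanning_center_min Minimum central-region distance fraction for
#'   scanning (inclusive); about four times the chance (area-fraction)
#'   level of the 30-cm central disc in a 170-cm pool.
#' @param min_block_run Trials of consecutive same-block strategies needed
#'   to establish a strategy block.
#' @return An object of class `strategy_thresholds`.
#' @export
strategy_thresholds <- function(thigmotaxis_outer_fraction = 0.70,
                                inner_area_fraction = 0.80,
                                corridor_fraction_directed = 0.60,
                                corridor_fraction_direct = 0.80,
                                corridor_half_angle = 20,
                                quadrant_balance_max = 0.50,
                                efficiency_min_direct = 0.70,
                                efficiency_min_directed = 0.30,
                                focal_fraction_min = 0.50,
                                circularity_min = 0.70,
                                chaining_radius_tol = 0.25,
                                scanning_center_min = 0.12,
                                min_block_run = 3L) {
  props <- c(thigmotaxis_outer_fraction, inner_area_fraction,
             corridor_fraction_directed, corridor_fraction_direct,
             quadrant_balance_max, efficiency_min_direct,
             efficiency_min_directed, focal_fraction_min,
             circularity_min, scanning_center_min)
  if (any(props <= 0 | props > 1)) {
    stop("all proportion thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (min_block_run < 1) stop("`min_block_run` must be >= 1", call. = FALSE)
  structure(
    list(
      thigmotaxis_outer_fraction = thigmotaxis_outer_fraction,
      inner_area_fraction = inner_area_fraction,
      corridor_fraction_directed = corridor_fraction_directed,
      corridor_fraction_direct = corridor_fraction_direct,
      corridor_half_angle = corridor_half_angle,
      quadrant_balance_max = quadrant_balance_max,
      efficiency_min_direct = efficiency_min_direct,
      efficiency_min_directed = efficiency_min_directed,
      focal_fraction_min = focal_fraction_min,
      circularity_min = circularity_min,
      chaining_radius_tol = chaining_radius_tol,
      scanning_center_min = scanning_center_min,
      min_block_run = as.integer(min_block_run)
    ),
    class = "strategy_thresholds"
  )
}

#' Strategy labels and their block membership
#'
#' Block 1 groups the non-hippocampal-dependent strategies (thigmotaxis
#' `Tt`, random swim `RS`, scanning `Sc`); block 2 the hippocampal-dependent
#' ones (directed search `DS`, focal search `FS`, direct swim `DSw`).
#' Chaining (`Ch`) and `Unclassified` belong to neither block.
#'
#' @param label Character vector of strategy labels.
#' @return Integer vector: 1, 2, or `NA` for block-less labels.
#' @export
strategy_block <- function(label) {
  out <- rep(NA_integer_, length(label))
  out[label %in% c("Tt", "RS", "Sc")] <- 1L
  out[label %in% c("DS", "FS", "DSw")] <- 2L
  out
}

strategy_labels <- c("Tt", "RS", "Sc", "Ch", "DS", "FS", "DSw", "Unclassified")

#' Classify one trial's features into a search strategy
#'
#' A deterministic precedence cascade, most specific rule first:
#' direct swim (`DSw`), focal search (`FS`), directed search (`DS`),
#' thigmotaxis (`Tt`), chaining (`Ch`), scanning (`Sc`), random swim (`RS`),
#' else `Unclassified`. A direct swim also satisfies the looser corridor and
#' inner-area rules, so ordering from specific to generic resolves every
#' overlap.
#'
#' @param features A [zone_fractions()] result.
#' @param thresholds A [strategy_thresholds()].
#' @param geometry The [pool_geometry()] the features were computed under
#'   (needed for the platform orbit radius used by the chaining rule).
#' @return An object of class `strategy_call` with elements `label`,
#'   `block` (1, 2 or `NA`) and `features`.
#' @export
classify_trial <- function(features, thresholds = strategy_thresholds(),
                           geometry = pool_geometry()) {
  stopifnot(inherits(features, "trial_features"))
  f <- features
  th <- thresholds
  orbit <- sqrt(sum(geometry$platform_center^2))
  label <-
    if (f$frac_corridor > th$corridor_fraction_direct &&
        f$heading_efficiency >= th$efficiency_min_direct) {
      "DSw"
    } else if (f$frac_focal_zone > th$focal_fraction_min) {
      "FS"
    } else if (f$frac_corridor > th$corridor_fraction_directed &&
               f$heading_efficiency >= th$efficiency_min_directed) {
      "DS"
    } else if (f$frac_outer_ring > th$thigmotaxis_outer_fraction) {
      "Tt"
    } else if (f$circularity > th$circularity_min && orbit > 0 &&
               abs(f$mean_radius - orbit) / orbit <= th$chaining_radius_tol) {
      "Ch"
    } else if (f$frac_inner_area > th$inner_area_fraction &&
               max(f$frac_per_quadrant) <= th$quadrant_balance_max &&
               f$circularity <= th$circularity_min &&
               f$frac_central >= th$scanning_center_min) {
      "Sc"
    } else if (f$frac_inner_area > th$inner_area_fraction) {
      "RS"
    } else {
      "Unclassified"
    }
  structure(list(label = label, block = strategy_block(label),
                 features = features),
            class = "strategy_call")
}

#' @export
print.strategy_call <- function(x, ...) {
  blk <- if (is.na(x$block)) "no block" else paste("block", x$block)
  cat(sprintf("<strategy_call> %s (%s)\n", x$label, blk))
  invisible(x)
}

#' Classify a swim trial end to end
#'
#' Convenience wrapper: computes [zone_fractions()] with the thresholds'
#' corridor half-angle, then applies [classify_trial()].
#'
#' @inheritParams zone_fractions
#' @inheritParams classify_trial
#' @return A `strategy_call`.
#' @export
classify_path <- function(trial, geometry = trial$geometry,
                          thresholds = strategy_thresholds()) {
  f <- zone_fractions(trial, geometry,
                      corridor_half_angle = thresholds$corridor_half_angle)
  classify_trial(f, thresholds, geometry)
}
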