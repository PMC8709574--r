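#' Swim trial: a timestamped planar path in a pool
#'
#' Bundles the tracked path of one maze trial with its pool geometry.
#' Timestamps must be strictly increasing; they are shifted so the trial
#' starts at t = 0. Points may exceed the pool radius by at most 1 cm
#' (tracking jitter); anything further out is an error rather than being
#' clipped silently.
#'
#' @param samples Data frame with numeric columns `t` (s), `x`, `y` (cm,
#'   pool-centered).
#' @param geometry A [pool_geometry()].
#' @param trial_id,animal_id Identifiers carried through to results.
#' @param start_position Optional compass label (`"N"`, `"E"`, `"S"`, `"W"`)
#'   of the release point.
#' @param tolerance Permitted overshoot beyond the pool radius, in cm.
#' @return An object of class `swim_trial`.
#' @export
swim_trial <- function(samples, geometry, trial_id = "trial",
                       animal_id = NA_character_, start_position = NA_character_,
                       tolerance = 1) {
  samples <- as.data.frame(samples)
  need <- c("t", "x", "y")
  if (!all(need %in% names(samples))) {
    stop("`samples` must have columns t, x, y", call. = FALSE)
  }
  samples <- samples[, need]
  if (nrow(samples) < 2L) stop("a swim trial needs at least 2 samples", call. = FALSE)
  if (anyNA(samples)) stop("samples contain missing values", call. = FALSE)
  if (any(diff(samples$t) <= 0)) {
    stop("non-monotone timestamps in trial samples", call. = FALSE)
  }
  r <- sqrt(samples$x^2 + samples$y^2)
  bad <- which(r > geometry$pool_radius + tolerance)
  if (length(bad)) {
    stop(sprintf("sample row %d lies %.2f cm outside the pool (beyond %.1f cm tolerance)",
                 bad[1], r[bad[1]] - geometry$pool_radius, tolerance),
         call. = FALSE)
  }
  samples$t <- samples$t - samples$t[1]
  rownames(samples) <- NULL
  if (!is.na(start_position)) {
    start_position <- match.arg(start_position, c("N", "E", "S", "W"))
  }
  structure(
    list(trial_id = trial_id, animal_id = animal_id, samples = samples,
         start_position = start_position, geometry = geometry),
    class = "swim_trial"
  )
}

#' @export
print.swim_trial <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<swim_trial> %s: %d samples over %.1f s, path %.1f cm\n",
              x$trial_id, nrow(s), s$t[nrow(s)], path_length(x)))
  invisible(x)
}

#' Total path length of a trial, in cm
#'
#' @param trial A [swim_trial()] (or a data frame with `x`, `y`).
#' @return Numeric scalar.
#' @export
path_length <- function(trial) {
  s <- if (inherits(trial, "swim_trial")) trial$samples else as.data.frame(trial)
  sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
}

detect_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (!length(l1)) stop(sprintf("empty file: %s", path), call. = FALSE)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read a swim trajectory from delimited text
#'
#' Expects a header with columns `t`, `x`, `y` (comma- or tab-delimited,
#' autodetected); extra columns are ignored.
#'
#' @param path File path.
#' @param geometry A [pool_geometry()].
#' @inheritParams swim_trial
#' @return A [swim_trial()].
#' @export
read_trajectory <- function(path, geometry, trial_id = basename(path),
                            animal_id = NA_character_,
                            start_position = NA_character_) {
  sep <- detect_sep(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("t", "x", "y"), names(d))
  if (length(miss)) {
    stop(sprintf("trajectory file %s is missing column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (cn in c("t", "x", "y")) {
    if (!is.numeric(d[[cn]])) {
      stop(sprintf("column %s of %s is not numeric", cn, path), call. = FALSE)
    }
  }
  swim_trial(d[, c("t", "x", "y")], geometry, trial_id = trial_id,
             animal_id = animal_id, start_position = start_position)
}

#' Write a swim trajectory as comma-delimited text
#'
#' Values are written with 10 significant digits so that write/read
#' round-trips reproduce coordinates to well beyond tracking precision.
#'
#' @param trial A [swim_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trial, path) {
  s <- trial$samples
  d <- data.frame(t = sprintf("%.10g", s$t),
                  x = sprintf("%.10g", s$x),
                  y = sprintf("%.10g", s$y))
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resample a trial onto a uniform time grid
#'
#' Linear interpolation of x and y onto `seq(0, T, by = dt)`. If the trial
#' duration is not a multiple of `dt` the final sample is appended as a
#' shorter step so that the endpoint is preserved exactly. By the triangle
#' inequality the resampled path is never longer than the original.
#'
#' @param trial A [swim_trial()].
#' @param dt Target sampling interval in seconds.
#' @return A [swim_trial()] on the uniform grid.
#' @export
resample_path <- function(trial, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a positive number", call. = FALSE)
  }
  s <- trial$samples
  total <- s$t[nrow(s)]
  if (dt > total) stop("`dt` exceeds the trial duration", call. = FALSE)
  grid <- seq(0, total, by = dt)
  if (total - grid[length(grid)] > 1e-9) grid <- c(grid, total)
  out <- data.frame(
    t = grid,
    x = stats::approx(s$t, s$x, xout = grid, rule = 2)$y,
    y = stats::approx(s$t, s$y, xout = grid, rule = 2)$y
  )
  swim_trial(out, trial$geometry, trial_id = trial$trial_id,
             animal_id = trial$animal_id, start_position = trial$start_position)
}
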