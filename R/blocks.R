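#' Strategy-block segmentation across a trial sequence
#'
#' A block is established at the first run of at least `min_block_run`
#' consecutive trials whose strategies belong to the same block, and the
#' establishment is dated from the first trial of that run. Once
#' established, a block persists until the other block is established by the
#' same rule; shorter relapses do not reset it. Trials with block-less
#' strategies (chaining, unclassified) interrupt runs but inherit the
#' currently established block in the timeline.
#'
#' @param calls Character vector of strategy labels, a list of
#'   [classify_trial()] results, or a data frame with a `label` column.
#' @param thresholds A [strategy_thresholds()] (supplies `min_block_run`).
#' @return An object of class `block_timeline`: a list with
#'   * `timeline` - data frame with `trial`, `label`, `block_category`
#'     (the trial's own block) and `established_block`;
#'   * `onsets` - data frame of establishment events (`trial`, `block`);
#'   * `block_lengths` - named vector, trials spent under each established
#'     block.
#' @examples
#' assign_blocks(c("Sc", "Sc", "Sc", "DS", "FS", "DSw"))
#' @export
assign_blocks <- function(calls, thresholds = strategy_thresholds()) {
  labels <- if (is.character(calls)) {
    calls
  } else if (is.data.frame(calls)) {
    as.character(calls$label)
  } else {
    vapply(calls, function(x) x$label, character(1))
  }
  if (!length(labels)) stop("need at least one strategy call", call. = FALSE)
  bad <- setdiff(unique(labels), strategy_labels)
  if (length(bad)) {
    stop(sprintf("unknown strategy label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  m <- thresholds$min_block_run
  cat_ <- strategy_block(labels)
  n <- length(cat_)

  vals <- ifelse(is.na(cat_), 0L, cat_)
  rl <- rle(vals)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L

  established <- rep(NA_integer_, n)
  cur <- NA_integer_
  onset_trial <- integer(0)
  onset_block <- integer(0)
  for (i in seq_along(rl$values)) {
    v <- rl$values[i]
    if (v != 0L && rl$lengths[i] >= m && (is.na(cur) || v != cur)) {
      cur <- v
      onset_trial <- c(onset_trial, starts[i])
      onset_block <- c(onset_block, v)
    }
    established[starts[i]:ends[i]] <- cur
  }

  lengths_out <- c(
    block1 = sum(established == 1L, na.rm = TRUE),
    block2 = sum(established == 2L, na.rm = TRUE)
  )
  structure(
    list(
      timeline = data.frame(trial = seq_len(n), label = labels,
                            block_category = cat_,
                            established_block = established),
      onsets = data.frame(trial = onset_trial, block = onset_block),
      block_lengths = lengths_out
    ),
    class = "block_timeline"
  )
}

#' @export
print.block_timeline <- function(x, ...) {
  cat(sprintf("<block_timeline> %d trials; block lengths: 1 -> %d, 2 -> %d\n",
              nrow(x$timeline), x$block_lengths["block1"],
              x$block_lengths["block2"]))
  if (nrow(x$onsets)) {
    cat(paste(sprintf("  block %d established at trial %d",
                      x$onsets$block, x$onsets$trial), collapse = "\n"), "\n")
  } else {
    cat("  no block established\n")
  }
  invisible(x)
}
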