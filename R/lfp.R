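#' Local field potential recording
#'
#' A single-channel sampled voltage trace (arbitrary units) with its
#' sampling rate. Spectral analyses up to `f` Hz require `fs > 2 f`.
#'
#' @param samples Numeric vector of voltage samples.
#' @param fs Sampling rate in Hz.
#' @param channel_id Channel label, e.g. `"dHip"` or `"mPFC"`.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, channel_id = "lfp") {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("empty LFP trace", call. = FALSE)
  if (anyNA(samples)) stop("LFP trace contains missing values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  structure(
    list(channel_id = channel_id, samples = samples, fs = fs,
         duration = length(samples) / fs),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s: %d samples at %g Hz (%.2f s)\n",
              x$channel_id, length(x$samples), x$fs, x$duration))
  invisible(x)
}

#' Read an LFP trace from delimited text
#'
#' Accepts a single numeric column (`value`) or two columns (`t`, `value`).
#' A header row is optional and autodetected. When a time column is present,
#' sampling must be uniform at `1/fs` within a relative tolerance of 1e-6.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz.
#' @param channel_id Channel label.
#' @return An [lfp_recording()].
#' @export
read_lfp <- function(path, fs, channel_id = basename(path)) {
  sep <- detect_sep(path)
  l1 <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(l1))))
  d <- utils::read.table(path, header = header, sep = sep,
                         stringsAsFactors = FALSE)
  if (!nrow(d)) stop(sprintf("empty LFP file: %s", path), call. = FALSE)
  if (ncol(d) == 1L) {
    v <- d[[1]]
  } else {
    tv <- d[[1]]
    v <- d[[2]]
    dtv <- diff(tv)
    if (any(abs(dtv - 1 / fs) > 1e-6 / fs)) {
      stop(sprintf("non-uniform sampling in %s: expected dt = %g s", path, 1 / fs),
           call. = FALSE)
    }
  }
  if (!is.numeric(v)) stop(sprintf("non-numeric values in %s", path), call. = FALSE)
  if (length(v) < 2L) {
    stop(sprintf("%s is too short for 1-s segmentation", path), call. = FALSE)
  }
  lfp_recording(v, fs, channel_id)
}

#' Write an LFP trace as a single-column text file
#'
#' @param rec An [lfp_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(rec, path) {
  writeLines(c("value", sprintf("%.10g", rec$samples)), path)
  invisible(path)
}
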