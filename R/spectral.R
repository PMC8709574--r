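#' Parameters for multi-taper spectral estimation
#'
#' Defaults match a standard anesthetized-rodent LFP protocol: 1-s
#' non-overlapping segments, DPSS tapers with time-bandwidth 3 and 5 tapers
#' (so a +/-3 Hz analysis bandwidth), and a 1-90 Hz reporting range on the
#' 1/segment-length Hz grid.
#'
#' @param segment_length Segment length in seconds.
#' @param time_bandwidth DPSS time-bandwidth product.
#' @param n_tapers Number of DPSS tapers; at most `2 * time_bandwidth - 1`.
#' @param freq_range Numeric length-2, reported frequency range in Hz.
#' @param overlap Fractional overlap between consecutive segments in
#'   \[0, 1).
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(segment_length = 1, time_bandwidth = 3,
                            n_tapers = 5, freq_range = c(1, 90),
                            overlap = 0) {
  if (segment_length <= 0) stop("`segment_length` must be positive", call. = FALSE)
  if (n_tapers > 2 * time_bandwidth - 1 + 1e-9) {
    stop("`n_tapers` must be <= 2 * time_bandwidth - 1", call. = FALSE)
  }
  if (length(freq_range) != 2L || freq_range[1] < 0 ||
      freq_range[2] <= freq_range[1]) {
    stop("`freq_range` must be an increasing (lo, hi) pair in Hz", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  structure(
    list(segment_length = segment_length, time_bandwidth = time_bandwidth,
         n_tapers = as.integer(n_tapers), freq_range = freq_range,
         overlap = overlap),
    class = "spectral_params"
  )
}

#' Frequency bands for band-summary statistics
#'
#' The conventional rodent LFP bands: delta 1-4, theta 4-12, beta 12-20,
#' low gamma 20-40 and high gamma 40-90 Hz. Band intervals are half-open
#' `[lo, hi)` with the final band closed at its upper edge, so each shared
#' edge belongs to exactly one band.
#'
#' @param delta,theta,beta,low_gamma,high_gamma Numeric (lo, hi) pairs, Hz.
#' @return An object of class `band_set`: a data frame with `name`, `lo`,
#'   `hi`.
#' @export
band_set <- function(delta = c(1, 4), theta = c(4, 12), beta = c(12, 20),
                     low_gamma = c(20, 40), high_gamma = c(40, 90)) {
  b <- rbind(delta, theta, beta, low_gamma, high_gamma)
  d <- data.frame(name = rownames(b), lo = b[, 1], hi = b[, 2],
                  row.names = NULL)
  if (any(d$hi <= d$lo)) stop("band edges must be increasing", call. = FALSE)
  o <- order(d$lo)
  d <- d[o, ]
  if (any(d$lo[-1] < d$hi[-nrow(d)])) {
    stop("bands overlap under the half-open convention", call. = FALSE)
  }
  structure(d, class = c("band_set", "data.frame"))
}

#' Cut a recording into equal analysis segments
#'
#' Non-overlapping (by default) windows of `segment_length` seconds, each
#' demeaned; the trailing remainder shorter than one segment is discarded.
#'
#' @param rec An [lfp_recording()].
#' @param params A [spectral_params()].
#' @return A numeric matrix, one demeaned segment per column.
#' @export
segment_lfp <- function(rec, params = spectral_params()) {
  stopifnot(inherits(rec, "lfp_recording"))
  seg_n <- round(params$segment_length * rec$fs)
  n <- length(rec$samples)
  if (n < seg_n) {
    stop(sprintf("recording (%.3f s) is shorter than one %g-s segment",
                 rec$duration, params$segment_length), call. = FALSE)
  }
  step <- max(1L, round(seg_n * (1 - params$overlap)))
  starts <- seq(1L, n - seg_n + 1L, by = step)
  m <- vapply(starts, function(s) rec$samples[s:(s + seg_n - 1L)],
              numeric(seg_n))
  m <- matrix(m, nrow = seg_n)
  sweep(m, 2L, colMeans(m))
}

check_spectral_setup <- function(fs, params) {
  if (params$freq_range[2] >= fs / 2) {
    stop("`freq_range` upper edge must be below the Nyquist frequency",
         call. = FALSE)
  }
}

# taper- (and optionally segment-) resolved eigen-FFTs; returns an
# n x k x nseg array of complex eigencoefficients
eigen_ffts <- function(segs, tapers) {
  k <- ncol(tapers)
  nseg <- ncol(segs)
  out <- array(0i, dim = c(nrow(segs), k, nseg))
  for (s in seq_len(nseg)) {
    out[, , s] <- stats::mvfft(tapers * segs[, s])
  }
  out
}

#' Multi-taper power spectral density, in dB
#'
#' Per segment and taper the spectrum is the squared modulus of the Fourier
#' transform of the tapered, demeaned segment; spectra are averaged over
#' tapers, then over segments, converted to a one-sided per-bin power scale
#' and reported as `10 * log10(power)` on the `1/segment_length` Hz grid
#' restricted to `freq_range`. On the linear scale the one-sided spectrum of
#' a signal sums to its variance (Parseval), which is how the scaling is
#' validated. Band means are computed on the linear scale and then
#' converted to dB.
#'
#' @param rec An [lfp_recording()].
#' @param params A [spectral_params()].
#' @param bands A [band_set()], or `NULL` to skip band summaries.
#' @return An object of class `mt_spectrum`: `freq` (Hz), `value` (dB),
#'   `linear` (one-sided per-bin power), `n_segments`, `band_means` (dB).
#' @export
mt_psd <- function(rec, params = spectral_params(), bands = band_set()) {
  check_spectral_setup(rec$fs, params)
  segs <- segment_lfp(rec, params)
  if (all(segs == 0)) {
    stop("degenerate signal: all segments are zero after demeaning", call. = FALSE)
  }
  seg_n <- nrow(segs)
  tapers <- dpss_tapers(seg_n, params$time_bandwidth, params$n_tapers)
  ef <- eigen_ffts(segs, tapers)
  # mean over tapers (dim 2) then segments (dim 3)
  S <- rowMeans(Mod(ef)^2, dims = 1L)

  half <- floor(seg_n / 2)
  freq <- (0:half) * rec$fs / seg_n
  lin <- S[1:(half + 1)] / seg_n
  dbl <- 2:(if (seg_n %% 2 == 0) half else half + 1) # interior (non-DC, non-Nyquist) bins
  lin[dbl] <- 2 * lin[dbl]

  keep <- freq >= params$freq_range[1] & freq <= params$freq_range[2]
  freq <- freq[keep]
  lin <- lin[keep]
  if (any(lin < 1e-20)) {
    warning("near-silent frequency bins floored at 1e-20 before log")
    lin <- pmax(lin, 1e-20)
  }
  obj <- structure(
    list(freq = freq, value = 10 * log10(lin), linear = lin,
         kind = "psd", n_segments = ncol(segs),
         params = params, band_means = NULL),
    class = "mt_spectrum"
  )
  if (!is.null(bands)) obj$band_means <- band_summary(obj, bands)
  obj
}

#' Multi-taper magnitude-squared coherence between two channels
#'
#' Both recordings are cut into matching demeaned segments and expanded on
#' the same DPSS tapers. By default (`average = "pooled"`) cross- and
#' auto-spectra are averaged over tapers and segments before forming
#' `|Sab|^2 / (Saa * Sbb)`, giving the estimator about
#' `n_tapers * n_segments` degrees of freedom and a null bias of roughly
#' their inverse. `average = "per_segment"` instead forms a
#' magnitude-squared coherence per segment (taper-averaged spectra) and
#' averages those across segments; with few tapers this carries a large
#' positive bias (about `1/n_tapers` under independence) and is provided
#' for comparability only.
#'
#' @param a,b [lfp_recording()]s with equal sampling rate and duration.
#' @param params A [spectral_params()].
#' @param bands A [band_set()], or `NULL` to skip band summaries.
#' @param average `"pooled"` or `"per_segment"`; see Details.
#' @return An object of class `mt_spectrum` with coherence values in
#'   \[0, 1\] on the grid restricted to `freq_range`.
#' @export
mt_coherence <- function(a, b, params = spectral_params(),
                         bands = band_set(),
                         average = c("pooled", "per_segment")) {
  average <- match.arg(average)
  if (a$fs != b$fs) stop("sampling rates differ between channels", call. = FALSE)
  if (length(a$samples) != length(b$samples)) {
    stop("channel durations differ", call. = FALSE)
  }
  check_spectral_setup(a$fs, params)
  sa <- segment_lfp(a, params)
  sb <- segment_lfp(b, params)
  seg_n <- nrow(sa)
  nseg <- ncol(sa)
  for (s in seq_len(nseg)) {
    if (all(sa[, s] == 0)) {
      stop(sprintf("segment %d of channel %s has zero power", s, a$channel_id),
           call. = FALSE)
    }
    if (all(sb[, s] == 0)) {
      stop(sprintf("segment %d of channel %s has zero power", s, b$channel_id),
           call. = FALSE)
    }
  }
  tapers <- dpss_tapers(seg_n, params$time_bandwidth, params$n_tapers)
  fa <- eigen_ffts(sa, tapers)
  fb <- eigen_ffts(sb, tapers)

  if (average == "pooled") {
    Sab <- rowMeans(fa * Conj(fb), dims = 1L)
    Saa <- rowMeans(Mod(fa)^2, dims = 1L)
    Sbb <- rowMeans(Mod(fb)^2, dims = 1L)
    coh <- Mod(Sab)^2 / (Saa * Sbb)
  } else {
    acc <- numeric(seg_n)
    for (s in seq_len(nseg)) {
      Sab <- rowMeans(fa[, , s, drop = FALSE] * Conj(fb[, , s, drop = FALSE]),
                      dims = 1L)
      Saa <- rowMeans(Mod(fa[, , s, drop = FALSE])^2, dims = 1L)
      Sbb <- rowMeans(Mod(fb[, , s, drop = FALSE])^2, dims = 1L)
      acc <- acc + Mod(Sab)^2 / (Saa * Sbb)
    }
    coh <- acc / nseg
  }

  freq <- (seq_len(seg_n) - 1) * a$fs / seg_n
  keep <- freq >= params$freq_range[1] & freq <= params$freq_range[2]
  obj <- structure(
    list(freq = freq[keep], value = as.numeric(coh[keep]), linear = NULL,
         kind = "coherence", n_segments = nseg,
         params = params, band_means = NULL),
    class = "mt_spectrum"
  )
  if (!is.null(bands)) obj$band_means <- band_summary(obj, bands)
  obj
}

#' @export
print.mt_spectrum <- function(x, ...) {
  cat(sprintf("<mt_spectrum> %s over %.6g-%.6g Hz (%d bins, %d segments)\n",
              x$kind, min(x$freq), max(x$freq), length(x$freq), x$n_segments))
  if (!is.null(x$band_means)) {
    cat("  band means:",
        paste(sprintf("%s %.3g", names(x$band_means), x$band_means),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Band means of a spectrum
#'
#' Means over the grid frequencies falling in each band, using the
#' half-open `[lo, hi)` convention with the final band closed at its upper
#' edge. PSD band means are averaged on the linear power scale and
#' converted back to dB; coherence band means are plain means.
#'
#' @param spec An `mt_spectrum` from [mt_psd()] or [mt_coherence()].
#' @param bands A [band_set()].
#' @return Named numeric vector of band means.
#' @export
band_summary <- function(spec, bands = band_set()) {
  stopifnot(inherits(spec, "mt_spectrum"))
  if (any(bands$lo < min(spec$freq) - 1e-9) ||
      any(bands$hi > max(spec$freq) + 1e-9)) {
    stop("band edges fall outside the spectrum's frequency range", call. = FALSE)
  }
  top <- max(bands$hi)
  out <- vapply(seq_len(nrow(bands)), function(i) {
    lo <- bands$lo[i]
    hi <- bands$hi[i]
    sel <- spec$freq >= lo & (spec$freq < hi | (hi == top & spec$freq == hi))
    if (!any(sel)) return(NA_real_)
    if (spec$kind == "psd") {
      10 * log10(mean(spec$linear[sel]))
    } else {
      mean(spec$value[sel])
    }
  }, numeric(1))
  stats::setNames(out, bands$name)
}
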