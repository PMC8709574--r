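#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at half-bandwidth
#' `nw/n` cycles per sample via the standard symmetric tridiagonal
#' eigenproblem, whose eigenvectors are the Slepian sequences ordered by
#' spectral concentration. Tapers are unit-energy; symmetric tapers are
#' oriented to have a positive mean, antisymmetric ones a positive initial
#' slope. Results are cached per `(n, nw, k)` because the eigendecomposition
#' dominates the cost of a multi-taper analysis.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (dimensionless).
#' @param k Number of tapers; at most `2 * nw - 1` for well-concentrated
#'   tapers.
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5) {
  if (n < 2 * k) stop("taper length too short for the requested tapers", call. = FALSE)
  if (nw <= 0) stop("`nw` must be positive", call. = FALSE)
  if (k < 1 || k > 2 * nw - 1 + 1e-9) {
    stop("`k` must be between 1 and 2*nw - 1", call. = FALSE)
  }
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  hit <- .hippophen_cache[[key]]
  if (!is.null(hit)) return(hit)

  w <- nw / n
  t0 <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  t1 <- 1:(n - 1)
  off <- t1 * (n - t1) / 2
  A <- matrix(0, n, n)
  diag(A) <- dg
  A[cbind(t1, t1 + 1L)] <- off
  A[cbind(t1 + 1L, t1)] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-7) {
      if (s < 0) v[, j] <- -v[, j]
    } else if (v[2, j] - v[1, j] < 0) {
      v[, j] <- -v[, j]
    }
  }
  .hippophen_cache[[key]] <- v
  v
}
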