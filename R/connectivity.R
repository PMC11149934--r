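#' Pairwise orthogonalization
#'
#' Removes the zero-lag (leakage) component of `y` that is collinear with
#' `x`: y_perp = y - x * (<x, y> / <x, x>), so <x, y_perp> = 0. A copy of
#' `x` (pure leakage) maps to the zero vector.
#'
#' @param x,y Numeric vectors of equal length; `x` must not be all zero.
#' @return The orthogonalized `y`.
#' @export
orthogonalizePair <- function(x, y) {
  stopifnot(length(x) == length(y))
  xx <- sum(x * x)
  if (xx <= 0) stop("cannot orthogonalize against a zero signal")
  y - x * (sum(x * y) / xx)
}

#' Amplitude envelope correlation of two signals
#'
#' Band-limited AEC with pairwise leakage correction: each signal is
#' band-passed, the other signal's zero-lag component is regressed out, and
#' the Pearson correlation of the Hilbert envelopes is computed in both
#' directions and averaged. A zero-variance envelope makes the correlation
#' undefined; the convention is 0 with a warning (so a pure leaked copy of a
#' signal has AEC 0).
#'
#' @param x,y Numeric vectors (>= 10 s of data).
#' @param fs Sampling rate (Hz).
#' @param band Band (Hz), default beta c(13, 30). `NULL` if the inputs are
#'   already band-limited.
#' @return AEC in \[-1, 1\].
#' @export
aec <- function(x, y, fs, band = c(13, 30)) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10 * fs) stop("need at least 10 s of data")
  M <- cbind(x, y)
  if (!is.null(band)) M <- bandFilter(M, band, fs)
  Z <- analyticSignal(M)
  A <- aecPairsC(Re(Z), Im(Z), envStride(fs))
  if (A$nDegenerate > 0) warning("zero-variance envelope: AEC set to 0")
  A$A[1, 2]
}

#' Build a connectome from region time courses
#'
#' All-pairs orthogonalized amplitude envelope correlation, symmetrized
#' (both regression directions averaged), zero diagonal.
#'
#' @param ve Regions x samples matrix, e.g. `parcelTimecourses()$ve`
#'   (already band-limited), or raw region signals with `band` set.
#' @param fs Sampling rate (Hz).
#' @param band Band (Hz) to filter to first; `NULL` when `ve` is already
#'   band-limited.
#' @param labels,groups Region labels and group tags.
#' @return A [Connectome-class].
#' @export
buildConnectome <- function(ve, fs, band = NULL,
                            labels = sprintf("R%02d", seq_len(nrow(ve))),
                            groups = rep("other", nrow(ve))) {
  if (nrow(ve) < 2) stop("need at least 2 regions")
  X <- t(ve)
  if (!is.null(band)) X <- bandFilter(X, band, fs)
  Z <- analyticSignal(X)
  res <- aecPairsC(Re(Z), Im(Z), envStride(fs))
  if (res$nDegenerate > 0) {
    warning(res$nDegenerate, " region pair(s) with zero-variance envelope: AEC set to 0")
  }
  A <- res$A
  A[!is.finite(A)] <- 0
  A <- pmin(pmax((A + t(A)) / 2, -1), 1)
  diag(A) <- 0
  new("Connectome", A = A, labels = labels, groups = groups)
}


# Envelope sampling stride for the AEC correlation: keep the envelope
# series at >= 75 Hz, several times the bandwidth of any analysis band
# used here, so the strided Pearson estimate equals the full one.
envStride <- function(fs) max(1L, as.integer(floor(fs / 75)))
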