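#' @importFrom stats fft rnorm runif rexp rlnorm var sd cor pt qt coef
#' @importFrom utils head tail write.csv
NULL

# Run `code` under a fixed RNG seed when one is supplied, otherwise use the
# current RNG stream. All exported stochastic operations funnel through this.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# Deterministic child seed, kept inside 32-bit integer range.
childSeed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1000003 + 7919 * as.double(index)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

opmMsg <- function(...) {
  if (isTRUE(getOption("opmbeta.quiet", TRUE))) return(invisible(NULL))
  message(...)
}

# ---- sample/window arithmetic ------------------------------------------------

# Half-open window [a, b): indices of time vector t falling inside.
winIdx <- function(t, a, b) which(t >= a - 1e-9 & t < b - 1e-9)

# Number of samples in a half-open window of length (b - a) at rate fs.
winLen <- function(a, b, fs) as.integer(round((b - a) * fs))

# ---- frequency-domain zero-phase filtering ----------------------------------

# Evaluate the transfer function of an IIR filter (b, a coefficients) at
# normalized angular frequencies w (radians/sample).
iirResponse <- function(filt, w) {
  z <- exp(-1i * outer(w, seq_along(filt$b) - 1))
  num <- drop(z %*% filt$b)
  z <- exp(-1i * outer(w, seq_along(filt$a) - 1))
  den <- drop(z %*% filt$a)
  num / den
}

# Squared-magnitude (zero-phase) gain of a cascade of IIR filters on the FFT
# grid of an n-point series sampled at fs. Cached: gain curves are reused
# heavily across channels/regions with identical (filters, n, fs).
gainCache <- new.env(parent = emptyenv())

cascadeGain <- function(filters, n, fs) {
  key <- paste(n, fs, paste(vapply(filters, function(f) {
    paste(signif(c(f$b, f$a), 12), collapse = ",")
  }, character(1)), collapse = ";"), sep = "|")
  hit <- gainCache[[key]]
  if (!is.null(hit)) return(hit)
  freq <- (seq_len(n) - 1) / n * fs
  freq[freq > fs / 2] <- freq[freq > fs / 2] - fs
  w <- 2 * pi * abs(freq) / fs
  g <- rep(1, n)
  for (f in filters) g <- g * Mod(iirResponse(f, w))^2
  if (length(gainCache) > 40) rm(list = ls(gainCache), envir = gainCache)
  gainCache[[key]] <- g
  g
}

# FFT length used for filtering an n-sample series with reflection pad:
# rounded up to a highly composite size (FFT speed).
fftLen <- function(n, pad) stats::nextn(n + 2L * pad, c(2, 3, 5))

# Apply a real gain vector (FFT-grid aligned) to each column of x with
# reflection padding against wrap-around transients, zero-extended to a
# composite FFT length. x: samples x channels.
fftFilterMat <- function(x, gain, pad) {
  x <- as.matrix(x)
  n <- nrow(x)
  nc <- ncol(x)
  pad <- min(pad, n - 1L)
  m <- fftLen(n, pad)
  xp <- matrix(0, m, nc)
  if (pad > 0) {
    xp[seq_len(pad), ] <- x[seq(pad + 1, 2), , drop = FALSE]
    xp[pad + n + seq_len(pad), ] <- x[seq(n - 1, n - pad), , drop = FALSE]
  }
  xp[pad + seq_len(n), ] <- x
  stopifnot(length(gain) == m)
  # pack column pairs into complex series: the gain is real and even on the
  # FFT grid, so filtering maps Re/Im channels independently
  half <- (nc + 1L) %/% 2L
  z <- matrix(0 + 0i, m, half)
  odd <- seq(1L, nc, by = 2L)
  z[, seq_along(odd)] <- xp[, odd, drop = FALSE]
  even <- if (nc >= 2L) seq(2L, nc, by = 2L) else integer(0)
  if (length(even)) {
    z[, seq_along(even)] <- z[, seq_along(even), drop = FALSE] +
      1i * xp[, even, drop = FALSE]
  }
  zf <- stats::mvfft(stats::mvfft(z) * gain, inverse = TRUE) / m
  out <- matrix(0, n, nc)
  sel <- pad + seq_len(n)
  out[, odd] <- Re(zf[sel, seq_along(odd), drop = FALSE])
  if (length(even)) out[, even] <- Im(zf[sel, seq_along(even), drop = FALSE])
  out
}

# Fast covariance of channel-major data (channels x samples), optionally
# restricted to sample indices.
rowCov <- function(X, idx = NULL) {
  if (!is.null(idx)) X <- X[, idx, drop = FALSE]
  Xc <- X - rowMeans(X)
  tcrossprod(Xc) / (ncol(X) - 1)
}

# Zero-phase Butterworth band-pass of columns of x (samples x channels).
bandFilter <- function(x, band, fs, order = 4, pad = NULL) {
  stopifnot(band[1] > 0, band[2] > band[1])
  if (band[2] >= fs / 2) stop("band edge at or above Nyquist (", fs / 2, " Hz)")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  pad <- pad %||% min(nrow(x) - 1L, as.integer(3 * fs))
  pad <- min(pad, nrow(x) - 1L)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  g <- cascadeGain(list(bf), fftLen(nrow(x), pad), fs)
  out <- fftFilterMat(x, g, pad)
  if (vec) drop(out) else out
}

# ---- analytic signal / envelopes --------------------------------------------

# Analytic signal via the FFT (Marple). x: vector or samples x channels
# matrix. Long inputs are reflection-padded to a composite FFT length for
# speed; the Hilbert kernel decays as 1/t, so interior values are unchanged
# to high accuracy and the operation stays linear in x.
analyticSignal <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  pad <- if (n > 4096) min(n - 1L, 2048L) else 0L
  m <- if (pad > 0) fftLen(n, pad) else n
  if (m > n) {
    xp <- matrix(0, m, ncol(x))
    xp[seq_len(pad), ] <- x[seq(pad + 1, 2), , drop = FALSE]
    xp[pad + n + seq_len(pad), ] <- x[seq(n - 1, n - pad), , drop = FALSE]
    xp[pad + seq_len(n), ] <- x
  } else {
    pad <- 0L
    xp <- x
  }
  h <- numeric(m)
  if (m %% 2 == 0) {
    h[c(1, m / 2 + 1)] <- 1
    h[2:(m / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((m + 1) / 2)] <- 2
  }
  a <- stats::mvfft(stats::mvfft(xp) * h, inverse = TRUE) / m
  a <- a[pad + seq_len(n), , drop = FALSE]
  if (vec) drop(a) else a
}

#' Band-limited Hilbert envelope
#'
#' Band-pass filters a signal (zero-phase Butterworth) and returns the
#' magnitude of its analytic signal, i.e. the instantaneous oscillatory
#' amplitude in that band.
#'
#' @param x Numeric vector, or samples-by-channels matrix.
#' @param band Length-2 numeric, band edges in Hz; must lie inside (0, fs/2).
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order of the band-pass (default 4).
#' @return Non-negative envelope with the shape of `x`.
#' @examples
#' fs <- 300; t <- seq(0, 5, by = 1 / fs)
#' env <- hilbertEnvelope(2 * sin(2 * pi * 20 * t), c(13, 30), fs)
#' mean(env[100:1200])  # ~2
#' @export
hilbertEnvelope <- function(x, band, fs, order = 4) {
  stopifnot(length(band) == 2, band[1] > 0)
  if (band[2] >= fs / 2) stop("band edge at or above Nyquist")
  Mod(analyticSignal(bandFilter(x, band, fs, order = order)))
}

# ---- Welch power spectra -----------------------------------------------------

# Mean Welch PSD per column of x in [flo, fhi]; Hann windows, 50% overlap.
# Returns list(freq, psd) with psd frequencies x channels.
welchPSD <- function(x, fs, segDur = 4, overlap = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  seg <- min(n, max(16L, as.integer(round(segDur * fs))))
  step <- max(1L, as.integer(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  u <- sum(win^2)
  nf <- seg %/% 2L + 1L
  acc <- matrix(0, nf, ncol(x))
  for (s in starts) {
    xs <- x[s:(s + seg - 1L), , drop = FALSE]
    xs <- sweep(xs, 2, colMeans(xs)) * win
    p <- Mod(stats::mvfft(xs))^2 / (u * fs)
    acc <- acc + p[seq_len(nf), , drop = FALSE]
  }
  psd <- acc / length(starts)
  if (seg %% 2 == 0) psd[2:(nf - 1), ] <- 2 * psd[2:(nf - 1), ] else psd[2:nf, ] <- 2 * psd[2:nf, ]
  list(freq = (seq_len(nf) - 1) * fs / seg, psd = psd)
}

# ---- DPSS tapers / multitaper PSD -------------------------------------------

dpssCache <- new.env(parent = emptyenv())

# Discrete prolate spheroidal sequences via the symmetric tridiagonal
# eigenproblem (Percival & Walden); n samples, time-bandwidth nw, k tapers.
dpssTapers <- function(n, nw = 4, k = 7) {
  key <- paste(n, nw, k, sep = "_")
  hit <- dpssCache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  tvec <- seq_len(n) - 1
  md <- ((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * w)
  od <- tvec[-1] * (n - tvec[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- md
  A[cbind(seq_len(n - 1), 2:n)] <- od
  A[cbind(2:n, seq_len(n - 1))] <- od
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign convention (positive mean for even tapers,
  # positive initial slope for odd ones)
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if ((j %% 2 == 1 && sum(v[, j]) < 0) ||
        (j %% 2 == 0 && sum((n - 1 - 2 * tvec) * v[, j]) < 0)) v[, j] <- -v[, j]
  }
  dpssCache[[key]] <- v
  v
}

#' Multitaper power spectral density
#'
#' Slepian-taper PSD estimate averaged over sliding windows, optionally with
#' per-window weights (used for HMM state-resolved spectra, where windows are
#' weighted by state occupancy).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param winDur Window duration in seconds (default 2).
#' @param nw Time-bandwidth product (default 4).
#' @param k Number of tapers (default 7).
#' @param weights Optional non-negative per-window weights (length = number of
#'   50%-overlapping windows); `NULL` weights all windows equally.
#' @param fmax Highest frequency to return (Hz).
#' @return List with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
multitaperPSD <- function(x, fs, winDur = 2, nw = 4, k = 7, weights = NULL,
                          fmax = fs / 2) {
  n <- length(x)
  seg <- min(n, as.integer(round(winDur * fs)))
  starts <- mtWindowStarts(n, seg)
  tp <- dpssTapers(seg, nw, k)
  nf <- seg %/% 2L + 1L
  if (is.null(weights)) weights <- rep(1, length(starts))
  stopifnot(length(weights) == length(starts), all(weights >= 0))
  if (sum(weights) <= 0) stop("all multitaper window weights are zero")
  acc <- numeric(nf)
  for (i in seq_along(starts)) {
    if (weights[i] == 0) next
    xs <- x[starts[i]:(starts[i] + seg - 1L)]
    xs <- xs - mean(xs)
    P <- Mod(stats::mvfft(xs * tp))^2 / fs
    acc <- acc + weights[i] * rowMeans(P[seq_len(nf), , drop = FALSE])
  }
  psd <- acc / sum(weights)
  if (seg %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)] else psd[2:nf] <- 2 * psd[2:nf]
  freq <- (seq_len(nf) - 1) * fs / seg
  keep <- freq <= fmax + 1e-9
  list(freq = freq[keep], psd = psd[keep])
}

# 50%-overlapping window start indices.
mtWindowStarts <- function(n, seg) {
  step <- max(1L, seg %/% 2L)
  seq(1L, n - seg + 1L, by = step)
}

# Tukey (tapered cosine) window, taper fraction alpha per side pair.
tukeyWindow <- function(n, alpha = 0.5) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(2 * pi / alpha * (t[lo] - alpha / 2)))
  w[hi] <- 0.5 * (1 + cos(2 * pi / alpha * (t[hi] - 1 + alpha / 2)))
  w
}

# Integer-factor decimation with the 1-48 Hz style band-limit assumed done by
# the caller; falls back to signal::resample for non-integer ratios.
resampleTo <- function(x, fs, targetFs) {
  if (abs(fs - targetFs) < 1e-9) return(x)
  ratio <- fs / targetFs
  if (abs(ratio - round(ratio)) < 1e-9) {
    x[seq(1L, length(x), by = as.integer(round(ratio)))]
  } else {
    signal::resample(x, p = round(targetFs), q = round(fs))
  }
}
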