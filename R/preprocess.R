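#' Detect bad channels
#'
#' Automated stand-in for visual inspection of channel power spectra: flags
#' channels with (near-)zero variance as "flat", and channels whose mean
#' log-PSD over 1-150 Hz (clipped below Nyquist) sits more than `zThreshold`
#' standard deviations above the across-channel mean as "noisy".
#'
#' @param recording [Recording-class] with at least 10 s of data.
#' @param zThreshold z-score threshold (default 3).
#' @return The recording with `channelKeep`/`channelReason` updated and a
#'   `badChannels` provenance entry.
#' @export
detectBadChannels <- function(recording, zThreshold = 3) {
  X <- recording@data
  fs <- recording@fs
  if (ncol(X) < 10 * fs) stop("need at least 10 s of data")
  v <- apply(X, 1, var)
  flat <- v <= 1e-24 | v <= 1e-12 * stats::median(v[v > 0])
  ps <- welchPSD(t(X), fs)
  band <- ps$freq >= 1 & ps$freq <= min(150, 0.48 * fs)
  meanLog <- colMeans(log10(pmax(ps$psd[band, , drop = FALSE], 1e-300)))
  ok <- !flat
  z <- rep(NA_real_, nrow(X))
  if (sum(ok) >= 3 && sd(meanLog[ok]) > 0) {
    z[ok] <- (meanLog[ok] - mean(meanLog[ok])) / sd(meanLog[ok])
  } else {
    z[ok] <- 0
  }
  noisy <- !flat & !is.na(z) & z > zThreshold
  keep <- !(flat | noisy)
  if (!any(keep)) stop("all channels flagged bad; aborting pipeline")
  if (sum(keep) < 3) stop("fewer than 3 channels kept; aborting pipeline")
  reason <- character(0)
  if (any(flat)) reason[recording@sensors@labels[flat]] <- "flat"
  if (any(noisy)) reason[recording@sensors@labels[noisy]] <- "noisy"
  recording@channelKeep <- recording@channelKeep & keep
  recording@channelReason <- c(recording@channelReason, reason)
  recording@provenance$badChannels <- list(
    nFlat = sum(flat), nNoisy = sum(noisy), zThreshold = zThreshold,
    flagged = which(!keep))
  recording
}

#' Notch and band-pass filter a recording
#'
#' Zero-phase filtering: notches at the powerline frequency and two
#' harmonics (Butterworth band-stop, Q = 30) and a Butterworth order-4
#' band-pass. Notches at or above 0.95 x Nyquist are skipped and the upper
#' band edge is clipped to 0.45 * fs when the sampling rate is too low for
#' the requested edge; both adjustments are recorded in provenance.
#'
#' @param recording [Recording-class].
#' @param band Pass band (Hz), default c(1, 150).
#' @param notch Powerline fundamental (Hz), default 50; `notch = 0` disables.
#' @param nHarmonics Number of notch frequencies including the fundamental.
#' @return Filtered recording with a `filters` provenance entry.
#' @export
applyFilters <- function(recording, band = c(1, 150), notch = 50,
                         nHarmonics = 3) {
  fs <- recording@fs
  requested <- band
  if (band[2] >= 0.45 * fs) {
    band[2] <- 0.45 * fs
    warning(sprintf("band edge clipped to %.1f Hz (0.45 * fs)", band[2]))
  }
  filters <- list(signal::butter(4, band / (fs / 2), type = "pass"))
  notched <- numeric(0)
  if (notch > 0) {
    for (h in seq_len(nHarmonics)) {
      f0 <- notch * h
      if (f0 >= 0.95 * fs / 2) next
      bw <- f0 / 30  # Q = 30
      filters <- c(filters, list(
        signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2), type = "stop")))
      notched <- c(notched, f0)
    }
  }
  n <- ncol(recording@data)
  pad <- min(n - 1L, as.integer(3 * fs))
  gain <- cascadeGain(filters, fftLen(n, pad), fs)
  # one transpose in/out; filter channel blocks to bound peak memory
  Xt <- t(recording@data)
  block <- 48L
  for (s in seq(1L, ncol(Xt), by = block)) {
    idx <- s:min(s + block - 1L, ncol(Xt))
    Xt[, idx] <- fftFilterMat(Xt[, idx, drop = FALSE], gain, pad)
  }
  recording@data <- t(Xt)
  recording@provenance$filters <- list(
    requestedBand = requested, band = band, notch = notched, order = 4, q = 30)
  recording
}

#' Homogeneous field correction
#'
#' Projects out the spatially homogeneous field component: with S the
#' channels x 3 matrix of kept-channel orientation vectors, the corrected
#' data are (I - S (S'S)^-1 S') data, so S' data' = 0. This removes
#' interference that is identical (as a field vector) across the array —
#' the dominant residual interference of wearable magnetometer arrays.
#'
#' @param recording [Recording-class] with triaxial orientations.
#' @return Corrected recording with an `hfc` provenance entry.
#' @export
homogeneousFieldCorrection <- function(recording) {
  keep <- recording@channelKeep
  S <- recording@sensors@orientations[keep, , drop = FALSE]
  if (qr(S)$rank < 3) stop("degenerate array: orientation matrix has rank < 3")
  P <- diag(nrow(S)) - S %*% solve(crossprod(S), t(S))
  recording@data[keep, ] <- P %*% recording@data[keep, , drop = FALSE]
  recording@provenance$hfc <- list(nChannels = nrow(S))
  recording
}

#' Epoch a recording around stimulus onsets
#'
#' Cuts one epoch per onset using the half-open sample convention
#' \[start, end): at 300 Hz the default \[-0.5, 3.0) window yields 1050
#' samples. Epochs extending beyond the recording are dropped (logged).
#' Rejected channels are excluded from the channel dimension.
#'
#' @param recording [Recording-class].
#' @param window Epoch window (s) relative to onset, default c(-0.5, 3.0).
#' @return An [EpochSet-class].
#' @export
epochRecording <- function(recording, window = c(-0.5, 3.0)) {
  onsets <- recording@paradigm@onsets
  if (length(onsets) == 0) stop("paradigm has no onsets")
  fs <- recording@fs
  nSamp <- winLen(window[1], window[2], fs)
  n <- ncol(recording@data)
  start <- as.integer(round(onsets * fs + window[1] * fs)) + 1L
  ok <- start >= 1L & (start + nSamp - 1L) <= n
  if (!any(ok)) stop("no complete epochs inside the recording")
  if (any(!ok)) {
    opmMsg(sum(!ok), " partial epoch(s) at the recording edges dropped")
  }
  keepCh <- recording@channelKeep
  nTr <- sum(ok)
  E <- array(0, c(nTr, sum(keepCh), nSamp))
  ii <- which(ok)
  for (k in seq_len(nTr)) {
    sel <- start[ii[k]]:(start[ii[k]] + nSamp - 1L)
    E[k, , ] <- recording@data[keepCh, sel, drop = FALSE]
  }
  new("EpochSet", data = E, fs = fs, window = window,
      time = window[1] + (seq_len(nSamp) - 1) / fs,
      fingers = recording@paradigm@fingers[ii],
      trialKeep = rep(TRUE, nTr),
      channelLabels = recording@sensors@labels[keepCh],
      onsets = onsets[ii])
}

#' Reject high-variance trials
#'
#' Single-pass automatic rejection: per-trial variance pooled over kept
#' channels; trials whose variance strictly exceeds mean + 3 SD (sample SD)
#' are masked out. Warns (but continues) when more than half the trials are
#' rejected.
#'
#' @param epochs [EpochSet-class] with at least 5 trials.
#' @param nSd SD multiplier (default 3).
#' @return The epoch set with `trialKeep` updated.
#' @export
rejectHighVarianceTrials <- function(epochs, nSd = 3) {
  d <- dim(epochs@data)
  if (d[1] < 5) stop("need at least 5 trials")
  v <- apply(epochs@data, 1, function(tr) mean(apply(tr, 1, var)))
  thr <- mean(v) + nSd * sd(v)
  bad <- v > thr  # strict: "exceeding"
  if (mean(bad) > 0.5) warning("more than 50% of trials rejected")
  epochs@trialKeep <- epochs@trialKeep & !bad
  attr(epochs, "trialVariance") <- v
  epochs
}

#' Run the full preprocessing chain
#'
#' Bad-channel detection, filtering, homogeneous field correction, epoching
#' and high-variance trial rejection, in the study's order.
#'
#' @param recording [Recording-class].
#' @param band Pass band (Hz).
#' @param notch Powerline frequency (Hz).
#' @param window Epoch window (s).
#' @param zThreshold Bad-channel z threshold.
#' @param varSd Trial-rejection SD multiplier.
#' @return List with the cleaned `recording` and the masked `epochs`.
#' @export
preprocess <- function(recording, band = c(1, 150), notch = 50,
                       window = c(-0.5, 3.0), zThreshold = 3, varSd = 3) {
  rec <- detectBadChannels(recording, zThreshold)
  rec <- suppressWarnings(applyFilters(rec, band = band, notch = notch))
  rec <- homogeneousFieldCorrection(rec)
  ep <- epochRecording(rec, window)
  ep <- rejectHighVarianceTrials(ep, varSd)
  list(recording = rec, epochs = ep)
}
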