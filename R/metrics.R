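#' Time-frequency spectrogram of a virtual electrode
#'
#' Hilbert-envelope TFS: the VE is filtered into a set of overlapping bands
#' (default 4 Hz wide, centres every 1 Hz from 3 to 46 Hz), the amplitude
#' envelope of each band is averaged across kept trials, and each band trace
#' is expressed as fractional change from its baseline-window mean, so the
#' baseline mean of every band is zero by construction.
#'
#' @param ve [VirtualElectrode-class].
#' @param centres Band centres (Hz).
#' @param halfWidth Band half-width (Hz, default 2).
#' @param window Epoch window (s).
#' @param baseline Baseline window (s), default c(2.5, 3.0).
#' @return List with `tfs` (bands x samples fractional change), `time`,
#'   `centres`, `baseline`.
#' @export
computeTFS <- function(ve, centres = 3:46, halfWidth = 2,
                       window = c(-0.5, 3.0), baseline = c(2.5, 3.0)) {
  if (length(centres) < 2) stop("need at least 2 bands")
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    stop("baseline must lie inside the epoch window")
  }
  fs <- ve@fs
  out <- NULL
  for (i in seq_along(centres)) {
    band <- c(max(centres[i] - halfWidth, 0.5), centres[i] + halfWidth)
    env <- hilbertEnvelope(ve@signal, band, fs)
    ep <- veEpochs(ve, window, signal = env)
    tr <- colMeans(ep$data)
    if (is.null(out)) {
      out <- matrix(0, length(centres), length(tr))
      time <- ep$time
    }
    b <- mean(tr[winIdx(ep$time, baseline[1], baseline[2])])
    if (b <= 0) stop("zero baseline mean in band ", centres[i], " Hz")
    out[i, ] <- (tr - b) / b
  }
  list(tfs = out, time = time, centres = centres, baseline = baseline)
}

#' Beta modulation index from window means
#'
#' The scalar index betamod = (betaPost - betaStim) / betaBaseline, where
#' the three terms are mean trial-averaged beta-envelope amplitudes in the
#' stimulus, post-stimulus and baseline windows.
#'
#' @param betaStim,betaPost,betaBaseline Window means (betaBaseline > 0).
#' @return The modulation index.
#' @examples
#' betaModIndex(0.5, 1.5, 1.0)  # 1
#' @export
betaModIndex <- function(betaStim, betaPost, betaBaseline) {
  if (betaBaseline <= 0) stop("betaBaseline must be positive")
  (betaPost - betaStim) / betaBaseline
}

#' Beta modulation index of a virtual electrode
#'
#' Trial-averaged 13-30 Hz Hilbert envelope, summarized over the stimulus
#' (0.3-0.8 s), post-stimulus (1-1.5 s) and baseline (2.5-3 s) windows.
#' Scale-invariant: rescaling the VE leaves the index unchanged.
#'
#' @param ve [VirtualElectrode-class].
#' @param band Beta band (Hz).
#' @param windowStim,windowPost,windowBaseline Analysis windows (s).
#' @param window Epoch window (s) containing all three.
#' @return List with `betamod`, `betaStim`, `betaPost`, `betaBaseline` and
#'   the trial-averaged envelope trace (`envelope`, `time`).
#' @export
betaModulationIndex <- function(ve, band = c(13, 30),
                                windowStim = c(0.3, 0.8),
                                windowPost = c(1.0, 1.5),
                                windowBaseline = c(2.5, 3.0),
                                window = c(-0.5, 3.0)) {
  for (w in list(windowStim, windowPost, windowBaseline)) {
    if (w[1] < window[1] || w[2] > window[2]) {
      stop("analysis window outside the epoch window")
    }
  }
  env <- hilbertEnvelope(ve@signal, band, ve@fs)
  ep <- veEpochs(ve, window, signal = env)
  tr <- colMeans(ep$data)
  bS <- mean(tr[winIdx(ep$time, windowStim[1], windowStim[2])])
  bP <- mean(tr[winIdx(ep$time, windowPost[1], windowPost[2])])
  bB <- mean(tr[winIdx(ep$time, windowBaseline[1], windowBaseline[2])])
  list(betamod = betaModIndex(bS, bP, bB), betaStim = bS, betaPost = bP,
       betaBaseline = bB, envelope = tr, time = ep$time)
}

#' Evoked response and M50 amplitude
#'
#' Trial average of the 4-40 Hz virtual electrode; the M50 is the signed
#' value of the average at the sample nearest 50 ms post stimulus (no peak
#' search by default; a peak-in-window variant is available).
#'
#' @param ve [VirtualElectrode-class].
#' @param band Evoked band (Hz), default c(4, 40).
#' @param window Epoch window (s).
#' @param at Read-out latency (s), default 0.050.
#' @param peakWindow When not `NULL` (e.g. c(0.03, 0.07)), return the
#'   largest-magnitude value in that window instead of the fixed latency.
#' @return List with `m50`, `evoked` (trial average), `time`, `nTrials`.
#' @export
evokedM50 <- function(ve, band = c(4, 40), window = c(-0.5, 3.0), at = 0.050,
                      peakWindow = NULL) {
  if (window[2] < at) stop("epoch ends before the read-out latency")
  sig <- bandFilter(ve@signal, band, ve@fs)
  ep <- veEpochs(ve, window, signal = sig)
  if (nrow(ep$data) < 2) stop("need at least 2 trials")
  evoked <- colMeans(ep$data)
  if (is.null(peakWindow)) {
    m50 <- evoked[which.min(abs(ep$time - at))]
  } else {
    sel <- winIdx(ep$time, peakWindow[1], peakWindow[2])
    m50 <- evoked[sel][which.max(abs(evoked[sel]))]
  }
  list(m50 = m50, evoked = evoked, time = ep$time, nTrials = nrow(ep$data))
}
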