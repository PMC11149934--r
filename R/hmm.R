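#' Time-delay embedding of a virtual electrode
#'
#' Prepares the 1-48 Hz source signal for the embedded HMM: band-pass at the
#' original rate (the 1-48 Hz filter doubles as the anti-alias filter),
#' resample to `targetFs`, standardize to unit variance, and build the lag
#' matrix with `lags` samples each side (row t holds x\[t-l .. t+l\]; edge
#' rows are dropped).
#'
#' @param ve [VirtualElectrode-class] or numeric vector.
#' @param fs Sampling rate of a numeric input (ignored for a VE).
#' @param lags Lags each side (default 7, i.e. +-70 ms at 100 Hz).
#' @param targetFs Embedded sampling rate (Hz, >= 96 for the 48 Hz edge).
#' @param band Band (Hz), default c(1, 48).
#' @return List with `X` (rows x (2*lags+1) lag matrix), `signal` (the
#'   band-limited resampled series, unstandardized), `time` (s, aligned to
#'   the rows of `X`), `fs`, `lags`, `onsets`, `fingers`.
#' @export
tdeEmbed <- function(ve, fs = NULL, lags = 7, targetFs = 100,
                     band = c(1, 48)) {
  if (is(ve, "VirtualElectrode")) {
    x <- ve@signal
    fs <- ve@fs
    onsets <- ve@onsets
    fingers <- ve@fingers
  } else {
    x <- as.numeric(ve)
    if (is.null(fs)) stop("fs required for a numeric input")
    onsets <- numeric(0)
    fingers <- character(0)
  }
  if (targetFs < 2 * band[2]) stop("targetFs must be at least twice the band edge")
  if (band[2] >= fs / 2) stop("band edge at or above Nyquist of the input")
  xb <- bandFilter(x, band, fs)
  xr <- resampleTo(xb, fs, targetFs)
  n <- length(xr)
  if (n < 2 * lags + 1) stop("series shorter than the embedding window")
  sdx <- sd(xr)
  if (sd(x) <= 1e-12 * max(abs(x), 1e-300) ||
      sdx <= 1e-10 * max(abs(x), 1e-300)) {
    stop("zero-variance series cannot be embedded")
  }
  xs <- xr / sdx
  rows <- (lags + 1):(n - lags)
  X <- vapply(-lags:lags, function(l) xs[rows + l], numeric(length(rows)))
  X <- matrix(X, nrow = length(rows))
  list(X = X, signal = xr, time = (rows - 1) / targetFs, fs = targetFs,
       lags = as.integer(lags), onsets = onsets, fingers = fingers)
}

# Log-density of zero-mean Gaussians per state; X: n x d, covs: d x d x K.
gaussLogB <- function(X, covs) {
  n <- nrow(X)
  d <- ncol(X)
  K <- dim(covs)[3]
  logB <- matrix(0, n, K)
  for (k in seq_len(K)) {
    R <- chol(covs[, , k])
    Z <- X %*% backsolve(R, diag(d))
    logB[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                           rowSums(Z^2))
  }
  logB
}

#' Forward-backward posteriors
#'
#' Scaled forward-backward recursion for a hidden Markov chain given log
#' observation densities, a transition matrix and an initial distribution.
#'
#' @param logB n x K matrix of log observation densities.
#' @param A K x K transition matrix (rows sum to 1).
#' @param initProb Initial state distribution.
#' @return List with `gamma` (n x K posteriors), `xiSum` (summed two-slice
#'   marginals) and `logLik`.
#' @export
forwardBackward <- function(logB, A, initProb) {
  forwardBackwardC(as.matrix(logB), as.matrix(A), as.numeric(initProb))
}

#' Fit a time-delay-embedded Gaussian HMM
#'
#' Baum-Welch EM for a K-state HMM with zero-mean Gaussian observation
#' models over the embedded space (states are distinguished by their
#' lag-space covariance, i.e. by their spectral signature). The best of
#' `nRestarts` random initializations by final log-likelihood is returned;
#' the log-likelihood trace is non-decreasing within every restart.
#'
#' @param X Embedded data matrix (rows x dims), e.g. `tdeEmbed()$X`.
#' @param K Number of states (default 3).
#' @param nRestarts Random restarts (default 5).
#' @param seed Optional integer master seed; restart seeds derive from it.
#' @param maxIter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-6).
#' @param fs Sampling rate of the embedded rows (stored in the fit).
#' @param lags Lags used for the embedding (stored in the fit).
#' @return A [TdeHmm-class].
#' @export
fitHmm <- function(X, K = 3, nRestarts = 5, seed = NULL, maxIter = 500,
                   tol = 1e-6, fs = 100, lags = 7L) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 50 * K) stop("need at least 50 rows per state")
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- withSeed(childSeed(seed, r), emRun(X, K, maxIter, tol))
    if (is.null(best) || tail(fit$logLik, 1) > tail(best$logLik, 1)) best <- fit
  }
  new("TdeHmm", K = as.integer(K), initProb = best$initProb,
      transMat = best$A, covs = best$covs, gamma = best$gamma,
      logLik = best$logLik, lags = as.integer(lags), fs = fs,
      converged = best$converged)
}

# One EM run from a random initialization.
emRun <- function(X, K, maxIter, tol) {
  n <- nrow(X)
  d <- ncol(X)
  # random soft assignment -> initial covariances
  G <- matrix(rexp(n * K), n, K)
  G <- G / rowSums(G)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) covs[, , k] <- wcov(X, G[, k])
  A <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  pi0 <- rep(1 / K, K)
  llTrace <- numeric(0)
  converged <- FALSE
  gamma <- G
  for (it in seq_len(maxIter)) {
    logB <- gaussLogB(X, covs)
    fb <- forwardBackwardC(logB, A, pi0)
    gamma <- fb$gamma
    llTrace <- c(llTrace, fb$logLik)
    if (it > 1 && abs(diff(tail(llTrace, 2))) <
        tol * abs(tail(llTrace, 1))) {
      converged <- TRUE
      break
    }
    xs <- fb$xiSum
    A <- xs / pmax(rowSums(xs), 1e-300)
    pi0 <- pmax(gamma[1, ], 1e-12)
    pi0 <- pi0 / sum(pi0)
    for (k in seq_len(K)) covs[, , k] <- wcov(X, gamma[, k])
  }
  list(initProb = pi0, A = A, covs = covs, gamma = gamma, logLik = llTrace,
       converged = converged)
}

# Weighted zero-mean covariance with diagonal loading against collapse.
wcov <- function(X, w) {
  sw <- sum(w)
  if (sw <= 1e-10) {
    opmMsg("state occupancy collapsed; reinitializing with diagonal loading")
    return(diag(ncol(X)))
  }
  C <- crossprod(X * sqrt(w / sw))
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  if (!ok) {
    opmMsg("covariance collapse; applying diagonal loading")
    C <- C + 1e-6 * mean(diag(C)) * diag(ncol(X))
  }
  C
}

#' Binarize HMM posteriors
#'
#' A state is "on" at a sample iff its posterior strictly exceeds the
#' threshold (2/3 by default); with normalized posteriors at most one state
#' can be on, and a row at exactly the threshold maps to all-off.
#'
#' @param gamma time x K posteriors.
#' @param threshold Default 2/3.
#' @return time x K binary (0/1) matrix.
#' @export
binarizeStates <- function(gamma, threshold = 2 / 3) {
  (gamma > threshold) + 0
}

# Per-trial occupancy of one binary state time course in a window.
windowOccupancy <- function(binary, time, onsets, window) {
  occ <- vapply(onsets, function(on) {
    sel <- which(time >= on + window[1] - 1e-9 & time < on + window[2] - 1e-9)
    if (length(sel) == 0) return(NA_real_)
    mean(binary[sel])
  }, numeric(1))
  occ[!is.na(occ)]
}

#' Select the task-modulated burst state
#'
#' For each state, the absolute difference between mean occupancy in the
#' post-stimulus (1.0-1.5 s) and stimulus (0.3-0.8 s) windows across trials;
#' the state with the largest modulation is the burst state. When `signal`
#' is supplied, candidates are first restricted to burst-like states —
#' states whose mean envelope amplitude during visits exceeds the overall
#' mean — because a burst is by definition a high-amplitude transient; the
#' quiescent-background state carries the complementary (sign-flipped)
#' occupancy modulation and would otherwise be selected whenever the burst
#' class is split across states. Ties break to the lowest index; when the
#' winning modulation is below `weakThreshold` a "weak modulation" warning
#' is issued.
#'
#' @param binary time x K binary matrix from [binarizeStates()].
#' @param time Time axis (s) of the binary rows.
#' @param onsets Kept-trial onsets (s), at least 10.
#' @param windowStim,windowPost Comparison windows (s).
#' @param weakThreshold Warning threshold on the winning modulation.
#' @param signal Optional band-limited source signal aligned with the rows
#'   of `binary`, used for the amplitude restriction.
#' @return List with `state` (index), `modulation` (per state),
#'   `amplitude` (per-state mean visit envelope, when `signal` given) and
#'   `weak`.
#' @export
selectBurstState <- function(binary, time, onsets,
                             windowStim = c(0.3, 0.8),
                             windowPost = c(1.0, 1.5),
                             weakThreshold = 0.02, signal = NULL) {
  if (length(onsets) < 10) stop("need at least 10 trials")
  K <- ncol(binary)
  mod <- vapply(seq_len(K), function(k) {
    abs(mean(windowOccupancy(binary[, k], time, onsets, windowPost)) -
          mean(windowOccupancy(binary[, k], time, onsets, windowStim)))
  }, numeric(1))
  amp <- rep(NA_real_, K)
  candidates <- rep(TRUE, K)
  if (!is.null(signal)) {
    n <- min(length(signal), nrow(binary))
    env <- Mod(analyticSignal(signal[seq_len(n)]))
    amp <- vapply(seq_len(K), function(k) {
      on <- binary[seq_len(n), k] > 0
      if (!any(on)) return(0)
      mean(env[on])
    }, numeric(1))
    candidates <- amp > mean(env)
    if (!any(candidates)) candidates <- rep(TRUE, K)
  }
  modC <- ifelse(candidates, mod, -Inf)
  state <- which.max(modC)  # ties break to the lowest index
  weak <- mod[state] < weakThreshold
  if (weak) warning("weak modulation: no state modulates with the task")
  list(state = state, modulation = mod, amplitude = amp, weak = weak)
}

#' Trial-averaged burst probability and its modulation
#'
#' P(t) is the fraction of trials with the burst state on at epoch time t;
#' the modulation is deltaP = mean P in \[1.0, 1.5) minus mean P in
#' \[0.3, 0.8).
#'
#' @param binaryBurst Binary burst-state time course.
#' @param time Time axis (s) of the samples.
#' @param onsets Kept-trial onsets (s).
#' @param window Epoch window (s).
#' @param windowStim,windowPost Modulation windows (s).
#' @param fs Sampling rate (Hz) of the binary series.
#' @return List with `P`, `time` (epoch axis), `deltaP`.
#' @export
burstProbability <- function(binaryBurst, time, onsets, fs,
                             window = c(-0.5, 3.0),
                             windowStim = c(0.3, 0.8),
                             windowPost = c(1.0, 1.5)) {
  nSamp <- winLen(window[1], window[2], fs)
  t0 <- time[1]
  rows <- lapply(onsets, function(on) {
    s0 <- as.integer(round((on + window[1] - t0) * fs)) + 1L
    if (s0 < 1L || s0 + nSamp - 1L > length(binaryBurst)) return(NULL)
    binaryBurst[s0:(s0 + nSamp - 1L)]
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows)) stop("no complete epochs for burst probability")
  P <- colMeans(rows)
  et <- window[1] + (seq_len(nSamp) - 1) / fs
  dP <- mean(P[winIdx(et, windowPost[1], windowPost[2])]) -
    mean(P[winIdx(et, windowStim[1], windowStim[2])])
  list(P = P, time = et, deltaP = dP, raster = rows)
}

#' State-resolved multitaper spectra
#'
#' Occupancy-weighted multitaper PSD per HMM state: sliding 2 s windows
#' (time-bandwidth 4, 7 tapers, 50% overlap) are weighted by the mean
#' posterior of the state within each window. States occupied for less than
#' `minOccupancy` seconds in total get an all-NA column (flagged).
#'
#' @param signal The 1-48 Hz band-limited series at the embedded rate,
#'   aligned with `gamma` rows (e.g. `tdeEmbed()$signal` trimmed by `lags`).
#' @param gamma time x K posteriors.
#' @param fs Sampling rate (Hz).
#' @param fmax Highest frequency (Hz), default 48.
#' @param winDur,nw,k Multitaper parameters.
#' @param minOccupancy Minimum total occupancy (s) for a defined PSD.
#' @return List with `freq` and `psd` (frequencies x K).
#' @export
stateSpectra <- function(signal, gamma, fs, fmax = 48, winDur = 2, nw = 4,
                         k = 7, minOccupancy = 1) {
  n <- min(length(signal), nrow(gamma))
  signal <- signal[seq_len(n)]
  gamma <- gamma[seq_len(n), , drop = FALSE]
  seg <- as.integer(round(winDur * fs))
  starts <- mtWindowStarts(n, seg)
  K <- ncol(gamma)
  psd <- NULL
  for (kk in seq_len(K)) {
    w <- vapply(starts, function(s) mean(gamma[s:(s + seg - 1L), kk]),
                numeric(1))
    if (sum(gamma[, kk]) / fs < minOccupancy || sum(w) <= 0) {
      est <- NULL
    } else {
      est <- multitaperPSD(signal, fs, winDur = winDur, nw = nw, k = k,
                           weights = w, fmax = fmax)
    }
    if (is.null(psd)) {
      freq <- if (is.null(est)) multitaperPSD(signal, fs, winDur = winDur,
                                              fmax = fmax)$freq else est$freq
      psd <- matrix(NA_real_, length(freq), K)
    }
    if (!is.null(est)) psd[, kk] <- est$psd
  }
  list(freq = freq, psd = psd)
}

#' Mean burst amplitude
#'
#' Mean magnitude of the 1-48 Hz analytic signal over burst-on samples.
#'
#' @param signal Band-limited (1-48 Hz) series.
#' @param binaryBurst Binary burst-state time course aligned with `signal`.
#' @return Scalar amplitude; `NA` with a warning when occupancy is zero.
#' @export
burstAmplitude <- function(signal, binaryBurst) {
  n <- min(length(signal), length(binaryBurst))
  on <- which(binaryBurst[seq_len(n)] > 0)
  if (length(on) == 0) {
    warning("zero burst occupancy: amplitude undefined")
    return(NA_real_)
  }
  env <- Mod(analyticSignal(signal[seq_len(n)]))
  mean(env[on])
}

#' Full burst analysis of a virtual electrode
#'
#' Convenience chain: time-delay embedding, K-state HMM fit, binarization,
#' burst-state selection, burst probability modulation, state spectra and
#' burst amplitude.
#'
#' @param ve [VirtualElectrode-class].
#' @param K States (default 3).
#' @param lags Embedding lags each side (default 7).
#' @param targetFs Embedded rate (Hz, default 100).
#' @param nRestarts EM restarts.
#' @param seed Optional integer seed.
#' @param window Epoch window (s).
#' @param maxIter,tol EM controls.
#' @return A [BurstResult-class]; the fitted [TdeHmm-class] is attached as
#'   attribute `"hmm"`.
#' @export
burstAnalysis <- function(ve, K = 3, lags = 7, targetFs = 100,
                          nRestarts = 5, seed = NULL, window = c(-0.5, 3.0),
                          maxIter = 500, tol = 1e-6) {
  emb <- tdeEmbed(ve, lags = lags, targetFs = targetFs)
  hmm <- fitHmm(emb$X, K = K, nRestarts = nRestarts, seed = seed,
                maxIter = maxIter, tol = tol, fs = emb$fs,
                lags = emb$lags)
  binary <- binarizeStates(hmm@gamma)
  sigAligned <- emb$signal[emb$lags + seq_len(nrow(binary))]
  sel <- withCallingHandlers(
    selectBurstState(binary, emb$time, emb$onsets, signal = sigAligned),
    warning = function(w) invokeRestart("muffleWarning"))
  bp <- burstProbability(binary[, sel$state], emb$time, emb$onsets, emb$fs,
                         window = window)
  sp <- stateSpectra(sigAligned, hmm@gamma, emb$fs)
  amp <- burstAmplitude(sigAligned, binary[, sel$state])
  res <- new("BurstResult", binary = binary,
             burstState = as.integer(sel$state), P = bp$P, time = bp$time,
             deltaP = bp$deltaP, amplitude = amp, psd = sp$psd,
             psdFreq = sp$freq, fs = emb$fs,
             weakModulation = sel$weak)
  attr(res, "hmm") <- hmm
  attr(res, "raster") <- bp$raster
  res
}
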