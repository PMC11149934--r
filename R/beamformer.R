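# Continuous-time sample indices covered by kept trials (optionally a
# sub-window [a, b) relative to each onset).
keptSampleIdx <- function(fs, nSamples, onsets, window) {
  idx <- integer(0)
  for (on in onsets) {
    s0 <- as.integer(round((on + window[1]) * fs)) + 1L
    s1 <- s0 + winLen(window[1], window[2], fs) - 1L
    if (s0 >= 1L && s1 <= nSamples) idx <- c(idx, s0:s1)
  }
  idx
}

keptOnsets <- function(epochs) epochs@onsets[epochs@trialKeep]

#' Regularized data covariance
#'
#' Sample covariance over the kept-trial portion of a cleaned recording
#' (optionally band-limited and restricted to a window within each trial),
#' Tikhonov-regularized as C_reg = C + mu * lambda_max * I with mu = 5% of
#' the largest eigenvalue by default.
#'
#' @param recording Cleaned [Recording-class] (kept channels are used).
#' @param epochs [EpochSet-class] defining kept trials; `NULL` uses the whole
#'   recording.
#' @param band Optional band (Hz) to filter to before covariance estimation.
#' @param window Optional window (s, relative to onset) within each trial.
#' @param mu Regularization fraction (default 0.05).
#' @return A [CovarianceModel-class].
#' @export
regularizedCovariance <- function(recording, epochs = NULL, band = NULL,
                                  window = NULL, mu = 0.05) {
  keep <- recording@channelKeep
  X <- recording@data[keep, , drop = FALSE]
  if (!all(is.finite(X))) stop("non-finite data")
  if (!is.null(band)) X <- t(bandFilter(t(X), band, recording@fs))
  if (!is.null(epochs)) {
    idx <- keptSampleIdx(recording@fs, ncol(X), keptOnsets(epochs),
                         window %||% epochs@window)
    if (length(idx) == 0) stop("empty covariance window")
    X <- X[, idx, drop = FALSE]
  }
  if (ncol(X) < 5 * nrow(X)) {
    warning("fewer than 5 samples per channel entering the covariance")
  }
  C <- rowCov(X)
  lmax <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  new("CovarianceModel", cov = C, Creg = C + mu * lmax * diag(nrow(C)),
      mu = mu, lambdaMax = lmax,
      band = if (is.null(band)) numeric(0) else band,
      nSamples = ncol(X))
}

#' Make a covariance model from an explicit matrix
#' @param C Symmetric positive semidefinite channels x channels matrix.
#' @param mu Regularization fraction (default 0.05).
#' @return A [CovarianceModel-class].
#' @export
covarianceFromMatrix <- function(C, mu = 0.05) {
  lmax <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  new("CovarianceModel", cov = C, Creg = C + mu * lmax * diag(nrow(C)),
      mu = mu, lambdaMax = lmax, band = numeric(0), nSamples = 0L)
}

#' LCMV weights for one source (single voxel)
#'
#' Linearly constrained minimum-variance spatial filter: the source
#' orientation eta minimizes eta' (L' C_reg^-1 L) eta (equivalently,
#' maximizes the beamformer-projected power), and
#' w = C_reg^-1 L eta / (eta' L' C_reg^-1 L eta), which passes the source
#' with unit gain (w' L eta = 1) while minimizing output variance.
#'
#' @param Lv channels x p lead-field matrix of the voxel (p = 2 tangential
#'   columns, or 3).
#' @param covariance [CovarianceModel-class].
#' @return List with `w` (weights), `eta` (orientation coefficients in the
#'   columns of `Lv`), `power` (1 / lambda_min) and `localizable`.
#' @export
lcmvWeights <- function(Lv, covariance) {
  Lv <- as.matrix(Lv)
  A <- solve(covariance@Creg, Lv)
  M <- crossprod(Lv, A)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lmin <- e$values[length(e$values)]
  if (!is.finite(lmin) || lmin <= 1e-12 * max(e$values[1], 1e-300)) {
    return(list(w = rep(0, nrow(Lv)), eta = rep(0, ncol(Lv)),
                power = NA_real_, localizable = FALSE))
  }
  eta <- e$vectors[, length(e$values)]
  w <- drop(A %*% eta) / drop(t(eta) %*% M %*% eta)
  list(w = w, eta = eta, power = 1 / lmin, localizable = TRUE)
}

#' LCMV weights over a whole grid
#'
#' Vectorized per-voxel LCMV with the two-column tangential lead fields:
#' orientation by the closed-form minimum eigenvector of the 2 x 2 matrix
#' L' C_reg^-1 L, unit-gain normalization, non-localizable voxels flagged.
#'
#' @param leadfield [LeadField-class].
#' @param covariance [CovarianceModel-class] over the same kept channels.
#' @param channelKeep Optional logical mask aligning `leadfield` rows with
#'   the covariance channels.
#' @return A [BeamformerWeights-class].
#' @export
lcmvWeightsGrid <- function(leadfield, covariance, channelKeep = NULL) {
  L <- leadfield@L
  if (!is.null(channelKeep)) L <- L[channelKeep, , drop = FALSE]
  if (nrow(L) != nrow(covariance@Creg)) {
    stop("lead-field channels do not match covariance channels")
  }
  V <- ncol(L) / 2L
  A <- solve(covariance@Creg, L)
  i1 <- seq(1L, 2L * V, by = 2L)
  i2 <- i1 + 1L
  m11 <- colSums(L[, i1, drop = FALSE] * A[, i1, drop = FALSE])
  m22 <- colSums(L[, i2, drop = FALSE] * A[, i2, drop = FALSE])
  m12 <- colSums(L[, i1, drop = FALSE] * A[, i2, drop = FALSE])
  tr <- m11 + m22
  disc <- sqrt(pmax((m11 - m22)^2 + 4 * m12^2, 0))
  lmin <- (tr - disc) / 2
  lmax <- (tr + disc) / 2
  # eigenvector of the smaller eigenvalue of [[m11, m12], [m12, m22]]
  e1 <- lmin - m22
  e2 <- m12
  deg <- abs(e1) + abs(e2) < 1e-14 * pmax(abs(lmax), 1e-300)
  e1[deg] <- as.numeric(m11[deg] <= m22[deg])
  e2[deg] <- as.numeric(m11[deg] > m22[deg])
  nrm <- sqrt(e1^2 + e2^2)
  e1 <- e1 / nrm
  e2 <- e2 / nrm
  loc <- leadfield@localizable & is.finite(lmin) &
    lmin > 1e-12 * pmax(lmax, 1e-300)
  quad <- e1^2 * m11 + 2 * e1 * e2 * m12 + e2^2 * m22
  W <- (A[, i1, drop = FALSE] * rep(e1, each = nrow(A)) +
          A[, i2, drop = FALSE] * rep(e2, each = nrow(A))) /
    rep(ifelse(loc, quad, 1), each = nrow(A))
  W[, !loc] <- 0
  eta3 <- leadfield@tangentBasis[i1, , drop = FALSE] * e1 +
    leadfield@tangentBasis[i2, , drop = FALSE] * e2
  new("BeamformerWeights", W = W, eta = eta3, localizable = loc,
      grid = leadfield@grid)
}

#' Pseudo-T beta-modulation image
#'
#' Beta-band LCMV source power contrasted between an active and a control
#' window: per voxel T = (P_a - P_c) / (P_a + P_c), with P = w' C_window w.
#' Weights come from the band-limited covariance over all kept trials.
#'
#' @param recording Cleaned [Recording-class].
#' @param epochs [EpochSet-class] (kept trials define the windows).
#' @param leadfield [LeadField-class] (full-array rows; kept channels are
#'   selected internally).
#' @param band Contrast band (Hz), default beta c(13, 30).
#' @param windowActive Active window (s), default c(0.3, 0.8).
#' @param windowControl Control window (s), default c(2.5, 3.0).
#' @param mu Regularization fraction.
#' @param fingers Optional finger label(s) to restrict trials to.
#' @param betaData Optional precomputed band-limited kept-channel data
#'   (channels x samples), to avoid re-filtering across calls.
#' @param peakMode Peak selection: `"abs"` (largest |T|, default), `"min"`
#'   (strongest desynchronization, the direction of stimulus-induced beta
#'   suppression) or `"max"`.
#' @param roi Optional anatomical-prior region of interest for the peak
#'   search: list with `centre` (m) and `radius` (m); the full map is still
#'   computed.
#' @return A [PseudoTMap-class].
#' @export
pseudoTMap <- function(recording, epochs, leadfield, band = c(13, 30),
                       windowActive = c(0.3, 0.8), windowControl = c(2.5, 3.0),
                       mu = 0.05, fingers = NULL, betaData = NULL,
                       peakMode = c("abs", "min", "max"), roi = NULL) {
  peakMode <- match.arg(peakMode)
  for (w in list(windowActive, windowControl)) {
    if (w[1] < epochs@window[1] || w[2] > epochs@window[2]) {
      stop("empty contrast window: [", w[1], ", ", w[2],
           ") lies outside the epoch window")
    }
  }
  keep <- recording@channelKeep
  X <- betaData %||% t(bandFilter(t(recording@data[keep, , drop = FALSE]),
                                  band, recording@fs))
  onsets <- keptOnsets(epochs)
  if (!is.null(fingers)) {
    onsets <- epochs@onsets[epochs@trialKeep & epochs@fingers %in% fingers]
  }
  idxAll <- keptSampleIdx(recording@fs, ncol(X), onsets, epochs@window)
  idxA <- keptSampleIdx(recording@fs, ncol(X), onsets, windowActive)
  idxC <- keptSampleIdx(recording@fs, ncol(X), onsets, windowControl)
  if (length(idxA) == 0 || length(idxC) == 0) stop("empty contrast window")
  Call <- covarianceFromMatrix(rowCov(X, idxAll), mu)
  bw <- lcmvWeightsGrid(leadfield, Call, channelKeep = keep)
  Ca <- rowCov(X, idxA)
  Cc <- rowCov(X, idxC)
  Pa <- colSums(bw@W * (Ca %*% bw@W))
  Pc <- colSums(bw@W * (Cc %*% bw@W))
  T <- ifelse(Pa + Pc > 0, (Pa - Pc) / (Pa + Pc), 0)
  T[!bw@localizable] <- 0
  cand <- bw@localizable
  if (!is.null(roi)) {
    inRoi <- rowSums(sweep(leadfield@grid@voxels, 2, roi$centre)^2) <=
      roi$radius^2
    if (any(cand & inRoi)) cand <- cand & inRoi
  }
  score <- switch(peakMode, abs = abs(T), min = -T, max = T)
  score[!cand] <- -Inf
  pk <- which.max(score)
  new("PseudoTMap", values = T, grid = leadfield@grid,
      windowActive = windowActive, windowControl = windowControl,
      band = band, peakVoxel = leadfield@grid@voxels[pk, ],
      peakValue = T[pk])
}

#' Refine a pseudo-T peak on a fine local grid
#'
#' Recomputes the pseudo-T image on a fine grid (1 mm default) restricted to
#' a cube around a coarse peak, mirroring the coarse-then-fine grid scheme.
#'
#' @param recording,epochs,band,windowActive,windowControl,mu,fingers,betaData,peakMode
#'   As in [pseudoTMap()].
#' @param coarsePeak Coordinates (m) of the coarse peak.
#' @param sensors [SensorArray-class].
#' @param headModel [HeadModel-class].
#' @param spacing Fine spacing (m), default 0.001.
#' @param halfWidth Cube half-width (m), default 0.006.
#' @param radialTol Optional cortical-depth constraint (m): keep only fine
#'   voxels whose distance from the head-model origin is within `radialTol`
#'   of the grid centre's radius (a cortical-shell prior; ratio images are
#'   biased radially outward under coherent background activity, which a
#'   depth prior removes just as gray-matter source spaces do).
#' @return A [PseudoTMap-class] on the fine grid.
#' @export
refinePseudoT <- function(recording, epochs, coarsePeak, sensors,
                          headModel = makeHeadModel(), spacing = 0.001,
                          halfWidth = 0.006, band = c(13, 30),
                          windowActive = c(0.3, 0.8),
                          windowControl = c(2.5, 3.0), mu = 0.05,
                          fingers = NULL, betaData = NULL,
                          peakMode = "abs", radialTol = NULL) {
  grid <- makeSourceGrid(spacing, headModel, centre = coarsePeak,
                         halfWidth = halfWidth)
  if (!is.null(radialTol)) {
    r0 <- sqrt(sum((coarsePeak - headModel@origin)^2))
    rv <- sqrt(rowSums(sweep(grid@voxels, 2, headModel@origin)^2))
    keepV <- abs(rv - r0) <= radialTol
    if (any(keepV)) {
      grid <- new("SourceGrid", voxels = grid@voxels[keepV, , drop = FALSE],
                  spacing = spacing)
    }
  }
  lf <- computeLeadField(grid, sensors, headModel)
  pseudoTMap(recording, epochs, lf, band = band,
             windowActive = windowActive, windowControl = windowControl,
             mu = mu, fingers = fingers, betaData = betaData,
             peakMode = peakMode)
}

#' Extract a virtual electrode
#'
#' Broadband LCMV projection of the cleaned continuous recording at one
#' location (typically the voxel of maximum beta modulation). Kept-trial
#' onsets are carried for downstream epoching.
#'
#' @param recording Cleaned [Recording-class].
#' @param epochs [EpochSet-class] defining kept trials.
#' @param voxel Source coordinates (m).
#' @param headModel [HeadModel-class].
#' @param band Band (Hz) of the covariance; `NULL` uses the recording as is
#'   (broadband).
#' @param mu Regularization fraction.
#' @param covariance Optional precomputed [CovarianceModel-class].
#' @return A [VirtualElectrode-class], or `NULL` with a warning when the
#'   voxel is not localizable.
#' @export
virtualElectrode <- function(recording, epochs, voxel,
                             headModel = makeHeadModel(), band = NULL,
                             mu = 0.05, covariance = NULL) {
  keep <- recording@channelKeep
  grid <- new("SourceGrid", voxels = matrix(voxel, 1), spacing = 0)
  lf <- computeLeadField(grid, recording@sensors, headModel)
  covm <- covariance %||%
    regularizedCovariance(recording, epochs, band = band, mu = mu)
  fit <- lcmvWeights(lf@L[keep, , drop = FALSE], covm)
  if (!fit$localizable) {
    warning("voxel not localizable")
    return(NULL)
  }
  sig <- drop(crossprod(fit$w, recording@data[keep, , drop = FALSE]))
  new("VirtualElectrode", signal = sig, fs = recording@fs, voxel = voxel,
      band = band %||% numeric(0), onsets = keptOnsets(epochs),
      fingers = epochs@fingers[epochs@trialKeep])
}

#' Epoch a virtual electrode
#'
#' @param ve [VirtualElectrode-class] (or a list with `signal`, `fs`,
#'   `onsets`).
#' @param window Window (s) relative to onset, half-open.
#' @param signal Optional replacement signal (e.g. band-filtered) sharing the
#'   VE's time axis.
#' @return List with `data` (trials x samples), `time`, `fs`.
#' @export
veEpochs <- function(ve, window = c(-0.5, 3.0), signal = NULL) {
  sig <- signal %||% ve@signal
  fs <- ve@fs
  nSamp <- winLen(window[1], window[2], fs)
  start <- as.integer(round((ve@onsets + window[1]) * fs)) + 1L
  ok <- start >= 1L & start + nSamp - 1L <= length(sig)
  M <- t(vapply(start[ok], function(s) sig[s:(s + nSamp - 1L)],
                numeric(nSamp)))
  list(data = M, time = window[1] + (seq_len(nSamp) - 1) / fs, fs = fs,
       fingers = ve@fingers[ok])
}

#' Region time courses at parcellation centroids
#'
#' One beamformer virtual electrode per region centre of mass, from a shared
#' band-limited covariance. Non-localizable centroids are dropped with a log
#' entry.
#'
#' @param recording Cleaned [Recording-class].
#' @param epochs [EpochSet-class].
#' @param parcellation [Parcellation-class].
#' @param headModel [HeadModel-class].
#' @param band Band (Hz) for the covariance (default beta).
#' @param mu Regularization fraction.
#' @param betaData Optional precomputed band-limited kept-channel data.
#' @param covariance Optional precomputed [CovarianceModel-class] matching
#'   `betaData`.
#' @return List with `ve` (regions x samples matrix of the band-limited
#'   projections), `labels`, `groups`, `fs`, `kept` (logical per region).
#' @export
parcelTimecourses <- function(recording, epochs, parcellation,
                              headModel = makeHeadModel(), band = c(13, 30),
                              mu = 0.05, betaData = NULL, covariance = NULL) {
  keep <- recording@channelKeep
  grid <- new("SourceGrid", voxels = parcellation@centroids, spacing = 0)
  lf <- computeLeadField(grid, recording@sensors, headModel)
  Xb <- betaData %||% t(bandFilter(t(recording@data[keep, , drop = FALSE]),
                                   band, recording@fs))
  covm <- covariance
  if (is.null(covm)) {
    idx <- keptSampleIdx(recording@fs, ncol(Xb), keptOnsets(epochs),
                         epochs@window)
    covm <- covarianceFromMatrix(rowCov(Xb, idx), mu)
  }
  bw <- lcmvWeightsGrid(lf, covm, channelKeep = keep)
  kept <- bw@localizable
  if (any(!kept)) {
    opmMsg(sum(!kept), " region centroid(s) not localizable; dropped")
  }
  VE <- crossprod(bw@W[, kept, drop = FALSE], Xb)
  list(ve = VE, labels = parcellation@labels[kept],
       groups = parcellation@groups[kept], fs = recording@fs, kept = kept)
}
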