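#' @import methods
NULL

#' Triaxial sensor array geometry
#'
#' Positions and channel orientations of a wearable triaxial magnetometer
#' array. Each sensor contributes three channels whose orientation unit
#' vectors form an orthonormal triad (one radial, two tangential).
#'
#' @slot positions n_sensors x 3 matrix of sensor positions (m, head-centred).
#' @slot orientations (3*n_sensors) x 3 matrix of channel orientation unit
#'   vectors, channels ordered sensor-major (radial, tangential-1, tangential-2).
#' @slot labels Character vector of channel labels.
#' @slot sensorIndex Integer vector mapping each channel to its sensor.
#' @export
setClass("SensorArray", slots = c(
  positions = "matrix", orientations = "matrix",
  labels = "character", sensorIndex = "integer"
))

setValidity("SensorArray", function(object) {
  ns <- nrow(object@positions)
  nc <- nrow(object@orientations)
  if (nc != 3L * ns) return("channel count must be 3 x n_sensors")
  if (length(object@labels) != nc) return("one label per channel required")
  for (s in seq_len(ns)) {
    E <- object@orientations[(3 * s - 2):(3 * s), ]
    if (max(abs(E %*% t(E) - diag(3))) > 1e-10) {
      return(sprintf("triad of sensor %d is not orthonormal to 1e-10", s))
    }
  }
  TRUE
})

#' Somatosensory stimulation paradigm
#'
#' Alternating two-finger trial structure: a short pin-tap stimulation block
#' followed by rest, repeated for each finger.
#'
#' @slot nTrialsPerFinger Trials per finger.
#' @slot stimDuration Stimulation duration (s).
#' @slot restDuration Rest duration (s).
#' @slot tapUp,tapDown Pin up/down times within a stimulation block (s).
#' @slot leadIn Quiet period before the first trial (s).
#' @slot onsets Stimulus onset times (s), strictly increasing.
#' @slot fingers Finger label per trial (alternating).
#' @export
setClass("Paradigm", slots = c(
  nTrialsPerFinger = "integer", stimDuration = "numeric",
  restDuration = "numeric", tapUp = "numeric", tapDown = "numeric",
  leadIn = "numeric", onsets = "numeric", fingers = "character"
))

setValidity("Paradigm", function(object) {
  if (any(diff(object@onsets) <= 0)) return("onsets must be strictly increasing")
  if (length(object@onsets) != length(object@fingers)) {
    return("one finger label per onset required")
  }
  TRUE
})

#' Multichannel OPM-MEG recording
#'
#' @slot data channels x samples matrix (T).
#' @slot fs Sampling rate (Hz).
#' @slot sensors [SensorArray-class] geometry.
#' @slot paradigm [Paradigm-class] trial structure.
#' @slot subjectId Subject identifier.
#' @slot age Age in years.
#' @slot channelKeep Logical per channel; FALSE marks rejected channels.
#' @slot channelReason Reason ("flat"/"noisy") per rejected channel, named by label.
#' @slot provenance List of per-stage processing records.
#' @export
setClass("Recording", slots = c(
  data = "matrix", fs = "numeric", sensors = "SensorArray",
  paradigm = "Paradigm", subjectId = "character", age = "numeric",
  channelKeep = "logical", channelReason = "character", provenance = "list"
))

setValidity("Recording", function(object) {
  if (nrow(object@data) != nrow(object@sensors@orientations)) {
    return("data rows must match channel count")
  }
  if (!all(is.finite(object@data))) return("data must be finite")
  if (length(object@channelKeep) != nrow(object@data)) {
    return("channelKeep must have one entry per channel")
  }
  TRUE
})

#' Epoched data
#'
#' Trials cut around stimulus onsets with a half-open window \[t0, t1):
#' sample k of a trial sits at time t0 + k/fs relative to onset.
#'
#' @slot data trials x channels x samples array.
#' @slot fs Sampling rate (Hz).
#' @slot window Length-2 epoch window (s) relative to onset.
#' @slot time Time axis (s) of epoch samples.
#' @slot fingers Finger label per trial.
#' @slot trialKeep Logical per trial.
#' @slot channelLabels Channel labels of the channel dimension.
#' @slot onsets Onset time (s) of each epoch in the source recording.
#' @export
setClass("EpochSet", slots = c(
  data = "array", fs = "numeric", window = "numeric", time = "numeric",
  fingers = "character", trialKeep = "logical", channelLabels = "character",
  onsets = "numeric"
))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be trials x channels x samples")
  if (length(object@trialKeep) != d[1]) return("trialKeep length must match trials")
  if (length(object@time) != d[3]) return("time axis must match sample count")
  TRUE
})

#' Spherical volume conductor
#' @slot origin Sphere centre (m).
#' @slot radius Sphere radius (m), > 0.
#' @export
setClass("HeadModel", slots = c(origin = "numeric", radius = "numeric"))

setValidity("HeadModel", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  if (length(object@origin) != 3) return("origin must be a 3-vector")
  TRUE
})

#' Source-space voxel grid
#' @slot voxels V x 3 matrix of voxel coordinates (m).
#' @slot spacing Grid spacing (m).
#' @export
setClass("SourceGrid", slots = c(voxels = "matrix", spacing = "numeric"))

#' Lead field over a source grid
#'
#' Per-voxel forward fields restricted to the two tangential dipole
#' directions (radial dipoles are magnetically silent in a sphere), stored as
#' one channels x 2V matrix.
#'
#' @slot L channels x (2 * V) matrix; columns 2v-1, 2v belong to voxel v.
#' @slot grid [SourceGrid-class].
#' @slot sensors [SensorArray-class].
#' @slot headModel [HeadModel-class].
#' @slot tangentBasis (2 * V) x 3 matrix of tangential unit vectors.
#' @slot localizable Logical per voxel (FALSE at/near the sphere origin).
#' @export
setClass("LeadField", slots = c(
  L = "matrix", grid = "SourceGrid", sensors = "SensorArray",
  headModel = "HeadModel", tangentBasis = "matrix", localizable = "logical"
))

#' Regularized data covariance
#'
#' @slot cov channels x channels sample covariance C.
#' @slot Creg Tikhonov-regularized covariance C + mu * lambda_max * I.
#' @slot mu Regularization fraction (default 0.05).
#' @slot lambdaMax Largest eigenvalue of C.
#' @slot band Band (Hz) the data were filtered to, or NULL-like numeric(0).
#' @slot nSamples Number of samples entering C.
#' @export
setClass("CovarianceModel", slots = c(
  cov = "matrix", Creg = "matrix", mu = "numeric", lambdaMax = "numeric",
  band = "numeric", nSamples = "integer"
))

#' LCMV beamformer weights over a grid
#' @slot W channels x V matrix of spatial-filter weights.
#' @slot eta V x 3 matrix of source orientations (unit vectors).
#' @slot localizable Logical per voxel.
#' @slot grid [SourceGrid-class].
#' @export
setClass("BeamformerWeights", slots = c(
  W = "matrix", eta = "matrix", localizable = "logical", grid = "SourceGrid"
))

#' Pseudo-T contrast image
#'
#' Voxel-wise normalized source-power contrast between an active and a
#' control window, T = (P_a - P_c) / (P_a + P_c).
#'
#' @slot values Pseudo-T per voxel, in \[-1, 1\].
#' @slot grid [SourceGrid-class].
#' @slot windowActive,windowControl Contrast windows (s, relative to onset).
#' @slot band Band (Hz).
#' @slot peakVoxel Coordinates (m) of max |T| among localizable voxels.
#' @slot peakValue Pseudo-T at the peak.
#' @export
setClass("PseudoTMap", slots = c(
  values = "numeric", grid = "SourceGrid", windowActive = "numeric",
  windowControl = "numeric", band = "numeric", peakVoxel = "numeric",
  peakValue = "numeric"
))

#' Beamformer-projected source time course
#'
#' Continuous projection of the cleaned recording at one source location,
#' with the kept-trial structure carried as metadata for epoching.
#'
#' @slot signal Source time course (source units).
#' @slot fs Sampling rate (Hz).
#' @slot voxel Source coordinates (m).
#' @slot band Band of the covariance used for the weights (Hz).
#' @slot onsets Kept-trial stimulus onsets (s).
#' @slot fingers Finger label per kept trial.
#' @export
setClass("VirtualElectrode", slots = c(
  signal = "numeric", fs = "numeric", voxel = "numeric", band = "numeric",
  onsets = "numeric", fingers = "character"
))

#' Cortical parcellation for the synthetic world
#' @slot labels Region labels (unique).
#' @slot centroids n x 3 matrix of region centre-of-mass coordinates (m).
#' @slot groups Region group tag: "frontal", "occipital" or "other".
#' @export
setClass("Parcellation", slots = c(
  labels = "character", centroids = "matrix", groups = "character"
))

setValidity("Parcellation", function(object) {
  if (anyDuplicated(object@labels)) return("region labels must be unique")
  if (nrow(object@centroids) != length(object@labels)) {
    return("one centroid per region required")
  }
  TRUE
})

#' Amplitude-envelope-correlation connectome
#' @slot A n x n symmetric AEC matrix with zero diagonal, entries in \[-1, 1\].
#' @slot labels Region labels.
#' @slot groups Region group tags.
#' @export
setClass("Connectome", slots = c(
  A = "matrix", labels = "character", groups = "character"
))

setValidity("Connectome", function(object) {
  A <- object@A
  if (nrow(A) != ncol(A)) return("A must be square")
  if (max(abs(A - t(A))) > 1e-10) return("A must be symmetric")
  if (any(abs(diag(A)) > 1e-12)) return("diagonal must be zero")
  if (any(A < -1 - 1e-9 | A > 1 + 1e-9)) return("entries must lie in [-1, 1]")
  TRUE
})

#' Time-delay-embedded Gaussian hidden Markov model fit
#'
#' @slot K Number of states.
#' @slot initProb Initial state distribution.
#' @slot transMat K x K transition matrix (rows sum to 1).
#' @slot covs d x d x K array of per-state covariances (zero-mean model).
#' @slot gamma time x K posterior state probabilities.
#' @slot logLik Log-likelihood trace over EM iterations (non-decreasing).
#' @slot lags Lags each side of the embedding.
#' @slot fs Sampling rate of the embedded series (Hz).
#' @slot converged Logical.
#' @export
setClass("TdeHmm", slots = c(
  K = "integer", initProb = "numeric", transMat = "matrix", covs = "array",
  gamma = "matrix", logLik = "numeric", lags = "integer", fs = "numeric",
  converged = "logical"
))

setValidity("TdeHmm", function(object) {
  if (max(abs(rowSums(object@transMat) - 1)) > 1e-10) {
    return("transition-matrix rows must sum to 1")
  }
  if (max(abs(rowSums(object@gamma) - 1)) > 1e-8) {
    return("posterior rows must sum to 1")
  }
  TRUE
})

#' Burst detection result
#'
#' @slot binary time x K binary state rasters (gamma > 2/3, strict).
#' @slot burstState Index of the task-modulated burst state.
#' @slot P Trial-averaged burst probability time course.
#' @slot time Epoch time axis of `P` (s, relative to onset).
#' @slot deltaP Burst probability modulation: mean P in \[1.0, 1.5) minus
#'   mean P in \[0.3, 0.8).
#' @slot amplitude Mean broadband (1-48 Hz) envelope during burst visits.
#' @slot psd frequencies x K matrix of state-resolved multitaper PSDs.
#' @slot psdFreq Frequency axis (Hz) of `psd`.
#' @slot fs Sampling rate of the binarized series (Hz).
#' @slot weakModulation TRUE when no state modulates appreciably with the task.
#' @export
setClass("BurstResult", slots = c(
  binary = "matrix", burstState = "integer", P = "numeric", time = "numeric",
  deltaP = "numeric", amplitude = "numeric", psd = "matrix",
  psdFreq = "numeric", fs = "numeric", weakModulation = "logical"
))

# ---- generics / accessors ----------------------------------------------------

#' Number of channels
#' @param x A SensorArray, Recording or EpochSet.
#' @return Integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "SensorArray", function(x) nrow(x@orientations))

#' @rdname nChannels
#' @export
setMethod("nChannels", "Recording", function(x) nrow(x@data))

#' @rdname nChannels
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])

#' Number of sensors in an array
#' @param x A SensorArray.
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' @rdname nSensors
#' @export
setMethod("nSensors", "SensorArray", function(x) nrow(x@positions))

#' Sampling rate (Hz)
#' @param x A Recording, EpochSet or VirtualElectrode.
#' @export
setGeneric("sampRate", function(x) standardGeneric("sampRate"))

#' @rdname sampRate
#' @export
setMethod("sampRate", "Recording", function(x) x@fs)

#' @rdname sampRate
#' @export
setMethod("sampRate", "EpochSet", function(x) x@fs)

#' @rdname sampRate
#' @export
setMethod("sampRate", "VirtualElectrode", function(x) x@fs)

#' Channels x samples data matrix of a recording
#' @param x A Recording.
#' @export
setGeneric("recData", function(x) standardGeneric("recData"))

#' @rdname recData
#' @export
setMethod("recData", "Recording", function(x) x@data)

#' Kept-channel logical mask
#' @param x A Recording.
#' @export
setGeneric("channelKeep", function(x) standardGeneric("channelKeep"))

#' @rdname channelKeep
#' @export
setMethod("channelKeep", "Recording", function(x) x@channelKeep)

#' Kept-trial logical mask
#' @param x An EpochSet.
#' @export
setGeneric("trialKeep", function(x) standardGeneric("trialKeep"))

#' @rdname trialKeep
#' @export
setMethod("trialKeep", "EpochSet", function(x) x@trialKeep)

#' Total paradigm duration (s)
#'
#' Number of trials times the trial period (stimulation + rest); for the
#' default paradigm of 42 trials per finger and two fingers at 3.5 s per
#' trial this is 294 s.
#'
#' @param x A Paradigm.
#' @export
setGeneric("paradigmDuration", function(x) standardGeneric("paradigmDuration"))

#' @rdname paradigmDuration
#' @export
setMethod("paradigmDuration", "Paradigm", function(x) {
  length(x@onsets) * (x@stimDuration + x@restDuration)
})

#' Adjacency matrix of a connectome
#' @param x A Connectome.
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname connMatrix
#' @export
setMethod("connMatrix", "Connectome", function(x) x@A)

#' Global connectivity: mean of all off-diagonal connectome entries
#' @param x A Connectome.
#' @export
setGeneric("globalConnectivity", function(x) standardGeneric("globalConnectivity"))

#' @rdname globalConnectivity
#' @export
setMethod("globalConnectivity", "Connectome", function(x) {
  A <- x@A
  n <- nrow(A)
  if (n < 2) return(NA_real_)
  sum(A[upper.tri(A) | lower.tri(A)]) / (n * (n - 1))
})

#' Node degree: column sums of off-diagonal connectome entries
#' @param x A Connectome.
#' @return Named numeric vector, one value per region.
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname nodeDegree
#' @export
setMethod("nodeDegree", "Connectome", function(x) {
  d <- colSums(x@A)  # diagonal is zero by class invariant
  names(d) <- x@labels
  d
})

# ---- show methods ------------------------------------------------------------

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray: %d sensors, %d channels (triaxial)\n",
              nSensors(object), nChannels(object)))
  r <- sqrt(rowSums(object@positions^2))
  cat(sprintf("  radius %.3f-%.3f m\n", min(r), max(r)))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' (age %.1f y): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@age, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
  cat(sprintf("  %d/%d channels kept; %d trials; stages: %s\n",
              sum(object@channelKeep), length(object@channelKeep),
              length(object@paradigm@onsets),
              paste(names(object@provenance), collapse = " > ") %||% "none"))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials (%d kept) x %d channels x %d samples, window [%g, %g) s\n",
              d[1], sum(object@trialKeep), d[2], d[3],
              object@window[1], object@window[2]))
})

setMethod("show", "Connectome", function(object) {
  cat(sprintf("Connectome: %d regions, global connectivity %.4f\n",
              nrow(object@A), globalConnectivity(object)))
})

setMethod("show", "TdeHmm", function(object) {
  cat(sprintf("TdeHmm: K=%d, %d lags each side, %d x %d posteriors, logLik %.2f (%s)\n",
              object@K, object@lags, nrow(object@gamma), object@K,
              tail(object@logLik, 1),
              if (object@converged) "converged" else "max iterations"))
})

setMethod("show", "PseudoTMap", function(object) {
  cat(sprintf("PseudoTMap: %d voxels @ %g mm, band %g-%g Hz, peak T=%.3f at (%.1f, %.1f, %.1f) mm\n",
              nrow(object@grid@voxels), object@grid@spacing * 1000,
              object@band[1], object@band[2], object@peakValue,
              object@peakVoxel[1] * 1000, object@peakVoxel[2] * 1000,
              object@peakVoxel[3] * 1000))
})

setMethod("show", "BurstResult", function(object) {
  cat(sprintf("BurstResult: burst state %d, deltaP=%.3f, amplitude=%.3f%s\n",
              object@burstState, object@deltaP, object@amplitude,
              if (object@weakModulation) " (weak modulation)" else ""))
})
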