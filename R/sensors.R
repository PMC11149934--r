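#' Construct a quasi-uniform triaxial sensor array
#'
#' Places `nSensors` sensors on a sphere of radius `headRadius + offset`
#' using a Fibonacci lattice (quasi-uniform coverage) and equips each with an
#' orthonormal triad: one radially oriented channel and two tangential ones.
#' A seed, when given, applies a random rigid rotation to the lattice so that
#' arrays differ between subjects while remaining quasi-uniform.
#'
#' @param nSensors Number of sensors (>= 4; 64 gives the full 192-channel array).
#' @param headRadius Head-model sphere radius (m).
#' @param offset Scalp-to-sensor standoff (m, > 0).
#' @param seed Optional integer seed for the random rotation.
#' @return A [SensorArray-class].
#' @examples
#' arr <- makeSensorArray(64)
#' nChannels(arr)  # 192
#' @export
makeSensorArray <- function(nSensors = 64, headRadius = 0.08, offset = 0.015,
                            seed = NULL) {
  if (headRadius <= 0 || offset <= 0) {
    stop("invalid geometry: headRadius and offset must be positive")
  }
  if (nSensors < 4) stop("invalid geometry: need at least 4 sensors")
  nSensors <- as.integer(nSensors)
  r <- headRadius + offset
  i <- seq_len(nSensors) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / nSensors
  rho <- sqrt(pmax(0, 1 - z^2))
  P <- cbind(rho * cos(phi), rho * sin(phi), z)
  R <- withSeed(seed, randomRotation(is.null(seed)))
  P <- P %*% t(R) * r
  orient <- matrix(0, 3L * nSensors, 3)
  for (s in seq_len(nSensors)) {
    rad <- P[s, ] / sqrt(sum(P[s, ]^2))
    t1 <- tangentialBasis(rad)
    orient[3 * s - 2, ] <- rad
    orient[3 * s - 1, ] <- t1[1, ]
    orient[3 * s, ] <- t1[2, ]
  }
  labels <- paste0("S", rep(seq_len(nSensors), each = 3), "_",
                   rep(c("rad", "tan1", "tan2"), nSensors))
  new("SensorArray", positions = P, orientations = orient, labels = labels,
      sensorIndex = rep(seq_len(nSensors), each = 3))
}

# Identity when `fixed`, otherwise a uniform random rotation matrix.
randomRotation <- function(fixed = TRUE) {
  if (fixed) return(diag(3))
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q * sign(det(Q))
}

# Two unit vectors spanning the tangent plane orthogonal to radial `rad`.
tangentialBasis <- function(rad) {
  ref <- if (abs(rad[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * rad) * rad
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(rad[2] * t1[3] - rad[3] * t1[2],
          rad[3] * t1[1] - rad[1] * t1[3],
          rad[1] * t1[2] - rad[2] * t1[1])
  rbind(t1, t2 / sqrt(sum(t2^2)))
}

#' Construct the somatosensory stimulation paradigm
#'
#' Alternating index/little-finger trials: `stimDuration` seconds of
#' stimulation (three pin taps) followed by `restDuration` seconds of rest.
#' The default reproduces the study paradigm: 42 trials per finger at a 3.5 s
#' trial period, i.e. a 294 s paradigm.
#'
#' @param nTrialsPerFinger Trials per finger (default 42).
#' @param stimDuration Stimulation duration (s, default 0.5).
#' @param restDuration Rest duration (s, default 3.0).
#' @param tapUp,tapDown Pin up/down times (s, default 0.082 each).
#' @param leadIn Quiet period before the first onset (s, default 1.0).
#' @param fingers Labels of the two alternated fingers.
#' @return A [Paradigm-class].
#' @examples
#' paradigmDuration(makeParadigm())  # 294
#' @export
makeParadigm <- function(nTrialsPerFinger = 42, stimDuration = 0.5,
                         restDuration = 3.0, tapUp = 0.082, tapDown = 0.082,
                         leadIn = 1.0, fingers = c("D2", "D5")) {
  stopifnot(nTrialsPerFinger >= 1, stimDuration > 0, restDuration >= 0)
  n <- 2L * as.integer(nTrialsPerFinger)
  period <- stimDuration + restDuration
  onsets <- leadIn + (seq_len(n) - 1) * period
  new("Paradigm", nTrialsPerFinger = as.integer(nTrialsPerFinger),
      stimDuration = stimDuration, restDuration = restDuration,
      tapUp = tapUp, tapDown = tapDown, leadIn = leadIn,
      onsets = onsets, fingers = rep(fingers, length.out = n))
}

#' Spherical head model
#' @param origin Sphere centre (m), default head-centred at the origin.
#' @param radius Sphere radius (m), default 0.08.
#' @return A [HeadModel-class].
#' @export
makeHeadModel <- function(origin = c(0, 0, 0), radius = 0.08) {
  new("HeadModel", origin = origin, radius = radius)
}

#' Synthetic cortical parcellation
#'
#' Places `n` region centroids deterministically (Fibonacci lattice) on an
#' inner sphere and tags them frontal (anterior, +y), occipital (posterior,
#' -y) or other. This stands in for an anatomical atlas in the synthetic
#' world; it reproduces the atlas's region count and a frontal/occipital
#' split, not its geometry.
#'
#' @param n Number of regions (default 78).
#' @param radius Centroid shell radius (m), inside the head model.
#' @param headModel [HeadModel-class] the centroids must lie inside.
#' @return A [Parcellation-class].
#' @export
makeParcellation <- function(n = 78, radius = 0.05, headModel = makeHeadModel()) {
  stopifnot(n >= 2, radius > 0, radius < headModel@radius)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  C <- cbind(rho * cos(phi), rho * sin(phi), z) * radius
  groups <- rep("other", n)
  groups[C[, 2] > 0.45 * radius] <- "frontal"
  groups[C[, 2] < -0.55 * radius] <- "occipital"
  new("Parcellation",
      labels = sprintf("R%02d_%s", seq_len(n), groups),
      centroids = C, groups = groups)
}
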