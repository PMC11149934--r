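#' Per-subject burst ground truth
#'
#' Parameters of the planted pan-spectral burst process at the sensorimotor
#' source. Burst occurrence is an inhomogeneous point process whose rate
#' drops by a fraction `modulationDepth` inside the 0-0.8 s post-onset
#' window; burst waveforms are amplitude-windowed coloured noise whose
#' low/high-frequency balance is set by `spectralTilt` plus a fixed-amplitude
#' alpha (9 Hz) component; broadband burst amplitude is age-invariant in the
#' default cohort.
#'
#' @slot baselineRate Baseline burst rate (bursts/s).
#' @slot modulationDepth Fraction d in \[0, 1\]; stimulus-window rate is
#'   baselineRate * (1 - d).
#' @slot burstDurationMean Mean burst duration (s).
#' @slot spectralTilt Dimensionless tilt in \[-1, 1\]: negative tilts power
#'   toward low frequencies (young), positive toward high (old); 9 Hz and
#'   total burst power are invariant by construction.
#' @slot alphaPeakAmp Amplitude of the fixed alpha component (source units).
#' @slot burstAmplitude RMS amplitude of the broadband burst waveform.
#' @slot floorSigma Between-burst noise-floor standard deviation.
#' @export
setClass("BurstGroundTruth", slots = c(
  baselineRate = "numeric", modulationDepth = "numeric",
  burstDurationMean = "numeric", spectralTilt = "numeric",
  alphaPeakAmp = "numeric", burstAmplitude = "numeric", floorSigma = "numeric"
))

setValidity("BurstGroundTruth", function(object) {
  if (object@modulationDepth < 0 || object@modulationDepth > 1) {
    return("modulationDepth must lie in [0, 1]")
  }
  if (object@baselineRate < 0) return("baselineRate must be >= 0")
  TRUE
})

#' @describeIn BurstGroundTruth-class Constructor with the default burst
#'   regime (2 bursts/s, 200 ms mean duration, giving ~0.3-0.4 burst-state
#'   occupancy, consistent with the beta-burst literature).
#' @param baselineRate,modulationDepth,burstDurationMean,spectralTilt
#'   See slots.
#' @param alphaPeakAmp,burstAmplitude,floorSigma See slots.
#' @export
burstGroundTruth <- function(baselineRate = 2.0, modulationDepth = 0.5,
                             burstDurationMean = 0.2, spectralTilt = 0,
                             alphaPeakAmp = 0.35, burstAmplitude = 1.0,
                             floorSigma = 0.1) {
  if (modulationDepth < 0 || modulationDepth > 1) {
    stop("modulationDepth must lie in [0, 1]")
  }
  if (baselineRate < 0) stop("baselineRate must be >= 0")
  new("BurstGroundTruth", baselineRate = baselineRate,
      modulationDepth = modulationDepth,
      burstDurationMean = burstDurationMean, spectralTilt = spectralTilt,
      alphaPeakAmp = alphaPeakAmp, burstAmplitude = burstAmplitude,
      floorSigma = floorSigma)
}

# Stimulus-suppression windows: [onset, onset + supLen) for each trial.
stimWindows <- function(paradigm, supLen = 0.8) {
  cbind(start = paradigm@onsets, end = paradigm@onsets + supLen)
}

inAnyWindow <- function(t, win) {
  res <- rep(FALSE, length(t))
  if (nrow(win) == 0) return(res)
  idx <- findInterval(t, win[, "start"])
  pos <- idx > 0
  res[pos] <- t[pos] < win[idx[pos], "end"]
  res
}

#' Simulate a task-modulated burst train
#'
#' Inhomogeneous Poisson onsets at `baselineRate`, thinned by the modulation
#' depth d inside each 0-0.8 s post-onset window; durations are lognormal
#' around `burstDurationMean` and truncated at the next onset so bursts never
#' overlap (window-rate statistics stay exactly Poisson).
#'
#' @param paradigm [Paradigm-class] providing the stimulus onsets.
#' @param groundTruth [BurstGroundTruth-class].
#' @param duration Total simulated duration (s).
#' @param seed Optional integer seed.
#' @param supLen Length of the rate-suppression window after onset (s).
#' @return data.frame with columns `onset` and `duration` (s).
#' @export
simulateBurstTrain <- function(paradigm, groundTruth, duration, seed = NULL,
                               supLen = 0.8) {
  d <- groundTruth@modulationDepth
  if (d < 0 || d > 1) stop("modulationDepth must lie in [0, 1]")
  lam <- groundTruth@baselineRate
  if (lam < 0) stop("baselineRate must be >= 0")
  win <- stimWindows(paradigm, supLen)
  withSeed(seed, {
    n <- stats::rpois(1, lam * duration)
    if (n == 0) return(data.frame(onset = numeric(0), duration = numeric(0)))
    on <- sort(runif(n, 0, duration))
    keep <- !(inAnyWindow(on, win) & runif(n) < d)
    on <- on[keep]
    if (length(on) == 0) return(data.frame(onset = numeric(0), duration = numeric(0)))
    sdlog <- 0.5
    dur <- stats::rlnorm(length(on), log(groundTruth@burstDurationMean) -
                           sdlog^2 / 2, sdlog)
    dur <- pmax(dur, 0.05)
    gap <- c(diff(on), duration - on[length(on)])
    dur <- pmin(dur, gap - 1e-6)
    ok <- dur > 0
    data.frame(onset = on[ok], duration = dur[ok])
  })
}

# ---- burst spectral shape ----------------------------------------------------

tiltCache <- new.env(parent = emptyenv())

# Spectral tilt shape S(f; tau) = max(1 + tau * g(f), 0.05) on [1, 48] Hz.
# g is a log-frequency sigmoid with two built-in invariances: g(9) = 0 (the
# alpha anchor frequency is tilt-free) and mean(g) = 0 over the band (total
# burst power is tilt-free). The sigmoid pivot f0 solving both is found once.
tiltShapeFun <- function() {
  hit <- tiltCache$fun
  if (!is.null(hit)) return(hit)
  s <- 1
  fgrid <- seq(1, 48, by = 0.01)
  mOf <- function(f0) mean(tanh(log(fgrid / f0) / s))
  root <- stats::uniroot(function(f0) tanh(log(9 / f0) / s) - mOf(f0),
                         c(1.5, 8.99))$root
  m <- mOf(root)
  fun <- function(f, tau) {
    g <- tanh(log(pmax(f, 1e-6) / root) / s) - m
    pmax(1 + tau * g, 0.05)
  }
  tiltCache$fun <- fun
  fun
}

# Coloured-noise burst waveform: FFT-shaped Gaussian noise with power
# spectrum S(f; tau) restricted to 1-48 Hz, Tukey-windowed, RMS-normalized.
burstWaveform <- function(len, fs, tau, amplitude) {
  n <- max(len, 16L)
  x <- rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  S <- ifelse(f >= 1 & f <= 48, tiltShapeFun()(f, tau), 0)
  w <- Re(fft(fft(x) * sqrt(S), inverse = TRUE)) / n
  w <- w[seq_len(len)] * tukeyWindow(len, 0.5)
  rms <- sqrt(mean(w^2))
  if (rms < 1e-12) return(numeric(len))
  w / rms * amplitude
}

#' Synthesize the sensorimotor source time course
#'
#' Sum of a weak white noise floor, one tilt-shaped coloured-noise waveform
#' per burst (plus a fixed-amplitude windowed 9 Hz alpha component), and a
#' phase-locked evoked deflection (Gaussian bump peaking 50 ms after each
#' stimulus onset).
#'
#' @param burstTrain data.frame from [simulateBurstTrain()].
#' @param groundTruth [BurstGroundTruth-class].
#' @param fs Sampling rate (Hz, >= 100).
#' @param duration Signal duration (s).
#' @param paradigm Optional [Paradigm-class]; required when `evokedAmp > 0`.
#' @param evokedAmp Amplitude of the M50 bump (source units).
#' @param seed Optional integer seed.
#' @return Numeric source time course of length `round(duration * fs)`.
#' @export
synthesizeSource <- function(burstTrain, groundTruth, fs, duration,
                             paradigm = NULL, evokedAmp = 0, seed = NULL) {
  if (fs < 100) stop("fs must be >= 100 Hz")
  n <- as.integer(round(duration * fs))
  withSeed(seed, {
    x <- rnorm(n, sd = groundTruth@floorSigma)
    if (nrow(burstTrain) > 0) {
      for (b in seq_len(nrow(burstTrain))) {
        i0 <- as.integer(floor(burstTrain$onset[b] * fs)) + 1L
        len <- max(2L, as.integer(round(burstTrain$duration[b] * fs)))
        if (i0 + len - 1L > n) len <- n - i0 + 1L
        if (len < 2L) next
        # per-burst seed derived from the onset: a burst shared by two
        # trains (e.g. across a coupled modulation-depth grid) gets an
        # identical waveform
        w <- withSeed(childSeed(seed, round(burstTrain$onset[b] * 1e4)), {
          wv <- burstWaveform(len, fs, groundTruth@spectralTilt,
                              groundTruth@burstAmplitude)
          tt <- (seq_len(len) - 1) / fs
          wv + groundTruth@alphaPeakAmp *
            sin(2 * pi * 9 * tt + runif(1, 0, 2 * pi)) * tukeyWindow(len, 0.5)
        })
        idx <- i0:(i0 + len - 1L)
        x[idx] <- x[idx] + w
      }
    }
    if (evokedAmp != 0) {
      if (is.null(paradigm)) stop("paradigm required for an evoked component")
      t <- (seq_len(n) - 1) / fs
      for (on in paradigm@onsets) {
        if (on + 0.05 > duration) next
        sel <- which(t > on - 0.05 & t < on + 0.2)
        x[sel] <- x[sel] + evokedAmp * exp(-((t[sel] - on - 0.05)^2) / (2 * 0.01^2))
      }
    }
    x
  })
}

# ---- coupled-envelope region sources ----------------------------------------

# Slow positive envelope processes with exact pairwise correlation structure:
# independent unit-variance 0.2-2 Hz Gaussian processes u_r mixed with a
# group-shared process u0_g as sqrt(rho) * u0_g + sqrt(1-rho) * u_r.
# The band covers the dominant fluctuation scale of beta-band amplitude
# envelopes while decorrelating within task windows.
slowProcess <- function(n, fs, m = 1) {
  u <- matrix(rnorm(n * m), n, m)
  lo <- bandFilter(u, c(0.2, 2), fs, order = 2)
  scale(lo)[, , drop = FALSE]
}

envFromSlow <- function(u) pmax(1 + 0.5 * u, 0.05)

# Narrowband carrier with slowly drifting phase at frequency f0.
betaCarrier <- function(n, fs, f0, phaseSd = 0.15) {
  ph <- 2 * pi * f0 * (seq_len(n) - 1) / fs + cumsum(rnorm(n, 0, phaseSd))
  cos(ph)
}

#' Simulate a pair of signals with a planted envelope correlation
#'
#' Two narrowband (beta-range) carriers at distinct frequencies whose slow
#' amplitude envelopes share a common component with correlation `rho` —
#' the generative construction used to validate amplitude envelope
#' correlation estimates.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param rho Planted envelope correlation in \[0, 1\].
#' @param seed Optional integer seed.
#' @param freqs Carrier frequencies (Hz) of the two signals.
#' @return List with `x`, `y` (signals) and `envx`, `envy` (true envelopes).
#' @export
makeCoupledEnvelopePair <- function(n, fs, rho, seed = NULL,
                                    freqs = c(17, 24)) {
  stopifnot(rho >= 0, rho <= 1)
  withSeed(seed, {
    u <- slowProcess(n, fs, 3)
    u1 <- sqrt(rho) * u[, 1] + sqrt(1 - rho) * u[, 2]
    u2 <- sqrt(rho) * u[, 1] + sqrt(1 - rho) * u[, 3]
    e1 <- envFromSlow(u1)
    e2 <- envFromSlow(u2)
    list(x = e1 * betaCarrier(n, fs, freqs[1]),
         y = e2 * betaCarrier(n, fs, freqs[2]),
         envx = e1, envy = e2)
  })
}

# Region source time courses with within-group planted envelope correlations.
# rhoByGroup: named numeric (frontal/occipital/other) of pairwise envelope
# correlations within each group; cross-group envelope correlation is zero.
simulateRegionSources <- function(parcellation, rhoByGroup, n, fs,
                                  amplitude = 0.25, seed = NULL) {
  nr <- length(parcellation@labels)
  withSeed(seed, {
    groups <- parcellation@groups
    ug <- unique(groups)
    # one batched filter call: group-shared processes first, then one
    # independent process per region
    U <- slowProcess(n, fs, length(ug) + nr)
    shared <- U[, seq_along(ug), drop = FALSE]
    colnames(shared) <- ug
    S <- matrix(0, nr, n)
    freqs <- seq(15, 28, length.out = nr)
    for (r in seq_len(nr)) {
      g <- groups[r]
      rho <- min(max(rhoByGroup[[g]] %||% 0, 0), 0.95)
      u <- sqrt(rho) * shared[, g] + sqrt(1 - rho) * U[, length(ug) + r]
      S[r, ] <- amplitude * envFromSlow(u) * betaCarrier(n, fs, freqs[r])
    }
    S
  })
}

# ---- sensor projection -------------------------------------------------------

#' Sensor-noise specification
#'
#' @param snr Signal-to-noise ratio: mean channel RMS of the projected brain
#'   signal divided by the white-noise SD. Ignored when `whiteSd` is given.
#' @param whiteSd Absolute white-noise SD (T); overrides `snr`.
#' @param lineFreqs Mains interference frequencies (Hz); components at or
#'   above 0.48 * fs are skipped.
#' @param lineAmp Mains amplitude as a multiple of the white-noise SD.
#' @param driftAmp Homogeneous-field drift amplitude (multiple of white SD):
#'   a 3-parameter slowly varying field seen identically by all sensors and
#'   projected onto each channel orientation — exactly the subspace removed
#'   by homogeneous field correction.
#' @param flatChannels,noisyChannels Channel indices planted as bad
#'   (zeroed / white noise scaled by `noisyFactor`).
#' @param noisyFactor Noise multiplier for `noisyChannels`.
#' @param badTrials Trial indices receiving extra broadband noise.
#' @param badTrialFactor Extra-noise SD multiplier for `badTrials`.
#' @return A noise-specification list for [projectToSensors()].
#' @export
noiseSpec <- function(snr = 1, whiteSd = NULL, lineFreqs = c(50, 100, 150),
                      lineAmp = 2, driftAmp = 20, flatChannels = integer(0),
                      noisyChannels = integer(0), noisyFactor = 10,
                      badTrials = integer(0), badTrialFactor = 5) {
  list(snr = snr, whiteSd = whiteSd, lineFreqs = lineFreqs, lineAmp = lineAmp,
       driftAmp = driftAmp, flatChannels = flatChannels,
       noisyChannels = noisyChannels, noisyFactor = noisyFactor,
       badTrials = badTrials, badTrialFactor = badTrialFactor)
}

#' Project source time courses to a sensor array
#'
#' data = gain %*% sources + white noise + mains sinusoids + homogeneous
#' field drift, with optional planted bad channels and high-variance trials.
#'
#' @param sources nSrc x samples matrix (or vector for one source).
#' @param gain channels x nSrc forward matrix, e.g. from [sourceGain()].
#' @param sensors [SensorArray-class].
#' @param fs Sampling rate (Hz).
#' @param noise Specification from [noiseSpec()]; pass
#'   `noiseSpec(whiteSd = 0, lineAmp = 0, driftAmp = 0)` for a noiseless
#'   projection.
#' @param paradigm Optional [Paradigm-class] (required for planted bad trials).
#' @param subjectId,age Recording metadata.
#' @param seed Optional integer seed.
#' @return A [Recording-class].
#' @export
projectToSensors <- function(sources, gain, sensors, fs,
                             noise = noiseSpec(), paradigm = makeParadigm(),
                             subjectId = "sim", age = NA_real_, seed = NULL) {
  if (is.null(dim(sources))) sources <- matrix(sources, 1)
  if (nrow(gain) != nChannels(sensors)) {
    stop("gain rows (", nrow(gain), ") do not match channel count (",
         nChannels(sensors), ")")
  }
  if (ncol(gain) != nrow(sources)) {
    stop("gain columns do not match the number of sources")
  }
  n <- ncol(sources)
  X <- gain %*% sources
  sigRms <- mean(sqrt(rowMeans(X^2)))
  whiteSd <- noise$whiteSd %||% (if (noise$snr > 0) sigRms / noise$snr else 0)
  nc <- nrow(X)
  withSeed(seed, {
    if (whiteSd > 0) X <- X + matrix(rnorm(nc * n, sd = whiteSd), nc, n)
    t <- (seq_len(n) - 1) / fs
    for (f0 in noise$lineFreqs) {
      if (f0 >= 0.48 * fs || noise$lineAmp <= 0 || whiteSd <= 0) next
      ph <- runif(1, 0, 2 * pi)
      amp <- noise$lineAmp * whiteSd * runif(nc, 0.5, 1.5)
      X <- X + amp %o% sin(2 * pi * f0 * t + ph)
    }
    if (noise$driftAmp > 0 && whiteSd > 0) {
      b <- bandFilter(matrix(rnorm(3 * n), n, 3), c(0.02, 0.4), fs, order = 2)
      b <- scale(b) * noise$driftAmp * whiteSd
      X <- X + sensors@orientations %*% t(b)
    }
    if (length(noise$badTrials) > 0) {
      for (tr in noise$badTrials) {
        on <- paradigm@onsets[tr]
        idx <- which(t >= on - 0.5 & t < on + 3.0)
        X[, idx] <- X[, idx] + matrix(
          rnorm(nc * length(idx), sd = noise$badTrialFactor * max(whiteSd, sigRms)),
          nc, length(idx))
      }
    }
    if (length(noise$noisyChannels) > 0) {
      X[noise$noisyChannels, ] <- matrix(
        rnorm(length(noise$noisyChannels) * n,
              sd = noise$noisyFactor * max(whiteSd, sigRms)),
        length(noise$noisyChannels), n)
    }
    if (length(noise$flatChannels) > 0) X[noise$flatChannels, ] <- 0
    new("Recording", data = X, fs = fs, sensors = sensors,
        paradigm = paradigm, subjectId = subjectId, age = age,
        channelKeep = rep(TRUE, nc), channelReason = character(0),
        provenance = list(simulate = list(
          whiteSd = whiteSd, snr = if (is.null(noise$whiteSd)) noise$snr else NA,
          flatChannels = noise$flatChannels,
          noisyChannels = noise$noisyChannels, badTrials = noise$badTrials)))
  })
}

# ---- cohort generation -------------------------------------------------------

#' Cohort age-trend specification
#'
#' Linear age trends of the planted parameters. Burst modulation depth and
#' spectral tilt increase with age; node-degree targets rise faster in
#' frontal than occipital regions (frontal 0.27/year vs occipital 0.10/year
#' by default); burst amplitude and the evoked M50 are age-invariant.
#'
#' @param depth c(intercept, slope, sd) of the modulation depth d vs age.
#' @param tilt c(intercept, slope, sd) of the burst spectral tilt vs age.
#' @param frontalDegree,occipitalDegree,otherDegree c(intercept, slope, sd)
#'   of the planted node-degree target vs age per region group.
#' @param burstAmplitude Age-invariant burst RMS amplitude.
#' @param evokedM50 Age-invariant evoked-response amplitude.
#' @return A named list of trend parameters.
#' @export
cohortTrends <- function(depth = c(intercept = 0.05, slope = 0.03, sd = 0.08),
                         tilt = c(intercept = -0.90, slope = 0.05, sd = 0.08),
                         frontalDegree = c(intercept = 0.26, slope = 0.27, sd = 0.30),
                         occipitalDegree = c(intercept = 2.92, slope = 0.10, sd = 0.30),
                         otherDegree = c(intercept = 1.50, slope = 0.18, sd = 0.30),
                         burstAmplitude = 1.0, evokedM50 = 0.5) {
  list(depth = depth, tilt = tilt, frontalDegree = frontalDegree,
       occipitalDegree = occipitalDegree, otherDegree = otherDegree,
       burstAmplitude = burstAmplitude, evokedM50 = evokedM50)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic developmental cohort
#'
#' Draws per-subject ages and planted parameters from the trend
#' specification, and returns the cohort ground truth together with a
#' deterministic per-subject simulator (recordings are large, so they are
#' generated on demand rather than materialized). Per-subject seeds are
#' derived from `seed` and the subject index.
#'
#' @param nSubjects Number of subjects (>= 2).
#' @param ageRange Age range in years (within \[2, 34\]).
#' @param trendSpec Trend specification from [cohortTrends()].
#' @param paradigm [Paradigm-class]; the default is the full 42-trials-per-
#'   finger study paradigm.
#' @param fs Simulation sampling rate (Hz, default 300).
#' @param nSensors Number of triaxial sensors (default 64).
#' @param seed Integer master seed.
#' @param connectivity Simulate the 78-region coupled network (default TRUE).
#' @param nRegions Number of parcellation regions.
#' @param plantArtifacts Plant bad channels and high-variance trials per
#'   subject (default TRUE).
#' @param snr Sensor signal-to-noise ratio for the sensorimotor source.
#' @param regionAmplitude Amplitude of the region network sources (source
#'   units); kept below the burst source so that sensorimotor beta dominates
#'   its neighbourhood, as in task data.
#' @return List with `groundTruth` (data.frame, one row per subject),
#'   `parcellation`, `headModel`, `dipolePos`, `paradigm`, `fs`, and
#'   `simulate(i)` returning the i-th subject's [Recording-class].
#' @export
makeCohort <- function(nSubjects = 30, ageRange = c(2, 34),
                       trendSpec = cohortTrends(), paradigm = makeParadigm(),
                       fs = 300, nSensors = 64, seed = 1,
                       connectivity = TRUE, nRegions = 78,
                       plantArtifacts = TRUE, snr = 1,
                       regionAmplitude = 0.25) {
  if (nSubjects < 2) stop("need at least 2 subjects")
  if (ageRange[1] < 2 || ageRange[2] > 34) stop("ages must lie within [2, 34]")
  if (diff(range(ageRange)) == 0) {
    opmMsg("degenerate age range: all subjects share one age")
  }
  headModel <- makeHeadModel()
  parc <- makeParcellation(nRegions, headModel = headModel)
  dipolePos <- c(-0.033, -0.010, 0.049)
  dipolePos <- dipolePos / sqrt(sum(dipolePos^2)) * 0.06
  nGroup <- table(parc@groups)
  lin <- function(p, age, noise) p[["intercept"]] + p[["slope"]] * age + noise
  gt <- withSeed(seed, {
    ages <- sort(runif(nSubjects, ageRange[1], ageRange[2]))
    data.frame(
      subjectId = sprintf("sub%02d", seq_len(nSubjects)),
      age = ages,
      seed = vapply(seq_len(nSubjects), function(i) childSeed(seed, i), 1L),
      depth = clip(lin(trendSpec$depth, ages,
                       rnorm(nSubjects, 0, trendSpec$depth[["sd"]])), 0, 1),
      tilt = clip(lin(trendSpec$tilt, ages,
                      rnorm(nSubjects, 0, trendSpec$tilt[["sd"]])), -0.9, 0.9),
      burstAmplitude = rep(trendSpec$burstAmplitude, nSubjects),
      evokedM50 = rep(trendSpec$evokedM50, nSubjects),
      degreeFrontal = pmax(lin(trendSpec$frontalDegree, ages,
                               rnorm(nSubjects, 0, trendSpec$frontalDegree[["sd"]])), 0),
      degreeOccipital = pmax(lin(trendSpec$occipitalDegree, ages,
                                 rnorm(nSubjects, 0, trendSpec$occipitalDegree[["sd"]])), 0),
      degreeOther = pmax(lin(trendSpec$otherDegree, ages,
                             rnorm(nSubjects, 0, trendSpec$otherDegree[["sd"]])), 0)
    )
  })
  # planted pairwise envelope correlation per group: degree target spread
  # over the (n_g - 1) within-group partners
  gt$rhoFrontal <- clip(gt$degreeFrontal / max(nGroup[["frontal"]] - 1, 1), 0, 0.9)
  gt$rhoOccipital <- clip(gt$degreeOccipital / max(nGroup[["occipital"]] - 1, 1), 0, 0.9)
  gt$rhoOther <- clip(gt$degreeOther / max(nGroup[["other"]] - 1, 1), 0, 0.9)
  duration <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5

  simulate <- function(i) {
    stopifnot(i >= 1, i <= nSubjects)
    sseed <- gt$seed[i]
    sensors <- makeSensorArray(nSensors, headRadius = headModel@radius,
                               seed = childSeed(sseed, 1))
    bgt <- burstGroundTruth(modulationDepth = gt$depth[i],
                            spectralTilt = gt$tilt[i],
                            burstAmplitude = gt$burstAmplitude[i])
    bursts <- simulateBurstTrain(paradigm, bgt, duration,
                                 seed = childSeed(sseed, 2))
    src <- synthesizeSource(bursts, bgt, fs, duration, paradigm = paradigm,
                            evokedAmp = gt$evokedM50[i],
                            seed = childSeed(sseed, 3))
    positions <- matrix(dipolePos, 1)
    moments <- matrix(tangentialMoment(dipolePos, headModel), 1)
    S <- matrix(src, 1)
    if (connectivity) {
      rho <- list(frontal = gt$rhoFrontal[i], occipital = gt$rhoOccipital[i],
                  other = gt$rhoOther[i])
      reg <- simulateRegionSources(parc, rho, length(src), fs,
                                   amplitude = regionAmplitude,
                                   seed = childSeed(sseed, 4))
      S <- rbind(S, reg)
      positions <- rbind(positions, parc@centroids)
      moments <- rbind(moments, t(apply(parc@centroids, 1, tangentialMoment,
                                        headModel = headModel)))
    }
    G <- sourceGain(positions, moments, sensors, headModel)
    # SNR is referenced to the sensorimotor source alone
    smRms <- mean(sqrt(rowMeans((G[, 1, drop = FALSE] %*% S[1, , drop = FALSE])^2)))
    ns <- noiseSpec(whiteSd = if (snr > 0) smRms / snr else 0)
    if (plantArtifacts) {
      nc <- nChannels(sensors)
      nTr <- length(paradigm@onsets)
      picks <- withSeed(childSeed(sseed, 5), {
        ch <- sample.int(nc, 2)
        # short paradigms get one planted bad trial: two >=5 sigma outliers
        # among few trials inflate the rejection threshold past both
        tr <- sample.int(nTr, if (nTr >= 40) 2 else 1)
        list(ch = ch, tr = tr)
      })
      ns$flatChannels <- picks$ch[1]
      ns$noisyChannels <- picks$ch[2]
      ns$badTrials <- picks$tr
    }
    rec <- projectToSensors(S, G, sensors, fs, noise = ns,
                            paradigm = paradigm,
                            subjectId = gt$subjectId[i], age = gt$age[i],
                            seed = childSeed(sseed, 6))
    attr(rec, "bursts") <- bursts
    rec
  }

  list(groundTruth = gt, parcellation = parc, headModel = headModel,
       dipolePos = dipolePos, paradigm = paradigm, fs = fs,
       nSensors = nSensors, snr = snr, connectivity = connectivity,
       plantArtifacts = plantArtifacts, seed = seed, simulate = simulate)
}
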