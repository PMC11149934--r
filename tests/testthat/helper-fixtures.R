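# Lazily built, cached fixtures shared across test files.
.fx <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

smallArray <- function() getFixture("arr16", function() makeSensorArray(16))

smallHead <- function() makeHeadModel()

# Small synthetic recording: one tangential burst source, 24 sensors.
smallSourceRecording <- function(seed = 3, depth = 0.8, snr = 3,
                                 nTrialsPerFinger = 8, connectivity = FALSE) {
  key <- paste("rec", seed, depth, snr, nTrialsPerFinger, connectivity,
               sep = "_")
  getFixture(key, function() {
    hm <- makeHeadModel()
    paradigm <- makeParadigm(nTrialsPerFinger = nTrialsPerFinger)
    dip <- c(-0.033, -0.010, 0.049)
    dip <- dip / sqrt(sum(dip^2)) * 0.06
    arr <- makeSensorArray(24)
    gt <- burstGroundTruth(modulationDepth = depth)
    dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
    bt <- simulateBurstTrain(paradigm, gt, dur, seed = seed)
    src <- synthesizeSource(bt, gt, 300, dur, paradigm = paradigm,
                            evokedAmp = 0.5, seed = seed + 1)
    G <- sourceGain(matrix(dip, 1),
                    matrix(opmbeta:::tangentialMoment(dip, hm), 1), arr, hm)
    rec <- projectToSensors(matrix(src, 1), G, arr, 300,
                            noise = noiseSpec(snr = snr),
                            paradigm = paradigm, seed = seed + 2)
    list(recording = rec, bursts = bt, source = src, dipole = dip,
         headModel = hm, paradigm = paradigm, groundTruth = gt)
  })
}

# A VirtualElectrode wrapping an arbitrary signal with a trial structure.
veFromSignal <- function(signal, fs, onsets,
                         fingers = rep(c("D2", "D5"), length.out = length(onsets))) {
  new("VirtualElectrode", signal = signal, fs = fs, voxel = c(0, 0, 0),
      band = numeric(0), onsets = onsets, fingers = fingers)
}

# Epoch set with exactly specified per-trial variances (single channel).
epochsWithVariance <- function(vars, n = 200, fs = 100) {
  nt <- length(vars)
  E <- array(0, c(nt, 1, n))
  for (k in seq_len(nt)) {
    x <- sin(2 * pi * 7 * (seq_len(n) + 13 * k) / fs) + 0.3 * cos(seq_len(n) * k)
    x <- x - mean(x)
    E[k, 1, ] <- x / sd(x) * sqrt(vars[k])
  }
  new("EpochSet", data = E, fs = fs, window = c(0, n / fs),
      time = (seq_len(n) - 1) / fs,
      fingers = rep("D2", nt), trialKeep = rep(TRUE, nt),
      channelLabels = "ch1", onsets = seq_len(nt) * 10)
}
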