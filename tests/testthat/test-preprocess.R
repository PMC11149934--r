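makeTestRecording <- function(X, fs = 300, ...) {
  ns <- nrow(X) / 3
  stopifnot(ns == round(ns))
  big <- makeSensorArray(max(4, ns))
  arr <- new("SensorArray",
             positions = big@positions[seq_len(ns), , drop = FALSE],
             orientations = big@orientations[seq_len(3 * ns), , drop = FALSE],
             labels = big@labels[seq_len(3 * ns)],
             sensorIndex = big@sensorIndex[seq_len(3 * ns)])
  paradigm <- makeParadigm(nTrialsPerFinger = 2)
  new("Recording", data = X, fs = fs, sensors = arr, paradigm = paradigm,
      subjectId = "t", age = 10, channelKeep = rep(TRUE, nrow(X)),
      channelReason = character(0), provenance = list())
}

test_that("flat and high-power channels are flagged; identical channels are not", {
  set.seed(1)
  n <- 300 * 12
  X <- matrix(rnorm(63 * n), 63, n)
  X[14, ] <- 0                       # flat
  X[40, ] <- rnorm(n, sd = 10)       # 10x noise
  rec <- detectBadChannels(makeTestRecording(X))
  expect_equal(sort(unname(which(!rec@channelKeep))), c(14L, 40L))
  expect_equal(unname(rec@channelReason[rec@sensors@labels[14]]), "flat")
  expect_equal(unname(rec@channelReason[rec@sensors@labels[40]]), "noisy")
  # identical channels: none flagged
  X2 <- matrix(rep(rnorm(n), 12), 12, n, byrow = TRUE)
  rec2 <- detectBadChannels(makeTestRecording(X2))
  expect_true(all(rec2@channelKeep))
  expect_error(detectBadChannels(makeTestRecording(X[, 1:600])), "10 s")
})

test_that("filters meet the notch and passband contracts", {
  fs <- 1200
  t <- (1:(fs * 12)) / fs
  tone <- function(f) sin(2 * pi * f * t)
  X <- rbind(tone(50), tone(20), tone(100), rep(1, length(t)) + tone(20),
             tone(150), tone(60))
  rec <- applyFilters(makeTestRecording(X, fs = fs))
  mid <- seq(2 * fs, 10 * fs)  # avoid edges
  amp <- function(ch) sqrt(2) * sd(rec@data[ch, mid])  # RMS-based amplitude
  expect_lt(amp(1), 0.01)            # 50 Hz residual <= 1%
  expect_equal(amp(2), 1, tolerance = 0.02)  # 20 Hz preserved within 2%
  expect_lt(amp(3), 0.01)            # first harmonic
  expect_lt(amp(5), 0.01)            # second harmonic
  expect_equal(amp(6), 1, tolerance = 0.02)  # 60 Hz passes between notches
  # DC removed by the 1 Hz high-pass edge
  expect_lt(abs(mean(rec@data[4, mid])), 0.01)
  expect_equal(max(abs(rec@data[4, mid])), 1, tolerance = 0.02)
})

test_that("low sampling rates clip the band edge with a warning", {
  set.seed(2)
  X <- matrix(rnorm(6 * 3000), 6, 3000)
  expect_warning(rec <- applyFilters(makeTestRecording(X, fs = 300)),
                 "clipped")
  expect_equal(rec@provenance$filters$band[2], 135)
  expect_false(150 %in% rec@provenance$filters$notch)
})

test_that("zero-phase filtering is idempotent in the passband", {
  fs <- 1200
  t <- (1:(fs * 10)) / fs
  X <- matrix(sin(2 * pi * 20 * t) + 0.5 * sin(2 * pi * 80 * t), 3,
              length(t), byrow = TRUE)
  r1 <- applyFilters(makeTestRecording(X, fs = fs))
  r2 <- applyFilters(r1)
  mid <- seq(fs, 9 * fs)
  expect_equal(r2@data[1, mid], r1@data[1, mid], tolerance = 0.02)
})

test_that("homogeneous field correction is an exact projector", {
  arr <- makeSensorArray(16)
  S <- arr@orientations
  n <- 400
  a <- matrix(rnorm(3 * n), 3, n)
  hom <- S %*% a                      # pure homogeneous field
  recH <- makeTestRecording(hom)
  outH <- homogeneousFieldCorrection(recH)
  expect_lt(max(abs(outH@data)), 1e-10 * max(abs(hom)))
  # component orthogonal to the columns of S passes unchanged
  X <- matrix(rnorm(48 * n), 48, n)
  P <- diag(48) - S %*% solve(crossprod(S), t(S))
  orth <- P %*% X
  outO <- homogeneousFieldCorrection(makeTestRecording(orth))
  expect_equal(outO@data, orth, tolerance = 1e-10)
  # random input: residual homogeneous content below 1e-8 of the input
  outR <- homogeneousFieldCorrection(makeTestRecording(X))
  expect_lt(norm(crossprod(S, outR@data), "F"), 1e-8 * norm(X, "F"))
  # applying twice equals applying once
  outRR <- homogeneousFieldCorrection(outR)
  expect_equal(outRR@data, outR@data, tolerance = 1e-10)
})

test_that("epoching follows the half-open window convention", {
  fs <- 300
  paradigm <- makeParadigm()  # 84 onsets, leadIn 1 s
  dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
  arr <- makeSensorArray(4)
  X <- matrix(rnorm(12 * round(dur * fs)), 12)
  rec <- new("Recording", data = X, fs = fs, sensors = arr,
             paradigm = paradigm, subjectId = "t", age = 5,
             channelKeep = rep(TRUE, 12), channelReason = character(0),
             provenance = list())
  ep <- epochRecording(rec)
  expect_equal(dim(ep@data), c(84L, 12L, 1050L))  # [-0.5, 3.0) at 300 Hz
  expect_equal(ep@time[1], -0.5)
  # truncated recording drops the last (partial) epoch
  rec2 <- rec
  rec2@data <- X[, 1:(ncol(X) - 400)]
  ep2 <- epochRecording(rec2)
  expect_equal(dim(ep2@data)[1], 83L)
  # no onsets is an error
  rec3 <- rec
  rec3@paradigm@onsets <- numeric(0)
  rec3@paradigm@fingers <- character(0)
  expect_error(epochRecording(rec3), "no onsets")
})

test_that("high-variance trial rejection matches the 3-SD single-pass rule", {
  # 84 trials: 83 at variance 1.0, one at 5.0 -> threshold 2.357, removed
  ep <- epochsWithVariance(c(rep(1, 83), 5))
  out <- rejectHighVarianceTrials(ep)
  expect_equal(which(!out@trialKeep), 84L)
  v <- attr(out, "trialVariance")
  expect_equal(mean(v) + 3 * sd(v), 2.357, tolerance = 1e-3)
  # 5 trials: 4 at 1.0, one at 2.0 -> threshold 2.542, none removed
  ep2 <- epochsWithVariance(c(rep(1, 4), 2))
  out2 <- rejectHighVarianceTrials(ep2)
  expect_true(all(out2@trialKeep))
  # identical variances: none removed
  ep3 <- epochsWithVariance(rep(1, 10))
  expect_true(all(rejectHighVarianceTrials(ep3)@trialKeep))
  expect_error(rejectHighVarianceTrials(epochsWithVariance(rep(1, 4))),
               "at least 5")
})

test_that("planted bad channels and trials are recovered exactly on synthetic data", {
  for (seed in c(21, 22, 23)) {
    fx <- fixtureCohort(seed = seed, nSensors = 16, connectivity = FALSE)
    for (i in c(1, 4)) {
      rec <- fx$recordings[[i]]
      planted <- fx$plantedBad[[i]]
      pre <- suppressWarnings(preprocess(rec))
      expect_equal(sort(unname(which(!pre$recording@channelKeep))),
                   sort(c(planted$flat, planted$noisy)))
      expect_equal(sort(which(!pre$epochs@trialKeep)), sort(planted$trials))
    }
  }
})
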