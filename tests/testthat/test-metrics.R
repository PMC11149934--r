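test_that("the Hilbert envelope recovers tone amplitudes and beats", {
  fs <- 300
  t <- seq(0, 20, by = 1 / fs)
  mid <- seq(2 * fs, 18 * fs)
  env <- hilbertEnvelope(2 * sin(2 * pi * 20 * t), c(13, 30), fs)
  expect_true(all(abs(env[mid] - 2) < 0.02))  # within 1% of amplitude 2
  # two tones at 19 and 21 Hz beat between ~0 and ~2 at 2 Hz
  envB <- hilbertEnvelope(sin(2 * pi * 19 * t) + sin(2 * pi * 21 * t),
                          c(13, 30), fs)
  expect_gt(max(envB[mid]), 1.9)
  expect_lt(min(envB[mid]), 0.1)
  # envelope is 2|cos(2 pi t)|: above half-maximum two thirds of the time
  expect_equal(mean(envB[mid] > 1), 2 / 3, tolerance = 0.05)
  expect_error(hilbertEnvelope(t, c(13, 200), fs), "Nyquist")
})

test_that("band-passed white noise has a Rayleigh-mean envelope", {
  set.seed(3)
  fs <- 300
  x <- rnorm(fs * 200)
  xb <- opmbeta:::bandFilter(x, c(13, 30), fs)
  env <- Mod(opmbeta:::analyticSignal(xb))
  expect_equal(mean(env), sd(xb) * sqrt(pi / 2), tolerance = 0.02)
})

test_that("TFS of stationary input is near zero and scale-invariant", {
  set.seed(4)
  fs <- 300
  paradigm <- makeParadigm(nTrialsPerFinger = 40)  # 80 trials
  dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
  sig <- rnorm(dur * fs)
  ve <- veFromSignal(sig, fs, paradigm@onsets, paradigm@fingers)
  tfs <- computeTFS(ve, centres = seq(4, 44, by = 4))
  # no systematic modulation: grand mean near zero, samples within their
  # own Rayleigh sampling envelope (CV / sqrt(nTrials) = 0.058)
  expect_lt(abs(mean(tfs$tfs)), 0.05)
  expect_lt(max(abs(tfs$tfs)), 6 * 0.52 / sqrt(80))
  # baseline-window mean is zero in every band by construction
  base <- tfs$time >= 2.5 & tfs$time < 3.0
  expect_lt(max(abs(rowMeans(tfs$tfs[, base]))), 1e-10)
  ve2 <- veFromSignal(2 * sig, fs, paradigm@onsets, paradigm@fingers)
  tfs2 <- computeTFS(ve2, centres = seq(4, 44, by = 4))
  expect_equal(tfs2$tfs, tfs$tfs, tolerance = 1e-10)
})

test_that("planted beta suppression appears in the TFS at the planted depth", {
  set.seed(5)
  fs <- 300
  paradigm <- makeParadigm(nTrialsPerFinger = 40)
  dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  beta <- opmbeta:::bandFilter(rnorm(n), c(15, 28), fs)
  gate <- rep(1, n)
  for (on in paradigm@onsets) gate[t >= on & t < on + 0.8] <- 0.5
  ve <- veFromSignal(beta * gate, fs, paradigm@onsets, paradigm@fingers)
  tfs <- computeTFS(ve, centres = c(15, 21, 27, 35))
  stim <- tfs$time >= 0.3 & tfs$time < 0.7
  betaRows <- tfs$centres %in% c(21)
  expect_equal(mean(tfs$tfs[betaRows, stim]), -0.5, tolerance = 0.1)
})

test_that("the beta modulation index follows its defining formula", {
  expect_equal(betaModIndex(0.5, 1.5, 1.0), 1.0)
  expect_equal(betaModIndex(0.7, 0.7, 2.0), 0)
  expect_error(betaModIndex(1, 1, 0), "positive")
  # scale invariance of the VE-level index
  set.seed(6)
  fs <- 300
  paradigm <- makeParadigm(nTrialsPerFinger = 10)
  dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
  sig <- rnorm(dur * fs)
  b1 <- betaModulationIndex(veFromSignal(sig, fs, paradigm@onsets))
  b2 <- betaModulationIndex(veFromSignal(5 * sig, fs, paradigm@onsets))
  expect_equal(b1$betamod, b2$betamod, tolerance = 1e-12)
})

test_that("estimated beta modulation is monotone in the planted depth", {
  fs <- 300
  paradigm <- makeParadigm()
  dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
  for (seed in 1:5) {
    bm <- vapply(c(0, 0.3, 0.6), function(d) {
      gt <- burstGroundTruth(modulationDepth = d)
      bt <- simulateBurstTrain(paradigm, gt, dur, seed = seed * 100 + round(d * 10))
      src <- synthesizeSource(bt, gt, fs, dur, seed = seed * 200 + round(d * 10))
      betaModulationIndex(veFromSignal(src, fs, paradigm@onsets))$betamod
    }, numeric(1))
    expect_equal(cor(bm, c(0, 0.3, 0.6), method = "spearman"), 1)
  }
})

test_that("the M50 is read from the trial-averaged evoked response", {
  fs <- 300
  paradigm <- makeParadigm(nTrialsPerFinger = 20)
  dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
  n <- round(dur * fs)
  # zero data -> zero M50
  ev0 <- evokedM50(veFromSignal(numeric(n), fs, paradigm@onsets))
  expect_equal(ev0$m50, 0)
  # planted Gaussian bump at 50 ms recovered within 10%
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  for (on in paradigm@onsets) {
    sig <- sig + 0.8 * exp(-(t - on - 0.05)^2 / (2 * 0.01^2))
  }
  ev <- evokedM50(veFromSignal(sig, fs, paradigm@onsets))
  # oracle: the same bump through the same 4-40 Hz zero-phase filter
  bump <- 0.8 * exp(-(t - 10 - 0.05)^2 / (2 * 0.01^2))
  bumpF <- opmbeta:::bandFilter(bump, c(4, 40), fs)
  expected <- bumpF[which.min(abs(t - 10.05))]
  expect_equal(ev$m50, expected, tolerance = 0.02)
  expect_equal(ev$m50, 0.8, tolerance = 0.3)  # distortion stays bounded
  # peak-in-window variant finds the same deflection
  evP <- evokedM50(veFromSignal(sig, fs, paradigm@onsets),
                   peakWindow = c(0.03, 0.07))
  expect_gte(abs(evP$m50), abs(ev$m50) - 1e-9)
})

test_that("non-phase-locked activity averages out of the evoked response", {
  fs <- 300
  paradigm <- makeParadigm(nTrialsPerFinger = 100)  # 200 trials
  dur <- paradigm@leadIn + paradigmDuration(paradigm) + 0.5
  gt <- burstGroundTruth(modulationDepth = 0)
  bt <- simulateBurstTrain(paradigm, gt, dur, seed = 31)
  src <- synthesizeSource(bt, gt, fs, dur, seed = 32)  # no evoked component
  ve <- veFromSignal(src, fs, paradigm@onsets)
  ev <- evokedM50(ve)
  ep <- veEpochs(ve, signal = opmbeta:::bandFilter(ve@signal, c(4, 40), ve@fs))
  i50 <- which.min(abs(ep$time - 0.05))
  se <- sd(ep$data[, i50]) / sqrt(nrow(ep$data))
  expect_lt(abs(ev$m50), 3 * se)
})
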