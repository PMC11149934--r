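test_that("burst-train rates match their planted values across a (rate, d) grid", {
  paradigm <- makeParadigm(nTrialsPerFinger = 25)
  dur <- 200
  frac <- sum(pmin(paradigm@onsets + 0.8, dur) -
                pmin(paradigm@onsets, dur)) / dur  # window time fraction
  for (rate in c(0.5, 2)) {
    for (d in c(0, 0.5)) {
      gt <- burstGroundTruth(baselineRate = rate, modulationDepth = d)
      bt <- simulateBurstTrain(paradigm, gt, dur, seed = 1000 + 10 * rate + d)
      expected <- rate * (1 - d * frac) * dur
      expect_lt(abs(nrow(bt) - expected), 3 * sqrt(expected))
    }
  }
})

test_that("d = 1 silences the stimulus windows and bursts never overlap", {
  paradigm <- makeParadigm()
  gt <- burstGroundTruth(modulationDepth = 1)
  bt <- simulateBurstTrain(paradigm, gt, 295, seed = 2)
  inWin <- opmbeta:::inAnyWindow(bt$onset, opmbeta:::stimWindows(paradigm))
  expect_equal(sum(inWin), 0L)
  expect_true(all(diff(bt$onset) >= bt$duration[-nrow(bt)]))
  expect_error(burstGroundTruth(modulationDepth = 1.2), "\\[0, 1\\]")
})

test_that("d = 0.5 halves the stimulus-window burst rate", {
  paradigm <- makeParadigm(nTrialsPerFinger = 900, restDuration = 3.0)
  gt <- burstGroundTruth(baselineRate = 1, modulationDepth = 0.5)
  dur <- max(paradigm@onsets) + 3.5
  bt <- simulateBurstTrain(paradigm, gt, dur, seed = 7)
  win <- opmbeta:::stimWindows(paradigm)
  inWin <- opmbeta:::inAnyWindow(bt$onset, win)
  tWin <- 0.8 * nrow(win)
  rateWin <- sum(inWin) / tWin
  rateRest <- sum(!inWin) / (dur - tWin)
  ratio <- rateWin / rateRest
  # binomial sampling error on the window counts
  se <- 0.5 * sqrt(1 / sum(inWin) + 1 / sum(!inWin))
  expect_lt(abs(ratio - 0.5), 3 * se)
})

test_that("degenerate source synthesis returns the noise floor", {
  gt <- burstGroundTruth(burstAmplitude = 0, alphaPeakAmp = 0,
                         floorSigma = 0.2)
  paradigm <- makeParadigm(nTrialsPerFinger = 4)
  bt <- simulateBurstTrain(paradigm, gt, 300, seed = 3)
  src <- synthesizeSource(bt, gt, 300, 300, seed = 4)
  expect_equal(var(src), 0.04, tolerance = 0.05)
  # empty burst train is allowed
  empty <- data.frame(onset = numeric(0), duration = numeric(0))
  src0 <- synthesizeSource(empty, gt, 300, 10, seed = 5)
  expect_equal(length(src0), 3000L)
})

test_that("spectral tilt shifts in-burst power from low to high frequencies, sparing alpha", {
  fs <- 300
  inBurstPSD <- function(tilt, seed) {
    gt <- burstGroundTruth(modulationDepth = 0, spectralTilt = tilt)
    paradigm <- makeParadigm(nTrialsPerFinger = 2)
    bt <- simulateBurstTrain(paradigm, gt, 120, seed = seed)
    src <- synthesizeSource(bt, gt, fs, 120, seed = seed + 1)
    tt <- (seq_along(src) - 1) / fs
    inb <- opmbeta:::inAnyWindow(tt, cbind(start = bt$onset,
                                           end = bt$onset + bt$duration))
    seg <- as.integer(2 * fs)
    starts <- opmbeta:::mtWindowStarts(length(src), seg)
    w <- vapply(starts, function(s) mean(inb[s:(s + seg - 1)]), numeric(1))
    multitaperPSD(src, fs, weights = w, fmax = 48)
  }
  young <- inBurstPSD(-0.8, seed = 11)
  old <- inBurstPSD(0.8, seed = 21)
  at <- function(est, f) est$psd[which.min(abs(est$freq - f))]
  expect_gt(at(young, 3), at(old, 3))
  expect_gt(at(old, 37), at(young, 37))
  # tilt monotonicity of the high/low power ratio
  mid <- inBurstPSD(0, seed = 31)
  ratios <- c(at(young, 37) / at(young, 3), at(mid, 37) / at(mid, 3),
              at(old, 37) / at(old, 3))
  expect_true(all(diff(ratios) > 0))
})

test_that("alpha-anchor power is uncorrelated with the planted tilt", {
  fs <- 300
  taus <- seq(-0.85, 0.85, length.out = 30)
  p9 <- vapply(seq_along(taus), function(i) {
    gt <- burstGroundTruth(modulationDepth = 0, spectralTilt = taus[i])
    paradigm <- makeParadigm(nTrialsPerFinger = 2)
    bt <- simulateBurstTrain(paradigm, gt, 60, seed = 500 + i)
    src <- synthesizeSource(bt, gt, fs, 60, seed = 600 + i)
    tt <- (seq_along(src) - 1) / fs
    inb <- opmbeta:::inAnyWindow(tt, cbind(start = bt$onset,
                                           end = bt$onset + bt$duration))
    seg <- as.integer(2 * fs)
    starts <- opmbeta:::mtWindowStarts(length(src), seg)
    w <- vapply(starts, function(s) mean(inb[s:(s + seg - 1)]), numeric(1))
    est <- multitaperPSD(src, fs, weights = w, fmax = 48)
    est$psd[which.min(abs(est$freq - 9))]
  }, numeric(1))
  expect_lt(abs(cor(taus, p9)), 0.35)
})

test_that("sensor projection is linear and homogeneous drift spans the orientation space", {
  fx <- smallSourceRecording()
  arr <- fx$recording@sensors
  G <- sourceGain(matrix(fx$dipole, 1),
                  matrix(opmbeta:::tangentialMoment(fx$dipole, fx$headModel), 1),
                  arr, fx$headModel)
  s <- matrix(sin(2 * pi * 5 * (1:600) / 300), 1)
  quiet <- noiseSpec(whiteSd = 0, lineFreqs = numeric(0), driftAmp = 0)
  r1 <- projectToSensors(s, G, arr, 300, noise = quiet, seed = 1)
  r3 <- projectToSensors(3 * s, G, arr, 300, noise = quiet, seed = 1)
  expect_equal(r3@data, 3 * r1@data, tolerance = 1e-12)
  # zero sources, zero noise -> all-zero recording
  r0 <- projectToSensors(0 * s, G, arr, 300, noise = quiet, seed = 1)
  expect_true(all(r0@data == 0))
  # drift-only data lie exactly in the column space of the orientations
  drift <- projectToSensors(0 * s, G, arr, 300,
                            noise = noiseSpec(whiteSd = 1e-30, lineFreqs = numeric(0),
                                              driftAmp = 1e15),
                            seed = 2)
  S <- arr@orientations
  P <- diag(nrow(S)) - S %*% solve(crossprod(S), t(S))
  resid <- P %*% drift@data
  expect_lt(max(abs(resid)) / max(abs(drift@data)), 1e-8)
  # mismatched channel counts are a dimension error
  expect_error(projectToSensors(s, G[1:10, , drop = FALSE], arr, 300),
               "channel count")
})

test_that("sensor-space variance decomposes into signal and noise parts", {
  fx <- smallSourceRecording()
  arr <- fx$recording@sensors
  G <- sourceGain(matrix(fx$dipole, 1),
                  matrix(opmbeta:::tangentialMoment(fx$dipole, fx$headModel), 1),
                  arr, fx$headModel)
  s <- matrix(fx$source[1:15000], 1)
  w <- mean(sqrt(rowMeans((G %*% s)^2)))  # whiteSd at snr 1
  full <- projectToSensors(s, G, arr, 300, noise = noiseSpec(whiteSd = w),
                           seed = 9)
  noiseOnly <- projectToSensors(0 * s, G, arr, 300,
                                noise = noiseSpec(whiteSd = w), seed = 9)
  sigOnly <- projectToSensors(s, G, arr, 300,
                              noise = noiseSpec(whiteSd = 0,
                                                lineFreqs = numeric(0),
                                                driftAmp = 0), seed = 9)
  # identical seed: the noise realization is shared, so parts add exactly;
  # variance additivity then holds to the signal-noise cross-term
  expect_equal(full@data, noiseOnly@data + sigOnly@data, tolerance = 1e-10)
  vFull <- mean(apply(full@data, 1, var))
  vParts <- mean(apply(noiseOnly@data, 1, var)) +
    mean(apply(sigOnly@data, 1, var))
  expect_equal(vFull, vParts, tolerance = 0.02)
})

test_that("cohort ground truth follows the planted age trends", {
  trends <- cohortTrends(depth = c(intercept = 0.05, slope = 0.03, sd = 0))
  cohort <- makeCohort(nSubjects = 10, trendSpec = trends, seed = 4,
                       connectivity = FALSE)
  gt <- cohort$groundTruth
  expect_true(all(diff(gt$age) >= 0))
  expect_true(all(diff(gt$depth) >= 0))  # noise-free trend is monotone in age
  expect_true(all(gt$depth >= 0 & gt$depth <= 1))
  expect_true(all(gt$burstAmplitude == gt$burstAmplitude[1]))  # age-invariant
  # zero slopes make parameters age-independent
  flat <- cohortTrends(depth = c(intercept = 0.4, slope = 0, sd = 0),
                       tilt = c(intercept = 0.1, slope = 0, sd = 0))
  c2 <- makeCohort(nSubjects = 5, trendSpec = flat, seed = 4,
                   connectivity = FALSE)
  expect_equal(var(c2$groundTruth$depth), 0)
  expect_equal(var(c2$groundTruth$tilt), 0)
  # default frontal degree trend is steeper than occipital
  def <- cohortTrends()
  expect_gt(def$frontalDegree[["slope"]], def$occipitalDegree[["slope"]])
  expect_error(makeCohort(nSubjects = 1), "at least 2")
  expect_error(makeCohort(nSubjects = 3, ageRange = c(0.5, 10)),
               "\\[2, 34\\]")
})

test_that("coupled pairs carry the planted envelope correlation", {
  pair <- makeCoupledEnvelopePair(30000, 300, rho = 0.6, seed = 8)
  expect_equal(cor(pair$envx, pair$envy), 0.6, tolerance = 0.1)
})
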