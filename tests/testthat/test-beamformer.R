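test_that("Tikhonov regularization shifts all eigenvalues by 5% of the largest", {
  cm <- covarianceFromMatrix(diag(c(10, 1)))
  expect_equal(sort(eigen(cm@Creg)$values), c(1.5, 10.5))
  cm2 <- covarianceFromMatrix(diag(3))
  expect_equal(cm2@Creg, 1.05 * diag(3))
})

test_that("white-noise covariance is close to identity", {
  set.seed(5)
  n <- 12000
  arr <- makeSensorArray(4)
  X <- matrix(rnorm(12 * n), 12, n)
  rec <- new("Recording", data = X, fs = 300, sensors = arr,
             paradigm = makeParadigm(nTrialsPerFinger = 2),
             subjectId = "t", age = 1, channelKeep = rep(TRUE, 12),
             channelReason = character(0), provenance = list())
  cm <- regularizedCovariance(rec)
  # Wishart sampling error ~ sqrt(2/n) on the diagonal
  expect_lt(max(abs(cm@cov - diag(12))), 5 * sqrt(2 / n))
  expect_error(regularizedCovariance({
    rec2 <- rec; rec2@data[1, 1] <- NA; rec2
  }), "finite|data")
})

test_that("LCMV satisfies unit gain at every localizable voxel", {
  set.seed(6)
  hm <- makeHeadModel()
  arr <- smallArray()
  grid <- makeSourceGrid(0.02, hm)
  lf <- computeLeadField(grid, arr, hm)
  C <- crossprod(matrix(rnorm(48 * 300), 300, 48)) / 300
  bw <- lcmvWeightsGrid(lf, covarianceFromMatrix(C))
  gains <- vapply(which(bw@localizable), function(v) {
    Lv <- lf@L[, (2 * v - 1):(2 * v)]
    tb <- lf@tangentBasis[(2 * v - 1):(2 * v), ]
    etaT <- drop(tb %*% bw@eta[v, ])  # orientation back in tangential coords
    sum(bw@W[, v] * (Lv %*% etaT))
  }, numeric(1))
  expect_lt(max(abs(gains - 1)), 1e-8)
})

test_that("LCMV matches closed forms and a constrained-QP oracle", {
  set.seed(7)
  # C = I, fixed orientation: w = L eta / ||L eta||^2
  l <- rnorm(6)
  cmI <- covarianceFromMatrix(diag(6), mu = 0)
  fitI <- lcmvWeights(matrix(l, ncol = 1), cmI)
  expect_equal(fitI$w, l / sum(l^2), tolerance = 1e-12)
  # random 6-channel instances vs explicit constrained minimization
  for (rep in 1:20) {
    L <- matrix(rnorm(12), 6, 2)
    C <- crossprod(matrix(rnorm(60), 10, 6)) / 10 + 0.1 * diag(6)
    cm <- covarianceFromMatrix(C)
    fit <- lcmvWeights(L, cm)
    le <- drop(L %*% fit$eta)
    # oracle: minimize w' C_reg w subject to w' (L eta) = 1
    wOracle <- solve(cm@Creg, le) / drop(crossprod(le, solve(cm@Creg, le)))
    expect_lt(max(abs(fit$w - wOracle)), 1e-8)
    # the returned orientation maximizes output power over all orientations
    theta <- seq(0, pi, length.out = 1801)
    M <- crossprod(L, solve(cm@Creg, L))
    pow <- 1 / (cos(theta)^2 * M[1, 1] + 2 * cos(theta) * sin(theta) * M[1, 2] +
                  sin(theta)^2 * M[2, 2])
    expect_gte(fit$power * (1 + 1e-6), max(pow))
  }
})

test_that("pseudo-T vanishes for statistically identical windows and stays bounded", {
  set.seed(12)
  hm <- makeHeadModel()
  arr <- makeSensorArray(4)
  paradigm <- makeParadigm(nTrialsPerFinger = 40)
  n <- as.integer((paradigm@leadIn + paradigmDuration(paradigm) + 0.5) * 300)
  rec <- new("Recording", data = matrix(rnorm(12 * n), 12, n), fs = 300,
             sensors = arr, paradigm = paradigm, subjectId = "t", age = 1,
             channelKeep = rep(TRUE, 12), channelReason = character(0),
             provenance = list())
  ep <- epochRecording(rec)
  grid <- makeSourceGrid(0.02, hm)
  lf <- computeLeadField(grid, arr, hm)
  # stationary input, equal-length disjoint windows: symmetric contrast
  ptm <- pseudoTMap(rec, ep, lf, windowActive = c(-0.5, 1.25),
                    windowControl = c(1.25, 3.0))
  expect_lt(max(abs(ptm@values)), 0.05)
  expect_true(all(ptm@values >= -1 & ptm@values <= 1))
  expect_error(pseudoTMap(rec, ep, lf, windowActive = c(5, 6)), "empty")
})

test_that("a planted beta-suppressed dipole is localized on the 4 mm grid", {
  fx <- smallSourceRecording(seed = 41, depth = 0.9, snr = 3,
                             nTrialsPerFinger = 21)
  pre <- suppressWarnings(preprocess(fx$recording))
  grid <- makeSourceGrid(0.004, fx$headModel)
  lf <- computeLeadField(grid, pre$recording@sensors, fx$headModel)
  ptm <- pseudoTMap(pre$recording, pre$epochs, lf)
  expect_lt(ptm@peakValue, 0)  # suppression during stimulation
  err <- sqrt(sum((ptm@peakVoxel - fx$dipole)^2))
  expect_lt(err, 2 * grid@spacing)  # within 2 grid spacings of the dipole
})

test_that("the virtual electrode reproduces a planted source and is linear", {
  fx <- smallSourceRecording(seed = 41, depth = 0.9, snr = 3,
                             nTrialsPerFinger = 21)
  hm <- fx$headModel
  arr <- fx$recording@sensors
  G <- sourceGain(matrix(fx$dipole, 1),
                  matrix(opmbeta:::tangentialMoment(fx$dipole, hm), 1),
                  arr, hm)
  quiet <- noiseSpec(whiteSd = 0, lineFreqs = numeric(0), driftAmp = 0)
  rec <- projectToSensors(matrix(fx$source, 1), G, arr, 300, noise = quiet,
                          paradigm = fx$paradigm)
  ep <- epochRecording(rec)
  # regularize off the rank-1 covariance via mu
  ve <- virtualElectrode(rec, ep, fx$dipole, hm, mu = 0.05)
  expect_gt(abs(cor(ve@signal, fx$source)), 0.99)
  rec2 <- rec
  rec2@data <- 2 * rec@data
  ve2 <- virtualElectrode(rec2, ep, fx$dipole, hm, mu = 0.05)
  expect_equal(ve2@signal, 2 * ve@signal, tolerance = 1e-6)
  # zero data give a zero virtual electrode
  rec0 <- rec
  rec0@data[] <- 0
  cm <- covarianceFromMatrix(diag(nrow(rec0@data)))
  ve0 <- virtualElectrode(rec0, ep, fx$dipole, hm, covariance = cm)
  expect_true(all(ve0@signal == 0))
})

test_that("duplicate parcel centroids give identical region time courses", {
  fx <- smallSourceRecording()
  pre <- suppressWarnings(preprocess(fx$recording))
  parc <- new("Parcellation", labels = c("a", "b", "c"),
              centroids = rbind(c(0.02, 0.02, 0.03), c(0.02, 0.02, 0.03),
                                c(-0.03, 0, 0.04)),
              groups = c("other", "other", "other"))
  pt <- parcelTimecourses(pre$recording, pre$epochs, parc, fx$headModel)
  expect_equal(pt$ve[1, ], pt$ve[2, ], tolerance = 1e-10)
  expect_equal(nrow(pt$ve), 3L)
})
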