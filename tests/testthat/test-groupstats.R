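test_that("pearsonFit matches the closed-form covariance oracle", {
  # exact line
  f <- pearsonFit(1:10, 2 * (1:10) + 1)
  expect_equal(f$r2, 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  # hand-computed oracle on a small instance
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  n <- 4
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  r <- sxy / (sd(x) * sd(y))
  slope <- sxy / var(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), n - 2)
  f2 <- pearsonFit(x, y)
  expect_equal(f2$r, r, tolerance = 1e-12)
  expect_equal(f2$slope, slope, tolerance = 1e-12)
  expect_equal(f2$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(f2$p, p, tolerance = 1e-12)
  expect_error(pearsonFit(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonFit(1:2, 1:2), "at least 3")
})

test_that("null p-values are uniform", {
  set.seed(1)
  p <- replicate(1000, pearsonFit(rnorm(100), rnorm(100))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 1e-3)
})

test_that("within-group z-transform standardizes each group", {
  set.seed(2)
  v <- c(rnorm(10, 5), rnorm(8, -3, 4))
  g <- rep(c("child", "adult"), c(10, 8))
  z <- zscoreWithinGroups(v, g)
  for (gg in c("child", "adult")) {
    expect_lt(abs(mean(z[g == gg])), 1e-12)
    expect_lt(abs(sd(z[g == gg]) - 1), 1e-12)
  }
  # two-point group
  expect_equal(sort(zscoreWithinGroups(c(1, 3), c("a", "a"))),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # location invariance
  v2 <- v; v2[g == "child"] <- v2[g == "child"] + 100
  expect_equal(zscoreWithinGroups(v2, g), z, tolerance = 1e-10)
  expect_error(zscoreWithinGroups(c(1, 1, 2), c("a", "a", "b")), "constant|fewer")
})

test_that("degree-age slopes recover exact and noisy linear trends", {
  age <- seq(3, 33, length.out = 16)
  D <- cbind(f1 = 0.27 * age + 0.26, o1 = 0.10 * age + 2.92)
  sl <- degreeAgeSlopes(D, age)
  expect_equal(sl$slope, c(0.27, 0.10), tolerance = 1e-12)
  expect_equal(sl$region, c("f1", "o1"))
  # age-independent degree: null slope, p > 0.05 in >= 90% of seeds
  pNull <- vapply(1:20, function(s) {
    set.seed(s)
    degreeAgeSlopes(cbind(r = rnorm(16)), age)$p
  }, numeric(1))
  expect_gte(mean(pNull > 0.05), 0.9)
  # unbiased slope under age-independent noise
  slopes <- vapply(1:100, function(s) {
    set.seed(100 + s)
    degreeAgeSlopes(cbind(r = 0.2 * age + rnorm(16, 0, 0.5)), age)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(100)
  expect_lt(abs(mean(slopes) - 0.2), 2 * se)
})

test_that("the PSD-age sweep flags planted trends and spares stable bands", {
  freq <- c(3, 9, 37)
  age <- seq(2, 34, length.out = 24)
  flagged9 <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    psd <- cbind(10 - 0.15 * age + rnorm(24, 0, 0.8),   # low f decreases
                 5 + rnorm(24, 0, 0.8),                 # alpha stable
                 1 + 0.05 * age + rnorm(24, 0, 0.3))    # high f increases
    pa <- psdAgeCorrelation(psd, age, freq)
    if (s == 1) {
      expect_lt(pa$r[1], 0)
      expect_gt(pa$r[3], 0)
    }
    flagged9[s] <- pa$flagged[2]
  }
  expect_gte(mean(!flagged9), 0.9)
  # constant PSD column is an error
  expect_error(psdAgeCorrelation(cbind(rep(1, 24)), age, 9), "constant")
})

test_that("age groups split children and adults at 18 years", {
  expect_equal(ageGroups(c(2, 17.9, 18, 34)),
               c("child", "child", "adult", "adult"))
})
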