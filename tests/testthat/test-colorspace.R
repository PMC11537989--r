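test_that("spectrometer calibration converts counts to irradiance", {
  expect_equal(irradianceFromCounts(rep(5, 3), rep(5, 3), rep(2, 3), 1, 1),
               rep(0, 3))
  i1 <- irradianceFromCounts(200, 100, 1, 1, 1)
  expect_equal(i1, 1)  # C (S - D) / (dt A 100) with unit factors
  i2 <- irradianceFromCounts(200, 100, 1, 2, 1)
  expect_equal(i2, i1 / 2)  # linear in 1/dt
  expect_error(irradianceFromCounts(1:3, 1:2, 1:3, 1, 1), "grid")
  expect_error(irradianceFromCounts(1, 0, 1, 0, 1), "integration_time")
  expect_error(irradianceFromCounts(1, 0, 1, 1, -1), "collection_area")
})

test_that("photon flux conversion matches direct formula evaluation", {
  expect_equal(photonFlux(0, 500), 0)
  # proportional to wavelength at fixed irradiance
  expect_equal(photonFlux(1, 600) / photonFlux(1, 300), 2)
  # direct scalar evaluation with the stated constants
  expected <- 1 * 500 / (2.998e8 * 6.63e-34 * 6.022e23 * 1e6)
  expect_equal(photonFlux(1, 500), expected)
  expect_error(photonFlux(-1, 500), "nonnegative")
})

test_that("opsin template peaks at lambda_max and is unimodal", {
  lam <- seq(300, 700, by = 1)
  for (lm in c(345, 437, 508)) {
    s <- opsinSensitivity(lm, lam)
    expect_equal(opsinSensitivity(lm, lm), 1)
    expect_true(all(s >= 0))
    # monotone decline moving away from the peak within +-80 nm
    up <- opsinSensitivity(lm, seq(lm, lm + 80, by = 5))
    dn <- opsinSensitivity(lm, seq(lm, lm - 80, by = -5))
    expect_true(all(diff(up) < 1e-10))
    expect_true(all(diff(dn) < 1e-10))
  }
  # full curve equals an independent pointwise evaluation of the
  # pigment-template formula
  lm <- 437
  x <- lm / lam
  a <- 0.8795 + 0.0459 * exp(-(lm - 300)^2 / 11940)
  raw <- function(xx) 1 / (exp(69.7 * (a - xx)) + exp(28 * (0.922 - xx)) +
                             exp(-14.9 * (1.104 - xx)) + 0.674)
  expect_equal(opsinSensitivity(lm, lam), pmin(raw(x) / raw(1), 1),
               tolerance = 1e-12)
})

test_that("relative captures are background-referenced and linear", {
  lam <- seq(300, 700, by = 1)
  bg <- exp(-(lam - 450)^2 / (2 * 60^2)) + 0.1
  expect_equal(unname(relativeCapture(bg, bg, lam)), rep(1, 4))
  q1 <- relativeCapture(2 * bg, bg, lam)
  expect_equal(unname(q1), rep(2, 4))
  # two Gaussian LEDs against the quadrature oracle on a 1 nm grid
  stim <- bg + exp(-(lam - 370)^2 / (2 * 10^2)) +
    0.5 * exp(-(lam - 520)^2 / (2 * 12^2))
  q <- relativeCapture(stim, bg, lam)
  peaks <- defaultOpsinPeaks()[c("Rh3", "Rh4", "Rh5", "Rh6")]
  oracle <- vapply(peaks, function(lm) {
    s <- opsinSensitivity(lm, lam)
    trapzOracle(lam, s * stim) / trapzOracle(lam, s * bg)
  }, numeric(1))
  expect_equal(unname(q), unname(oracle), tolerance = 1e-10)
  # rescaling stimulus and background together changes nothing
  expect_equal(relativeCapture(3 * stim, 3 * bg, lam), q)
})

test_that("log capture uses the stated additive offset", {
  expect_identical(logCapture(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_equal(logCapture(0), log(0.001 / 1.001))
  q <- seq(0, 4, by = 0.25)
  expect_true(all(diff(logCapture(q)) > 0))
  expect_error(logCapture(-0.1), "nonnegative")
})

test_that("chromatic/luminance decomposition is an isometry with a frozen basis", {
  # frozen basis
  B <- rbind(c(1, -1, -1, 1), c(1, -1, 1, -1), c(1, 1, -1, -1)) / 2
  expect_equal(tetrahedronBasis(), B)
  expect_equal(B %*% t(B), diag(3))
  expect_equal(drop(B %*% rep(1, 4)), rep(0, 3))
  # white axis input
  d <- decomposeLogCapture(rep(3, 4))
  expect_equal(d$x, rep(0, 3))
  expect_equal(d$l, 6)
  # orthogonal split of the norm and exact round trip
  set.seed(1)
  for (i in 1:20) {
    X <- rnorm(4)
    d <- decomposeLogCapture(X)
    expect_equal(sum(d$x^2) + d$l^2, sum(X^2))
    expect_lt(max(abs(embedChromatic(d$x, d$l) - X)), 1e-10)
  }
  # matrix form agrees with vector form
  Xm <- matrix(rnorm(12), ncol = 4)
  dm <- decomposeLogCapture(Xm)
  for (i in 1:3) {
    di <- decomposeLogCapture(Xm[i, ])
    expect_equal(unname(dm$x[i, ]), di$x)
    expect_equal(dm$l[i], di$l)
  }
  # opsin axes map to a regular tetrahedron
  V <- t(apply(diag(4), 1, function(e) decomposeLogCapture(e)$x))
  D <- as.matrix(dist(V))
  expect_equal(unname(D[upper.tri(D)]), rep(sqrt(2), 6))
  expect_equal(unname(sqrt(rowSums(V^2))), rep(sqrt(3) / 2, 4))
})

test_that("opponent projection computes the two printed axis differences", {
  expect_equal(opponentProjection(rep(0, 4)), c(0, 0))
  expect_equal(opponentProjection(c(0, 0, 0, 1)), c(1, -1))
  # swapping Rh3<->Rh4 and Rh5<->Rh6 negates only the second component
  X <- c(0.3, -0.2, 0.5, 0.1)
  Xs <- X[c(2, 1, 4, 3)]
  o <- opponentProjection(X); os <- opponentProjection(Xs)
  expect_equal(os[1], o[1])
  expect_equal(os[2], -o[2])
  # linearity
  X2 <- c(-0.1, 0.4, 0.2, -0.3)
  expect_equal(opponentProjection(2 * X + 3 * X2),
               2 * o + 3 * opponentProjection(X2))
})

test_that("hue/saturation coordinates follow the preferred direction", {
  p <- c(1, 0, 0)
  expect_equal(hueSaturation(p, p), list(s = 1, cos_theta = 1))
  expect_equal(hueSaturation(-p, p)$cos_theta, -1)
  expect_equal(hueSaturation(c(0, 1, 0), p)$cos_theta, 0)
  expect_equal(hueSaturation(c(0, 0, 0), p)$cos_theta, 0)
  expect_error(hueSaturation(p, c(1, 1, 0)), "unit")
})

test_that("stimulus sets round-trip through CSV", {
  st <- fixtureGamut(10, seed = 2, m = 3L)
  f <- tempfile(fileext = ".csv")
  writeStimulusSet(st, f)
  st2 <- readStimulusSet(f)
  expect_equal(captures(st2), captures(st), tolerance = 1e-12)
  expect_equal(obsCounts(st2), obsCounts(st))
  expect_equal(chromaticCoords(st2), chromaticCoords(st),
               tolerance = 1e-12)
})
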