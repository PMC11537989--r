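test_that("gamut sampling respects the isoluminant constraint and seed", {
  st <- sampleGamut(40, iso_total = 5, seed = 9)
  expect_lt(max(abs(rowSums(captures(st)) - 5)), 1e-9)
  expect_true(all(captures(st) >= 0))
  st2 <- sampleGamut(40, iso_total = 5, seed = 9)
  expect_identical(captures(st2), captures(st))
  # symmetric sampling has mean C/4 per opsin
  big <- sampleGamut(20000, iso_total = 5, seed = 1)
  expect_equal(unname(colMeans(captures(big))), rep(1.25, 4),
               tolerance = 0.02)
  # half-space constraints are honored
  cs <- list(list(a = c(1, 0, 0, 0), b = 1.0))
  stc <- sampleGamut(30, iso_total = 5, constraints = cs, seed = 3)
  expect_true(all(captures(stc)[, 1] <= 1.0 + 1e-9))
  expect_error(sampleGamut(5, constraints =
    list(list(a = c(1, 1, 1, 1), b = 1))), "infeasible")
})

test_that("session scheme accumulates varying observation counts", {
  m <- sessionObservationCounts(100, n_sessions = 10, seed = 4)
  expect_true(all(m >= 1))
  expect_gt(length(unique(m)), 1)
  expect_identical(m, sessionObservationCounts(100, n_sessions = 10,
                                               seed = 4))
})

test_that("max-distance subsampling is greedy over the candidate pool", {
  st <- fixtureGamut(30, seed = 11)
  expect_identical(sort(maxDistanceSubsample(st, 1, seed = 1)), 1:30)
  # three collinear points, pool 1: second pick is always the point
  # farthest from the first, whatever the first draw was
  q <- rbind(c(2, 1, 1, 1), c(1.5, 1.5, 1, 1), c(1, 2, 1, 1))
  st3 <- makeStimulusSet(q)
  x3 <- chromaticCoords(st3)
  for (seed in 1:10) {
    sel <- maxDistanceSubsample(st3, 2 / 3, pool = 1, seed = seed)
    d <- as.matrix(dist(x3))
    expect_identical(sel[2], unname(which.max(d[sel[1], ])))
  }
  # selected subsets spread out more than random ones on average
  st50 <- fixtureGamut(50, seed = 13)
  mind <- function(idx) min(dist(chromaticCoords(st50)[idx, ]))
  greedy <- mean(vapply(1:40, function(s)
    mind(maxDistanceSubsample(st50, 0.3, seed = s)), numeric(1)))
  rand <- mean(vapply(1:40, function(s) {
    set.seed(1000 + s); mind(sample.int(50, 15))
  }, numeric(1)))
  expect_gt(greedy, rand)
})

test_that("LED drive solving inverts the capture map", {
  led <- ledSystem()
  # a four-LED subsystem makes the solution unique
  led4 <- ledSystem(peaks = c(U = 375, V = 420, B = 460, L = 550),
                    widths = 15,
                    max_intensity = c(U = 7, V = 11, B = 18, L = 25),
                    background = c(U = 0.06, V = 0.1, B = 0.25, L = 0.33))
  bg_target <- rep(1, 4)
  sol <- solveLedDrive(bg_target, led4)
  expect_equal(unname(sol$drive), unname(led4$background),
               tolerance = 1e-4)
  expect_lt(sol$residual, 1e-6)
  expect_true(sol$in_gamut)
  # doubling the background mixture is recovered
  M <- flyhue:::.ledCaptureMatrix(led4)
  target2 <- drop(M %*% (2 * led4$background))
  sol2 <- solveLedDrive(target2, led4)
  expect_equal(unname(sol2$drive), unname(2 * led4$background),
               tolerance = 1e-3)
  # a target far outside the gamut is flagged and clipped feasible
  out <- solveLedDrive(c(1000, 0, 0, 0), led)
  expect_false(out$in_gamut)
  expect_true(all(out$drive <= led$max_intensity + 1e-9))
  expect_true(all(out$drive >= 0))
})

test_that("contrast set has the designed cardinality and mixture rule", {
  led <- ledSystem()
  cs <- buildContrastSet(led)
  d <- stimulusData(cs)
  expect_identical(nrow(d), 6L * 6L + 11L * 6L)
  expect_true(all(d$set == "contrast"))
  # a violet+blue mixture at 1 uE adds 1 uE on each member LED: its
  # captures equal those of a manually built 2 uE two-LED addition
  bg_flux <- drop(led$spectra %*% led$background)
  add <- setNames(rep(0, 6), led$names); add[c("V", "B")] <- 1
  flux <- drop(led$spectra %*% (led$background + add))
  q_oracle <- relativeCapture(flux, bg_flux, led$wavelength)
  got <- captures(cs)[d$stimulus_id == "V+B@1", ]
  expect_equal(unname(got), unname(q_oracle), tolerance = 1e-10)
  expect_error(buildContrastSet(led, mixtures = "Q+Z"), "unknown")
})

test_that("response simulation is exact at zero noise and reproducible", {
  st <- fixtureGamut(25, seed = 21)
  fit <- new("TuningFit", kind = "linear", p = c(1, 0, 0), gain = 2,
             b = 0.5)
  r0 <- simulateResponses(st, fit, sigma = 0, seed = 1)
  amp <- SummarizedExperiment::assay(r0, "amplitude")
  expect_equal(unname(amp[1, ]),
               unname(linearResponse(chromaticCoords(st), luminance(st),
                                     fit)))
  r1 <- simulateResponses(st, fit, sigma = 0.2, seed = 7)
  r2 <- simulateResponses(st, fit, sigma = 0.2, seed = 7)
  expect_identical(SummarizedExperiment::assay(r1, "amplitude"),
                   SummarizedExperiment::assay(r2, "amplitude"))
  expect_equal(unique(SummarizedExperiment::rowData(r1)$sigma2), 0.04)
})

test_that("more observations shrink the amplitude noise as 1/sqrt(m)", {
  st1 <- makeStimulusSet(matrix(rep(1.25, 8), ncol = 4), m = 1L)
  st4 <- makeStimulusSet(matrix(rep(1.25, 8), ncol = 4), m = 4L)
  fit <- new("TuningFit", kind = "linear", p = c(1, 0, 0), gain = 1, b = 0)
  draw <- function(st, s)
    SummarizedExperiment::assay(
      simulateResponses(st, fit, sigma = 1, seed = s), "amplitude")[1, 1]
  v1 <- var(vapply(1:400, function(s) draw(st1, s), numeric(1)))
  v4 <- var(vapply(1:400, function(s) draw(st4, s), numeric(1)))
  expect_equal(v1 / v4, 4, tolerance = 0.35)
})

test_that("simulated traces round-trip through amplitude extraction", {
  amps <- rbind(roiA = c(0, 0.8, 1.5, -0.4, 0.3))
  tr0 <- simulateTraces(amps * 0, fs = 30, noise_sd = 0, seed = 1)
  expect_equal(max(abs(tr0$traces)), 0)
  tr <- simulateTraces(amps, fs = 30, noise_sd = 0, seed = 1)
  got <- extractAmplitude(tr$traces[1, ], tr$time, tr$onsets$onset)
  expect_equal(got, unname(amps[1, ]), tolerance = 0.02)
  # slow drift handled by the rolling-percentile baseline
  trd <- simulateTraces(amps, fs = 30, noise_sd = 0, drift = 0.5, seed = 2)
  # smoothing off: a Savitzky-Golay window as long as the step attenuates
  # the trailing read-out window of an ideal square step
  corrected <- dffBaseline(trd$traces[1, ], fs = 30, smooth = 0)
  gotd <- extractAmplitude(corrected, trd$time, trd$onsets$onset)
  keep <- abs(amps[1, ]) > 0
  expect_equal(gotd[keep], unname(amps[1, keep]), tolerance = 0.05)
})
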