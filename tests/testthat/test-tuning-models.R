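test_that("linear model evaluates a_L s cos(theta) + b l", {
  fit <- new("TuningFit", kind = "linear", p = c(0, 1, 0), gain = 2, b = 1)
  expect_equal(linearResponse(c(0, 0, 0), 0, fit), 0)
  expect_equal(linearResponse(c(0, 1, 0), 0, fit), 2)
  expect_equal(linearResponse(c(0, 0.5, 0), 3, fit), 4)
  # batch evaluation equals per-stimulus evaluation
  x <- matrix(rnorm(15), ncol = 3); l <- rnorm(5)
  batch <- linearResponse(x, l, fit)
  each <- vapply(1:5, function(i) linearResponse(x[i, ], l[i], fit),
                 numeric(1))
  expect_equal(batch, each)
})

test_that("modified tanh is continuous, odd at gamma 0, with set asymptotes", {
  u <- seq(-10, 10, by = 0.01)
  expect_equal(saturatingOutput(u, 1.5, 0), 1.5 * tanh(u))
  # unit slope at the origin for any gamma
  for (g in c(-0.8, 0, 0.5)) {
    eps <- 1e-6
    slope <- (saturatingOutput(eps, 2, g) -
                saturatingOutput(-eps, 2, g)) / (2 * eps)
    expect_equal(slope, 2, tolerance = 1e-6)
    # continuity at 0
    expect_lt(abs(saturatingOutput(1e-12, 2, g) -
                    saturatingOutput(-1e-12, 2, g)), 1e-10)
  }
  # branch asymptotes a (1 -+ gamma)
  expect_equal(saturatingOutput(50, 1, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(saturatingOutput(-50, 1, 0.5), -1.5, tolerance = 1e-9)
  expect_error(saturatingOutput(1, 1, 1), "gamma")
})

test_that("selectivity model matches direct evaluation and its linear limit", {
  p <- c(1, 0, 0)
  fit3 <- new("TuningFit", kind = "selectivity", p = p, gain = 1, b = 0,
              kappa = 3, alpha = 1)
  vals <- selectivityResponse(rbind(-p, c(0, 1, 0), p), rep(0, 3), fit3)
  expect_equal(vals, c((exp(-3) - 1) / 3, 0, (exp(3) - 1) / 3))
  # chromatic term vanishes at the white point
  fitb <- new("TuningFit", kind = "selectivity", p = p, gain = 1, b = 2,
              kappa = 3, alpha = 1)
  expect_equal(selectivityResponse(c(0, 0, 0), 1.5, fitb), 3)
  # kappa -> 0 with alpha = 1 converges to the linear model
  lin <- new("TuningFit", kind = "linear", p = p, gain = 1.3, b = 0.2)
  small <- new("TuningFit", kind = "selectivity", p = p, gain = 1.3,
               b = 0.2, kappa = 1e-6, alpha = 1)
  ct <- seq(-1, 1, by = 0.01)
  x <- cbind(ct, sqrt(pmax(0, 1 - ct^2)), 0)  # unit saturation circle
  dev <- abs(selectivityResponse(x, rep(1, nrow(x)), small) -
               linearResponse(x, rep(1, nrow(x)), lin))
  expect_lt(max(dev / pmax(abs(linearResponse(x, rep(1, nrow(x)), lin)),
                           1)), 1e-5)
  expect_error(selectivityResponse(c(1, 0, 0), 0,
    new("TuningFit", kind = "selectivity", p = p, gain = 1, b = 0,
        kappa = 1, alpha = -1)), "alpha")
})

test_that("weighted linear fit recovers planted parameters exactly", {
  st <- fixtureGamut(40, seed = 51, m = 2L)
  x <- chromaticCoords(st); l <- luminance(st)
  tru <- new("TuningFit", kind = "linear", p = c(2, -1, 1) / sqrt(6),
             gain = 1.7, b = -0.4)
  v <- linearResponse(x, l, tru)
  fit <- fitLinear(st, v)
  expect_equal(fit@p, tru@p, tolerance = 1e-8)
  expect_equal(fit@gain, tru@gain, tolerance = 1e-8)
  expect_equal(fit@b, tru@b, tolerance = 1e-8)
  expect_equal(fit@r2, 1, tolerance = 1e-10)
  # all-zero responses give zero gains
  f0 <- fitLinear(st, rep(0, 40))
  expect_equal(f0@gain, 0)
  expect_equal(f0@b, 0)
  # duplicating stimuli with proportional weights changes nothing
  d2 <- list(x = rbind(x, x), l = c(l, l), m = rep(obsCounts(st), 2))
  fit2 <- fitLinear(d2, c(v, v))
  expect_equal(fit2@p, fit@p)
  expect_equal(fit2@gain, fit@gain)
})

test_that("LNL fit nests the linear fit and recovers its own data", {
  st <- fixtureGamut(60, seed = 61)
  x <- chromaticCoords(st); l <- luminance(st)
  # small amplitudes: the saturating stage is linear, fits agree
  v_small <- 0.05 * (x[, 1] - 0.3 * l)
  flin <- fitLinear(st, v_small)
  flnl <- fitLNL(st, v_small)
  expect_equal(flnl@r2, flin@r2, tolerance = 1e-3)
  # noiseless LNL-generated data: response-level recovery
  u <- drop(x %*% c(1.5, -0.5, 0.8)) + 0.3 * l
  v <- saturatingOutput(u, a_nl = 1.2, gamma = 0.4)
  fit <- fitLNL(st, v)
  pred <- lnlResponse(x, l, fit)
  expect_lt(sqrt(mean((pred - v)^2)) / sd(v), 0.01)
  expect_gte(fit@r2, fitLinear(st, v)@r2 - 1e-6)
})

test_that("selectivity grid search recovers on-grid truth and linear data", {
  st <- fixtureGamut(50, seed = 71, m = 3L)
  x <- chromaticCoords(st); l <- luminance(st)
  g <- selectivityGrid()
  expect_length(g$kappa, 20)
  expect_length(g$alpha, 13)
  expect_equal(range(g$kappa), c(1e-2, 1e1))
  expect_equal(range(g$alpha), c(1e-1, 1e1))
  tru <- new("TuningFit", kind = "selectivity",
             p = c(1, 1, -1) / sqrt(3), gain = 1.5, b = 0.2,
             kappa = g$kappa[14], alpha = g$alpha[8])
  v <- selectivityResponse(x, l, tru)
  fit <- fitSelectivity(st, v)
  expect_equal(fit@kappa, tru@kappa)
  expect_equal(fit@alpha, tru@alpha)
  expect_equal(fit@p, tru@p, tolerance = 1e-4)
  expect_gte(fit@r2, 1 - 1e-8)
  # noiseless linear data selects the near-linear grid corner
  vlin <- drop(x %*% c(0.8, 0.2, -0.1)) + 0.1 * l
  flin <- fitSelectivity(st, vlin)
  expect_equal(flin@kappa, g$kappa[1])
  expect_equal(flin@alpha, g$alpha[which.min(abs(g$alpha - 1))])
  # the grid's near-linear corner is linear only up to O(kappa_min)
  expect_gte(flin@r2, fitLinear(st, vlin)@r2 - 1e-4)
})

test_that("iso-response contours of a sharp selectivity fit are curved", {
  # level sets in the chromatic plane: linear model has parallel normals,
  # high-kappa selectivity bends them
  p <- c(1, 0, 0)
  sharp <- new("TuningFit", kind = "selectivity", p = p, gain = 1, b = 0,
               kappa = 8, alpha = 1)
  lin <- new("TuningFit", kind = "linear", p = p, gain = 1, b = 0)
  grad_at <- function(fit, x) {
    h <- 1e-5
    vapply(1:2, function(k) {
      e <- c(0, 0, 0); e[k] <- h
      (predictTuning(fit, rbind(x + e), 0) -
         predictTuning(fit, rbind(x - e), 0)) / (2 * h)
    }, numeric(1))
  }
  # two points on the same level set of the sharp model
  level <- selectivityResponse(c(0.4, 0.25, 0), 0, sharp)
  f <- function(r) selectivityResponse(c(r * 0.8, -r * 0.6, 0), 0,
                                       sharp) - level
  r2 <- uniroot(f, c(0.05, 3))$root
  x1 <- c(0.4, 0.25, 0); x2 <- c(r2 * 0.8, -r2 * 0.6, 0)
  ang <- function(a, b) acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  ang_sharp <- ang(grad_at(sharp, x1), grad_at(sharp, x2))
  ang_lin <- ang(grad_at(lin, x1), grad_at(lin, x2))
  expect_lt(ang_lin, 1e-6)
  expect_gt(ang_sharp, 0.3)
})

test_that("tuning fits serialize to JSON and back", {
  fit <- new("TuningFit", kind = "selectivity", p = c(0, 0, 1),
             gain = 1.2, b = -0.3, kappa = 2.1, alpha = 0.5, r2 = 0.87)
  f <- tempfile(fileext = ".json")
  tuningFitToJSON(fit, f)
  back <- tuningFitFromJSON(f)
  expect_equal(back@p, fit@p)
  expect_equal(back@kappa, fit@kappa)
  expect_equal(back@r2, fit@r2)
  expect_identical(back@kind, "selectivity")
})
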