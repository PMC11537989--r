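test_that("synaptic-count normalization yields unit row budgets", {
  w <- normalizeWeights(matrix(c(30, 10, 10), 1), matrix(c(-1, 1, 1), 1))
  expect_equal(drop(w), c(-0.6, 0.2, 0.2))
  w1 <- normalizeWeights(matrix(17, 1, 1), matrix(-1, 1, 1))
  expect_equal(abs(drop(w1)), 1)
  counts <- matrix(rpois(25, 8) + 1, 5)
  wn <- normalizeWeights(counts)
  expect_equal(unname(rowSums(abs(wn))), rep(1, 5))
  expect_error(normalizeWeights(matrix(0, 1, 2)), "all-zero")
})

test_that("the example spec satisfies the stated normalization and audit", {
  sp <- exampleCircuitSpec()
  expect_equal(unname(rowSums(abs(sp@w)) + rowSums(sp@j)), rep(1, 12))
  audit <- freeParameterAudit(sp)
  expect_identical(unname(audit["total"]), 29L)
  expect_identical(unname(audit["gains"]), 8L)
  expect_identical(unname(audit["gamma"]), 11L)
  expect_identical(unname(audit["opsin_input"]), 1L)
  expect_identical(unname(audit["achromatic"]), 7L)
  expect_identical(unname(audit["dm8_weights"]), 2L)
  # direct + disynaptic counts aggregate onto one Tm-Tm edge
  agg <- circuitCountsFromTable(exampleConnectivityTable())
  expect_equal(agg$counts["Tm5a", "Tm5b"], 10)
  expect_equal(agg$counts["pTm20", "Tm5c"], 20)
  expect_identical(nrow(agg$freeSigns), 2L)
})

test_that("steady state solves the fixed point and its limits", {
  sp <- exampleCircuitSpec()
  # zero input gives the zero fixed point
  Y0 <- steadyState(sp, matrix(0, 3, 4), numeric(3), tol = 1e-10)
  expect_lt(max(abs(Y0)), 1e-8)
  # without recurrence the solution is one application of the map
  spf <- sp
  spf@w[] <- 0
  X <- matrix(rnorm(20), ncol = 4); x0 <- rnorm(5)
  Yff <- steadyState(spf, X, x0, tol = 1e-10)
  direct <- flyhue:::circuitMap(spf, matrix(0, 12, 5), X, x0)
  expect_equal(unname(Yff), unname(direct), tolerance = 1e-8)
  # agreement with forward integration of the dynamics on random
  # contractive circuits
  for (seed in 1:4) {
    spr <- randomStableSpec(seed)
    Xi <- matrix(rnorm(8, sd = 0.5), ncol = 4)
    x0i <- rnorm(2, sd = 0.3)
    fast <- steadyState(spr, Xi, x0i, tol = 1e-10)
    slow <- eulerSteadyState(spr, Xi, x0i)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("anderson acceleration solves generic fixed points", {
  # linear contraction with known solution x = (I - A)^-1 b
  set.seed(2)
  A <- matrix(rnorm(36, sd = 0.1), 6); b <- rnorm(6)
  sol <- andersonFixedPoint(function(x) drop(A %*% x) + b, numeric(6),
                            tol = 1e-12)
  expect_equal(sol$x, drop(solve(diag(6) - A, b)), tolerance = 1e-8)
  # a map with no fixed point reports non-convergence with its residual
  expect_error(andersonFixedPoint(function(x) x + 1, 0, max_iter = 30),
               "not reached")
})

test_that("correlation loss counts matched neurons", {
  set.seed(3)
  V <- matrix(rnorm(12 * 10), 12)
  expect_equal(correlationLoss(V, V), -12)
  expect_equal(correlationLoss(3 * V, V), -12)
  Yf <- V; Yf[4, ] <- -V[4, ]
  expect_equal(correlationLoss(Yf, V), -10)
  V0 <- V; V0[2, ] <- 0
  expect_warning(L <- correlationLoss(V, V0), "zero-norm")
  expect_equal(L, -11)
})

test_that("implicit fixed-point gradients match finite differences", {
  sp <- exampleCircuitSpec()
  st <- fixtureGamut(15, seed = 81)
  X <- logCaptures(st); x0 <- achromaticInput(st)
  V <- steadyState(sp, X, x0, tol = 1e-10)
  m <- obsCounts(st)
  applyFun <- function(s, th) flyhue:::stageApply(s, "stage3", th)
  theta <- flyhue:::stageTheta(sp, "stage3") * 1.05 + 0.02
  lg <- circuitLossGrad(sp, applyFun, theta, X, x0, V, m, neurons = 8:12,
                        tol = 1e-10)
  set.seed(4)
  for (k in sample(seq_along(theta), 5)) {
    h <- 1e-5
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    fd <- (correlationLoss(steadyState(applyFun(sp, tp), X, x0,
                                       tol = 1e-11), V, m, 8:12) -
             correlationLoss(steadyState(applyFun(sp, tm), X, x0,
                                         tol = 1e-11), V, m, 8:12)) /
      (2 * h)
    expect_equal(lg$grad[k], fd, tolerance = 1e-4)
  }
})

test_that("perturbation operators edit only the intended weights", {
  sp <- exampleCircuitSpec()
  abl <- ablateRecurrence(sp)
  expect_true(all(abl@w[8:12, 8:12] == 0))
  expect_identical(abl@w[1:7, ], sp@w[1:7, ])
  expect_identical(abl@w[8:12, 1:7], sp@w[8:12, 1:7])
  tnt <- simulateTent(sp, "Tm5a")
  expect_true(all(tnt@w[, 8] == 0))
  expect_identical(tnt@w[8, -8], sp@w[8, -8])
  expect_error(simulateTent(sp, "Dm9"), "Tm")
  # silencing a neuron with no outgoing weights changes nothing
  sp2 <- simulateTent(sp, "yTm20")
  sp3 <- simulateTent(sp2, "yTm20")
  st <- fixtureGamut(8, seed = 91)
  expect_equal(steadyState(sp2, logCaptures(st), achromaticInput(st)),
               steadyState(sp3, logCaptures(st), achromaticInput(st)))
})

test_that("Tm20 mixing weights pale and yellow columns 1:2", {
  expect_equal(mixTm20(c(1, 1), c(1, 1)), c(1, 1))
  expect_equal(mixTm20(1, 0), 1 / 3)
  expect_equal(mixTm20(0, 1), 2 / 3)
  expect_error(mixTm20(1:3, 1:2), "share")
})

test_that("connectivity accounting applies thresholds and totals", {
  empty <- data.frame(pre = character(0), post = character(0),
                      count = numeric(0))
  z <- summarizeConnectivity(empty, seeds = "Tm5a",
                             total_post_sites = 10, total_pre_sites = 10)
  expect_equal(z$input_sites, 0)
  expect_equal(z$output_partners, 0L)
  # toy table against hand enumeration with threshold > 4
  toy <- data.frame(pre = c("a", "b", "c", "Tm5a", "Tm5a"),
                    post = c("Tm5a", "Tm5a", "Tm5a", "d", "e"),
                    count = c(7, 3, 5, 6, 4))
  s <- summarizeConnectivity(toy, seeds = "Tm5a", input_threshold = 4,
                             output_threshold = 4,
                             total_post_sites = 20, total_pre_sites = 20)
  expect_equal(s$input_sites, 12)       # a (7) and c (5) survive
  expect_equal(s$input_partners, 2L)
  expect_equal(s$output_sites, 6)       # only d (6) survives
  expect_equal(s$input_pct, 100 * 12 / 20)
})

test_that("sign search is exhaustive within budget and seed-invariant", {
  sp <- exampleCircuitSpec()
  st <- fixtureGamut(40, seed = 15)
  V <- steadyState(sp, logCaptures(st), achromaticInput(st), tol = 1e-8)
  ctrl <- fitControl(epochs = 6, lr = 0.03, seed = 2)
  s1 <- signSearch(sp, V, st, budget = 8, seed = 1, control = ctrl)
  s2 <- signSearch(sp, V, st, budget = 8, seed = 99, control = ctrl)
  expect_identical(s1$signs, s2$signs)
  expect_identical(nrow(s1$table), 4L)  # 2 free edges enumerated
  # the optimum over the searched set is no worse than all-positive
  allpos <- s1$table$loss[s1$table$Var1 == 1 & s1$table$Var2 == 1]
  expect_lte(s1$loss, allpos)
  # the generating signs (both negative) win on self-generated data
  expect_identical(unname(s1$signs), c(-1, -1))
})
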