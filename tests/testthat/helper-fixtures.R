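## Shared fixtures, all generated in code.

## A small gamut stimulus set reused across tests.
fixtureGamut <- function(n = 60, seed = 5, m = 1L)
  sampleGamut(n, iso_total = 5, m = m, seed = seed)

## Random contractive circuit spec on the example wiring pattern: gains and
## asymmetries drawn small enough that the one-step map is a sup-norm
## contraction, so plain forward integration and the accelerated solver
## must agree.
randomStableSpec <- function(seed) {
  set.seed(seed)
  base <- exampleCircuitSpec()
  counts <- base@counts
  nz <- counts > 0
  counts[nz] <- sample(5:50, sum(nz), replace = TRUE)
  p <- numeric(12)
  p[6:7] <- runif(2, 0.1, 0.6)
  p[8:12] <- runif(5, -0.5, 0.5)
  g <- numeric(12)
  g[1:4] <- runif(1, 0.4, 0.9); g[5] <- runif(1, 0.4, 0.9)
  g[6:7] <- runif(1, 0.4, 0.9); g[8:12] <- runif(5, 0.4, 0.9)
  gamma <- numeric(12)
  gamma[-5] <- runif(11, -0.5, 0.5)
  makeCircuitSpec(counts, base@signs, j_frac = runif(1, 0.5, 0.9),
                  dm8_frac = runif(2, 0.1, 0.4), p = p, g = g,
                  gamma = gamma, freeSigns = base@freeSigns)
}

## Forward-Euler integration of the circuit dynamics to equilibrium; the
## independent oracle for the fixed-point solver.
eulerSteadyState <- function(spec, X, x0, dt = 0.005, t_end = 20) {
  n <- nrow(X)
  Y <- matrix(0, 12, n)
  steps <- ceiling(t_end / dt)
  for (s in seq_len(steps)) {
    G <- flyhue:::circuitMap(spec, Y, X, x0)
    Ynew <- Y + (dt / spec@tau) * (G - Y)
    if (max(abs(Ynew - Y)) < 1e-12) return(Ynew)
    Y <- Ynew
  }
  Y
}

## Trapezoid quadrature written out longhand (independent of pracma).
trapzOracle <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
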