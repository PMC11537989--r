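## The three stimulus -> response encoding models: linear, linear-nonlinear
## (modified tanh output), and the nonlinear hue-selectivity model with its
## kappa / alpha grid search. All fits weight stimuli by observation counts.

#' Linear encoding model
#'
#' y = a_L (p . x) + b l = a_L s cos(theta) + b l.
#'
#' @param x n x 3 chromatic coordinates (or 3-vector).
#' @param l luminance values.
#' @param fit a \code{TuningFit} of kind "linear" (or any fit; its p, gain
#'   and b are used linearly).
#' @return predicted responses.
#' @export
linearResponse <- function(x, l, fit) {
  x <- rbind(x)  # promotes a vector to 1 x 3
  unname(drop(x %*% fit@p) * fit@gain + fit@b * l)
}

#' Modified tanh output nonlinearity
#'
#' An asymmetric saturating function with unit slope at zero:
#' y = a (1 + gamma) tanh(u / (1 + gamma)) for u <= 0 and
#' y = a (1 - gamma) tanh(u / (1 - gamma)) for u > 0. gamma in (-1, 1) sets
#' where the two branches saturate; gamma = 0 recovers a tanh.
#'
#' @param u numeric input.
#' @param a_nl output gain.
#' @param gamma asymmetry in (-1, 1).
#' @return numeric of the same shape as \code{u}.
#' @export
saturatingOutput <- function(u, a_nl = 1, gamma = 0) {
  if (abs(gamma) >= 1) stop("gamma must lie in (-1, 1)")
  neg <- u <= 0
  out <- u
  out[neg] <- a_nl * (1 + gamma) * tanh(u[neg] / (1 + gamma))
  out[!neg] <- a_nl * (1 - gamma) * tanh(u[!neg] / (1 - gamma))
  out
}

## Derivatives of the modified tanh, used by the circuit model gradients.
saturatingOutputPrime <- function(u, gamma = 0) {
  s <- ifelse(u <= 0, 1 + gamma, 1 - gamma)
  1 - tanh(u / s)^2
}

saturatingOutputDGamma <- function(u, gamma = 0) {
  s <- ifelse(u <= 0, 1 + gamma, 1 - gamma)
  sgn <- ifelse(u <= 0, 1, -1)
  t <- tanh(u / s)
  sgn * (t - (u / s) * (1 - t^2))
}

#' Nonlinear hue-selectivity model
#'
#' y = (a_NL s^alpha / kappa) (exp(kappa cos(theta)) - 1) + b l, with s the
#' saturation and theta the angle to the preferred direction. kappa sets the
#' hue sharpness (the von Mises concentration of the tuning), alpha how the
#' response grows with saturation. As kappa -> 0 with alpha = 1 the model
#' converges to the linear model; \code{kappa = 0} evaluates that analytic
#' limit.
#'
#' @param x n x 3 chromatic coordinates (or 3-vector).
#' @param l luminance values.
#' @param fit a \code{TuningFit} of kind "selectivity" (slots p, gain, b,
#'   kappa, alpha are used).
#' @return predicted responses.
#' @export
selectivityResponse <- function(x, l, fit) {
  if (fit@alpha <= 0) stop("alpha must be positive")
  x <- rbind(x)
  s <- sqrt(rowSums(x^2))
  ct <- ifelse(s > 0, drop(x %*% fit@p) / s, 0)
  k <- fit@kappa
  chrom <- if (k == 0) {
    # analytic kappa -> 0 limit: (exp(k ct) - 1)/k -> ct
    fit@gain * s^fit@alpha * ct
  } else {
    fit@gain * s^fit@alpha / k * (exp(k * ct) - 1)
  }
  chrom[s == 0] <- 0
  unname(chrom + fit@b * l)
}

## Pull chromatic coordinates / luminance / counts out of a StimulusSet or a
## plain list(x =, l =).
.design <- function(stimuli) {
  if (is(stimuli, "StimulusSet"))
    list(x = chromaticCoords(stimuli), l = luminance(stimuli),
         m = obsCounts(stimuli))
  else stimuli
}

#' Fit the linear encoding model
#'
#' Weighted least squares of the responses on the three chromatic
#' coordinates and the luminance (no intercept), weighting each stimulus by
#' its observation count. The chromatic coefficient vector is returned as a
#' unit preferred direction with its norm as the gain a_L.
#'
#' @param stimuli a \code{StimulusSet} (or list with x, l, m).
#' @param v response amplitudes, one per stimulus.
#' @param m observation counts; defaults to the stimulus set's counts.
#' @param sigma2 noise power for the noise-corrected R^2.
#' @return a \code{TuningFit} of kind "linear".
#' @export
fitLinear <- function(stimuli, v, m = NULL, sigma2 = 0) {
  d <- .design(stimuli)
  if (is.null(m)) m <- if (!is.null(d$m)) d$m else 1
  if (length(m) == 1) m <- rep(m, length(v))
  Z <- cbind(d$x, d$l)
  qrz <- qr(sqrt(m) * Z)
  if (qrz$rank < 4) stop("rank-deficient design: stimuli must span x and l")
  beta <- unname(qr.coef(qrz, sqrt(m) * v))
  cvec <- beta[1:3]; b <- beta[4]
  aL <- sqrt(sum(cvec^2))
  p <- if (aL > 0) cvec / aL else c(0, 0, 0)
  yhat <- drop(Z %*% beta)
  r2 <- if (sum(v^2) > 0)
    noiseCorrectedR2(yhat, v, m, sigma2) else NA_real_
  new("TuningFit", kind = "linear", p = p, gain = aL, b = b,
      r2 = r2, sse = sum(m * (v - yhat)^2))
}

#' Fit the linear-nonlinear (LNL) encoding model
#'
#' The linear stage of \code{fitLinear} followed by the modified tanh output
#' (gain a_NL, asymmetry gamma), fitted jointly by weighted nonlinear least
#' squares. Initialized from the linear fit with gamma = 0; restarted from
#' jittered initial values if the optimizer fails to converge.
#'
#' @inheritParams fitLinear
#' @param restarts maximum number of jittered restarts.
#' @return a \code{TuningFit} of kind "lnl".
#' @export
fitLNL <- function(stimuli, v, m = NULL, sigma2 = 0, restarts = 50) {
  d <- .design(stimuli)
  if (is.null(m)) m <- if (!is.null(d$m)) d$m else 1
  if (length(m) == 1) m <- rep(m, length(v))
  lin <- fitLinear(d, v, m)
  x <- d$x; l <- d$l
  predict_theta <- function(th) {
    # th = (c1, c2, c3, b, a_nl, gamma_raw), gamma = 0.999 tanh(gamma_raw)
    u <- drop(x %*% th[1:3]) + th[4] * l
    saturatingOutput(u, a_nl = th[5], gamma = 0.999 * tanh(th[6]))
  }
  obj <- function(th) sum(m * (v - predict_theta(th))^2)
  th0 <- c(lin@p * lin@gain, lin@b, 1, 0)
  best <- stats::optim(th0, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
  tries <- 0
  while (best$convergence != 0 && tries < restarts) {
    tries <- tries + 1
    th_try <- th0 * (1 + stats::rnorm(6, sd = 0.1)) +
      stats::rnorm(6, sd = 0.01)
    cand <- stats::optim(th_try, obj, method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-12))
    if (cand$value < best$value) best <- cand
  }
  th <- best$par
  cvec <- th[1:3]
  nrm <- sqrt(sum(cvec^2))
  # fold the linear-stage norm into the input of the tanh: keep coefficients
  # as-is, report unit p with the input scale absorbed into sse/predictions.
  p <- if (nrm > 0) cvec / nrm else c(0, 0, 0)
  yhat <- predict_theta(th)
  fit <- new("TuningFit", kind = "lnl", p = p, gain = th[5] * nrm,
             b = th[4], gamma = 0.999 * tanh(th[6]),
             r2 = noiseCorrectedR2(yhat, v, m, sigma2),
             sse = best$value, converged = best$convergence == 0,
             extra = list(theta = th))
  fit
}

#' Predict from a fitted LNL model
#'
#' @param fit a TuningFit of kind "lnl" produced by \code{fitLNL}.
#' @param x chromatic coordinates; @param l luminance.
#' @return predicted responses.
#' @export
lnlResponse <- function(x, l, fit) {
  th <- fit@extra$theta
  if (is.null(th)) stop("fit carries no LNL parameters")
  x <- rbind(x)
  u <- drop(x %*% th[1:3]) + th[4] * l
  unname(saturatingOutput(u, a_nl = th[5], gamma = 0.999 * tanh(th[6])))
}

#' The kappa / alpha search grid of the selectivity model
#'
#' kappa: 20 uniform log steps between 1e-2 and 1e1; alpha: 13 uniform log
#' steps between 1e-1 and 1e1 (endpoints inclusive).
#'
#' @return list with numeric vectors \code{kappa} and \code{alpha}.
#' @export
selectivityGrid <- function() {
  list(kappa = 10^seq(-2, 1, length.out = 20),
       alpha = 10^seq(-1, 1, length.out = 13))
}

## Weighted SSE of the selectivity model at fixed (kappa, alpha), minimized
## over the preferred direction (outer optim) with (a_NL, b) solved by
## weighted least squares at each direction (variable projection).
.selectivitySSE <- function(u0, x, l, v, m, kappa, alpha, s, shat) {
  fitdir <- function(u) {
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(list(val = sum(m * v^2), ab = c(0, 0)))
    p <- u / nu
    ct <- drop(shat %*% p)
    reg <- s^alpha / kappa * (exp(kappa * ct) - 1)
    Z <- cbind(reg, l)
    sw <- sqrt(m)
    ab <- qr.coef(qr(sw * Z), sw * v)
    ab[is.na(ab)] <- 0
    res <- v - drop(Z %*% ab)
    list(val = sum(m * res^2), ab = ab)
  }
  opt <- stats::optim(u0, function(u) fitdir(u)$val, method = "BFGS",
                      control = list(maxit = 100, reltol = 1e-9))
  fin <- fitdir(opt$par)
  list(par = opt$par, value = fin$val, ab = fin$ab)
}

#' Fit the nonlinear hue-selectivity model
#'
#' For every (kappa, alpha) on the log grid of \code{selectivityGrid}, the
#' preferred direction, gain and luminance coefficient are fitted by
#' weighted least squares (direction by quasi-Newton search with the gain
#' and b profiled out); the grid point with the smallest weighted SSE wins,
#' ties broken toward smaller kappa.
#'
#' @inheritParams fitLinear
#' @param grid optional list(kappa, alpha) overriding the default grid.
#' @return a \code{TuningFit} of kind "selectivity".
#' @export
fitSelectivity <- function(stimuli, v, m = NULL, sigma2 = 0, grid = NULL) {
  d <- .design(stimuli)
  if (is.null(m)) m <- if (!is.null(d$m)) d$m else 1
  if (length(m) == 1) m <- rep(m, length(v))
  if (is.null(grid)) grid <- selectivityGrid()
  x <- d$x; l <- d$l
  s <- sqrt(rowSums(x^2))
  shat <- x / ifelse(s > 0, s, 1)
  lin <- fitLinear(d, v, m)
  inits <- list(lin@p, -lin@p)
  if (sum(lin@p^2) == 0) inits <- list(c(1, 0, 0), c(-1, 0, 0))
  best <- NULL
  # ascend kappa within each alpha, warm-starting the direction search from
  # the previous grid point (both signed inits are tried at the first one)
  for (alpha in grid$alpha) {
    warm <- NULL
    for (kappa in grid$kappa) {
      starts <- if (is.null(warm)) inits else list(warm)
      r0 <- NULL
      for (u0 in starts) {
        r <- .selectivitySSE(u0, x, l, v, m, kappa, alpha, s, shat)
        if (is.null(r0) || r$value < r0$value) r0 <- r
      }
      warm <- r0$par
      if (is.null(best) || r0$value < best$value - 1e-12) {
        best <- r0; best$kappa <- kappa; best$alpha <- alpha
      }
    }
  }
  p <- unname(best$par / sqrt(sum(best$par^2)))
  fit <- new("TuningFit", kind = "selectivity", p = p,
             gain = unname(best$ab[1]), b = unname(best$ab[2]),
             kappa = best$kappa, alpha = best$alpha, sse = best$value)
  yhat <- selectivityResponse(x, l, fit)
  fit@r2 <- noiseCorrectedR2(yhat, v, m, sigma2)
  validObject(fit)
  fit
}

#' Serialize / restore a TuningFit as JSON
#'
#' @param fit a TuningFit; @param file optional path (returns the JSON
#'   string when NULL).
#' @return JSON string or (invisibly) the path written.
#' @export
tuningFitToJSON <- function(fit, file = NULL) {
  obj <- list(kind = fit@kind, p = fit@p, gain = fit@gain, b = fit@b,
              gamma = fit@gamma, kappa = fit@kappa, alpha = fit@alpha,
              r2 = fit@r2, sse = fit@sse, converged = fit@converged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(file)) return(as.character(js))
  writeLines(as.character(js), file)
  invisible(file)
}

#' @rdname tuningFitToJSON
#' @export
tuningFitFromJSON <- function(file) {
  obj <- jsonlite::fromJSON(file)
  num1 <- function(z) if (is.null(z)) NA_real_ else as.numeric(z)
  new("TuningFit", kind = obj$kind, p = as.numeric(obj$p),
      gain = num1(obj$gain), b = num1(obj$b), gamma = num1(obj$gamma),
      kappa = num1(obj$kappa), alpha = num1(obj$alpha), r2 = num1(obj$r2),
      sse = num1(obj$sse),
      converged = isTRUE(obj$converged))
}
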