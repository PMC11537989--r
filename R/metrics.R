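## Tuning indices, noise-corrected goodness of fit and the ROI bootstrap.

#' Sparsity index of a response profile
#'
#' 1 - mean over stimuli of |v_i| / max_j |v_j|. Equal responses give 0, a
#' single responder among N stimuli gives 1 - 1/N, and amplitudes drawn from
#' a uniform distribution give about 0.5.
#'
#' @param v numeric vector of response amplitudes.
#' @return scalar in [0, 1].
#' @export
sparsityIndex <- function(v) {
  mx <- max(abs(v))
  if (mx == 0) stop("all responses are zero; sparsity undefined")
  1 - mean(abs(v) / mx)
}

## Uncentered R^2 of a no-intercept least-squares fit of v on design matrix Z.
uncenteredR2 <- function(v, Z) {
  Z <- as.matrix(Z)
  beta <- qr.coef(qr(Z), v)
  beta[is.na(beta)] <- 0
  res <- v - drop(Z %*% beta)
  1 - sum(res^2) / sum(v^2)
}

#' Luminance invariance index
#'
#' Ratio of the goodness of fit (uncentered R^2, no intercepts) of a
#' regression of the responses on the chromatic coordinates alone to that of
#' a regression on the luminance alone. Values much larger than 1 indicate a
#' luminance-invariant (chromatic) neuron. The chromatic fit estimates the
#' preferred direction by the same least squares as the linear encoding
#' model restricted to its chromatic terms.
#'
#' @param v response amplitudes (one per stimulus).
#' @param x n x 3 chromatic coordinates.
#' @param l luminance values.
#' @param floor lower floor for the luminance R^2; ratios whose denominator
#'   falls below it are capped and flagged.
#' @return list with \code{index}, \code{r2_chromatic}, \code{r2_luminance}
#'   and logical \code{capped}.
#' @export
luminanceInvarianceIndex <- function(v, x, l, floor = 1e-6) {
  if (length(v) < 4) stop("need at least 4 stimuli")
  r2c <- uncenteredR2(v, x)
  r2l <- uncenteredR2(v, matrix(l, ncol = 1))
  capped <- r2l < floor
  idx <- r2c / max(r2l, floor)
  list(index = idx, r2_chromatic = r2c, r2_luminance = r2l, capped = capped)
}

#' Hue sensitivity index
#'
#' Opponent-plane stimulus vectors are normalized to unit direction, their
#' saturations scaled to [0, 1] by the set maximum, and stimuli at or above
#' 0.5 scaled saturation (or exactly at the white point) are dropped. The
#' hue vector is the observation-weighted, signed-response-weighted sum of
#' unit directions divided by the weighted absolute responses,
#' h = sum_i m_i p_hat_i y_i / sum_i m_i |y_i|; the index is its L2 norm.
#' 1 means the neuron responds along a single direction, 0 means equal
#' responses in all directions.
#'
#' @param y mean responses per stimulus (signed).
#' @param P n x 2 opponent-plane coordinates.
#' @param m observation counts (scalar or length n).
#' @param saturation_cut retain stimuli with scaled saturation strictly
#'   below this value (default 0.5).
#' @param sat_max reference maximum saturation for the [0, 1] scaling;
#'   defaults to the maximum over the supplied stimuli. Supply it
#'   explicitly when the stimuli are a subset (for example a single ring)
#'   of a larger design.
#' @return list with \code{h_vec} (2-vector) and \code{hsi} (its norm).
#' @export
hueSensitivityIndex <- function(y, P, m = 1, saturation_cut = 0.5,
                                sat_max = NULL) {
  P <- as.matrix(P)
  stopifnot(ncol(P) == 2, nrow(P) == length(y))
  if (length(m) == 1) m <- rep(m, length(y))
  sat <- sqrt(rowSums(P^2))
  smax <- if (is.null(sat_max)) max(sat) else sat_max
  if (smax == 0) stop("all stimuli at the white point")
  scaled <- sat / smax
  keep <- scaled < saturation_cut & sat > 0
  if (!any(keep)) stop("no stimuli retained below the saturation cut")
  y <- y[keep]; m <- m[keep]
  phat <- P[keep, , drop = FALSE] / sat[keep]
  denom <- sum(m * abs(y))
  if (denom == 0) stop("all retained responses are zero")
  h <- colSums(phat * (m * y)) / denom
  list(h_vec = h, hsi = sqrt(sum(h^2)))
}

#' Noise-corrected R squared
#'
#' Goodness of fit between model predictions y and measured amplitudes v
#' corrected for measurement noise:
#' R2 = [ (sum m y v)^2 - (sigma2/mbar) sum m y^2 ] /
#'      [ sum m y^2 sum m v^2 - (sigma2 (mhat - 1)/mbar) sum m y^2 ],
#' with m the per-stimulus observation counts, mbar their mean, mhat their
#' total, and sigma2 the baseline noise power. At sigma2 = 0 this is the
#' squared m-weighted uncentered correlation. The typeset source of this
#' correction admits a second (literal) reading of the numerator,
#' sum m (y v)^2, retained behind \code{numerator = "literal"}; the default
#' is the reading consistent with an R^2.
#'
#' @param y model predictions.
#' @param v measured amplitudes.
#' @param m observation counts (scalar or vector).
#' @param sigma2 estimated noise power (default 0).
#' @param numerator "consistent" (default) or "literal".
#' @return scalar R^2; NaN with a warning when the denominator is
#'   nonpositive.
#' @export
noiseCorrectedR2 <- function(y, v, m = 1, sigma2 = 0,
                             numerator = c("consistent", "literal")) {
  numerator <- match.arg(numerator)
  n <- length(y)
  if (length(m) == 1) m <- rep(m, n)
  syy <- sum(m * y^2); svv <- sum(m * v^2)
  if (syy <= 0 || svv <= 0) stop("zero-norm y or v")
  mbar <- mean(m); mhat <- sum(m)
  num_main <- if (numerator == "consistent") sum(m * y * v)^2 else
    sum(m * (y * v)^2)
  num <- num_main - (sigma2 / mbar) * syy
  den <- syy * svv - (sigma2 * (mhat - 1) / mbar) * syy
  if (den <= 0) {
    warning("nonpositive denominator; noise-corrected R2 undefined")
    return(NaN)
  }
  num / den
}

#' Bootstrap of a tuning statistic over ROIs
#'
#' Resamples ROIs with replacement, recomputes the ROI-mean response per
#' stimulus for each draw, applies the statistic, and returns the empirical
#' distribution with a percentile confidence interval.
#'
#' @param responses ROI x stimulus matrix of amplitudes (or a
#'   \code{HueResponseSet}, in which case its amplitude assay is used).
#' @param statistic function taking the per-stimulus mean response vector
#'   and returning a scalar.
#' @param n_boot number of bootstrap draws (study default 1000).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return list with \code{estimate} (statistic of the full-data ROI means),
#'   \code{distribution} and \code{ci}.
#' @export
bootstrapIndex <- function(responses, statistic, n_boot = 1000, seed = 1,
                           conf = 0.95) {
  if (is(responses, "HueResponseSet"))
    responses <- SummarizedExperiment::assay(responses, "amplitude")
  responses <- as.matrix(responses)
  n_roi <- nrow(responses)
  if (n_roi < 2) stop("need at least 2 ROIs to bootstrap")
  est <- statistic(colMeans(responses))
  rng <- local({ set.seed(seed); lapply(seq_len(n_boot), function(i)
    sample.int(n_roi, n_roi, replace = TRUE)) })
  dist <- vapply(rng, function(idx)
    statistic(colMeans(responses[idx, , drop = FALSE])), numeric(1))
  a <- (1 - conf) / 2
  list(estimate = est, distribution = dist,
       ci = unname(stats::quantile(dist, c(a, 1 - a))))
}
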