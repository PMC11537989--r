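## Thin-plate-spline interpolation of responses over photoreceptor
## excitation space, convex-hull projection, spectral and nonspectral
## tuning curves, and the spectral-vs-nonspectral classification.

## Thin-plate kernel phi(r) = r^2 log r (0 at r = 0).
.tpsKernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Fit a thin-plate-spline interpolator without a constant term
#'
#' Exact radial-basis interpolation of response amplitudes over points in
#' 4D log-capture space with the thin-plate kernel and a degree-one
#' polynomial tail whose constant term is removed (amplitudes are
#' baseline-subtracted, so the interpolant need not carry an offset).
#' Training typically combines the gamut and contrast stimulus sets to
#' enlarge the convex hull.
#'
#' @param X n x d matrix of training coordinates (rows unique).
#' @param v training amplitudes (length n).
#' @return an object of class "tpsInterpolator" with \code{predict} support
#'   via \code{evalInterpolator}.
#' @export
fitInterpolator <- function(X, v) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < d + 2) stop("need at least d + 2 training points")
  dup <- duplicated(X)
  if (any(dup)) {
    for (i in which(dup)) {
      j <- which(colSums(abs(t(X) - X[i, ])) == 0)[1]
      if (abs(v[i] - v[j]) > 1e-12)
        stop("duplicate points with conflicting values")
    }
    keep <- !dup
    X <- X[keep, , drop = FALSE]; v <- v[keep]; n <- nrow(X)
  }
  K <- .tpsKernel(as.matrix(stats::dist(X)))
  A <- rbind(cbind(K, X), cbind(t(X), matrix(0, d, d)))
  rhs <- c(v, numeric(d))
  # exact solve when the kernel system is well conditioned; a relative
  # ridge keeps dense, nearly-coincident designs solvable
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    ridge <- 1e-10 * max(abs(A))
    solve(A + ridge * diag(nrow(A)), rhs)
  })
  structure(list(X = X, coef = sol[seq_len(n)],
                 poly = sol[n + seq_len(d)], d = d),
            class = "tpsInterpolator")
}

#' Evaluate a thin-plate-spline interpolator
#'
#' @param interp a "tpsInterpolator" from \code{fitInterpolator}.
#' @param Xnew query points (matrix with the training dimensionality).
#' @return interpolated amplitudes.
#' @export
evalInterpolator <- function(interp, Xnew) {
  Xnew <- rbind(Xnew)
  D2 <- outer(rowSums(Xnew^2), rowSums(interp$X^2), "+") -
    2 * Xnew %*% t(interp$X)
  D <- sqrt(pmax(D2, 0))
  drop(.tpsKernel(D) %*% interp$coef + Xnew %*% interp$poly)
}

#' Project query points onto the convex hull of the training set
#'
#' Finds, for each query point outside the convex hull of \code{hull_pts},
#' the nearest point of the hull (Euclidean); interior points are returned
#' unchanged. The projection solves the simplex-constrained least-squares
#' problem min ||P' lambda - q|| over lambda >= 0, sum lambda = 1 (the
#' equality enforced by a heavily weighted augmented row), which is exactly
#' the nearest-point map and is idempotent.
#'
#' @param Xq query points (matrix, d columns).
#' @param hull_pts points whose convex hull is the target set.
#' @param tol residual below which a point is declared inside the hull.
#' @return list with \code{projected} (matrix like Xq) and logical
#'   \code{inside}.
#' @export
projectToHull <- function(Xq, hull_pts, tol = 1e-4) {
  Xq <- rbind(Xq); P <- as.matrix(hull_pts)
  W <- 100
  # tiny Tikhonov rows make the nonnegative least-squares problem strictly
  # overdetermined, which keeps the active-set solver nonsingular when many
  # hull points are affinely dependent; scales chosen so the QR inside the
  # solver never looks rank-deficient
  A <- rbind(t(P), rep(W, nrow(P)), 1e-3 * diag(nrow(P)))
  out <- Xq; inside <- logical(nrow(Xq))
  for (i in seq_len(nrow(Xq))) {
    b <- c(Xq[i, ], W, numeric(nrow(P)))
    lam <- pracma::lsqnonneg(A, b)$x
    lam <- lam / sum(lam)
    proj <- drop(t(P) %*% lam)
    inside[i] <- sqrt(sum((proj - Xq[i, ])^2)) < tol
    if (!inside[i]) out[i, ] <- proj
  }
  list(projected = out, inside = inside)
}

#' The single-wavelength locus in log-capture space
#'
#' Computes, for Gaussian lights of the given spectral width with peaks
#' stepping through the wavelength range, the opsin captures normalized to
#' the isoluminant total of the gamut design, and maps them to log-capture
#' coordinates. This is the spectral locus along which spectral tuning
#' curves are read out.
#'
#' @param peaks_nm vector of peak wavelengths (default 320-580 nm in 2 nm
#'   steps).
#' @param width_nm Gaussian standard-deviation-equivalent width (the lights
#'   have sd \code{width_nm}; study value 10 nm).
#' @param iso_total the isoluminant summed-capture constant.
#' @param opsin_peaks lambda_max values for Rh3..Rh6.
#' @param wavelength evaluation grid.
#' @return list with \code{peak} (nm), \code{q} (n x 4), \code{X} (n x 4).
#' @export
singleWavelengthLine <- function(peaks_nm = seq(320, 580, by = 2),
                                 width_nm = 10, iso_total = 5,
                                 opsin_peaks = defaultOpsinPeaks()[OPSINS],
                                 wavelength = seq(300, 700, by = 1)) {
  S <- vapply(opsin_peaks, function(lm)
    opsinSensitivity(lm, wavelength), numeric(length(wavelength)))
  q <- t(vapply(peaks_nm, function(pk) {
    flux <- exp(-(wavelength - pk)^2 / (2 * width_nm^2))
    cap <- vapply(seq_len(4), function(mu)
      pracma::trapz(wavelength, S[, mu] * flux), numeric(1))
    iso_total * cap / sum(cap)
  }, numeric(4)))
  colnames(q) <- OPSINS
  list(peak = peaks_nm, q = q, X = logCapture(q))
}

#' Nonspectral mixture lines between nonadjacent opsins
#'
#' Connects, for each nonadjacent opsin pair (Rh3-Rh5, Rh3-Rh6, Rh4-Rh6),
#' the two single-wavelength points of maximal excitation of the pair's
#' opsins by a straight segment in capture space, renormalized to the
#' isoluminant total and parameterized by the mixture fraction of the
#' shorter-wavelength opsin's endpoint.
#'
#' @param swl output of \code{singleWavelengthLine}.
#' @param fractions mixture fractions in [0, 1] (0 and 1 are the
#'   endpoints).
#' @param iso_total isoluminant total.
#' @return named list (one per pair) of lists with \code{fraction},
#'   \code{q}, \code{X}.
#' @export
nonspectralLines <- function(swl, fractions = seq(0, 1, by = 0.02),
                             iso_total = 5) {
  pairs <- list(`Rh3-Rh5` = c(1, 3), `Rh3-Rh6` = c(1, 4),
                `Rh4-Rh6` = c(2, 4))
  lapply(pairs, function(pr) {
    i1 <- which.max(swl$q[, pr[1]])
    i2 <- which.max(swl$q[, pr[2]])
    q1 <- swl$q[i1, ]; q2 <- swl$q[i2, ]
    q <- t(vapply(fractions, function(f) {
      mix <- f * q1 + (1 - f) * q2
      iso_total * mix / sum(mix)
    }, numeric(4)))
    colnames(q) <- OPSINS
    list(fraction = fractions, q = q, X = logCapture(q),
         endpoints = swl$peak[c(i1, i2)])
  })
}

#' Tuning curves along the spectral and nonspectral lines
#'
#' Evaluates a fitted interpolator along the single-wavelength locus and
#' the three nonspectral mixture lines, after projecting every query point
#' onto the convex hull of the training set.
#'
#' @param interp a "tpsInterpolator" fitted in 4D log-capture space.
#' @param swl single-wavelength locus (\code{singleWavelengthLine}).
#' @param nsl nonspectral lines (\code{nonspectralLines}).
#' @return list with \code{spectral} (data.frame peak, response) and
#'   \code{nonspectral} (named list of data.frames fraction, response).
#' @export
tuningCurves <- function(interp, swl, nsl) {
  evalLine <- function(X) {
    pr <- projectToHull(X, interp$X)
    evalInterpolator(interp, pr$projected)
  }
  spectral <- data.frame(peak = swl$peak, response = evalLine(swl$X))
  nonspectral <- lapply(nsl, function(line)
    data.frame(fraction = line$fraction, response = evalLine(line$X)))
  list(spectral = spectral, nonspectral = nonspectral)
}

#' Classify a neuron as spectrally or nonspectrally tuned
#'
#' A neuron is nonspectral when its peak interpolated response along any
#' nonspectral mixture line exceeds its peak along the single-wavelength
#' line; otherwise it is spectral. The winning line and the location of the
#' maximum are returned. Invariant to positive rescaling of the responses.
#'
#' @param curves output of \code{tuningCurves}.
#' @return list with \code{class} ("spectral"/"nonspectral"), \code{line},
#'   \code{peak_at} (wavelength in nm or mixture fraction) and
#'   \code{peak_response}.
#' @export
classifySpectral <- function(curves) {
  sp_max <- max(curves$spectral$response)
  sp_at <- curves$spectral$peak[which.max(curves$spectral$response)]
  ns_max <- vapply(curves$nonspectral, function(d) max(d$response),
                   numeric(1))
  if (length(ns_max) && max(ns_max) > sp_max) {
    ln <- names(ns_max)[which.max(ns_max)]
    d <- curves$nonspectral[[ln]]
    list(class = "nonspectral", line = ln,
         peak_at = d$fraction[which.max(d$response)],
         peak_response = max(ns_max))
  } else {
    list(class = "spectral", line = "single-wavelength",
         peak_at = sp_at, peak_response = sp_max)
  }
}
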