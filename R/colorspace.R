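## The tetrachromatic color space: spectrometer calibration, opsin templates,
## photon captures, the 4D -> (3D chromatic + luminance) decomposition, hue /
## saturation and the 2D opponent projection.

## Physical constants used in the photon-flux conversion.
PLANCK_H <- 6.63e-34      # J s
LIGHT_C <- 2.998e8        # m / s
AVOGADRO_NA <- 6.022e23   # 1 / mol

## Unit white-axis vector of the 4D log-capture space.
WHITE_AXIS <- rep(1, 4) / 2

## Orthonormal basis of the chromatic subspace (orthogonal to the white
## axis). Rows are basis vectors; the four opsin axes map to vertices of a
## regular tetrahedron under this basis. Frozen by a test.
TETRA_BASIS <- rbind(c(1, -1, -1, 1),
                     c(1, -1, 1, -1),
                     c(1, 1, -1, -1)) / 2

#' Absolute irradiance from spectrometer counts
#'
#' Converts a raw spectrometer reading to absolute irradiance
#' I(lambda) = C(lambda) (S(lambda) - D(lambda)) / (dt * A * 100) in
#' W/m^2/nm, where C is the per-wavelength calibration (uJ/count), S the
#' sample spectrum and D the dark spectrum (counts), dt the integration time
#' (s) and A the collection area (cm^2).
#'
#' @param sample_counts numeric vector of sample counts S(lambda).
#' @param dark_counts numeric vector of dark counts D(lambda).
#' @param calibration numeric vector of calibration factors (uJ/count).
#' @param integration_time scalar integration time in seconds.
#' @param collection_area scalar collection area in cm^2.
#' @return numeric vector of irradiances (W/m^2/nm).
#' @export
irradianceFromCounts <- function(sample_counts, dark_counts, calibration,
                                 integration_time, collection_area) {
  n <- length(sample_counts)
  if (length(dark_counts) != n || length(calibration) != n)
    stop("sample, dark and calibration spectra must share one wavelength grid")
  if (integration_time <= 0) stop("integration_time must be positive")
  if (collection_area <= 0) stop("collection_area must be positive")
  calibration * (sample_counts - dark_counts) /
    (integration_time * collection_area * 100)
}

#' Photon flux from absolute irradiance
#'
#' E(lambda) = I(lambda) * lambda / (c * h * N_A * 1e6), giving photon flux
#' in microEinstein per nm (lambda in nm; the nm -> m factor is absorbed in
#' the stated 1e6 scaling).
#'
#' @param irradiance numeric vector in W/m^2/nm (must be nonnegative).
#' @param wavelength numeric vector of wavelengths in nm (positive).
#' @return numeric vector of photon fluxes (uE/nm).
#' @export
photonFlux <- function(irradiance, wavelength) {
  if (any(irradiance < 0)) stop("irradiance must be nonnegative")
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  irradiance * wavelength / (LIGHT_C * PLANCK_H * AVOGADRO_NA * 1e6)
}

#' Opsin spectral sensitivity from a visual-pigment nomogram
#'
#' Evaluates a standard A1 visual-pigment alpha-band template (Govardovskii
#' nomogram) parameterized by the wavelength of peak absorbance, and
#' normalizes it to 1 at \code{lambda_max}. The lambda_max values shipped in
#' \code{defaultOpsinPeaks} are approximate fixtures, not measured fits.
#'
#' @param lambda_max peak wavelength in nm.
#' @param lambda numeric vector of wavelengths (nm) at which to evaluate.
#' @return numeric vector of relative sensitivities in [0, 1].
#' @export
opsinSensitivity <- function(lambda_max, lambda) {
  tmpl <- function(lam) {
    x <- lambda_max / lam
    a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
    1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
           exp(-14.9 * (1.104 - x)) + 0.674)
  }
  s <- tmpl(lambda) / tmpl(lambda_max)
  pmin(pmax(s, 0), 1)
}

#' Approximate opsin peak wavelengths (fixture defaults)
#'
#' Nominal lambda_max values (nm) for the fly opsins used by the synthetic
#' stimulus machinery. These are configuration, not measured truth; override
#' them for real work.
#'
#' @return named numeric vector for Rh1, Rh3, Rh4, Rh5, Rh6.
#' @export
defaultOpsinPeaks <- function() {
  c(Rh1 = 480, Rh3 = 345, Rh4 = 375, Rh5 = 437, Rh6 = 508)
}

#' Relative photon captures of a stimulus
#'
#' q_mu = integral(S_mu(lambda) E_stim(lambda)) /
#'        integral(S_mu(lambda) E_bg(lambda)), by trapezoid quadrature on the
#' supplied grid, for each opsin sensitivity curve. A stimulus equal to the
#' background gives q = 1 for every opsin.
#'
#' @param stimulus_flux photon flux of the stimulus on \code{wavelength}.
#' @param background_flux photon flux of the adapting background.
#' @param wavelength shared wavelength grid (nm).
#' @param peaks named numeric vector of opsin lambda_max values; defaults to
#'   the Rh3-Rh6 entries of \code{defaultOpsinPeaks()}.
#' @return named numeric vector of relative captures, one per opsin in
#'   \code{peaks}.
#' @export
relativeCapture <- function(stimulus_flux, background_flux, wavelength,
                            peaks = defaultOpsinPeaks()[OPSINS]) {
  if (length(stimulus_flux) != length(wavelength) ||
      length(background_flux) != length(wavelength))
    stop("spectra and wavelength grid must share length")
  if (min(wavelength) > 300 || max(wavelength) < 700)
    warning("wavelength grid does not cover 300-700 nm")
  q <- vapply(peaks, function(lm) {
    s <- opsinSensitivity(lm, wavelength)
    bg <- pracma::trapz(wavelength, s * background_flux)
    if (bg <= 0) stop("zero background capture for an opsin")
    pracma::trapz(wavelength, s * stimulus_flux) / bg
  }, numeric(1))
  names(q) <- names(peaks)
  q
}

#' Log relative captures
#'
#' X_mu = log((q_mu + 0.001) / 1.001), natural log; the background (q = 1)
#' maps to X = 0 exactly.
#'
#' @param q numeric vector or matrix of relative captures (nonnegative).
#' @return object of the same shape with log captures.
#' @export
logCapture <- function(q) {
  if (any(q < 0)) stop("captures must be nonnegative")
  log((q + 0.001) / 1.001)
}

#' Decompose log captures into chromatic vector and luminance
#'
#' Splits a 4D log-capture vector X into the scalar luminance
#' l = X . u (u the unit white-axis vector (1,1,1,1)/2) and the 3D chromatic
#' vector x = B (X - l u) expressed in a fixed orthonormal tetrahedron basis
#' B. The round trip \code{embedChromatic} reconstructs X exactly.
#'
#' @param X numeric 4-vector, or matrix with 4 columns (one row per
#'   stimulus).
#' @return list with \code{x} (3-vector or 3-column matrix) and \code{l}.
#' @export
decomposeLogCapture <- function(X) {
  if (is.matrix(X)) {
    stopifnot(ncol(X) == 4)
    l <- drop(X %*% WHITE_AXIS)
    x <- (X - outer(l, WHITE_AXIS)) %*% t(TETRA_BASIS)
    list(x = x, l = l)
  } else {
    stopifnot(length(X) == 4)
    l <- sum(X * WHITE_AXIS)
    list(x = drop(TETRA_BASIS %*% (X - l * WHITE_AXIS)), l = l)
  }
}

#' Reconstruct log captures from chromatic vector and luminance
#'
#' Inverse of \code{decomposeLogCapture}: X = t(B) x + l u.
#'
#' @param x chromatic 3-vector or 3-column matrix.
#' @param l luminance scalar or vector.
#' @return 4-vector or 4-column matrix of log captures.
#' @export
embedChromatic <- function(x, l) {
  if (is.matrix(x)) {
    x %*% TETRA_BASIS + outer(l, WHITE_AXIS)
  } else {
    drop(t(TETRA_BASIS) %*% x) + l * WHITE_AXIS
  }
}

#' Two-dimensional opponent projection
#'
#' Component 1 = (Rh5 + Rh6) - (Rh3 + Rh4); component 2 =
#' (Rh4 + Rh5) - (Rh3 + Rh6). Operates on log relative captures X by
#' default; set \code{space = "q"} to project raw captures instead (the
#' choice of space is exposed, not fixed).
#'
#' @param X 4-vector or 4-column matrix ordered (Rh3, Rh4, Rh5, Rh6).
#' @param space "X" (default) or "q"; informational only, the arithmetic is
#'   identical -- pass the matching input.
#' @return 2-vector or 2-column matrix of opponent coordinates.
#' @export
opponentProjection <- function(X, space = c("X", "q")) {
  space <- match.arg(space)
  M <- cbind(c(-1, -1, 1, 1), c(-1, 1, 1, -1))
  if (is.matrix(X)) {
    stopifnot(ncol(X) == 4)
    out <- X %*% M
    colnames(out) <- c("opp1", "opp2")
    out
  } else {
    stopifnot(length(X) == 4)
    drop(crossprod(M, X))
  }
}

#' Hue and saturation of a chromatic vector
#'
#' Saturation s is the length of the chromatic vector; the hue angle theta
#' relative to a unit preferred direction p satisfies p . x = s cos(theta).
#' At s = 0 the direction is undefined and cos(theta) is returned as 0.
#'
#' @param x chromatic 3-vector or 3-column matrix.
#' @param p unit preferred-direction 3-vector.
#' @return list with \code{s} and \code{cos_theta}.
#' @export
hueSaturation <- function(x, p) {
  if (abs(sqrt(sum(p^2)) - 1) > 1e-8) stop("p must be a unit vector")
  if (is.matrix(x)) {
    s <- sqrt(rowSums(x^2))
    ct <- ifelse(s > 0, drop(x %*% p) / s, 0)
  } else {
    s <- sqrt(sum(x^2))
    ct <- if (s > 0) sum(x * p) / s else 0
  }
  list(s = s, cos_theta = ct)
}

#' The frozen tetrahedron basis
#'
#' Returns the fixed 3x4 orthonormal basis of the chromatic subspace used
#' throughout the package (rows orthonormal, orthogonal to the white axis;
#' opsin axes map to regular-tetrahedron vertices).
#'
#' @return 3x4 numeric matrix.
#' @export
tetrahedronBasis <- function() TETRA_BASIS

## Internal: build the full stimulus coordinate table from a capture matrix.
## qmat: n x 4 (Rh3..Rh6); q1: optional Rh1 captures; m: observation counts.
stimulusTableFromQ <- function(qmat, m, q1 = NULL, set = "gamut",
                               stimulus_id = NULL) {
  n <- nrow(qmat)
  if (is.null(stimulus_id)) stimulus_id <- sprintf("s%04d", seq_len(n))
  if (length(m) == 1) m <- rep(m, n)
  if (is.null(q1)) q1 <- rowMeans(qmat)  # broadband-opsin proxy
  X <- logCapture(qmat)
  dec <- decomposeLogCapture(X)
  opp <- opponentProjection(X)
  d <- S4Vectors::DataFrame(
    stimulus_id = stimulus_id,
    q_Rh3 = qmat[, 1], q_Rh4 = qmat[, 2], q_Rh5 = qmat[, 3],
    q_Rh6 = qmat[, 4], q_Rh1 = q1,
    X_Rh3 = X[, 1], X_Rh4 = X[, 2], X_Rh5 = X[, 3], X_Rh6 = X[, 4],
    x1 = dec$x[, 1], x2 = dec$x[, 2], x3 = dec$x[, 3], l = dec$l,
    opp1 = opp[, 1], opp2 = opp[, 2],
    m = as.integer(round(m)), set = rep(set, length.out = n))
  d
}

#' Construct a StimulusSet from relative captures
#'
#' Computes the full set of color-space coordinates (log captures, chromatic
#' vector, luminance, opponent projection) for a matrix of relative captures.
#'
#' @param q n x 4 matrix of relative captures ordered (Rh3, Rh4, Rh5, Rh6).
#' @param m observation counts (scalar or length n).
#' @param q_Rh1 optional Rh1 captures; defaults to the row mean of q as a
#'   broadband proxy.
#' @param set label for the stimulus set ("gamut" or "contrast").
#' @param isoTotal the summed-capture constant if the set is isoluminant.
#' @param stimulus_id optional ids.
#' @return a \code{StimulusSet}.
#' @export
makeStimulusSet <- function(q, m = 1L, q_Rh1 = NULL, set = "gamut",
                            isoTotal = NA_real_, stimulus_id = NULL) {
  q <- as.matrix(q)
  stopifnot(ncol(q) == 4)
  new("StimulusSet",
      data = stimulusTableFromQ(q, m, q_Rh1, set, stimulus_id),
      isoTotal = isoTotal)
}

#' @describeIn makeStimulusSet accessor for the underlying DataFrame.
#' @param x a StimulusSet
#' @export
stimulusData <- function(x) x@data

#' Accessors for StimulusSet coordinates
#'
#' \code{captures} returns the n x 4 relative-capture matrix;
#' \code{logCaptures} the log captures; \code{chromaticCoords} the n x 3
#' tetrahedron coordinates; \code{luminance} the white-axis projection;
#' \code{opponentCoords} the n x 2 opponent coordinates; \code{obsCounts}
#' the per-stimulus observation counts.
#'
#' @param x a StimulusSet.
#' @return matrix or vector as described.
#' @name stimulus-accessors
NULL

#' @rdname stimulus-accessors
#' @export
captures <- function(x) {
  d <- x@data
  out <- cbind(d$q_Rh3, d$q_Rh4, d$q_Rh5, d$q_Rh6)
  colnames(out) <- OPSINS
  out
}

#' @rdname stimulus-accessors
#' @export
logCaptures <- function(x) {
  d <- x@data
  out <- cbind(d$X_Rh3, d$X_Rh4, d$X_Rh5, d$X_Rh6)
  colnames(out) <- OPSINS
  out
}

#' @rdname stimulus-accessors
#' @export
chromaticCoords <- function(x) {
  d <- x@data
  cbind(x1 = d$x1, x2 = d$x2, x3 = d$x3)
}

#' @rdname stimulus-accessors
#' @export
luminance <- function(x) x@data$l

#' @rdname stimulus-accessors
#' @export
opponentCoords <- function(x) {
  d <- x@data
  cbind(opp1 = d$opp1, opp2 = d$opp2)
}

#' @rdname stimulus-accessors
#' @export
obsCounts <- function(x) x@data$m

#' @rdname stimulus-accessors
#' @export
achromaticInput <- function(x) logCapture(x@data$q_Rh1)

#' Read / write stimulus capture tables
#'
#' CSV interchange: one row per stimulus with columns stimulus_id,
#' q_Rh3..q_Rh6, optional q_Rh1, m, set.
#'
#' @param file path to a CSV file.
#' @param x a StimulusSet (for writing).
#' @return \code{readStimulusSet} returns a StimulusSet.
#' @export
readStimulusSet <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  q <- as.matrix(d[, paste0("q_", OPSINS)])
  makeStimulusSet(q, m = if ("m" %in% names(d)) d$m else 1L,
                  q_Rh1 = if ("q_Rh1" %in% names(d)) d$q_Rh1 else NULL,
                  set = if ("set" %in% names(d)) d$set else "gamut",
                  stimulus_id = if ("stimulus_id" %in% names(d))
                    d$stimulus_id else NULL)
}

#' @rdname readStimulusSet
#' @export
writeStimulusSet <- function(x, file) {
  d <- as.data.frame(x@data)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
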