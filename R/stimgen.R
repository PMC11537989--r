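## Synthetic-data and stimulus-design stage: isoluminant gamut sets,
## max-distance subsampling, LED intensity solving, contrast sets, and
## ground-truth response / trace generation.

#' Sample an isoluminant gamut stimulus set
#'
#' Draws capture 4-vectors uniformly on the simplex of constant summed
#' capture (a symmetric Dirichlet scaled to the isoluminant constant),
#' optionally clipped to additional half-space constraints a . q <= b by
#' rejection.
#'
#' @param n number of stimuli.
#' @param iso_total the summed-capture constant of the isoluminant design
#'   (the study design centers the gamut on a total relative capture of 5).
#' @param constraints optional list of lists with elements \code{a}
#'   (4-vector) and \code{b} (scalar), each defining a half-space
#'   a . q <= b.
#' @param m observation counts per stimulus (scalar or length n); see
#'   \code{sessionObservationCounts} for the session-accumulated scheme.
#' @param seed integer seed.
#' @return a \code{StimulusSet} labelled "gamut".
#' @export
sampleGamut <- function(n, iso_total = 5, constraints = NULL, m = 1L,
                        seed = 1) {
  stopifnot(n >= 1, iso_total > 0)
  set.seed(seed)
  draw <- function(k) {
    g <- matrix(stats::rgamma(4 * k, shape = 1), ncol = 4)
    iso_total * g / rowSums(g)
  }
  keep <- function(qm) {
    ok <- rep(TRUE, nrow(qm))
    for (cs in constraints)
      ok <- ok & (drop(qm %*% cs$a) <= cs$b + 1e-12)
    ok
  }
  out <- matrix(numeric(0), ncol = 4)
  tries <- 0
  while (nrow(out) < n) {
    cand <- draw(max(2L * n, 64L))
    cand <- cand[keep(cand), , drop = FALSE]
    out <- rbind(out, cand)
    tries <- tries + 1
    if (tries > 200 && nrow(out) == 0)
      stop("gamut constraints appear infeasible")
  }
  makeStimulusSet(out[seq_len(n), , drop = FALSE], m = m,
                  set = "gamut", isoTotal = iso_total)
}

#' Observation counts from the session design
#'
#' Emulates the imaging design in which each session covers about 20% of the
#' stimulus set with three repeats per stimulus, accumulated over sessions,
#' so counts vary across stimuli.
#'
#' @param n number of stimuli.
#' @param n_sessions number of sessions to accumulate.
#' @param coverage fraction of stimuli covered per session.
#' @param repeats repeats per covered stimulus per session.
#' @param seed integer seed.
#' @return integer vector of counts (>= 1; stimuli never covered get 1).
#' @export
sessionObservationCounts <- function(n, n_sessions = 10, coverage = 0.2,
                                     repeats = 3, seed = 1) {
  set.seed(seed)
  m <- integer(n)
  k <- max(1L, round(coverage * n))
  for (s in seq_len(n_sessions)) {
    idx <- sample.int(n, k)
    m[idx] <- m[idx] + repeats
  }
  pmax(m, 1L)
}

#' Greedy maximum-distance subsampling of a stimulus set
#'
#' Picks a random first stimulus, then iteratively draws each next stimulus
#' uniformly from the \code{pool} not-yet-chosen stimuli that are farthest
#' (summed chromatic-space distance) from those already chosen, until
#' round(fraction * n) stimuli are selected. This spans color space within a
#' session while staying stochastic.
#'
#' @param stimuli a \code{StimulusSet}.
#' @param fraction fraction of stimuli to keep (0 < fraction <= 1).
#' @param pool candidate pool size (study default 10).
#' @param seed integer seed.
#' @return integer vector of selected row indices.
#' @export
maxDistanceSubsample <- function(stimuli, fraction, pool = 10, seed = 1) {
  x <- chromaticCoords(stimuli)
  n <- nrow(x)
  if (n == 0) stop("empty stimulus set")
  stopifnot(fraction > 0, fraction <= 1)
  k <- round(fraction * n)
  set.seed(seed)
  chosen <- sample.int(n, 1)
  D <- as.matrix(stats::dist(x))
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(n), chosen)
    tot <- colSums(D[chosen, rest, drop = FALSE])
    ord <- rest[order(tot, decreasing = TRUE)]
    cand <- ord[seq_len(min(pool, length(ord)))]
    chosen <- c(chosen, if (length(cand) == 1) cand else sample(cand, 1))
  }
  chosen
}

#' A synthetic six-LED stimulation system
#'
#' Gaussian emission spectra at the six nominal peaks (deep UV, UV, violet,
#' blue, lime, orange), each normalized to unit integrated photon flux per
#' unit drive, with the study's maximum and background intensities (uE) as
#' defaults. The spectra are synthetic stand-ins: only the captures they
#' induce matter downstream.
#'
#' @param peaks named numeric vector of LED peak wavelengths (nm).
#' @param widths Gaussian standard deviations (nm).
#' @param max_intensity named maximum intensities (uE).
#' @param background named background intensities (uE).
#' @param wavelength evaluation grid (nm).
#' @return list with elements \code{wavelength}, \code{spectra} (grid x 6
#'   matrix, unit drive), \code{max_intensity}, \code{background},
#'   \code{names}.
#' @export
ledSystem <- function(peaks = c(D = 340, U = 375, V = 420, B = 460,
                                L = 550, O = 590),
                      widths = 15,
                      max_intensity = c(D = 6, U = 7, V = 11, B = 18,
                                        L = 25, O = 160),
                      background = c(D = 0.01, U = 0.06, V = 0.1, B = 0.25,
                                     L = 0.33, O = 0.25),
                      wavelength = seq(300, 700, by = 1)) {
  if (length(widths) == 1) widths <- rep(widths, length(peaks))
  spectra <- vapply(seq_along(peaks), function(k) {
    s <- exp(-(wavelength - peaks[k])^2 / (2 * widths[k]^2))
    s / pracma::trapz(wavelength, s)
  }, numeric(length(wavelength)))
  colnames(spectra) <- names(peaks)
  if (any(background < 0) || any(background > max_intensity))
    stop("background intensities must lie in [0, max]")
  list(wavelength = wavelength, spectra = spectra,
       max_intensity = max_intensity, background = background,
       names = names(peaks))
}

## Capture matrix of an LED system: entry [opsin, led] is the capture of a
## unit drive of that LED relative to the background mixture.
.ledCaptureMatrix <- function(led, peaks = defaultOpsinPeaks()[OPSINS]) {
  bg_flux <- drop(led$spectra %*% led$background)
  M <- vapply(seq_along(led$names), function(k)
    relativeCapture(led$spectra[, k], bg_flux, led$wavelength, peaks),
    numeric(length(peaks)))
  colnames(M) <- led$names
  M
}

#' Solve LED drives for a target capture vector
#'
#' Finds nonnegative LED intensities (bounded by the per-LED maxima) whose
#' mixture best matches a target relative-capture 4-vector, by nonnegative
#' least squares on the linear capture map with a tiny ridge toward the
#' background drives (which makes the solution unique among equivalent
#' mixtures). Targets outside the achievable gamut are flagged and the best
#' feasible point returned.
#'
#' @param target_q target relative captures (Rh3..Rh6).
#' @param led an \code{ledSystem()}.
#' @param peaks opsin lambda_max values.
#' @param tol residual norm above which the target is flagged infeasible.
#' @return list with \code{drive} (named 6-vector, uE), \code{achieved_q},
#'   \code{residual}, logical \code{in_gamut}.
#' @export
solveLedDrive <- function(target_q, led, peaks = defaultOpsinPeaks()[OPSINS],
                          tol = 1e-6) {
  if (any(target_q < 0)) stop("target captures must be nonnegative")
  M <- .ledCaptureMatrix(led, peaks)
  eps <- 1e-6
  A <- rbind(M, sqrt(eps) * diag(ncol(M)))
  bvec <- c(target_q, sqrt(eps) * led$background)
  d <- pracma::lsqnonneg(A, bvec)$x
  # enforce the per-LED maxima: fix violators at their maximum and re-solve
  # the remaining drives until the active set stabilizes
  fix <- integer(0)
  repeat {
    over <- which(d > led$max_intensity + 1e-12)
    if (!length(over)) break
    fix <- union(fix, over)
    free <- setdiff(seq_along(d), fix)
    d[fix] <- led$max_intensity[fix]
    if (!length(free)) break
    rhs <- target_q - drop(M[, fix, drop = FALSE] %*%
                             led$max_intensity[fix])
    Af <- rbind(M[, free, drop = FALSE], sqrt(eps) * diag(length(free)))
    bf <- c(rhs, sqrt(eps) * led$background[free])
    d[free] <- pracma::lsqnonneg(Af, bf)$x
  }
  d <- pmin(d, led$max_intensity)
  names(d) <- led$names
  achieved <- drop(M %*% d)
  resid <- sqrt(sum((achieved - target_q)^2))
  list(drive = d, achieved_q = achieved, residual = resid,
       in_gamut = resid <= max(tol, 1e-4 * sqrt(sum(target_q^2))))
}

#' The single-LED and mixture contrast stimulus set
#'
#' One stimulus per (LED or mixture) x intensity step: within a mixture,
#' each member LED is set to the step intensity, added on top of the
#' background (so a two-LED mixture at 1 uE adds 2 uE of total intensity).
#'
#' @param led an \code{ledSystem()}.
#' @param steps added intensities in uE (study values 0.1, 0.3, 0.5, 0.75,
#'   1, 3).
#' @param mixtures character vector of mixtures as "+"-joined LED letters;
#'   defaults to the study's eleven mixtures.
#' @param peaks opsin lambda_max values.
#' @param m observation counts.
#' @return a \code{StimulusSet} labelled "contrast".
#' @export
buildContrastSet <- function(led,
                             steps = c(0.1, 0.3, 0.5, 0.75, 1, 3),
                             mixtures = c("D+U", "U+L", "D+U+L+O",
                                          "V+B+L+O", "U+V+B", "B+L+O",
                                          "D+L+O", "D+U+V+B+L+O", "V+B",
                                          "D+U+O", "D+U+V"),
                             peaks = defaultOpsinPeaks()[OPSINS],
                             m = 1L) {
  singles <- led$names
  combos <- c(as.list(singles), strsplit(mixtures, "+", fixed = TRUE))
  labels <- c(singles, mixtures)
  bg_flux <- drop(led$spectra %*% led$background)
  rows <- list(); ids <- character(0)
  for (ci in seq_along(combos)) {
    members <- combos[[ci]]
    if (!all(members %in% led$names))
      stop("unknown LED name in mixture: ", labels[ci])
    for (st in steps) {
      add <- stats::setNames(rep(0, length(led$names)), led$names)
      add[members] <- st
      flux <- drop(led$spectra %*% (led$background + add))
      q <- relativeCapture(flux, bg_flux, led$wavelength, peaks)
      rows[[length(rows) + 1L]] <- q
      ids <- c(ids, sprintf("%s@%g", labels[ci], st))
    }
  }
  qm <- do.call(rbind, rows)
  # Rh1 capture computed from the same spectra (broadband channel)
  rh1 <- vapply(seq_along(ids), function(i) {
    members <- combos[[ceiling(i / length(steps))]]
    st <- steps[(i - 1) %% length(steps) + 1]
    add <- stats::setNames(rep(0, length(led$names)), led$names)
    add[members] <- st
    flux <- drop(led$spectra %*% (led$background + add))
    relativeCapture(flux, bg_flux, led$wavelength,
                    peaks = defaultOpsinPeaks()["Rh1"])
  }, numeric(1))
  makeStimulusSet(qm, m = m, q_Rh1 = rh1, set = "contrast",
                  stimulus_id = ids)
}

#' Simulate response amplitudes from a ground-truth model
#'
#' Mean responses come from the ground truth (a \code{CircuitSpec}, in which
#' case all 12 model neurons respond, or a \code{TuningFit} / list of fits);
#' observed per-ROI amplitudes add Gaussian noise with standard deviation
#' sigma / sqrt(m_i). The noise power sigma^2 is recorded in rowData for the
#' noise-corrected R^2.
#'
#' @param stimuli a \code{StimulusSet}.
#' @param ground_truth a CircuitSpec, a TuningFit, or a named list of
#'   TuningFits (one ROI per element).
#' @param sigma amplitude noise standard deviation (>= 0).
#' @param n_roi number of ROIs per ground-truth unit (replicated with
#'   independent noise).
#' @param seed integer seed.
#' @return a \code{HueResponseSet}.
#' @export
simulateResponses <- function(stimuli, ground_truth, sigma = 0, n_roi = 1,
                              seed = 1) {
  stopifnot(sigma >= 0)
  x <- chromaticCoords(stimuli); l <- luminance(stimuli)
  m <- obsCounts(stimuli)
  means <- if (is(ground_truth, "CircuitSpec")) {
    Y <- steadyState(ground_truth, logCaptures(stimuli),
                     achromaticInput(stimuli))
    rownames(Y) <- circuitRoster()
    Y
  } else if (is(ground_truth, "TuningFit")) {
    rbind(unit = predictTuning(ground_truth, x, l))
  } else {
    t(vapply(ground_truth, function(f) predictTuning(f, x, l),
             numeric(nrow(x))))
  }
  units <- rownames(means)
  set.seed(seed)
  amp <- do.call(rbind, lapply(seq_len(nrow(means)), function(a) {
    t(vapply(seq_len(n_roi), function(r)
      means[a, ] + stats::rnorm(ncol(means), sd = sigma / sqrt(m)),
      numeric(ncol(means))))
  }))
  roi <- paste0(rep(units, each = n_roi), "_roi",
                rep(seq_len(n_roi), times = length(units)))
  rownames(amp) <- roi
  colnames(amp) <- stimulusData(stimuli)$stimulus_id
  rd <- S4Vectors::DataFrame(unit = rep(units, each = n_roi),
                             sigma2 = rep(sigma^2, length(roi)),
                             row.names = roi)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(amplitude = amp), rowData = rd,
    colData = stimulusData(stimuli))
  S4Vectors::metadata(se) <- list(seed = seed, sigma = sigma,
                                  isoTotal = stimuli@isoTotal)
  new("HueResponseSet", se)
}

#' Predict responses from any TuningFit
#'
#' Dispatches on the fit kind (linear, lnl, selectivity).
#'
#' @param fit a TuningFit; @param x chromatic coordinates; @param l
#'   luminance.
#' @return predicted responses.
#' @export
predictTuning <- function(fit, x, l) {
  switch(fit@kind,
         linear = linearResponse(x, l, fit),
         lnl = lnlResponse(x, l, fit),
         selectivity = selectivityResponse(x, l, fit),
         stop("unknown fit kind"))
}

#' Simulate stimulus-locked dF/F traces
#'
#' Builds per-ROI dF/F traces with 0.5 s step responses of the given
#' amplitudes at randomized onsets, optional slow sinusoidal baseline drift
#' and white noise, plus at least 15 s of pre- and post-stimulation
#' baseline. Exercise for the signal-extraction stage: running the traces
#' through \code{dffBaseline}/\code{extractAmplitude} recovers the planted
#' amplitudes.
#'
#' @param amplitudes matrix (ROI x stimulus) or vector of step amplitudes.
#' @param fs sampling rate in Hz (>= 15).
#' @param stim_dur stimulus duration (s).
#' @param isi interstimulus interval (s).
#' @param noise_sd white-noise standard deviation on the trace.
#' @param drift amplitude of a slow sinusoidal baseline drift.
#' @param baseline_s baseline duration before and after stimulation (s).
#' @param seed integer seed.
#' @return list with \code{time}, \code{traces} (ROI x sample matrix),
#'   \code{onsets} (data.frame stimulus_id, onset), \code{fs}.
#' @export
simulateTraces <- function(amplitudes, fs = 30, stim_dur = 0.5, isi = 2,
                           noise_sd = 0, drift = 0, baseline_s = 15,
                           seed = 1) {
  stopifnot(fs >= 15)
  if (!is.matrix(amplitudes)) amplitudes <- rbind(roi1 = amplitudes)
  n_stim <- ncol(amplitudes)
  onsets <- baseline_s + (seq_len(n_stim) - 1) * (stim_dur + isi)
  total <- max(onsets) + stim_dur + baseline_s
  time <- seq(0, total, by = 1 / fs)
  set.seed(seed)
  traces <- t(vapply(seq_len(nrow(amplitudes)), function(r) {
    tr <- numeric(length(time))
    for (i in seq_len(n_stim)) {
      # closed step: the boundary sample belongs to the stimulus, matching
      # the closed amplitude-extraction windows
      on <- time >= onsets[i] & time <= onsets[i] + stim_dur
      tr[on] <- tr[on] + amplitudes[r, i]
    }
    tr + drift * sin(2 * pi * time / (4 * 40)) +
      stats::rnorm(length(time), sd = noise_sd)
  }, numeric(length(time))))
  rownames(traces) <- rownames(amplitudes)
  ids <- colnames(amplitudes)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_len(n_stim))
  list(time = time, traces = traces,
       onsets = data.frame(stimulus_id = ids, onset = onsets),
       fs = fs)
}
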