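## Signal extraction: dF/F baselining, amplitude extraction, SNR filtering
## and response normalization. The entry point for real or synthetic traces.

#' Rolling-percentile dF/F with Savitzky-Golay smoothing
#'
#' The baseline F0 is the 25th percentile of a rolling 40 s window of the
#' raw trace; dF/F = (F - F0) / F0 when the trace is a raw fluorescence
#' signal, or F - F0 when \code{ratio = FALSE} (synthetic traces already on
#' a dF/F scale). The result is smoothed with a third-order Savitzky-Golay
#' filter of 0.5 s width.
#'
#' @param trace numeric fluorescence (or dF/F) vector.
#' @param fs sampling rate (Hz).
#' @param window baseline window length (s).
#' @param percentile baseline percentile (0-100).
#' @param smooth smoothing window length (s); 0 disables smoothing.
#' @param ratio divide by the baseline (TRUE for raw fluorescence).
#' @return baseline-corrected, smoothed trace.
#' @export
dffBaseline <- function(trace, fs, window = 40, percentile = 25,
                        smooth = 0.5, ratio = FALSE) {
  n <- length(trace)
  w <- round(window * fs)
  if (w >= n) stop("record shorter than the baseline window")
  f0 <- zoo::rollapply(zoo::zoo(trace), width = w,
                       FUN = function(z) stats::quantile(z, percentile / 100,
                                                         names = FALSE),
                       fill = NA, partial = TRUE, align = "center")
  f0 <- as.numeric(f0)
  dff <- if (ratio) (trace - f0) / f0 else trace - f0
  if (smooth > 0) {
    sw <- round(smooth * fs)
    if (sw %% 2 == 0) sw <- sw + 1
    if (sw > 3) dff <- signal::sgolayfilt(dff, p = 3, n = sw)
  }
  dff
}

#' Extract a response amplitude around a stimulus onset
#'
#' v = mean dF/F over [onset + 0.35, onset + 0.5] s minus the mean over
#' [onset - 0.35, onset - 0.1] s; samples whose timestamps fall in the
#' closed intervals are included.
#'
#' @param trace dF/F vector.
#' @param time timestamps (s), strictly increasing, same length as trace.
#' @param onset stimulus onset (s), or vector of onsets.
#' @return amplitude, or vector of amplitudes.
#' @export
extractAmplitude <- function(trace, time, onset) {
  one <- function(on) {
    stim <- time >= on + 0.35 & time <= on + 0.5
    base <- time >= on - 0.35 & time <= on - 0.1
    if (!any(stim) || !any(base) || on - 0.35 < time[1] ||
        on + 0.5 > time[length(time)])
      stop("amplitude windows fall outside the record")
    mean(trace[stim]) - mean(trace[base])
  }
  vapply(onset, one, numeric(1))
}

#' SNR filter for ROIs
#'
#' SNR = ||v_stim||^2 / ||v_baseline||^2, where v_stim are the stimulus
#' response amplitudes and v_baseline are mean dF/F values over randomly
#' placed 0.15 s windows in the pre- and post-stimulation baseline. ROIs
#' with SNR below 2 are dropped; a zero baseline norm keeps the ROI with a
#' warning (SNR undefined).
#'
#' @param v_stim stimulus amplitudes for one ROI.
#' @param trace dF/F vector; @param time timestamps (s).
#' @param stim_range c(first_onset, last_offset) of the stimulation period.
#' @param n_windows number of random baseline windows (default 100).
#' @param threshold keep threshold (default 2).
#' @param seed integer seed for window placement.
#' @return list with \code{keep}, \code{snr}, \code{sigma2} (mean squared
#'   baseline amplitude) and \code{v_baseline}.
#' @export
snrFilter <- function(v_stim, trace, time, stim_range, n_windows = 100,
                      threshold = 2, seed = 1) {
  if (!length(v_stim)) stop("empty stimulus response vector")
  pre <- time < stim_range[1]
  post <- time > stim_range[2]
  ok_start <- which((pre & time <= stim_range[1] - 0.15) |
                      (post & time <= time[length(time)] - 0.15))
  if (!length(ok_start)) stop("no baseline segments available")
  set.seed(seed)
  starts <- sample(ok_start, n_windows, replace = TRUE)
  v_base <- vapply(starts, function(i) {
    w <- time >= time[i] & time <= time[i] + 0.15
    mean(trace[w])
  }, numeric(1))
  base_pow <- mean(v_base^2)
  if (base_pow == 0) {
    warning("zero baseline norm; SNR undefined, keeping ROI")
    return(list(keep = TRUE, snr = Inf, sigma2 = 0, v_baseline = v_base))
  }
  snr <- mean(v_stim^2) / base_pow
  list(keep = snr >= threshold, snr = snr, sigma2 = base_pow,
       v_baseline = v_base)
}

#' Normalize a response vector
#'
#' v' = v / sqrt( (1/(N-1)) sum v_i^2 ), so that sum v'^2 = N - 1. Scale
#' invariant and idempotent on already-normalized vectors.
#'
#' @param v response amplitudes (length >= 2, not all zero).
#' @return normalized vector.
#' @export
normalizeResponses <- function(v) {
  n <- length(v)
  if (n < 2) stop("need at least 2 stimuli")
  ss <- sum(v^2)
  if (ss == 0) stop("all responses are zero")
  v / sqrt(ss / (n - 1))
}

#' Traces to a response table
#'
#' Full signal-extraction pass for a set of simulated (or long-format real)
#' traces: baseline correction, per-onset amplitude extraction, per-stimulus
#' averaging over repeats, SNR filtering, and amplitude normalization.
#'
#' @param traces list as produced by \code{simulateTraces}.
#' @param stimuli optional \code{StimulusSet} whose table becomes colData.
#' @param baseline logical; run \code{dffBaseline} first.
#' @param snr_threshold SNR cutoff (ROIs below are flagged, not removed).
#' @param seed seed for baseline window placement.
#' @return a \code{HueResponseSet} with assays \code{amplitude} (raw) and
#'   \code{normalized}; rowData has snr, keep, sigma2.
#' @export
tracesToResponses <- function(traces, stimuli = NULL, baseline = FALSE,
                              snr_threshold = 2, seed = 1) {
  time <- traces$time; fs <- traces$fs
  ons <- traces$onsets
  stim_range <- c(min(ons$onset), max(ons$onset) + 0.5)
  ids <- unique(ons$stimulus_id)
  n_roi <- nrow(traces$traces)
  amp <- matrix(0, n_roi, length(ids),
                dimnames = list(rownames(traces$traces), ids))
  snr <- numeric(n_roi); keep <- logical(n_roi); sig2 <- numeric(n_roi)
  for (r in seq_len(n_roi)) {
    tr <- traces$traces[r, ]
    if (baseline) tr <- dffBaseline(tr, fs)
    v_all <- extractAmplitude(tr, time, ons$onset)
    v_mean <- tapply(v_all, ons$stimulus_id, mean)[ids]
    amp[r, ] <- v_mean
    f <- snrFilter(v_mean, tr, time, stim_range, seed = seed + r,
                   threshold = snr_threshold)
    snr[r] <- f$snr; keep[r] <- f$keep; sig2[r] <- f$sigma2
  }
  norm <- t(apply(amp, 1, normalizeResponses))
  cd <- if (!is.null(stimuli)) stimulusData(stimuli) else
    S4Vectors::DataFrame(stimulus_id = ids)
  rd <- S4Vectors::DataFrame(snr = snr, keep = keep, sigma2 = sig2,
                             row.names = rownames(amp))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(amplitude = amp, normalized = norm),
    rowData = rd, colData = cd)
  new("HueResponseSet", se)
}
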