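#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

OPSINS <- c("Rh3", "Rh4", "Rh5", "Rh6")

#' Neuron roster of the medulla chromatic circuit model
#'
#' Fixed ordering of the twelve modeled neurons: the pale/yellow R7 and R8
#' photoreceptor terminals, the Dm9 and Dm8 interneurons, and the five
#' transmedullary output types (Tm5a, Tm5b, Tm5c and the pale/yellow Tm20).
#'
#' @return Character vector of length 12.
#' @export
circuitRoster <- function() {
  c("pR7", "yR7", "pR8", "yR8", "Dm9", "pDm8", "yDm8",
    "Tm5a", "Tm5b", "Tm5c", "pTm20", "yTm20")
}

#' StimulusSet: chromatic stimuli in the four-opsin color space
#'
#' Holds one row per stimulus with its relative photon captures q (background
#' = 1), log relative captures X, chromatic tetrahedron coordinates, luminance
#' (projection on the white axis), 2D opponent coordinates and the number of
#' observations m.
#'
#' @slot data a \code{\link[S4Vectors]{DataFrame}} with columns
#'   \code{stimulus_id}, \code{q_Rh3..q_Rh6}, optional \code{q_Rh1},
#'   \code{X_Rh3..X_Rh6}, \code{x1,x2,x3}, \code{l}, \code{opp1,opp2},
#'   \code{m}, \code{set}.
#' @slot isoTotal numeric(1), the summed-capture constant of the isoluminant
#'   design (NA for sets not built on the isoluminant hyperplane).
#'
#' @export
setClass("StimulusSet",
         representation(data = "DataFrame", isoTotal = "numeric"),
         prototype(isoTotal = NA_real_))

setValidity("StimulusSet", function(object) {
  d <- object@data
  need <- c("stimulus_id", paste0("q_", OPSINS), paste0("X_", OPSINS),
            "x1", "x2", "x3", "l", "opp1", "opp2", "m")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(d$m < 1) || any(d$m != round(d$m)))
    return("observation counts m must be integers >= 1")
  qm <- as.matrix(as.data.frame(d[, paste0("q_", OPSINS)]))
  if (any(qm < 0)) return("captures q must be nonnegative")
  TRUE
})

#' HueResponseSet: ROI-by-stimulus response amplitudes
#'
#' A \code{SummarizedExperiment} whose rows are ROIs (or model neurons) and
#' whose columns are stimuli. The \code{"amplitude"} assay holds response
#' amplitudes v; \code{rowData} carries per-ROI baseline noise power
#' \code{sigma2} and the SNR used for filtering; \code{colData} carries the
#' stimulus table (captures, chromatic coordinates, observation counts m).
#'
#' @export
setClass("HueResponseSet", contains = "SummarizedExperiment")

#' TuningFit: fitted parameters of a chromatic encoding model
#'
#' @slot kind "linear", "lnl" or "selectivity".
#' @slot p unit preferred-direction 3-vector in the color tetrahedron.
#' @slot gain output gain (a_L for the linear model, a_NL otherwise).
#' @slot b luminance coefficient.
#' @slot gamma saturation asymmetry of the modified tanh (lnl only, else NA).
#' @slot kappa hue-sharpness of the selectivity model (else NA).
#' @slot alpha saturation exponent of the selectivity model (else NA).
#' @slot r2 noise-corrected R squared of the fit.
#' @slot sse weighted sum of squared errors at the optimum.
#' @slot converged logical flag from the optimizer.
#' @export
setClass("TuningFit",
         representation(kind = "character", p = "numeric", gain = "numeric",
                        b = "numeric", gamma = "numeric", kappa = "numeric",
                        alpha = "numeric", r2 = "numeric", sse = "numeric",
                        converged = "logical", extra = "list"),
         prototype(gamma = NA_real_, kappa = NA_real_, alpha = NA_real_,
                   r2 = NA_real_, sse = NA_real_, converged = TRUE,
                   extra = list()))

setValidity("TuningFit", function(object) {
  if (!object@kind %in% c("linear", "lnl", "selectivity"))
    return("kind must be linear, lnl or selectivity")
  if (length(object@p) != 3) return("p must be a 3-vector")
  n <- sqrt(sum(object@p^2))
  if (n > 0 && abs(n - 1) > 1e-6) return("p must be unit norm (or zero)")
  if (!is.na(object@gamma) && abs(object@gamma) >= 1)
    return("gamma must lie in (-1, 1)")
  TRUE
})

#' CircuitSpec: the twelve-neuron connectome-constrained rate model
#'
#' Parameters of the recurrent model
#' tau_a dy_a/dt = -y_a + f(g_a(sum_b w_ab y_b + sum_mu j_amu X_mu + p_a x0)),
#' where f is a modified tanh with per-neuron asymmetry gamma_a (Dm9 fixed at
#' 0). Row a of w holds the inputs to neuron a; every row is normalized so
#' that sum_b |w_ab| + sum_mu j_amu = 1.
#'
#' @slot w 12x12 signed normalized weight matrix (w[a,b]: b -> a).
#' @slot j 12x4 opsin input weights; nonzero only on the photoreceptor
#'   diagonal, one shared magnitude.
#' @slot p length-12 achromatic (R1-6) input weights; nonzero only for the
#'   two Dm8s and the five Tm neurons.
#' @slot g length-12 gains; one value shared across the four photoreceptors
#'   and one across the two Dm8s.
#' @slot gamma length-12 saturation asymmetries; Dm9 fixed at 0.
#' @slot tau length-12 time constants in seconds (irrelevant at steady state).
#' @slot counts the raw 12x12 synaptic count matrix the weights came from
#'   (direct + disynaptic for Tm-Tm entries), kept for re-normalization.
#' @slot signs 12x12 sign matrix (+1/-1, 0 where no edge); entries marked
#'   free in the source table are recorded in \code{freeSigns}.
#' @slot freeSigns two-column matrix (a, b) of recurrent Tm edges whose sign
#'   is determined by search rather than by transmitter identity.
#' @export
setClass("CircuitSpec",
         representation(w = "matrix", j = "matrix", p = "numeric",
                        g = "numeric", gamma = "numeric", tau = "numeric",
                        counts = "matrix", signs = "matrix",
                        freeSigns = "matrix"))

setValidity("CircuitSpec", function(object) {
  n <- 12L
  if (!all(dim(object@w) == c(n, n))) return("w must be 12x12")
  if (!all(dim(object@j) == c(n, 4))) return("j must be 12x4")
  if (length(object@p) != n || length(object@g) != n ||
      length(object@gamma) != n || length(object@tau) != n)
    return("p, g, gamma, tau must have length 12")
  if (any(abs(object@gamma) >= 1)) return("gamma must lie in (-1, 1)")
  if (abs(object@gamma[5]) > 0) return("Dm9 gamma is fixed at 0")
  if (any(object@tau <= 0)) return("tau must be positive")
  if (any(object@j < 0)) return("opsin input weights j must be nonnegative")
  rs <- rowSums(abs(object@w)) + rowSums(object@j)
  live <- rs > 0
  if (any(abs(rs[live] - 1) > 1e-8))
    return("rows must satisfy sum|w| + sum j = 1 (ablation excepted)")
  TRUE
})

#' @rdname StimulusSet-class
#' @param object a StimulusSet
#' @export
setMethod("show", "StimulusSet", function(object) {
  d <- object@data
  cat("StimulusSet with", nrow(d), "stimuli\n")
  if (!is.na(object@isoTotal))
    cat("  isoluminant total capture:", object@isoTotal, "\n")
  if ("set" %in% colnames(d))
    cat("  sets:", paste(names(table(d$set)), table(d$set),
                         sep = "=", collapse = ", "), "\n")
  cat("  observations m:", paste(range(d$m), collapse = "-"), "\n")
})

#' @rdname TuningFit-class
#' @param object a TuningFit
#' @export
setMethod("show", "TuningFit", function(object) {
  cat(sprintf("TuningFit <%s>  gain=%.4g  b=%.4g", object@kind,
              object@gain, object@b))
  if (object@kind == "lnl") cat(sprintf("  gamma=%.4g", object@gamma))
  if (object@kind == "selectivity")
    cat(sprintf("  kappa=%.4g  alpha=%.4g", object@kappa, object@alpha))
  cat(sprintf("\n  p = (%.3f, %.3f, %.3f)", object@p[1], object@p[2],
              object@p[3]))
  if (!is.na(object@r2)) cat(sprintf("  R2 = %.4f", object@r2))
  cat("\n")
})

#' @rdname CircuitSpec-class
#' @param object a CircuitSpec
#' @export
setMethod("show", "CircuitSpec", function(object) {
  cat("CircuitSpec: 12-neuron recurrent rate model\n")
  cat("  roster:", paste(circuitRoster(), collapse = ", "), "\n")
  cat(sprintf("  gains %.3g-%.3g, shared j = %.4g, free-sign Tm edges: %d\n",
              min(object@g), max(object@g), max(object@j),
              nrow(object@freeSigns)))
  audit <- freeParameterAudit(object)
  cat("  free parameters:", audit["total"], "\n")
})
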