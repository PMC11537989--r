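## CircuitSpec construction: synaptic-count weight normalization, the
## free-parameter audit, connectivity accounting, and the packaged
## (synthetic) example circuit.

## Roster index helpers.
PR_IDX <- 1:4; DM9_IDX <- 5L; DM8_IDX <- 6:7; TM_IDX <- 8:12

#' Normalize synaptic counts into signed weights
#'
#' Scales each row of a count matrix so the absolute weights sum to one,
#' then applies the sign pattern. When a row also receives a direct opsin
#' input fraction (photoreceptors) or a free-parameter weight (the
#' unreconstructed Dm8-Dm8 connections), the count-derived entries share the
#' remaining budget so that sum_b |w_ab| + sum_mu j_amu = 1 holds exactly.
#'
#' @param counts nonnegative matrix, counts[a, b] = synapses from b onto a
#'   (Tm-Tm entries should already sum direct + disynaptic paths).
#' @param signs matrix of the same shape with entries +1, -1 (or 0 where no
#'   edge exists).
#' @param budget per-row weight budget left for the counts (1 - j fraction -
#'   free-weight fraction); scalar or vector.
#' @return signed weight matrix with rowSums(abs(w)) equal to \code{budget}.
#' @export
normalizeWeights <- function(counts, signs = NULL, budget = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("synaptic counts must be nonnegative")
  if (is.null(signs)) signs <- matrix(1, nrow(counts), ncol(counts))
  if (length(budget) == 1) budget <- rep(budget, nrow(counts))
  rs <- rowSums(counts)
  w <- counts
  for (a in seq_len(nrow(counts))) {
    if (rs[a] == 0) {
      if (budget[a] > 0) stop("all-zero input row ", a)
      next
    }
    w[a, ] <- budget[a] * counts[a, ] / rs[a]
  }
  w * sign(signs)
}

## Build (w, j) from counts + signs + the free fractions. j_frac is the
## shared opsin-input magnitude on the photoreceptor diagonal; dm8_frac is
## the length-2 vector of |w| for the (unreconstructed) yDm8 -> pDm8 and
## pDm8 -> yDm8 connections (sign negative, indirect connections are
## inhibitory).
buildWeights <- function(counts, signs, j_frac, dm8_frac) {
  n <- 12L
  budget <- rep(1, n)
  budget[PR_IDX] <- 1 - j_frac
  budget[DM8_IDX] <- 1 - dm8_frac
  w <- normalizeWeights(counts, signs, budget)
  # the Dm8-Dm8 entries come from the free parameters, not counts
  w[6, 7] <- -dm8_frac[1]
  w[7, 6] <- -dm8_frac[2]
  j <- matrix(0, n, 4)
  diag(j[PR_IDX, ]) <- j_frac
  list(w = w, j = j)
}

#' Construct a CircuitSpec from synaptic counts
#'
#' @param counts 12x12 synaptic count matrix (counts[a, b]: b -> a; Tm-Tm
#'   entries must already contain direct + disynaptic sums).
#' @param signs 12x12 sign matrix (+1/-1, 0 for absent edges).
#' @param j_frac shared opsin-input weight of the four photoreceptors (their
#'   row budget not taken by synaptic inputs).
#' @param dm8_frac magnitudes of the two free Dm8-Dm8 weights.
#' @param p length-12 achromatic R1-6 input weights (nonzero only for Dm8s,
#'   positive, and Tm neurons, free sign).
#' @param g length-12 gains (photoreceptors share one value, Dm8s another).
#' @param gamma length-12 tanh asymmetries (Dm9 must be 0).
#' @param tau time constants in seconds.
#' @param freeSigns optional k x 2 matrix of (a, b) index pairs of recurrent
#'   Tm edges whose sign is settled by search.
#' @return a validated \code{CircuitSpec}.
#' @export
makeCircuitSpec <- function(counts, signs, j_frac = 0.8,
                            dm8_frac = c(0.2, 0.2), p = numeric(12),
                            g = rep(1, 12), gamma = numeric(12),
                            tau = rep(0.05, 12),
                            freeSigns = matrix(integer(0), 0, 2)) {
  if (any(p[c(PR_IDX, DM9_IDX)] != 0))
    stop("achromatic input p only reaches Dm8 and Tm neurons")
  if (any(p[DM8_IDX] < 0)) stop("R1-6 input onto Dm8 must be positive")
  g[PR_IDX] <- g[PR_IDX[1]]   # shared photoreceptor gain
  g[DM8_IDX] <- g[DM8_IDX[1]] # shared Dm8 gain
  gamma[DM9_IDX] <- 0
  wj <- buildWeights(counts, signs, j_frac, dm8_frac)
  new("CircuitSpec", w = wj$w, j = wj$j, p = p, g = g, gamma = gamma,
      tau = tau, counts = as.matrix(counts), signs = as.matrix(signs),
      freeSigns = freeSigns)
}

#' Free-parameter audit of the circuit model
#'
#' Counts the free parameters of the staged fit from the model structure:
#' gains (one shared across the four photoreceptors, one across the two
#' Dm8s, one per remaining neuron), tanh asymmetries (every neuron except
#' Dm9), the single shared opsin-input magnitude, the achromatic R1-6
#' weights (two Dm8s + five Tm neurons) and the two unreconstructed Dm8-Dm8
#' weights.
#'
#' @param spec a CircuitSpec.
#' @return named integer vector with gains, gamma, opsin_input, achromatic,
#'   dm8_weights and total.
#' @export
freeParameterAudit <- function(spec) {
  gain_groups <- c(list(PR_IDX, DM9_IDX, DM8_IDX), as.list(TM_IDX))
  n_gain <- length(gain_groups)
  n_gamma <- 12L - 1L                       # Dm9 fixed at 0
  n_j <- 1L                                 # shared photoreceptor magnitude
  n_p <- length(DM8_IDX) + length(TM_IDX)   # R1-6 targets
  n_dm8 <- 2L
  c(gains = n_gain, gamma = n_gamma, opsin_input = n_j, achromatic = n_p,
    dm8_weights = n_dm8,
    total = n_gain + n_gamma + n_j + n_p + n_dm8)
}

#' Read a connectivity edge list and aggregate it into circuit counts
#'
#' The CSV (or data.frame) has columns \code{pre}, \code{post},
#' \code{count}, \code{path} ("direct" or "disynaptic") and \code{sign}
#' ("+", "-" or "free"). Direct and disynaptic counts on the same Tm-Tm edge
#' are summed before normalization; edges marked "free" get sign -1
#' initially and are recorded for the sign search.
#'
#' @param table data.frame or CSV path.
#' @return list with \code{counts}, \code{signs} (12x12 matrices in roster
#'   order) and \code{freeSigns} (k x 2 index matrix).
#' @export
circuitCountsFromTable <- function(table) {
  if (is.character(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  roster <- circuitRoster()
  bad <- setdiff(unique(c(table$pre, table$post)), roster)
  if (length(bad)) stop("unknown neurons: ", paste(bad, collapse = ", "))
  n <- length(roster)
  counts <- matrix(0, n, n, dimnames = list(roster, roster))
  signs <- matrix(0, n, n, dimnames = list(roster, roster))
  free <- NULL
  for (k in seq_len(nrow(table))) {
    a <- match(table$post[k], roster); b <- match(table$pre[k], roster)
    counts[a, b] <- counts[a, b] + table$count[k]
    sg <- table$sign[k]
    signs[a, b] <- if (sg == "+") 1 else -1
    if (sg == "free") free <- rbind(free, c(a, b))
  }
  if (is.null(free)) free <- matrix(integer(0), 0, 2)
  list(counts = counts, signs = signs, freeSigns = unique(free))
}

#' The packaged example circuit (synthetic)
#'
#' A clearly synthetic, illustrative CircuitSpec: the synapse counts are
#' invented integers (real counts are user-suppliable via
#' \code{circuitCountsFromTable}), but the wiring motifs and sign
#' constraints follow the medulla chromatic circuit: photoreceptors drive
#' Dm9, which feeds back negatively onto all photoreceptors (opponency);
#' R7s inhibit their home-column Dm8s, which receive excitatory R1-6 input
#' and inhibit each other; R7/R8 are inhibitory onto Tm5a, Tm5b and the
#' Tm20s, R8 is excitatory onto Tm5c; pDm8 excites Tm5b and yDm8 inhibits
#' Tm5a; and the Tm neurons are coupled by direct + disynaptic recurrent
#' connections (inhibitory here; the Tm5a/Tm5b pair is marked sign-free for
#' the sign search).
#'
#' @return a \code{CircuitSpec}.
#' @export
exampleCircuitSpec <- function() {
  tbl <- exampleConnectivityTable()
  agg <- circuitCountsFromTable(tbl)
  p <- numeric(12)
  p[DM8_IDX] <- 0.5             # R1-6 -> Dm8, positive
  p[TM_IDX] <- -0.2             # R1-6 -> Tm, sign free in the fit
  p[10] <- 0.6                  # Tm5c: tonic positive drive, so its
                                # inhibition onto the other Tms carries an
                                # offset that recurrence ablation removes
  g <- numeric(12)
  g[PR_IDX] <- 1.6; g[DM9_IDX] <- 0.8; g[DM8_IDX] <- 1.4; g[TM_IDX] <- 3
  gamma <- numeric(12)
  gamma[TM_IDX] <- -0.7         # hyperpolarizing side saturates early,
                                # depolarizing side stays expansive
  makeCircuitSpec(agg$counts, agg$signs, j_frac = 0.8,
                  dm8_frac = c(0.25, 0.25), p = p, g = g, gamma = gamma,
                  freeSigns = agg$freeSigns)
}

#' @rdname exampleCircuitSpec
#' @export
exampleConnectivityTable <- function() {
  edge <- function(pre, post, count, path, sign)
    data.frame(pre = pre, post = post, count = count, path = path,
               sign = sign, stringsAsFactors = FALSE)
  rbind(
    # photoreceptors drive Dm9; Dm9 inhibits them back
    edge(c("pR7", "yR7", "pR8", "yR8"), "Dm9", c(40, 40, 40, 40),
         "direct", "+"),
    edge("Dm9", c("pR7", "yR7", "pR8", "yR8"), c(30, 30, 30, 30),
         "direct", "-"),
    # home-column R7 inhibits its Dm8
    edge("pR7", "pDm8", 35, "direct", "-"),
    edge("yR7", "yDm8", 35, "direct", "-"),
    # Tm5a: yellow-column inhibition, self-excitation, Tm5c suppression
    edge("yR7", "Tm5a", 30, "direct", "-"),
    edge("yDm8", "Tm5a", 20, "direct", "-"),
    edge("Tm5a", "Tm5a", 25, "direct", "+"),
    edge("Tm5b", "Tm5a", 10, "direct", "free"),
    edge("Tm5c", "Tm5a", 20, "disynaptic", "-"),
    # Tm5b: pale-column inputs, mirrored motifs
    edge("pR7", "Tm5b", 30, "direct", "-"),
    edge("pDm8", "Tm5b", 20, "direct", "+"),
    edge("Tm5b", "Tm5b", 25, "direct", "+"),
    edge("Tm5a", "Tm5b", 10, "direct", "free"),
    edge("Tm5c", "Tm5b", 20, "disynaptic", "-"),
    # Tm5c: excitatory yR8 drive, light recurrence
    edge("yR8", "Tm5c", 35, "direct", "+"),
    edge("Tm5b", "Tm5c", 5, "direct", "-"),
    # Tm20s: home-column R8 (and R7) inhibition plus Tm5c recurrence
    edge("pR8", "pTm20", 30, "direct", "-"),
    edge("pR7", "pTm20", 10, "direct", "-"),
    edge("pTm20", "pTm20", 25, "direct", "+"),
    edge("Tm5c", "pTm20", 20, "disynaptic", "-"),
    edge("yR8", "yTm20", 30, "direct", "-"),
    edge("yR7", "yTm20", 10, "direct", "-"),
    edge("yTm20", "yTm20", 25, "direct", "+"),
    edge("Tm5c", "yTm20", 20, "disynaptic", "-"))
}

#' Zero the recurrent connections among Tm neurons
#'
#' Sets the direct + disynaptic weights between all Tm neurons (including
#' Tm5c) to zero, leaving every other entry untouched; rows are deliberately
#' not re-normalized, so the ablated circuit violates the unit row budget by
#' construction.
#'
#' @param spec a CircuitSpec.
#' @return the ablated CircuitSpec (not re-validated).
#' @export
ablateRecurrence <- function(spec) {
  spec@w[TM_IDX, TM_IDX] <- 0
  spec
}

#' Block the synaptic output of one Tm neuron (TeNT)
#'
#' Zeroes the outgoing weights of the target neuron so it no longer
#' influences the rest of the circuit while still receiving its inputs and
#' responding -- the model analogue of expressing tetanus toxin light chain
#' in that cell type. Refit the target's gain and asymmetry afterwards with
#' \code{refitTent}.
#'
#' @param spec a CircuitSpec.
#' @param target roster name or index of a Tm neuron.
#' @return the perturbed CircuitSpec.
#' @export
simulateTent <- function(spec, target) {
  a <- if (is.character(target)) match(target, circuitRoster()) else target
  if (is.na(a) || !(a %in% TM_IDX))
    stop("TeNT target must be a Tm neuron")
  spec@w[, a] <- 0
  spec
}

#' Mix pale and yellow Tm20 responses
#'
#' The recorded Tm20 population mixes pale and yellow columns in their
#' retinal proportions, so model predictions are compared as the weighted
#' average y = (1/3) y_pTm20 + (2/3) y_yTm20.
#'
#' @param y_pTm20,y_yTm20 response vectors on the same stimulus index.
#' @return mixed response vector.
#' @export
mixTm20 <- function(y_pTm20, y_yTm20) {
  if (length(y_pTm20) != length(y_yTm20))
    stop("pTm20 and yTm20 responses must share the stimulus index")
  y_pTm20 / 3 + 2 * y_yTm20 / 3
}

#' Connectivity accounting
#'
#' Counts the identified input and output sites of a set of seed neurons in
#' an edge list, applying the reconstruction thresholds (inputs kept when a
#' presynaptic partner contributes more than \code{input_threshold}
#' synapses, outputs when a postsynaptic partner receives more than
#' \code{output_threshold}), and expresses them as percentages of the total
#' post- and presynaptic site counts.
#'
#' @param table data.frame with columns pre, post, count (path/sign
#'   ignored), or a CSV path.
#' @param seeds character vector of seed neuron names.
#' @param input_threshold keep input partners with count > this (default 2).
#' @param output_threshold keep output partners with count > this (default
#'   4).
#' @param total_post_sites,total_pre_sites total site counts of the seeds
#'   (denominators of the percentages; NA if unknown).
#' @return list with input_sites, input_partners, input_pct, output_sites,
#'   output_partners, output_pct.
#' @export
summarizeConnectivity <- function(table, seeds,
                                  input_threshold = 2, output_threshold = 4,
                                  total_post_sites = NA,
                                  total_pre_sites = NA) {
  if (is.character(table) && length(table) == 1 && file.exists(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  if (any(table$count < 0)) stop("synapse counts must be nonnegative")
  inputs <- table[table$post %in% seeds & !(table$pre %in% seeds), ,
                  drop = FALSE]
  outputs <- table[table$pre %in% seeds & !(table$post %in% seeds), ,
                   drop = FALSE]
  per_partner <- function(d, key) {
    if (!nrow(d)) return(numeric(0))
    tapply(d$count, d[[key]], sum)
  }
  pin <- per_partner(inputs, "pre")
  pout <- per_partner(outputs, "post")
  pin <- pin[pin > input_threshold]
  pout <- pout[pout > output_threshold]
  list(input_sites = sum(pin), input_partners = length(pin),
       input_pct = 100 * sum(pin) / total_post_sites,
       output_sites = sum(pout), output_partners = length(pout),
       output_pct = 100 * sum(pout) / total_pre_sites)
}
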