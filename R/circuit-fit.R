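## Staged gradient fitting of the circuit model, sign search over the
## free-sign recurrent edges, TeNT refits and the random-weight null.

.atanhG <- function(g) atanh(pmin(pmax(g / 0.999, -0.99999), 0.99999))

## Stage neuron sets: photoreceptor-Dm9, Dm8, Tm.
stageNeurons <- function(stage) {
  switch(stage, stage1 = 1:5, stage2 = 6:7, stage3 = 8:12,
         stop("unknown stage"))
}

## Extract the free-parameter vector of a stage from a spec
## (unconstrained parameterization: log gains, logit weight fractions,
## atanh-scaled gammas; achromatic Tm weights are raw).
stageTheta <- function(spec, stage) {
  switch(stage,
    stage1 = c(log(spec@g[1]), log(spec@g[5]),
               stats::qlogis(sum(spec@j[1, ])),
               .atanhG(spec@gamma[PR_IDX])),
    stage2 = c(log(spec@p[6]), log(spec@p[7]),
               stats::qlogis(max(-spec@w[6, 7], 1e-6)),
               stats::qlogis(max(-spec@w[7, 6], 1e-6)),
               log(spec@g[6]), .atanhG(spec@gamma[DM8_IDX])),
    stage3 = c(spec@p[TM_IDX], log(spec@g[TM_IDX]),
               .atanhG(spec@gamma[TM_IDX])),
    stop("unknown stage"))
}

## Apply a stage parameter vector to a spec. Each stage rebuilds only the
## weight rows it owns, so perturbations (ablation, TeNT, null draws)
## elsewhere survive refits.
stageApply <- function(spec, stage, theta) {
  if (stage == "stage1") {
    spec@g[PR_IDX] <- exp(theta[1])
    spec@g[DM9_IDX] <- exp(theta[2])
    jf <- stats::plogis(theta[3])
    rs <- rowSums(spec@counts[PR_IDX, , drop = FALSE])
    spec@w[PR_IDX, ] <- sign(spec@signs[PR_IDX, ]) *
      (1 - jf) * spec@counts[PR_IDX, ] / rs
    spec@j[PR_IDX, ] <- 0
    for (a in PR_IDX) spec@j[a, a] <- jf
    spec@gamma[PR_IDX] <- 0.999 * tanh(theta[4:7])
  } else if (stage == "stage2") {
    spec@p[6] <- exp(theta[1]); spec@p[7] <- exp(theta[2])
    d1 <- stats::plogis(theta[3]); d2 <- stats::plogis(theta[4])
    cts <- spec@counts; cts[6, 7] <- 0; cts[7, 6] <- 0
    rs <- rowSums(cts[DM8_IDX, , drop = FALSE])
    spec@w[6, ] <- sign(spec@signs[6, ]) * (1 - d1) * cts[6, ] / rs[1]
    spec@w[7, ] <- sign(spec@signs[7, ]) * (1 - d2) * cts[7, ] / rs[2]
    spec@w[6, 7] <- -d1
    spec@w[7, 6] <- -d2
    spec@g[DM8_IDX] <- exp(theta[5])
    spec@gamma[DM8_IDX] <- 0.999 * tanh(theta[6:7])
  } else if (stage == "stage3") {
    spec@p[TM_IDX] <- theta[1:5]
    spec@g[TM_IDX] <- exp(theta[6:10])
    spec@gamma[TM_IDX] <- 0.999 * tanh(theta[11:15])
  } else if (startsWith(stage, "tent")) {
    a <- as.integer(sub("tent", "", stage))
    spec@g[a] <- exp(theta[1])
    spec@gamma[a] <- 0.999 * tanh(theta[2])
  } else stop("unknown stage")
  spec
}

#' Control settings for the circuit fit
#'
#' Batch size 64, at most 100 epochs at learning rate 0.001 with Adam, early
#' stop when the full-data loss improves by less than \code{reltol} over an
#' epoch. \code{solver_tol} is the fixed-point tolerance used during
#' optimization (tighter than the reporting default so gradients are clean).
#'
#' @param batch_size,epochs,lr,reltol,patience,solver_tol,seed see above.
#' @return list of settings.
#' @export
fitControl <- function(batch_size = 64, epochs = 100, lr = 0.001,
                       reltol = 1e-5, patience = 2, solver_tol = 1e-7,
                       seed = 1) {
  list(batch_size = batch_size, epochs = epochs, lr = lr, reltol = reltol,
       patience = patience, solver_tol = solver_tol, seed = seed)
}

## Adam on one stage. Returns spec with fitted parameters, plus the
## per-epoch full-data loss trajectory.
adamStage <- function(spec, stage, X, x0, V, m, control) {
  neurons <- if (startsWith(stage, "tent"))
    as.integer(sub("tent", "", stage)) else stageNeurons(stage)
  theta <- stageTheta0 <- if (startsWith(stage, "tent")) {
    a <- as.integer(sub("tent", "", stage))
    c(log(spec@g[a]), .atanhG(spec@gamma[a]))
  } else stageTheta(spec, stage)
  applyFun <- function(sp, th) stageApply(sp, stage, th)
  n <- nrow(X)
  mvec <- if (length(m) == 1) rep(m, n) else m
  mAdam <- numeric(length(theta)); vAdam <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  # parameter regions where the fixed point cannot be reached are treated
  # as infeasible: the loss is +Inf and the batch update is skipped
  full_loss <- function(th)
    tryCatch(correlationLoss(steadyState(applyFun(spec, th), X, x0,
                                         tol = control$solver_tol),
                             V, mvec, neurons),
             error = function(e) Inf)
  traj <- full_loss(theta)
  best_theta <- theta; best_loss <- traj[1]
  stall <- 0
  for (ep in seq_len(control$epochs)) {
    set.seed(control$seed + 1000L * ep)
    ord <- sample.int(n)
    starts <- seq(1, n, by = control$batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + control$batch_size - 1, n)]
      lg <- tryCatch(
        circuitLossGrad(spec, applyFun, theta,
                        X[idx, , drop = FALSE], x0[idx],
                        V[, idx, drop = FALSE], mvec[idx], neurons,
                        tol = control$solver_tol),
        error = function(e) NULL)
      if (is.null(lg)) next
      t <- t + 1
      mAdam <- b1 * mAdam + (1 - b1) * lg$grad
      vAdam <- b2 * vAdam + (1 - b2) * lg$grad^2
      mhat <- mAdam / (1 - b1^t); vhat <- vAdam / (1 - b2^t)
      theta <- theta - control$lr * mhat / (sqrt(vhat) + eps)
    }
    L <- full_loss(theta)
    traj <- c(traj, L)
    if (is.finite(L) && L < best_loss - 1e-12) {
      best_loss <- L; best_theta <- theta
    }
    prev <- traj[length(traj) - 1]
    if (is.finite(L) && is.finite(prev) &&
        abs(prev - L) < control$reltol) {
      stall <- stall + 1
      if (stall >= control$patience) break
    } else stall <- 0
  }
  list(spec = applyFun(spec, best_theta), loss = best_loss, traj = traj)
}

## Mean per-unit response matrix (roster x stimuli) from a HueResponseSet
## whose rowData carries a `unit` column naming circuit neurons.
responseMatrix <- function(responses) {
  if (is(responses, "HueResponseSet")) {
    amp <- SummarizedExperiment::assay(responses, "amplitude")
    unit <- SummarizedExperiment::rowData(responses)$unit
    if (is.null(unit)) unit <- rownames(amp)
    V <- do.call(rbind, lapply(circuitRoster(), function(u)
      colMeans(amp[unit == u, , drop = FALSE])))
    rownames(V) <- circuitRoster()
    V
  } else as.matrix(responses)
}

#' Three-stage fit of the circuit model
#'
#' Fits the 29 free parameters in three stages -- photoreceptor/Dm9 (shared
#' photoreceptor gain, Dm9 gain, shared opsin-input magnitude, photoreceptor
#' asymmetries), then the Dm8 circuit (positive R1-6 weights, the two
#' negative Dm8-Dm8 weights, shared gain, asymmetries), then the Tm circuit
#' (per-Tm R1-6 weight with free sign, gain and asymmetry) -- by Adam on the
#' negative-correlation loss, with gradients through the fixed point
#' supplied by implicit differentiation. Feedforward and recurrent Tm
#' weights stay fixed at their synaptic-count values throughout.
#'
#' @param spec the starting CircuitSpec (structure + initial values).
#' @param responses a \code{HueResponseSet} (ROIs tagged with circuit units
#'   in rowData$unit) or a 12 x n matrix in roster order.
#' @param stimuli the \code{StimulusSet} the responses index.
#' @param control a \code{fitControl()} list.
#' @param sigma2 noise power for the reported noise-corrected R^2.
#' @param stages which stages to run (default all three).
#' @return list with \code{spec} (fitted), \code{loss} (final full-data
#'   loss), \code{traj} (named list of per-stage loss trajectories),
#'   \code{r2} (per-neuron noise-corrected R^2) and \code{stages}.
#' @export
stagedFit <- function(spec, responses, stimuli, control = fitControl(),
                      sigma2 = 0,
                      stages = c("stage1", "stage2", "stage3")) {
  V <- responseMatrix(responses)
  if (any(!is.finite(V)))
    stop("response data missing for stage neurons")
  X <- logCaptures(stimuli)
  x0 <- achromaticInput(stimuli)
  m <- obsCounts(stimuli)
  traj <- list()
  for (st in stages) {
    res <- adamStage(spec, st, X, x0, V, m, control)
    spec <- res$spec
    traj[[st]] <- res$traj
  }
  Y <- tryCatch(steadyState(spec, X, x0, tol = control$solver_tol),
                error = function(e) NULL)
  if (is.null(Y)) {
    r2 <- rep(NA_real_, 12); names(r2) <- circuitRoster()
    return(list(spec = spec, loss = Inf, traj = traj, r2 = r2,
                stages = stages))
  }
  r2 <- vapply(seq_len(12), function(a)
    noiseCorrectedR2(Y[a, ], V[a, ], m, sigma2), numeric(1))
  names(r2) <- circuitRoster()
  list(spec = spec, loss = correlationLoss(Y, V, m), traj = traj,
       r2 = r2, stages = stages)
}

#' Refit a TeNT-perturbed circuit
#'
#' After \code{simulateTent}, only the perturbed neuron's gain and tanh
#' asymmetry (two parameters) are refit; everything else stays frozen.
#'
#' @param spec the TeNT-perturbed CircuitSpec.
#' @param responses,stimuli,control as in \code{stagedFit}.
#' @param target roster name or index of the silenced Tm neuron.
#' @return list as from \code{stagedFit} restricted to the target.
#' @export
refitTent <- function(spec, responses, stimuli, target,
                      control = fitControl()) {
  a <- if (is.character(target)) match(target, circuitRoster()) else target
  if (is.na(a) || !(a %in% TM_IDX)) stop("TeNT target must be a Tm neuron")
  V <- responseMatrix(responses)
  X <- logCaptures(stimuli); x0 <- achromaticInput(stimuli)
  m <- obsCounts(stimuli)
  res <- adamStage(spec, paste0("tent", a), X, x0, V, m, control)
  list(spec = res$spec, loss = res$loss, traj = res$traj, target = a)
}

#' Search the signs of the free recurrent Tm edges
#'
#' Enumerates all sign assignments of the spec's free-sign edges when
#' 2^k fits the budget, otherwise samples assignments at random, refits the
#' Tm stage for each, and returns the assignment with the smallest loss.
#'
#' @param spec a CircuitSpec with a nonempty \code{freeSigns} slot.
#' @param responses,stimuli,control as in \code{stagedFit}.
#' @param budget maximum number of assignments evaluated (default 64).
#' @param seed seed for randomized sampling when 2^k exceeds the budget.
#' @return list with \code{signs} (best +-1 vector, one per free edge),
#'   \code{spec} (refitted), \code{loss}, and \code{table} of all evaluated
#'   assignments with their losses.
#' @export
signSearch <- function(spec, responses, stimuli, budget = 64, seed = 1,
                       control = fitControl()) {
  edges <- spec@freeSigns
  k <- nrow(edges)
  if (k == 0) stop("spec has no free-sign edges")
  if (2^k <= budget) {
    grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  } else {
    set.seed(seed)
    grid <- matrix(sample(c(-1, 1), budget * k, replace = TRUE),
                   ncol = k)
    grid <- unique(grid)
  }
  best <- NULL
  losses <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    sp <- spec
    for (e in seq_len(k)) {
      a <- edges[e, 1]; b <- edges[e, 2]
      sp@signs[a, b] <- grid[r, e]
      sp@w[a, b] <- grid[r, e] * abs(sp@w[a, b])
    }
    fit <- stagedFit(sp, responses, stimuli, control, stages = "stage3")
    losses[r] <- fit$loss
    if (is.null(best) || fit$loss < best$loss)
      best <- list(signs = grid[r, ], spec = fit$spec, loss = fit$loss)
  }
  best$table <- cbind(as.data.frame(grid), loss = losses)
  best
}

#' Random-weight null distribution for the Tm fit
#'
#' Per draw, the synaptic-count-derived input weights of the five Tm neurons
#' are replaced by standard-uniform draws on the same edges (signs kept),
#' re-normalized to the unit row budget, and the Tm stage is refit; the mean
#' Tm noise-corrected R^2 of each draw forms the null distribution against
#' which the count-constrained model is compared.
#'
#' @param spec the count-constrained CircuitSpec.
#' @param responses,stimuli,control as in \code{stagedFit}.
#' @param n_draws number of draws (desk-scale default 200; the full-scale
#'   experiment uses 10,000).
#' @param seed integer seed.
#' @return list with \code{r2} (null draws), \code{q95}, and
#'   \code{intact_r2} (mean Tm R^2 of the count-constrained refit).
#' @export
randomWeightNull <- function(spec, responses, stimuli, n_draws = 200,
                             seed = 1, control = fitControl()) {
  stopifnot(n_draws >= 1)
  # both the count-constrained refit and every null draw start from the
  # same tame Tm parameterization (unit gain, symmetric tanh, weak
  # achromatic weight): the comparison is then between weight patterns, and
  # the starting circuit is contractive for any admissible weight draw
  tame <- function(sp) {
    sp@g[TM_IDX] <- 1
    sp@gamma[TM_IDX] <- 0
    sp@p[TM_IDX] <- -0.1
    sp
  }
  intact <- stagedFit(tame(spec), responses, stimuli, control,
                      stages = "stage3")
  intact_r2 <- mean(intact$r2[TM_IDX])
  r2 <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    set.seed(seed + d)
    sp <- tame(spec)
    for (a in TM_IDX) {
      nz <- which(sp@w[a, ] != 0)
      u <- stats::runif(length(nz))
      sp@w[a, nz] <- sign(sp@w[a, nz]) * u / sum(u)
    }
    fit <- stagedFit(sp, responses, stimuli, control, stages = "stage3")
    r2[d] <- mean(fit$r2[TM_IDX])
  }
  ok <- is.finite(r2)
  if (!all(ok))
    warning(sum(!ok), " null draw(s) had no reachable steady state and ",
            "were excluded")
  list(r2 = r2[ok], q95 = unname(stats::quantile(r2[ok], 0.95)),
       intact_r2 = intact_r2, n_failed = sum(!ok))
}
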