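## Steady-state solution of the recurrent rate model by Anderson
## acceleration, the correlation loss, and implicit differentiation of the
## fixed point.

## Elementwise modified tanh with per-row gamma on a 12 x n matrix.
fModMat <- function(U, gamma) {
  G <- matrix(gamma, nrow(U), ncol(U))
  s <- ifelse(U <= 0, 1 + G, 1 - G)
  s * tanh(U / s)
}

fModPrimeMat <- function(U, gamma) {
  G <- matrix(gamma, nrow(U), ncol(U))
  s <- ifelse(U <= 0, 1 + G, 1 - G)
  1 - tanh(U / s)^2
}

## One application of the circuit map G(Y) = f(g (W Y + j X' + p x0')).
## X: n x 4, x0: length n, Y: 12 x n. Returns 12 x n.
circuitMap <- function(spec, Y, X, x0) {
  U <- spec@w %*% Y + spec@j %*% t(X) + outer(spec@p, x0)
  fModMat(spec@g * U, spec@gamma)
}

## Pre-activation (inside f) used by the gradient code.
circuitPreact <- function(spec, Y, X, x0) {
  spec@g * (spec@w %*% Y + spec@j %*% t(X) + outer(spec@p, x0))
}

#' Anderson-accelerated fixed-point solve
#'
#' Solves x = G(x) by Anderson acceleration (type II): each step
#' extrapolates over the last \code{memory} residuals by a least-squares
#' combination. Iteration starts from \code{x0} and stops when the sup-norm
#' residual falls below \code{tol}.
#'
#' @param G the fixed-point map, a function of a numeric vector.
#' @param x0 initial iterate.
#' @param tol sup-norm residual tolerance (model default 1e-4).
#' @param max_iter iteration cap.
#' @param memory history depth (default 5).
#' @param damping mixing parameter beta in [0, 1] (default 1).
#' @return list with \code{x}, \code{residual}, \code{iterations}.
#' @export
andersonFixedPoint <- function(G, x0, tol = 1e-4, max_iter = 500,
                               memory = 5, damping = 1) {
  x <- x0
  gx <- G(x)
  f <- gx - x
  Xh <- matrix(x, ncol = 1)
  Gh <- matrix(gx, ncol = 1)
  for (k in seq_len(max_iter)) {
    if (max(abs(f)) < tol)
      return(list(x = x, residual = max(abs(f)), iterations = k - 1L))
    mk <- ncol(Xh)
    if (mk > 1) {
      dF <- matrix(0, length(x), mk - 1)
      Fh <- Gh - Xh
      for (i in seq_len(mk - 1)) dF[, i] <- Fh[, i + 1] - Fh[, i]
      gam <- tryCatch(qr.solve(dF, f), error = function(e)
        drop(solve(crossprod(dF) + 1e-12 * diag(mk - 1), crossprod(dF, f))))
      dG <- Gh[, -1, drop = FALSE] - Gh[, -mk, drop = FALSE]
      x_new <- damping * (gx - drop(dG %*% gam)) +
        (1 - damping) * (x - drop((Xh[, -1, drop = FALSE] -
                                     Xh[, -mk, drop = FALSE]) %*% gam))
    } else {
      x_new <- damping * gx + (1 - damping) * x
    }
    x <- x_new
    gx <- G(x)
    f <- gx - x
    Xh <- cbind(Xh, x); Gh <- cbind(Gh, gx)
    if (ncol(Xh) > memory + 1) {
      Xh <- Xh[, -1, drop = FALSE]; Gh <- Gh[, -1, drop = FALSE]
    }
  }
  stop(sprintf("fixed point not reached in %d iterations (residual %.3g)",
               max_iter, max(abs(f))))
}

#' Steady-state responses of the circuit model
#'
#' Solves the fixed point y = f(g (W y + j X + p x0)) for every stimulus
#' simultaneously (the stacked problem is block diagonal), starting from
#' zeros, by Anderson acceleration.
#'
#' @param spec a CircuitSpec.
#' @param X n x 4 matrix of log relative captures (or a 4-vector).
#' @param x0 achromatic inputs, length n (default 0).
#' @param tol sup-norm residual tolerance (default 1e-4 as in the model;
#'   tighten for gradient work).
#' @param max_iter,memory,damping solver controls.
#' @return 12 x n matrix of steady-state responses (rownames = roster).
#' @export
steadyState <- function(spec, X, x0 = NULL, tol = 1e-4, max_iter = 500,
                        memory = 5, damping = 1) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 4)
  n <- nrow(X)
  if (is.null(x0)) x0 <- numeric(n)
  G <- function(yvec)
    as.vector(circuitMap(spec, matrix(yvec, 12, n), X, x0))
  sol <- tryCatch(
    andersonFixedPoint(G, numeric(12 * n), tol = tol,
                       max_iter = max_iter, memory = memory,
                       damping = damping),
    error = function(e) NULL)
  Y <- if (is.null(sol)) newtonFixedPoint(spec, X, x0, tol = tol)
  else matrix(sol$x, 12, n)
  rownames(Y) <- circuitRoster()
  Y
}

## Damped-Newton fallback on the residual G(Y) - Y, used when the
## accelerated Picard iteration stalls (the map can be locally expansive at
## intermediate parameter values during optimization, where the fixed point
## still exists by continuity of the saturating map). A short homotopy in
## the gains (solving at reduced gain and warm-starting the next level)
## keeps the start deterministic -- zeros at the first level -- while
## staying inside each Newton basin.
newtonFixedPoint <- function(spec, X, x0, tol = 1e-4, max_iter = 60) {
  n <- nrow(X)
  I12 <- diag(12)
  newton_at <- function(sp, Y) {
    Fm <- circuitMap(sp, Y, X, x0) - Y
    for (it in seq_len(max_iter)) {
      if (max(abs(Fm)) < tol) return(list(Y = Y, ok = TRUE))
      Z <- circuitPreact(sp, Y, X, x0)
      fp <- fModPrimeMat(Z, sp@gamma)
      D <- Y
      for (i in seq_len(n)) {
        J <- (fp[, i] * sp@g) * sp@w
        D[, i] <- tryCatch(solve(I12 - J, Fm[, i]),
                           error = function(e) Fm[, i])
      }
      step <- 1
      repeat {
        Y_new <- Y + step * D
        F_new <- circuitMap(sp, Y_new, X, x0) - Y_new
        if (max(abs(F_new)) < max(abs(Fm)) || step < 1e-3) break
        step <- step / 2
      }
      Y <- Y_new; Fm <- F_new
    }
    list(Y = Y, ok = max(abs(Fm)) < tol)
  }
  # adaptive continuation in the gains: advance t from 0 to 1, bisecting the
  # step whenever Newton fails to converge from the previous level's branch
  Y <- matrix(0, 12, n)
  t_cur <- 0; dt <- 0.5; levels <- 0
  while (t_cur < 1 && levels < 60) {
    t_try <- min(1, t_cur + dt)
    sp <- spec; sp@g <- spec@g * t_try
    res <- newton_at(sp, Y)
    levels <- levels + 1
    if (res$ok) {
      Y <- res$Y; t_cur <- t_try
      dt <- min(dt * 2, 1 - t_cur + 1e-12)
    } else {
      dt <- dt / 2
      if (dt < 1e-4)
        stop("fixed point not reached (continuation stalled at t = ",
             signif(t_cur, 3), ")")
    }
  }
  if (t_cur < 1) stop("fixed point not reached (continuation exhausted)")
  Y
}

#' Observation-weighted correlation loss
#'
#' L = - sum over neurons of the m-weighted uncentered correlation between
#' model and measured responses. Perfect proportional agreement on all 12
#' neurons gives -12. Zero-norm neurons are excluded with a warning.
#'
#' @param Y model responses, neurons x stimuli.
#' @param V measured responses, same shape.
#' @param m observation counts per stimulus (scalar or length n).
#' @param neurons optional row indices over which to sum (default all).
#' @return scalar loss.
#' @export
correlationLoss <- function(Y, V, m = 1, neurons = NULL) {
  if (is.null(neurons)) neurons <- seq_len(nrow(Y))
  if (length(m) == 1) m <- rep(m, ncol(Y))
  L <- 0
  for (a in neurons) {
    sy <- sum(m * Y[a, ]^2); sv <- sum(m * V[a, ]^2)
    if (sy == 0 || sv == 0) {
      warning("zero-norm neuron ", a, " excluded from the loss")
      next
    }
    L <- L - sum(m * Y[a, ] * V[a, ]) / (sqrt(sy) * sqrt(sv))
  }
  L
}

## Gradient of correlationLoss with respect to Y (neurons x stimuli);
## rows outside `neurons` are zero.
correlationLossGradY <- function(Y, V, m, neurons) {
  n <- ncol(Y)
  if (length(m) == 1) m <- rep(m, n)
  Gr <- matrix(0, nrow(Y), n)
  for (a in neurons) {
    sy <- sum(m * Y[a, ]^2); sv <- sum(m * V[a, ]^2)
    if (sy == 0 || sv == 0) next
    A <- sum(m * Y[a, ] * V[a, ])
    Gr[a, ] <- -(m * V[a, ] / (sqrt(sv) * sqrt(sy)) -
                   A * m * Y[a, ] / (sqrt(sv) * sy^1.5))
  }
  Gr
}

## Implicit gradient of a loss at the fixed point. Given the solved Y
## (12 x n), the adjoint lambda_i solves (I - J_i)' lambda_i = dL/dy_i with
## J_i = diag(f'(z_i) g) W the Jacobian of the map at the fixed point. The
## parameter direction dG/dtheta_k (holding Y fixed) is supplied as a
## 12 x n matrix; the chain rule gives dL/dtheta_k = sum_i lambda_i . dG_k,i.
## Returns the 12 x n adjoint matrix.
fixedPointAdjoint <- function(spec, Y, X, x0, dLdY) {
  n <- ncol(Y)
  Z <- circuitPreact(spec, Y, X, x0)
  fp <- fModPrimeMat(Z, spec@gamma)
  lam <- matrix(0, 12, n)
  I12 <- diag(12)
  for (i in seq_len(n)) {
    J <- (fp[, i] * spec@g) * spec@w   # diag(f' g) %*% W
    lam[, i] <- solve(t(I12 - J), dLdY[, i])
  }
  lam
}

#' Implicit gradient of the correlation loss
#'
#' Differentiates the loss at the solved fixed point through the
#' implicit-function theorem (adjoint solves against the analytic Jacobian
#' of the one-step map), never by unrolling the Anderson iterations. The
#' parameter Jacobian of the one-step map is taken by central differences on
#' the explicit map, which is cheap and exact to O(h^2).
#'
#' @param spec a CircuitSpec (already carrying the parameter values).
#' @param applyFun function(spec, theta) returning the spec with parameter
#'   vector theta applied.
#' @param theta parameter vector at which to differentiate.
#' @param X,x0 stimulus inputs as in \code{steadyState}.
#' @param V measured responses (neurons x stimuli).
#' @param m observation counts.
#' @param neurons neuron indices entering the loss.
#' @param tol fixed-point tolerance for the forward solve.
#' @param h finite-difference step for the parameter Jacobian of the map.
#' @return list with \code{loss}, \code{grad} (length of theta) and the
#'   solved \code{Y}.
#' @export
circuitLossGrad <- function(spec, applyFun, theta, X, x0, V, m,
                            neurons = seq_len(12), tol = 1e-8, h = 1e-6) {
  sp <- applyFun(spec, theta)
  Y <- steadyState(sp, X, x0, tol = tol)
  loss <- correlationLoss(Y, V, m, neurons)
  dLdY <- correlationLossGradY(Y, V, m, neurons)
  lam <- fixedPointAdjoint(sp, Y, X, x0, dLdY)
  grad <- vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    dG <- (circuitMap(applyFun(spec, tp), Y, X, x0) -
             circuitMap(applyFun(spec, tm), Y, X, x0)) / (2 * h)
    sum(lam * dG)
  }, numeric(1))
  list(loss = loss, grad = grad, Y = Y)
}
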