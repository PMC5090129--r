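# V-update, the four X-update backends, dual ascent, the ADMM drivers and
# the ISRA baseline.
#
# Complexity convention: every inner X-update iteration performs exactly two
# counted system-matrix products (one P, one P^T).  Quantities that are
# constant across a run (A1 = P'Sigma Y, the CG right-hand-side constant,
# flux-matched initialization) and diagnostic cost traces use uncounted
# products, so the counter reports 2 x (total inner iterations), the proxy
# used for algorithm comparison.  Products with the TV operator are not
# counted at all: R has ~2 entries per row and is negligible next to P.

#' Soft-thresholding V-update
#'
#' Elementwise shrinkage \eqn{V_i = (|z_i| - \beta/\rho)_+ \,
#' \mathrm{sgn}(z_i)} with \eqn{z = RX + \mu}: the closed-form minimizer of
#' \eqn{\beta|v| + (\rho/2)(v - z_i)^2}.  At the kink \eqn{|z| = \beta/\rho}
#' the output is exactly 0.
#'
#' @param z numeric vector \eqn{RX + \mu}.
#' @param beta,rho positive penalty parameters.
#' @return numeric vector of the same length.
#' @export
vUpdate <- function(z, beta, rho) {
  if (rho <= 0) stop("rho must be positive")
  pmax(abs(z) - beta / rho, 0) * sign(z)
}

#' Dual ascent update
#'
#' \eqn{\mu \leftarrow \mu + RX - V}: the scaled dual variable accumulates
#' the primal residual.
#'
#' @param mu current dual vector.
#' @param RX \eqn{RX^{t+1}}.
#' @param V \eqn{V^{t+1}}.
#' @return updated dual vector.
#' @export
dualUpdate <- function(mu, RX, V) mu + RX - V

## Sparse Gram pieces of the regularizer that are fixed for a whole run.
.regPrecomp <- function(reg) {
  Rsum <- reg@Rpos + reg@Rneg
  list(Rsum = Rsum,
       Q2 = .asSparse(crossprod(Rsum)),
       Q4 = .asSparse(crossprod(reg@Rpos) + crossprod(reg@Rneg)))
}

## One multiplicative-update sweep; exactly 2 counted matvecs per inner
## iteration.  c2 = (Rbar+Rhat)'(Cbar+Chat), c4 = Rbar'Cbar + Rhat'Chat.
.emKernel <- function(P, w, Y, S, X, rho, pre, c2, c4, A1, nInner) {
  for (k in seq_len(nInner)) {
    d <- .fwdCount(P, X)
    A3 <- .bwdCount(P, w * (d + S))
    if (rho > 0) {
      num <- A1 + 0.5 * rho * (as.numeric(pre$Q2 %*% X) + c2)
      den <- A3 + rho * (as.numeric(pre$Q4 %*% X) + c4)
    } else {
      num <- A1
      den <- A3
    }
    bad <- den <= 0
    if (any(bad & num > 0))
      stop("degenerate pixel: zero update denominator with positive ",
           "numerator; mask pixels outside the scan support")
    fac <- num / den
    fac[bad] <- 1
    X <- X * fac
  }
  X
}

#' Multiplicative EM image update
#'
#' Applies the multiplicative rule
#' \eqn{X_j \leftarrow X_j\,(A_1 + (\rho/2)A_2)_j / (A_3 + \rho A_4)_j}
#' (see \code{\link{emTerms}}) \code{nInner} times.  Each sweep minimizes a
#' separable majorizer of the subproblem cost \eqn{\Phi(X) = F(X) +
#' (\rho/2)\|RX + C\|_2^2}, so \eqn{\Phi} decreases monotonically, every
#' iterate stays strictly positive when started positive (with nonnegative
#' counts), no step size is needed, and each inner iteration costs exactly
#' two system-matrix products.
#'
#' @param problem a \code{\link{reconProblem}}.
#' @param X strictly positive starting image.
#' @param C constant vector \eqn{-V + \mu} (zero vector for the
#'   unregularized \eqn{\rho = 0} case).
#' @param rho nonnegative ADMM penalty.
#' @param nInner number of multiplicative sweeps.
#' @return updated positive image vector.
#' @export
emXUpdate <- function(problem, X, C, rho, nInner = 1L) {
  P <- problem@P
  w <- problem@weights@weights
  pre <- .regPrecomp(problem@reg)
  Cs <- splitSigned(as.numeric(C))
  c2 <- as.numeric(crossprod(pre$Rsum, Cs$pos + Cs$neg))
  c4 <- as.numeric(crossprod(problem@reg@Rpos, Cs$pos)) +
        as.numeric(crossprod(problem@reg@Rneg, Cs$neg))
  A1 <- .bwd(P, w * problem@Y)
  .emKernel(P, w, problem@Y, problem@S, as.numeric(X), rho, pre, c2, c4,
            A1, nInner)
}

#' Default projected Landweber step size
#'
#' The norm-product bound \eqn{\alpha = 1 / (\|P\|_1\|P\|_\infty +
#' \beta\|R\|_1\|R\|_\infty)}; set \code{useRho = TRUE} to weight the
#' regularizer norms by \eqn{\rho} instead (the subproblem Hessian weights
#' \eqn{R^TR} by \eqn{\rho}).
#'
#' @param problem a \code{\link{reconProblem}}.
#' @param beta,rho penalty parameters.
#' @param useRho use \eqn{\rho} in place of \eqn{\beta}.
#' @return positive scalar step size.
#' @export
landweberAlpha <- function(problem, beta, rho, useRho = FALSE) {
  Pe <- problem@P@entries
  Rm <- problem@reg@R
  p1 <- max(Matrix::colSums(abs(Pe)))
  pinf <- max(Matrix::rowSums(abs(Pe)))
  r1 <- if (nrow(Rm)) max(Matrix::colSums(abs(Rm))) else 0
  rinf <- if (nrow(Rm)) max(Matrix::rowSums(abs(Rm))) else 0
  coef <- if (useRho) rho else beta
  1 / (p1 * pinf + coef * r1 * rinf)
}

#' Projected Landweber image update
#'
#' Gradient steps \eqn{X \leftarrow \max(X - \alpha \nabla\Phi(X), 0)} on
#' the subproblem cost, with a fixed step \eqn{\alpha}; two counted
#' system-matrix products per iteration.
#'
#' @inheritParams emXUpdate
#' @param alpha positive step size (see \code{\link{landweberAlpha}}).
#' @return updated nonnegative image vector.
#' @export
plXUpdate <- function(problem, X, C, rho, nInner = 1L, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  P <- problem@P
  w <- problem@weights@weights
  Rm <- problem@reg@R
  X <- as.numeric(X)
  for (k in seq_len(nInner)) {
    r <- .fwdCount(P, X) + problem@S - problem@Y
    grad <- 2 * .bwdCount(P, w * r) +
      rho * as.numeric(crossprod(Rm, as.numeric(Rm %*% X) + C))
    X <- pmax(X - alpha * grad, 0)
  }
  X
}

## H v = (2 P'Sigma P + rho R'R) v -- two counted P-products per call.
.makeHapply <- function(P, w, Rm, rho) {
  function(v, counted = TRUE) {
    pv <- if (counted) .fwdCount(P, v) else .fwd(P, v)
    bp <- if (counted) .bwdCount(P, w * pv) else .bwd(P, w * pv)
    2 * bp + rho * as.numeric(crossprod(Rm, as.numeric(Rm %*% v)))
  }
}

#' Conjugate gradient image update
#'
#' Runs \code{nInner} conjugate-gradient steps on the quadratic subproblem
#' \eqn{HX = b}, \eqn{H = 2P^T\Sigma P + \rho R^TR}, \eqn{b = 2P^T\Sigma(Y -
#' S) - \rho R^TC}, then truncates negatives once at the end (the
#' per-iteration projection, available via \code{projectEachStep}, restarts
#' CG after each clip).  The product \eqn{H X} is warm-started across calls
#' through \code{cache} so each CG step costs one \eqn{H}-product (two
#' system-matrix products); end-of-loop truncation invalidates the cache
#' and the recomputation is counted when it happens.
#'
#' @inheritParams emXUpdate
#' @param projectEachStep clip negatives at every CG step.
#' @param cache environment reused across outer iterations (optional).
#' @return updated nonnegative image vector.
#' @export
cgXUpdate <- function(problem, X, C, rho, nInner = 1L,
                      projectEachStep = FALSE, cache = NULL) {
  P <- problem@P
  w <- problem@weights@weights
  Rm <- problem@reg@R
  Happly <- .makeHapply(P, w, Rm, rho)
  X <- as.numeric(X)
  b <- 2 * .bwd(P, w * (problem@Y - problem@S)) -
    rho * as.numeric(crossprod(Rm, as.numeric(C)))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$Hx) || !identical(cache$X, X)) {
    cache$Hx <- Happly(X)
    cache$X <- X
  }
  r <- b - cache$Hx
  p <- r
  rs <- sum(r * r)
  for (k in seq_len(nInner)) {
    if (rs <= 0) break
    q <- Happly(p)
    pq <- sum(p * q)
    if (pq <= 0) break
    al <- rs / pq
    X <- X + al * p
    cache$Hx <- cache$Hx + al * q
    if (projectEachStep && any(X < 0)) {
      X <- pmax(X, 0)
      cache$Hx <- Happly(X)
      r <- b - cache$Hx
      p <- r
      rs <- sum(r * r)
      next
    }
    rnew <- r - al * q
    rsNew <- sum(rnew * rnew)
    p <- rnew + (rsNew / rs) * p
    r <- rnew
    rs <- rsNew
  }
  Xout <- pmax(X, 0)
  if (identical(Xout, X)) {
    cache$X <- X
  } else {
    cache$Hx <- NULL  # truncation changed X; recompute (counted) next call
    cache$X <- NULL
  }
  Xout
}

#' Direct (small-instance) subproblem solve
#'
#' Solves the \eqn{\Sigma}-weighted normal equations of the subproblem and
#' truncates below zero:
#' \deqn{X = \max\big(0,\ (2P^T\Sigma P + \rho R^TR)^{-1}
#'   (2P^T\Sigma(Y - S) + \rho R^T(V - \mu))\big).}
#' Dense; intended as an oracle for small \eqn{N}.
#'
#' @param problem a \code{\link{reconProblem}}.
#' @param rho positive penalty.
#' @param V,mu auxiliary and dual vectors.
#' @return nonnegative image vector.
#' @export
directXSolve <- function(problem, rho, V, mu) {
  Pe <- as.matrix(problem@P@entries)
  w <- problem@weights@weights
  Rm <- problem@reg@R
  H <- 2 * crossprod(Pe, w * Pe) + rho * as.matrix(crossprod(Rm))
  rhs <- 2 * as.numeric(crossprod(Pe, w * (problem@Y - problem@S))) +
    rho * as.numeric(crossprod(Rm, V - mu))
  pmax(solve(H, rhs), 0)
}

#' Run the ADMM reconstruction
#'
#' The driver loops soft-thresholding V-update, \code{nInner} iterations of
#' the configured X-update backend, and dual ascent, for \code{nOuter}
#' outer iterations or until the relative-change statistic \eqn{\chi} drops
#' below \code{epsilon}.  \code{nInner} large is the greedy driver;
#' \code{nInner = 1} with the EM backend is the simplified driver, which
#' only decreases (rather than minimizes) the subproblem cost per outer
#' iteration.  Initialization: a uniform positive image flux-matched so
#' that \eqn{\sum PX^0 = \sum Y}, \eqn{V^0 = RX^0}, \eqn{\mu^0 = 0}.
#'
#' @param problem a \code{\link{reconProblem}}.
#' @param config a \code{\link{solverConfig}}.
#' @return an \code{\link{ADMMState-class}} object with per-outer-iteration
#'   traces.
#' @export
runADMM <- function(problem, config) {
  validObject(config)
  P <- problem@P
  Pe <- P@entries
  w <- problem@weights@weights
  Y <- if (config@clampNegativeCounts) pmax(problem@Y, 0) else problem@Y
  S <- problem@S
  reg <- problem@reg
  Rm <- reg@R
  N <- ncol(Pe)
  beta <- config@beta
  rho <- config@rho

  # uniform positive start, flux-matched to the measured counts
  X <- rep(1, N)
  f0 <- sum(.fwd(P, X))
  sy <- sum(Y)
  if (f0 > 0 && sy > 0) X <- X * (sy / f0)
  V <- as.numeric(Rm %*% X)
  mu <- numeric(nrow(Rm))

  pre <- .regPrecomp(reg)
  A1 <- .bwd(P, w * Y)
  backend <- config@xBackend
  alpha <- if (backend == "projected_landweber") {
    if (length(config@alphaOverride)) config@alphaOverride
    else landweberAlpha(problem, beta, rho, useRho = config@landweberUseRho)
  } else NA_real_
  cgCache <- new.env(parent = emptyenv())
  if (backend == "conjugate_gradient") {
    Happly0 <- .makeHapply(P, w, Rm, rho)
    cgCache$Hx <- Happly0(X, counted = FALSE)  # fixed setup cost
    cgCache$X <- X
  }
  probClamped <- if (config@clampNegativeCounts && !identical(Y, problem@Y))
    reconProblem(P, Y, S, problem@weights, reg) else problem

  matvec0 <- matvecCount(P)
  tr <- vector("list", config@nOuter)
  t0 <- proc.time()[["elapsed"]]
  tDone <- 0L
  for (it in seq_len(config@nOuter)) {
    z <- as.numeric(Rm %*% X) + mu
    V <- vUpdate(z, beta, rho)
    C <- -V + mu
    Cs <- splitSigned(C)
    Xold <- X
    X <- switch(backend,
      em = {
        c2 <- as.numeric(crossprod(pre$Rsum, Cs$pos + Cs$neg))
        c4 <- as.numeric(crossprod(reg@Rpos, Cs$pos)) +
              as.numeric(crossprod(reg@Rneg, Cs$neg))
        .emKernel(P, w, Y, S, X, rho, pre, c2, c4, A1, config@nInner)
      },
      projected_landweber =
        plXUpdate(probClamped, X, C, rho, config@nInner, alpha),
      conjugate_gradient =
        cgXUpdate(probClamped, X, C, rho, config@nInner,
                  projectEachStep = config@cgProjectEachStep,
                  cache = cgCache),
      direct = directXSolve(probClamped, rho, V, mu))
    rx <- as.numeric(Rm %*% X)
    mu <- dualUpdate(mu, rx, V)
    chi <- stoppingChi(X, Xold, squared = config@squaredChi)
    Fv <- wlsCost(P, w, Y, S, X)
    tv <- sum(abs(rx))
    tr[[it]] <- data.frame(
      outer_iter = it,
      inner_iters_used = config@nInner,
      F = Fv,
      tv_l1 = tv,
      primal_objective = Fv + beta * tv,
      aug_lagrangian = Fv + beta * sum(abs(V)) +
        (rho / 2) * sum((rx - V + mu)^2) - (rho / 2) * sum(mu^2),
      chi = chi,
      primal_residual = sqrt(sum((rx - V)^2)),
      matvec_count = matvecCount(P) - matvec0,
      wall_time = proc.time()[["elapsed"]] - t0)
    tDone <- it
    if (config@epsilon > 0 && chi < config@epsilon) break
  }
  new("ADMMState", X = X, V = V, mu = mu, t = tDone,
      traces = do.call(rbind, tr[seq_len(tDone)]))
}

#' ISRA baseline (weighted image-space reconstruction algorithm)
#'
#' The unregularized multiplicative comparator
#' \eqn{X_j \leftarrow X_j\,(P^T\Sigma Y)_j / (P^T\Sigma(PX + S))_j}: the
#' \eqn{\rho = 0} specialization of the EM update.  Pixels whose
#' denominator vanishes are frozen (with one warning).  Two counted
#' system-matrix products per iteration.
#'
#' @param problem a \code{\link{reconProblem}}.
#' @param nIter number of iterations.
#' @param X0 strictly positive starting image (default: flux-matched
#'   uniform).
#' @return positive image vector.
#' @export
runIsra <- function(problem, nIter, X0 = NULL) {
  P <- problem@P
  w <- problem@weights@weights
  Y <- pmax(problem@Y, 0)
  S <- problem@S
  if (is.null(X0)) {
    X <- rep(1, ncol(P@entries))
    f0 <- sum(.fwd(P, X))
    sy <- sum(Y)
    if (f0 > 0 && sy > 0) X <- X * (sy / f0)
  } else X <- as.numeric(X0)
  if (any(X <= 0)) stop("X0 must be strictly positive")
  A1 <- .bwd(P, w * Y)
  warned <- FALSE
  for (k in seq_len(nIter)) {
    d <- .fwdCount(P, X)
    den <- .bwdCount(P, w * (d + S))
    bad <- den <= 0
    if (any(bad) && !warned) {
      warning("frozen ", sum(bad), " pixel(s) with zero ISRA denominator")
      warned <- TRUE
    }
    fac <- A1 / den
    fac[bad] <- 1
    X <- X * fac
  }
  X
}
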