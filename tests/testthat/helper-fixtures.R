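# Fixtures and independent oracles shared across the test files.
# Oracles are deliberately written with dense base-R linear algebra and
# brute-force enumeration, independent of the package's solver paths.

## Random penalized-WLS instance on an n x n pixel grid (N = n^2 pixels,
## M = 2N bins): sparse nonnegative P with no all-zero column, positive
## weights, nonnegative counts, TV regularizer, random V/mu.
randomInstance <- function(n = 4, seed = 1, density = 0.25) {
  set.seed(seed)
  N <- n * n
  M <- 2L * N
  P <- matrix(0, M, N)
  nz <- matrix(runif(M * N) < density, M, N)
  nz[cbind(sample.int(M, N), seq_len(N))] <- TRUE  # every column touched
  P[nz] <- runif(sum(nz), 0.2, 1)
  xTrue <- runif(N, 0.5, 2)
  Y <- pmax(as.numeric(P %*% xTrue) + rnorm(M, 0, 0.05), 0)
  w <- runif(M, 0.5, 2)
  reg <- buildAnisotropicTV(n)
  K <- nrow(regOperator(reg))
  V <- rnorm(K)
  mu <- rnorm(K, 0, 0.3)
  problem <- reconProblem(systemMatrix(P), Y, numeric(M),
                          new("WeightModel", weights = w, floor = 1), reg)
  list(P = P, Y = Y, w = w, reg = reg, problem = problem, n = n, N = N,
       M = M, V = V, mu = mu, C = -V + mu, xTrue = xTrue)
}

## Dense subproblem pieces: Phi(X) = 1/2 X'HX - b'X + const.
denseQuadratic <- function(inst, rho) {
  Rm <- as.matrix(regOperator(inst$reg))
  H <- 2 * crossprod(inst$P, inst$w * inst$P) + rho * crossprod(Rm)
  b <- 2 * as.numeric(crossprod(inst$P, inst$w * inst$Y)) -
    rho * as.numeric(crossprod(Rm, inst$C))
  list(H = H, b = b)
}

phiOf <- function(inst, rho, X) {
  xSubproblemCost(inst$problem@P, inst$w, inst$Y, numeric(inst$M),
                  inst$reg, rho, X, inst$C)
}

## Exact active-set solver for min_{x >= 0} 1/2 x'Hx - b'x with H SPD.
qpNonnegOracle <- function(H, b, tol = 1e-10, maxit = 10000L) {
  N <- length(b)
  free <- rep(TRUE, N)
  x <- numeric(N)
  for (it in seq_len(maxit)) {
    x[] <- 0
    if (any(free))
      x[free] <- solve(H[free, free, drop = FALSE], b[free])
    if (any(x < -tol)) {
      # drop the most negative free variable and re-solve
      cand <- which(free)[x[free] < -tol]
      free[cand[which.min(x[cand])]] <- FALSE
      next
    }
    x <- pmax(x, 0)
    g <- as.numeric(H %*% x) - b
    bound <- which(!free)
    if (!length(bound) || all(g[bound] >= -tol)) return(x)
    free[bound[which.min(g[bound])]] <- TRUE
  }
  stop("active-set oracle failed to converge")
}

## Exhaustive ray-pixel clipping oracle for the parallel-beam projector:
## intersection length of every ray with every pixel box (slab method).
clippingOracle <- function(geometry, gridSide, pixelSizeMm) {
  n <- gridSide
  nb <- geometry@nBins
  nv <- geometry@nViews
  h <- pixelSizeMm
  half <- n * h / 2
  sOff <- (seq_len(nb) - (nb + 1) / 2) * geometry@binSizeMm
  theta <- (seq_len(nv) - 1) * pi / nv
  out <- matrix(0, nb * nv, n * n)
  for (v in seq_len(nv)) for (k in seq_len(nb)) {
    i <- (v - 1) * nb + k
    ct <- cos(theta[v]); st <- sin(theta[v])
    ox <- sOff[k] * ct; oy <- sOff[k] * st
    dx <- -st; dy <- ct
    for (r in seq_len(n)) for (cc in seq_len(n)) {
      xlo <- -half + (cc - 1) * h; xhi <- xlo + h
      yhi <- half - (r - 1) * h; ylo <- yhi - h
      tmin <- -Inf; tmax <- Inf
      if (abs(dx) > 1e-14) {
        t1 <- (xlo - ox) / dx; t2 <- (xhi - ox) / dx
        tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
      } else if (ox <= xlo || ox >= xhi) next
      if (abs(dy) > 1e-14) {
        t1 <- (ylo - oy) / dy; t2 <- (yhi - oy) / dy
        tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
      } else if (oy <= ylo || oy >= yhi) next
      if (tmax > tmin) out[i, (r - 1) * n + cc] <- tmax - tmin
    }
  }
  out
}
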