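# Shrinkage, the X-update backends, dual ascent, the drivers and ISRA.

test_that("shrinkage matches the brute-force scalar minimizer", {
  expect_equal(vUpdate(0, 1, 2), 0)
  expect_equal(vUpdate(1.0, 0.3, 1), 0.7)       # beta/rho = 0.3
  expect_equal(vUpdate(c(0.3, -0.3), 0.3, 1), c(0, 0))  # kink -> exactly 0
  set.seed(31)
  for (k in 1:200) {
    z <- runif(1, -3, 3)
    tau <- runif(1, 0.01, 2)     # beta/rho
    grid <- seq(min(0, z) - 0.1, max(0, z) + 0.1, by = 1e-4)
    obj <- tau * abs(grid) + 0.5 * (grid - z)^2
    best <- grid[which.min(obj)]
    expect_lt(abs(vUpdate(z, tau, 1) - best), 1.1e-4)
  }
})

test_that("dual ascent accumulates primal residuals additively", {
  mu <- c(0.1, -0.2)
  rx <- c(1, 2); V <- c(0.5, 2.5)
  expect_equal(dualUpdate(mu, rx, V), mu + rx - V)
  expect_equal(dualUpdate(mu, rx, rx), mu)                  # V = RX
  expect_equal(dualUpdate(numeric(2), rx, V), rx - V)       # mu = 0
  two <- dualUpdate(dualUpdate(mu, rx, V), rx, V)
  expect_equal(two, mu + 2 * (rx - V))
})

test_that("EM update has the exact scalar and fixed-point behavior", {
  zeroReg <- linearRegularizer(matrix(0, 1, 1))
  w1 <- new("WeightModel", weights = 1, floor = 1)
  # scalar WLS: P = 1, Y = 2, X0 = 1 -> X1 = 2, the minimizer
  prob <- reconProblem(systemMatrix(matrix(1)), 2, 0, w1, zeroReg)
  expect_equal(emXUpdate(prob, 1, 0, rho = 0, nInner = 1L), 2)
  # identity problem at the data: fixed point
  N <- 4
  regN <- linearRegularizer(matrix(0, 1, N))
  probI <- reconProblem(systemMatrix(diag(N)), c(1, 2, 3, 4), numeric(N),
                        new("WeightModel", weights = rep(1, N), floor = 1),
                        regN)
  X <- c(1, 2, 3, 4)
  expect_equal(emXUpdate(probI, X, 0, rho = 0, nInner = 3L), X)
})

test_that("EM iterations decrease the subproblem cost and stay positive", {
  for (seed in 1:20) {
    inst <- randomInstance(sample(4:6, 1), seed = seed)
    rho <- 10^runif(1, -3, 0)
    X <- runif(inst$N, 0.5, 2)
    phiPrev <- phiOf(inst, rho, X)
    for (k in 1:15) {
      X <- emXUpdate(inst$problem, X, inst$C, rho, nInner = 1L)
      expect_true(all(X > 0))
      phiNow <- phiOf(inst, rho, X)
      expect_lte(phiNow, phiPrev + 1e-10 * abs(phiPrev))
      phiPrev <- phiNow
    }
  }
})

test_that("EM limit solves the nonnegative quadratic program", {
  for (seed in 1:5) {
    inst <- randomInstance(4, seed = 40 + seed)
    rho <- 0.5
    dq <- denseQuadratic(inst, rho)
    xStar <- qpNonnegOracle(dq$H, dq$b)
    X <- runif(inst$N, 0.5, 2)
    X <- emXUpdate(inst$problem, X, inst$C, rho, nInner = 4000L)
    expect_lt(abs(phiOf(inst, rho, X) - phiOf(inst, rho, xStar)),
              1e-6 * abs(phiOf(inst, rho, xStar)))
    g <- as.numeric(dq$H %*% X) - dq$b
    scale <- max(abs(dq$b))
    expect_true(all(g > -1e-6 * scale | X > 1e-8))   # bound pixels: g >= 0
    active <- X > 1e-6 * max(X)
    expect_lt(max(abs(g[active])), 1e-5 * scale)     # interior: g ~ 0
  }
})

test_that("projected Landweber descends, clamps and honors fixed points", {
  inst <- randomInstance(4, seed = 51)
  rho <- 0.3
  alpha <- landweberAlpha(inst$problem, beta = 0.01, rho = rho)
  X <- runif(inst$N, 0.5, 2)
  phiPrev <- phiOf(inst, rho, X)
  for (k in 1:500) {
    X <- plXUpdate(inst$problem, X, inst$C, rho, nInner = 1L, alpha = alpha)
    expect_gte(min(X), 0)
    phiNow <- phiOf(inst, rho, X)
    expect_lte(phiNow, phiPrev + 1e-10 * max(1, abs(phiPrev)))
    phiPrev <- phiNow
  }
  # unconstrained interior minimum is a fixed point
  dq <- denseQuadratic(inst, rho)
  xU <- solve(dq$H, dq$b)
  if (all(xU > 0)) {
    expect_equal(plXUpdate(inst$problem, xU, inst$C, rho, 1L, alpha), xU,
                 tolerance = 1e-8)
  }
  # a gradient step that crosses zero is clamped to exactly 0
  zeroReg2 <- linearRegularizer(matrix(0, 1, 2))
  probClamp <- reconProblem(systemMatrix(diag(2)), c(0, 10), numeric(2),
                            new("WeightModel", weights = c(1, 1), floor = 1),
                            zeroReg2)
  Xneg <- plXUpdate(probClamp, c(1, 1), 0, rho = 0.5, nInner = 1L,
                    alpha = 10)
  expect_identical(Xneg[1], 0)  # overmeasured-zero pixel driven negative
  expect_gt(Xneg[2], 0)
})

test_that("CG on a tiny unconstrained system matches the direct solve", {
  inst <- randomInstance(2, seed = 61)  # N = 4
  rho <- 0.4
  dq <- denseQuadratic(inst, rho)
  xU <- solve(dq$H, dq$b)
  skipNeeded <- any(xU <= 0)  # fixture chosen to have an interior solution
  expect_false(skipNeeded)
  X <- emXUpdate(inst$problem, runif(inst$N, 0.5, 2), inst$C, rho, 50L)
  Xcg <- cgXUpdate(inst$problem, X, inst$C, rho, nInner = 8L)
  expect_equal(Xcg, xU, tolerance = 1e-8)
  # all-nonnegative CG output: truncation is the identity
  expect_gte(min(Xcg), 0)
})

test_that("all four backends agree on an interior-solution subproblem", {
  inst <- randomInstance(3, seed = 62)
  rho <- 0.4
  dq <- denseQuadratic(inst, rho)
  xU <- solve(dq$H, dq$b)
  expect_true(all(xU > 0))
  V <- inst$V; mu <- inst$mu   # C = -V + mu as in the fixture
  xDir <- directXSolve(inst$problem, rho, V, mu)
  phi <- function(X) phiOf(inst, rho, X)
  expect_equal(xDir, xU, tolerance = 1e-10)
  x0 <- runif(inst$N, 0.5, 2)
  xEm <- emXUpdate(inst$problem, x0, inst$C, rho, 8000L)
  xCg <- cgXUpdate(inst$problem, x0, inst$C, rho, 40L)
  alpha <- landweberAlpha(inst$problem, 0.01, rho)
  xPl <- plXUpdate(inst$problem, x0, inst$C, rho, 4000L, alpha)
  for (x in list(xEm, xCg, xPl))
    expect_lt(abs(phi(x) - phi(xDir)), 1e-4 * abs(phi(xDir)))
})

test_that("direct solve truncates engineered negative solutions to zero", {
  # one well-measured pixel, one pixel pushed negative by the coupling
  P <- matrix(c(1, 0), 1, 2)
  reg <- linearRegularizer(matrix(c(1, 1), 1, 2))
  prob <- reconProblem(systemMatrix(P), 2, 0,
                       new("WeightModel", weights = 1, floor = 1), reg)
  # V - mu large negative drives the second pixel below zero unconstrained
  x <- directXSolve(prob, rho = 2, V = -5, mu = 0)
  expect_identical(x[2], 0)
})

test_that("weighted ISRA is the rho = 0 specialization, bit for bit", {
  inst <- randomInstance(4, seed = 71)
  X0 <- runif(inst$N, 0.5, 2)
  for (k in c(1L, 7L)) {
    em <- emXUpdate(inst$problem, X0, numeric(nrow(regOperator(inst$reg))),
                    rho = 0, nInner = k)
    isra <- runIsra(inst$problem, k, X0 = X0)
    expect_identical(em, isra)
    expect_true(all(isra > 0))
  }
  # consistent data: WLS cost driven to (near) zero
  Yc <- as.numeric(inst$P %*% inst$xTrue)
  probC <- reconProblem(inst$problem@P, Yc, numeric(inst$M),
                        inst$problem@weights, inst$reg)
  Xfit <- runIsra(probC, 3000, X0 = X0)
  expect_lt(wlsCost(probC@P, inst$w, Yc, numeric(inst$M), Xfit),
            1e-8 * wlsCost(probC@P, inst$w, Yc, numeric(inst$M), X0))
})

test_that("ADMM with a vanishing penalty recovers the WLS minimizer", {
  inst <- randomInstance(3, seed = 81)
  # unregularized WLS minimizer (dense normal equations)
  H <- 2 * crossprod(inst$P, inst$w * inst$P)
  b <- 2 * as.numeric(crossprod(inst$P, inst$w * inst$Y))
  xWls <- solve(H, b)
  expect_true(all(xWls > 0))
  cfg <- solverConfig(beta = 1e-12, rho = 1e-6, nOuter = 30, nInner = 300)
  st <- runADMM(inst$problem, cfg)
  Fwls <- wlsCost(inst$problem@P, inst$w, inst$Y, numeric(inst$M), xWls)
  Fadmm <- wlsCost(inst$problem@P, inst$w, inst$Y, numeric(inst$M), st@X)
  expect_lt(abs(Fadmm - Fwls), 1e-4 * max(1e-8, abs(Fwls)))
})

test_that("matvec accounting is two products per inner iteration", {
  inst <- randomInstance(4, seed = 82)
  for (backend in c("em", "projected_landweber")) {
    inst2 <- randomInstance(4, seed = 82)
    cfg <- solverConfig(beta = 0.01, rho = 0.1, nOuter = 5, nInner = 10,
                        xBackend = backend)
    st <- runADMM(inst2$problem, cfg)
    expect_identical(complexityReport(st), 2L * 5L * 10L)
  }
  # CG with warm-started H x on an interior run matches the same accounting
  inst3 <- randomInstance(3, seed = 62)
  cfg <- solverConfig(beta = 0.01, rho = 0.4, nOuter = 4, nInner = 3,
                      xBackend = "conjugate_gradient")
  st <- runADMM(inst3$problem, cfg)
  expect_identical(complexityReport(st), 2L * 4L * 3L)
})

test_that("the outer loop stops when chi falls below epsilon", {
  inst <- randomInstance(4, seed = 83)
  cfg <- solverConfig(beta = 0.01, rho = 0.1, nOuter = 500, nInner = 2,
                      epsilon = 1e-6)
  st <- runADMM(inst$problem, cfg)
  expect_lt(st@t, 500L)
  tr <- solverTraces(st)
  expect_lt(tr$chi[nrow(tr)], 1e-6)
  expect_true(all(diff(tr$matvec_count) == 4))
})

test_that("ADMM drives the primal residual to feasibility", {
  inst <- randomInstance(4, seed = 84)
  cfg <- solverConfig(beta = 0.05, rho = 0.5, nOuter = 800, nInner = 10)
  st <- runADMM(inst$problem, cfg)
  tr <- solverTraces(st)
  rxNorm <- sqrt(sum(as.numeric(regOperator(inst$reg) %*% st@X)^2))
  expect_lt(tr$primal_residual[nrow(tr)], 1e-3 * rxNorm)
})

test_that("solver runs are deterministic for a fixed configuration", {
  inst1 <- randomInstance(4, seed = 85)
  inst2 <- randomInstance(4, seed = 85)
  cfg <- solverConfig(beta = 0.02, rho = 0.2, nOuter = 20, nInner = 3)
  s1 <- runADMM(inst1$problem, cfg)
  s2 <- runADMM(inst2$problem, cfg)
  expect_identical(s1@X, s2@X)
  expect_identical(solverTraces(s1)$primal_objective,
                   solverTraces(s2)$primal_objective)
})
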