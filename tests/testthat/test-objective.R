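# Cost functions, surrogates and the multiplicative-update terms.

test_that("WLS cost matches scalar arithmetic and the brute-force sum", {
  # scalar: P = [1], Sigma = 0.5, Y = 3, S = 1, X = 1 -> 0.5 (1+1-3)^2
  reg1 <- linearRegularizer(matrix(0, 1, 1))
  expect_equal(wlsCost(matrix(1), 0.5, 3, 1, 1), 0.5)
  inst <- randomInstance(4, seed = 21)
  X <- runif(inst$N)
  S <- runif(inst$M)
  brute <- 0
  for (i in seq_len(inst$M))
    brute <- brute + inst$w[i] * (sum(inst$P[i, ] * X) + S[i] - inst$Y[i])^2
  expect_equal(wlsCost(inst$problem@P, inst$w, inst$Y, S, X), brute,
               tolerance = 1e-10)
  # perfect fit
  expect_equal(wlsCost(diag(3), rep(1, 3), c(1, 2, 3), numeric(3),
                       c(1, 2, 3)), 0)
})

test_that("primal objective is the sum of its two terms", {
  inst <- randomInstance(4, seed = 22)
  X <- runif(inst$N)
  S <- numeric(inst$M)
  for (beta in c(1e-6, 0.1, 2)) {
    expect_equal(
      primalObjective(inst$problem@P, inst$w, inst$Y, S, inst$reg, beta, X),
      wlsCost(inst$problem@P, inst$w, inst$Y, S, X) +
        beta * tvSeminorm(inst$reg, X),
      tolerance = 1e-12)
  }
})

test_that("augmented Lagrangian reduces correctly in special states", {
  inst <- randomInstance(4, seed = 23)
  X <- runif(inst$N)
  S <- numeric(inst$M)
  beta <- 0.3; rho <- 0.7
  rx <- as.numeric(regOperator(inst$reg) %*% X)
  # constraint satisfied, zero dual: equals the primal objective
  expect_equal(
    augmentedLagrangian(inst$problem@P, inst$w, inst$Y, S, inst$reg,
                        beta, rho, X, rx, numeric(length(rx))),
    primalObjective(inst$problem@P, inst$w, inst$Y, S, inst$reg, beta, X),
    tolerance = 1e-12)
  # all-zero state with S = 0: weighted sum of squared counts
  K <- nrow(regOperator(inst$reg))
  expect_equal(
    augmentedLagrangian(inst$problem@P, inst$w, inst$Y, S, inst$reg,
                        beta, rho, numeric(inst$N), numeric(K), numeric(K)),
    sum(inst$w * inst$Y^2), tolerance = 1e-12)
  # random state: term-by-term brute force
  V <- rnorm(K); mu <- rnorm(K)
  expect_equal(
    augmentedLagrangian(inst$problem@P, inst$w, inst$Y, S, inst$reg,
                        beta, rho, X, V, mu),
    sum(inst$w * (as.numeric(inst$P %*% X) - inst$Y)^2) +
      beta * sum(abs(V)) + rho / 2 * sum((rx - V + mu)^2) -
      rho / 2 * sum(mu^2),
    tolerance = 1e-12)
})

test_that("subproblem cost drops the X-independent Lagrangian terms", {
  inst <- randomInstance(4, seed = 24)
  S <- numeric(inst$M)
  rho <- 0.9; beta <- 0.2
  X1 <- runif(inst$N); X2 <- runif(inst$N)
  C <- inst$C
  # Phi differences equal Lagrangian differences at fixed V, mu
  dPhi <- xSubproblemCost(inst$problem@P, inst$w, inst$Y, S, inst$reg,
                          rho, X1, C) -
          xSubproblemCost(inst$problem@P, inst$w, inst$Y, S, inst$reg,
                          rho, X2, C)
  dL <- augmentedLagrangian(inst$problem@P, inst$w, inst$Y, S, inst$reg,
                            beta, rho, X1, inst$V, inst$mu) -
        augmentedLagrangian(inst$problem@P, inst$w, inst$Y, S, inst$reg,
                            beta, rho, X2, inst$V, inst$mu)
  expect_equal(dPhi, dL, tolerance = 1e-8)
  # C = -RX kills the quadratic term
  rx <- as.numeric(regOperator(inst$reg) %*% X1)
  expect_equal(
    xSubproblemCost(inst$problem@P, inst$w, inst$Y, S, inst$reg, rho,
                    X1, -rx),
    wlsCost(inst$problem@P, inst$w, inst$Y, S, X1), tolerance = 1e-12)
  # X = 0, S = 0
  expect_equal(
    xSubproblemCost(inst$problem@P, inst$w, inst$Y, S, inst$reg, rho,
                    numeric(inst$N), C),
    sum(inst$w * inst$Y^2) + rho / 2 * sum(C^2), tolerance = 1e-12)
})

test_that("Jensen coefficients form a convex combination per bin", {
  inst <- randomInstance(4, seed = 25)
  Xt <- runif(inst$N, 0.5, 2)
  S <- runif(inst$M, 0, 0.5)
  d <- as.numeric(inst$P %*% Xt) + S
  lamStar <- S / d
  lamSum <- as.numeric((inst$P * outer(1 / d, Xt)) %*% rep(1, inst$N))
  expect_equal(lamStar + lamSum, rep(1, inst$M), tolerance = 1e-12)
})

test_that("surrogates are tangent at Xt and majorize F and G", {
  inst <- randomInstance(4, seed = 26)
  S <- runif(inst$M, 0, 0.5)
  Xt <- runif(inst$N, 0.5, 2)
  FXt <- wlsCost(inst$problem@P, inst$w, inst$Y, S, Xt)
  fXt <- surrogateF(inst$problem@P, inst$w, inst$Y, S, Xt, Xt)
  expect_equal(fXt, FXt, tolerance = 1e-9)
  rx <- as.numeric(regOperator(inst$reg) %*% Xt)
  GXt <- sum((rx + inst$C)^2)
  gXt <- surrogateG(inst$reg, inst$C, Xt, Xt)
  expect_equal(gXt, GXt, tolerance = 1e-9)
  set.seed(27)
  for (k in 1:200) {
    X <- Xt * exp(rnorm(inst$N, 0, 0.5))
    fS <- surrogateF(inst$problem@P, inst$w, inst$Y, S, X, Xt)
    FX <- wlsCost(inst$problem@P, inst$w, inst$Y, S, X)
    expect_gte(fS - FX, -1e-9 * max(1, abs(FX)))
    gS <- surrogateG(inst$reg, inst$C, X, Xt)
    GX <- sum((as.numeric(regOperator(inst$reg) %*% X) + inst$C)^2)
    expect_gte(gS - GX, -1e-9 * max(1, abs(GX)))
  }
  expect_error(surrogateF(inst$problem@P, inst$w, inst$Y, S,
                          Xt, Xt * 0), "positive")
})

test_that("surrogate gradient at Xt matches the subproblem gradient", {
  inst <- randomInstance(3, seed = 28)
  S <- numeric(inst$M)
  rho <- 0.6
  Xt <- runif(inst$N, 0.5, 2)
  phiSur <- function(X)
    surrogateF(inst$problem@P, inst$w, inst$Y, S, X, Xt) +
      rho / 2 * surrogateG(inst$reg, inst$C, X, Xt)
  phi <- function(X)
    xSubproblemCost(inst$problem@P, inst$w, inst$Y, S, inst$reg, rho, X,
                    inst$C)
  h <- 1e-6
  for (j in seq_len(inst$N)) {
    e <- numeric(inst$N); e[j] <- h
    gSur <- (phiSur(Xt + e) - phiSur(Xt - e)) / (2 * h)
    gPhi <- (phi(Xt + e) - phi(Xt - e)) / (2 * h)
    expect_equal(gSur, gPhi, tolerance = 1e-4)
  }
})

test_that("update terms match dense longhand algebra and are nonnegative", {
  inst <- randomInstance(3, seed = 29)
  S <- runif(inst$M, 0, 0.3)
  Xt <- runif(inst$N, 0.5, 2)
  Cs <- splitSigned(inst$C)
  tm <- emTerms(inst$problem@P, inst$w, inst$Y, S, inst$reg, Cs, Xt)
  Rm <- as.matrix(regOperator(inst$reg))
  Rp <- pmax(Rm, 0); Rn <- pmax(-Rm, 0)
  A1 <- as.numeric(t(inst$P) %*% (inst$w * inst$Y))
  A2 <- as.numeric(t(Rp + Rn) %*% ((Rp + Rn) %*% Xt)) +
        as.numeric(t(Rp + Rn) %*% (Cs$pos + Cs$neg))
  A3 <- as.numeric(t(inst$P) %*% (inst$w * (inst$P %*% Xt + S)))
  A4 <- as.numeric((t(Rp) %*% Rp + t(Rn) %*% Rn) %*% Xt) +
        as.numeric(t(Rp) %*% Cs$pos + t(Rn) %*% Cs$neg)
  expect_equal(tm$A1, A1, tolerance = 1e-10)
  expect_equal(tm$A2, A2, tolerance = 1e-10)
  expect_equal(tm$A3, A3, tolerance = 1e-10)
  expect_equal(tm$A4, A4, tolerance = 1e-10)
  expect_true(all(tm$A1 >= 0 & tm$A2 >= 0 & tm$A3 >= 0 & tm$A4 >= 0))
  # A1, A3 do not depend on the regularizer or C
  Cs2 <- splitSigned(rnorm(nrow(Rm)))
  tm2 <- emTerms(inst$problem@P, inst$w, inst$Y, S,
                 buildAnisotropicTV(inst$n), Cs2, Xt)
  expect_identical(tm$A1, tm2$A1)
  expect_identical(tm$A3, tm2$A3)
  # zero operator kills A2 and A4
  zeroReg <- linearRegularizer(Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0),
    dims = c(4L, inst$N)))
  tm0 <- emTerms(inst$problem@P, inst$w, inst$Y, S, zeroReg,
                 splitSigned(numeric(4)), Xt)
  expect_equal(tm0$A2, numeric(inst$N))
  expect_equal(tm0$A4, numeric(inst$N))
})
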