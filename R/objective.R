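# Cost functions and the majorizing surrogates behind the multiplicative
# image update.  All evaluations here are diagnostics: they use uncounted
# operator products so the matvec counter keeps the
# two-products-per-inner-iteration complexity accounting of the solvers.

## Accept SystemMatrix / Matrix / base matrix; return a sparse matrix.
.opEntries <- function(P) {
  if (is(P, "SystemMatrix")) P@entries else .asSparse(P)
}

## Accept WeightModel or plain numeric weights.
.wvec <- function(weights, m) {
  w <- if (is(weights, "WeightModel")) weights@weights else as.numeric(weights)
  rep_len(w, m)
}

.xvec <- function(X) if (is(X, "ActivityImage")) X@pixels else as.numeric(X)

.triplets <- function(M) {
  T3 <- as(M, "TsparseMatrix")
  list(i = T3@i + 1L, j = T3@j + 1L, x = T3@x)
}

#' Weighted least squares data term
#'
#' \eqn{F(X) = \sum_i \Sigma_{ii}\,((PX + S - Y)_i)^2}.
#'
#' @param P system matrix (a \code{SystemMatrix} or matrix).
#' @param weights \code{WeightModel} or numeric diagonal of \eqn{\Sigma}.
#' @param Y measured counts.
#' @param S scatter/randoms estimate.
#' @param X image vector.
#' @return nonnegative scalar.
#' @export
wlsCost <- function(P, weights, Y, S, X) {
  Pe <- .opEntries(P)
  r <- as.numeric(Pe %*% .xvec(X)) + S - Y
  sum(.wvec(weights, length(r)) * r^2)
}

#' Penalized primal objective
#'
#' \eqn{F(X) + \beta\|RX\|_1}, the function the ADMM drivers minimize over
#' \eqn{X \ge 0}.
#'
#' @inheritParams wlsCost
#' @param reg a \code{LinearRegularizer}.
#' @param beta positive penalty weight.
#' @return scalar.
#' @export
primalObjective <- function(P, weights, Y, S, reg, beta, X) {
  wlsCost(P, weights, Y, S, X) + beta * tvSeminorm(reg, X)
}

#' Scaled augmented Lagrangian
#'
#' \eqn{L(X, V, \mu) = F(X) + \beta\|V\|_1 +
#'   (\rho/2)\|RX - V + \mu\|_2^2 - (\rho/2)\|\mu\|_2^2}.
#'
#' @inheritParams primalObjective
#' @param rho positive ADMM penalty.
#' @param V auxiliary variable.
#' @param mu scaled dual variable.
#' @return scalar.
#' @export
augmentedLagrangian <- function(P, weights, Y, S, reg, beta, rho, X, V, mu) {
  rx <- as.numeric(reg@R %*% .xvec(X))
  wlsCost(P, weights, Y, S, X) + beta * sum(abs(V)) +
    (rho / 2) * sum((rx - V + mu)^2) - (rho / 2) * sum(mu^2)
}

#' Image-subproblem cost
#'
#' \eqn{\Phi(X) = F(X) + (\rho/2)\|RX + C\|_2^2} with the per-outer-
#' iteration constant \eqn{C = -V + \mu}; this equals the augmented
#' Lagrangian up to the X-independent terms \eqn{\beta\|V\|_1} and
#' \eqn{-(\rho/2)\|\mu\|_2^2}.
#'
#' @inheritParams augmentedLagrangian
#' @param C constant vector \eqn{-V + \mu}.
#' @return scalar.
#' @export
xSubproblemCost <- function(P, weights, Y, S, reg, rho, X, C) {
  rx <- as.numeric(reg@R %*% .xvec(X))
  wlsCost(P, weights, Y, S, X) + (rho / 2) * sum((rx + C)^2)
}

#' Jensen surrogate of the data term
#'
#' The separable majorizer of \eqn{F} at \eqn{X^t} built from the convex
#' combination coefficients
#' \eqn{\lambda_{i*} = S_i / (PX^t + S)_i},
#' \eqn{\lambda_{ij} = P_{ij} X_j^t / (PX^t + S)_i}:
#' \deqn{f(X \mid X^t) = \sum_i \Sigma_{ii} \Big[
#'   \lambda_{i*}\big(S_i/\lambda_{i*} - Y_i\big)^2 +
#'   \sum_j \lambda_{ij}\big(P_{ij}X_j/\lambda_{ij} - Y_i\big)^2 \Big].}
#' Bins with \eqn{(PX^t + S)_i = 0} have undefined coefficients; their
#' (constant) contribution \eqn{\Sigma_{ii} Y_i^2} is added directly, which
#' is the limit of the construction.  Tangency \eqn{f(X^t|X^t) = F(X^t)}
#' and majorization \eqn{f \ge F} hold.
#'
#' @inheritParams wlsCost
#' @param Xt expansion point, strictly positive elementwise.
#' @return scalar.
#' @export
surrogateF <- function(P, weights, Y, S, X, Xt) {
  Pe <- .opEntries(P)
  x <- .xvec(X); xt <- .xvec(Xt)
  if (any(xt <= 0)) stop("Xt must be strictly positive")
  m <- nrow(Pe)
  w <- .wvec(weights, m)
  d <- as.numeric(Pe %*% xt) + S
  tr <- .triplets(Pe)
  ok <- d[tr$i] > 0
  val <- 0
  if (any(ok)) {
    i <- tr$i[ok]; j <- tr$j[ok]; p <- tr$x[ok]
    lam <- p * xt[j] / d[i]
    val <- sum(w[i] * lam * (d[i] * x[j] / xt[j] - Y[i])^2)
  }
  pos <- d > 0
  val <- val + sum(w[pos] * (S[pos] / d[pos]) * (d[pos] - Y[pos])^2)
  val + sum(w[!pos] * Y[!pos]^2)
}

#' Splitting surrogate of the quadratic coupling term
#'
#' The separable majorizer of \eqn{G(X) = \|RX + C\|_2^2} at \eqn{X^t},
#' built in two stages from the nonnegative splittings \eqn{R = \bar R -
#' \hat R}, \eqn{C = \bar C - \hat C}: first the half/half intermediate
#' surrogate, then a Jensen step on each half with coefficients
#' \eqn{\bar\lambda_{ij} = \bar R_{ij}X_j^t / (\bar R X^t + \bar C)_i}
#' (and the hat analogue).  The constant \eqn{\lambda_*} terms (which the
#' minimization may drop) are retained here so that tangency
#' \eqn{g(X^t|X^t) = G(X^t)} holds exactly.  Rows whose split denominator
#' vanishes contribute their (constant) limit value.
#'
#' @param reg a \code{LinearRegularizer}.
#' @param C constant vector \eqn{-V + \mu}.
#' @param X evaluation point.
#' @param Xt strictly positive expansion point.
#' @return scalar.
#' @export
surrogateG <- function(reg, C, X, Xt) {
  x <- .xvec(X); xt <- .xvec(Xt)
  if (any(xt <= 0)) stop("Xt must be strictly positive")
  Cs <- splitSigned(as.numeric(C))
  half <- function(Rpart, Cpart) {
    p <- as.numeric(Rpart %*% xt) + Cpart          # split denominator
    wv <- as.numeric((reg@Rpos + reg@Rneg) %*% xt) + Cs$pos + Cs$neg
    tr <- .triplets(Rpart)
    ok <- p[tr$i] > 0
    val <- 0
    if (any(ok)) {
      i <- tr$i[ok]; j <- tr$j[ok]; r <- tr$x[ok]
      lam <- r * xt[j] / p[i]
      val <- sum(lam * (2 * p[i] * x[j] / xt[j] - wv[i])^2)
    }
    pos <- p > 0
    val <- val + sum((Cpart[pos] / p[pos]) * (2 * p[pos] - wv[pos])^2)
    (val + sum(wv[!pos]^2)) / 2
  }
  half(reg@Rpos, Cs$pos) + half(reg@Rneg, Cs$neg)
}

#' Terms of the multiplicative image update
#'
#' The four nonnegative vectors entering the update
#' \eqn{X^{t+1}_j = X^t_j\,(A_1 + (\rho/2)A_2)_j / (A_3 + \rho A_4)_j}:
#' \deqn{A_1 = P^T\Sigma Y, \quad
#'       A_2 = (\bar R + \hat R)^T\big((\bar R + \hat R)X^t +
#'             \bar C + \hat C\big),}
#' \deqn{A_3 = P^T\Sigma(PX^t + S), \quad
#'       A_4 = (\bar R^T\bar R + \hat R^T\hat R)X^t +
#'             \bar R^T\bar C + \hat R^T\hat C.}
#' All four are elementwise nonnegative whenever \eqn{X^t \ge 0} and
#' \eqn{Y \ge 0}.
#'
#' @inheritParams wlsCost
#' @param reg a \code{LinearRegularizer}.
#' @param Csplit list with nonnegative components \code{pos}, \code{neg}
#'   (from \code{\link{splitSigned}} of \eqn{C = -V + \mu}).
#' @param Xt current nonnegative image.
#' @return named list with numeric vectors \code{A1}, \code{A2}, \code{A3},
#'   \code{A4}.
#' @export
emTerms <- function(P, weights, Y, S, reg, Csplit, Xt) {
  Pe <- .opEntries(P)
  xt <- .xvec(Xt)
  if (length(xt) != ncol(Pe)) stop("Xt length must equal ncol(P)")
  w <- .wvec(weights, nrow(Pe))
  Rsum <- reg@Rpos + reg@Rneg
  Csum <- Csplit$pos + Csplit$neg
  A1 <- as.numeric(crossprod(Pe, w * Y))
  A2 <- as.numeric(crossprod(Rsum, as.numeric(Rsum %*% xt) + Csum))
  A3 <- as.numeric(crossprod(Pe, w * (as.numeric(Pe %*% xt) + S)))
  A4 <- as.numeric(crossprod(reg@Rpos, as.numeric(reg@Rpos %*% xt) +
                               Csplit$pos)) +
        as.numeric(crossprod(reg@Rneg, as.numeric(reg@Rneg %*% xt) +
                               Csplit$neg))
  list(A1 = A1, A2 = A2, A3 = A3, A4 = A4)
}
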