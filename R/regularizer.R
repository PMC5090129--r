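# Anisotropic TV operator and nonnegative splittings.

#' Split a signed matrix or vector into nonnegative parts
#'
#' Returns \code{list(pos, neg)} with \code{pos = max(A, 0)},
#' \code{neg = max(-A, 0)}, so \code{pos - neg == A} bit-exactly and
#' \code{pos * neg == 0} elementwise (the split is an elementwise
#' selection, never an arithmetic combination).
#'
#' @param A numeric vector, dense matrix or sparse Matrix with finite
#'   entries.
#' @return list with components \code{pos} and \code{neg} of the same shape
#'   as \code{A}.
#' @export
splitSigned <- function(A) {
  if (is(A, "sparseMatrix")) {
    M <- .asSparse(A)
    pos <- M; pos@x <- pmax(M@x, 0); pos <- Matrix::drop0(pos)
    neg <- M; neg@x <- pmax(-M@x, 0); neg <- Matrix::drop0(neg)
    return(list(pos = pos, neg = neg))
  }
  if (any(!is.finite(A))) stop("entries must be finite")
  list(pos = pmax(A, 0), neg = pmax(-A, 0))
}

#' Build the anisotropic total-variation difference operator
#'
#' One row per (pixel, right neighbor) pair and per (pixel, below neighbor)
#' pair of the row-major \code{gridSide} x \code{gridSide} raster, with
#' coefficients +1 on the pixel and -1 on the neighbor, so
#' \eqn{\|RX\|_1 = \sum_j |X_j - X_{j,\mathrm{right}}| +
#' |X_j - X_{j,\mathrm{below}}|}.  Pairs whose neighbor falls outside the
#' grid are omitted (Neumann-style boundary), giving \eqn{K = 2n(n-1)}
#' rows: all horizontal pairs in raster order first, then all vertical
#' pairs in raster order.
#'
#' @param gridSide image side length \eqn{n \ge 2}.
#' @return a \code{\link{LinearRegularizer-class}} object.
#' @export
buildAnisotropicTV <- function(gridSide) {
  n <- as.integer(gridSide)
  if (n < 2L) stop("gridSide must be >= 2")
  N <- n * n
  idx <- matrix(seq_len(N), nrow = n, byrow = TRUE)  # [row, col]
  # horizontal pairs (pixel, right neighbor), raster order
  j1h <- as.vector(t(idx[, -n, drop = FALSE]))
  j2h <- j1h + 1L
  # vertical pairs (pixel, below neighbor), raster order
  j1v <- as.vector(t(idx[-n, , drop = FALSE]))
  j2v <- j1v + n
  j1 <- c(j1h, j1v)
  j2 <- c(j2h, j2v)
  K <- length(j1)
  R <- Matrix::sparseMatrix(i = rep(seq_len(K), 2L), j = c(j1, j2),
                            x = c(rep(1, K), rep(-1, K)), dims = c(K, N))
  sp <- splitSigned(R)
  new("LinearRegularizer", R = .asSparse(R), Rpos = sp$pos, Rneg = sp$neg,
      gridSide = n)
}

#' Wrap an arbitrary signed operator as a regularizer
#'
#' @param R sparse or dense matrix.
#' @return a \code{\link{LinearRegularizer-class}} object (gridSide 0).
#' @export
linearRegularizer <- function(R) {
  Rs <- .asSparse(R)
  sp <- splitSigned(Rs)
  new("LinearRegularizer", R = Rs, Rpos = sp$pos, Rneg = sp$neg,
      gridSide = 0L)
}

#' Anisotropic TV seminorm
#'
#' Returns \eqn{\|RX\|_1}, the sum of absolute penalized differences.
#'
#' @param reg a \code{LinearRegularizer}.
#' @param X image vector (or \code{ActivityImage}).
#' @return nonnegative scalar.
#' @export
tvSeminorm <- function(reg, X) {
  x <- if (is(X, "ActivityImage")) X@pixels else as.numeric(X)
  sum(abs(as.numeric(reg@R %*% x)))
}

#' Export a sparse operator as coordinate triples
#'
#' Writes (row, col, value) triples as whitespace-separated text, for
#' debugging and interchange.
#'
#' @param reg a \code{LinearRegularizer}.
#' @param path output file path.
#' @export
writeOperatorTriples <- function(reg, path) {
  T3 <- as(reg@R, "TsparseMatrix")
  utils::write.table(
    data.frame(i = T3@i + 1L, j = T3@j + 1L, x = T3@x),
    file = path, row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}
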