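#' @importClassesFrom Matrix dgCMatrix
#' @importFrom Matrix sparseMatrix Diagonal drop0 colSums rowSums
#' @importMethodsFrom Matrix %*% t crossprod
#' @importFrom methods new validObject is as show setValidity slot
#' @importFrom stats rpois sd
NULL

## Internal: coerce anything matrix-like to the canonical sparse class.
.asSparse <- function(M) {
  if (is(M, "dgCMatrix")) return(M)
  as(as(as(M, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# ---------------------------------------------------------------------------
# ScanGeometry
# ---------------------------------------------------------------------------

#' Parallel-beam scan geometry
#'
#' Describes a 2-D parallel-beam acquisition: \code{nBins} radial bins of
#' width \code{binSizeMm} per view, and \code{nViews} view angles evenly
#' spaced over \eqn{[0, \pi)}.  The sinogram has \eqn{M = nBins \times
#' nViews} elements, stored bin-fastest (all bins of view 1, then view 2,
#' ...).
#'
#' @slot nBins integer, number of radial bins per view.
#' @slot nViews integer, number of angular views over \eqn{\pi}.
#' @slot binSizeMm positive numeric, radial bin width in mm.
#' @export
setClass("ScanGeometry",
  representation(nBins = "integer", nViews = "integer", binSizeMm = "numeric"))

setValidity("ScanGeometry", function(object) {
  if (object@nBins < 1L || object@nViews < 1L)
    return("nBins and nViews must be >= 1")
  if (length(object@binSizeMm) != 1L || object@binSizeMm <= 0)
    return("binSizeMm must be a single positive number")
  TRUE
})

#' @param nBins,nViews,binSizeMm see slots.
#' @rdname ScanGeometry-class
#' @export
scanGeometry <- function(nBins, nViews, binSizeMm = 4) {
  new("ScanGeometry", nBins = as.integer(nBins), nViews = as.integer(nViews),
      binSizeMm = as.numeric(binSizeMm))
}

#' Number of sinogram elements of a geometry
#' @param geometry a \code{ScanGeometry}.
#' @return integer \eqn{M = nBins \times nViews}.
#' @export
nSinogramBins <- function(geometry) geometry@nBins * geometry@nViews

setMethod("show", "ScanGeometry", function(object) {
  cat("ScanGeometry:", object@nBins, "bins x", object@nViews,
      "views over pi, bin size", object@binSizeMm, "mm\n")
})

# ---------------------------------------------------------------------------
# ActivityImage
# ---------------------------------------------------------------------------

#' Emission activity image
#'
#' A nonnegative activity distribution on a square pixel grid, stored as a
#' row-major raster vector (row 1 is the top image row), together with named
#' region-of-interest masks.  The image center sits on the rotation axis.
#'
#' @slot pixels numeric vector of length \code{gridSide^2}, all \eqn{\ge 0}.
#' @slot gridSide integer, pixels per side.
#' @slot pixelSizeMm positive numeric, pixel width in mm.
#' @slot roiMasks named list of logical vectors over pixels; phantoms
#'   populate at least \code{"background"}, \code{"low_roi"} and
#'   \code{"high_roi"}.
#' @export
setClass("ActivityImage",
  representation(pixels = "numeric", gridSide = "integer",
                 pixelSizeMm = "numeric", roiMasks = "list"))

setValidity("ActivityImage", function(object) {
  n <- object@gridSide
  if (length(object@pixels) != n * n)
    return("pixels must have length gridSide^2")
  if (any(!is.finite(object@pixels)) || any(object@pixels < 0))
    return("pixels must be finite and nonnegative")
  if (object@pixelSizeMm <= 0) return("pixelSizeMm must be positive")
  for (nm in names(object@roiMasks)) {
    m <- object@roiMasks[[nm]]
    if (!is.logical(m) || length(m) != n * n)
      return(sprintf("mask '%s' must be logical of length gridSide^2", nm))
  }
  TRUE
})

#' @param pixels,gridSide,pixelSizeMm,roiMasks see slots.
#' @rdname ActivityImage-class
#' @export
activityImage <- function(pixels, gridSide, pixelSizeMm = 4,
                          roiMasks = list()) {
  new("ActivityImage", pixels = as.numeric(pixels),
      gridSide = as.integer(gridSide), pixelSizeMm = as.numeric(pixelSizeMm),
      roiMasks = roiMasks)
}

#' @param object,image an \code{ActivityImage}.
#' @rdname ActivityImage-class
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname ActivityImage-class
#' @export
setMethod("pixels", "ActivityImage", function(object) object@pixels)

#' @rdname ActivityImage-class
#' @export
setGeneric("gridSide", function(object) standardGeneric("gridSide"))

#' @rdname ActivityImage-class
#' @export
setMethod("gridSide", "ActivityImage", function(object) object@gridSide)

#' Retrieve a named ROI mask
#' @param name mask name, e.g. \code{"background"}.
#' @rdname ActivityImage-class
#' @export
roiMask <- function(image, name) {
  m <- image@roiMasks[[name]]
  if (is.null(m)) stop("no ROI mask named '", name, "'")
  m
}

#' Image as a gridSide x gridSide matrix (row 1 = top row)
#' @rdname ActivityImage-class
#' @export
asImageMatrix <- function(image) {
  matrix(image@pixels, nrow = image@gridSide, byrow = TRUE)
}

setMethod("show", "ActivityImage", function(object) {
  cat("ActivityImage:", object@gridSide, "x", object@gridSide, "grid,",
      object@pixelSizeMm, "mm pixels\n")
  cat("  activity range [", format(min(object@pixels)), ",",
      format(max(object@pixels)), "], total", format(sum(object@pixels)), "\n")
  if (length(object@roiMasks))
    cat("  ROI masks:", paste(names(object@roiMasks), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SystemMatrix
# ---------------------------------------------------------------------------

#' Instrumented sparse system matrix
#'
#' The sparse nonnegative \eqn{M \times N} projector \eqn{P}.  Applications
#' of \eqn{P} or \eqn{P^T} through \code{\link{projectForward}} /
#' \code{\link{backProject}} increment a counter, which is the complexity
#' proxy used throughout: solver cost is reported as the number of
#' system-matrix--vector products.
#'
#' @slot entries a \code{dgCMatrix} with nonnegative entries.
#' @slot counter environment holding the monotone matvec count \code{n}.
#' @export
setClass("SystemMatrix",
  representation(entries = "dgCMatrix", counter = "environment"))

setValidity("SystemMatrix", function(object) {
  if (length(object@entries@x) && min(object@entries@x) < 0)
    return("system matrix entries must be nonnegative")
  if (!is.numeric(object@counter$n) || object@counter$n < 0)
    return("matvec counter must be a nonnegative number")
  TRUE
})

#' @param entries matrix-like, coerced to sparse.
#' @rdname SystemMatrix-class
#' @export
systemMatrix <- function(entries) {
  env <- new.env(parent = emptyenv())
  env$n <- 0
  new("SystemMatrix", entries = .asSparse(entries), counter = env)
}

#' @param P a \code{SystemMatrix}.
#' @return \code{matvecCount}: the number of counted \eqn{P}/\eqn{P^T}
#'   products so far.
#' @rdname SystemMatrix-class
#' @export
matvecCount <- function(P) P@counter$n

#' @rdname SystemMatrix-class
#' @export
resetMatvecCount <- function(P) {
  P@counter$n <- 0
  invisible(P)
}

setMethod("show", "SystemMatrix", function(object) {
  d <- dim(object@entries)
  cat("SystemMatrix:", d[1], "x", d[2], "sparse,",
      length(object@entries@x), "nonzeros,", object@counter$n,
      "matvecs counted\n")
})

## Internal uncounted products: used for fixed per-run constants and
## diagnostic cost traces, so the counter reproduces the 2-products-per-
## inner-iteration accounting of the reconstruction algorithms themselves.
.fwd <- function(P, x) as.numeric(P@entries %*% x)
.bwd <- function(P, y) as.numeric(crossprod(P@entries, y))

## Internal counted products.
.fwdCount <- function(P, x) {
  P@counter$n <- P@counter$n + 1
  as.numeric(P@entries %*% x)
}
.bwdCount <- function(P, y) {
  P@counter$n <- P@counter$n + 1
  as.numeric(crossprod(P@entries, y))
}

#' Apply the system matrix (counted)
#'
#' \code{projectForward(P, x)} returns \eqn{Px}; \code{backProject(P, y)}
#' returns \eqn{P^T y}.  Each call increments the matvec counter by exactly
#' one.
#'
#' @param P a \code{SystemMatrix}.
#' @param x image-domain numeric vector (length \eqn{N}).
#' @param y sinogram-domain numeric vector (length \eqn{M}).
#' @return numeric vector.
#' @export
projectForward <- function(P, x) .fwdCount(P, x)

#' @rdname projectForward
#' @export
backProject <- function(P, y) .bwdCount(P, y)

# ---------------------------------------------------------------------------
# Sinogram
# ---------------------------------------------------------------------------

#' Sinogram container
#'
#' Measured counts \eqn{Y} with the noise-free projection \eqn{y^*}, the
#' additive scatter/randoms estimate \eqn{S}, the per-bin randoms fraction
#' \eqn{a_i} and detector efficiency \eqn{c_i}.  \code{counts} may contain
#' negatives only when the noise simulation was run with \code{clamp =
#' FALSE} (the two-Poisson randoms correction can go negative).
#'
#' @slot counts numeric vector \eqn{Y}.
#' @slot noiseFree nonnegative vector \eqn{y^*}.
#' @slot scatter nonnegative vector \eqn{S}.
#' @slot randomsFraction per-bin \eqn{a_i \in [0,1)}.
#' @slot efficiency per-bin \eqn{c_i > 0}.
#' @slot clamped logical, whether negative counts were clamped to zero.
#' @export
setClass("Sinogram",
  representation(counts = "numeric", noiseFree = "numeric",
                 scatter = "numeric", randomsFraction = "numeric",
                 efficiency = "numeric", clamped = "logical"))

setValidity("Sinogram", function(object) {
  m <- length(object@counts)
  if (length(object@noiseFree) != m || length(object@scatter) != m ||
      length(object@randomsFraction) != m || length(object@efficiency) != m)
    return("all sinogram vectors must share one length")
  if (any(object@noiseFree < 0)) return("noiseFree must be nonnegative")
  if (any(object@scatter < 0)) return("scatter must be nonnegative")
  if (any(object@randomsFraction < 0) || any(object@randomsFraction >= 1))
    return("randomsFraction must lie in [0, 1)")
  if (any(object@efficiency <= 0)) return("efficiency must be positive")
  if (object@clamped && any(object@counts < 0))
    return("clamped sinogram cannot hold negative counts")
  TRUE
})

#' @param counts,noiseFree,scatter,randomsFraction,efficiency,clamped see
#'   slots; scalars are recycled to the sinogram length.
#' @rdname Sinogram-class
#' @export
sinogram <- function(counts, noiseFree = counts,
                     scatter = numeric(length(counts)),
                     randomsFraction = 0, efficiency = 1, clamped = TRUE) {
  m <- length(counts)
  new("Sinogram", counts = as.numeric(counts),
      noiseFree = as.numeric(noiseFree), scatter = rep_len(scatter, m),
      randomsFraction = rep_len(randomsFraction, m),
      efficiency = rep_len(efficiency, m), clamped = clamped)
}

#' @param object a \code{Sinogram}.
#' @rdname Sinogram-class
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname Sinogram-class
#' @export
setMethod("counts", "Sinogram", function(object) object@counts)

setMethod("show", "Sinogram", function(object) {
  cat("Sinogram:", length(object@counts), "bins, total counts",
      format(sum(object@counts)),
      if (object@clamped) "(clamped)" else "(unclamped)", "\n")
})

# ---------------------------------------------------------------------------
# WeightModel
# ---------------------------------------------------------------------------

#' Diagonal WLS weights
#'
#' The diagonal of \eqn{\Sigma} in the weighted least squares data term,
#' \eqn{\Sigma_{ii} = 1/\sigma_i} with \eqn{\sigma_i} the variance of bin
#' \eqn{i}.  Built by \code{\link{pluginWeights}}.
#'
#' @slot weights positive finite numeric vector (diagonal of \eqn{\Sigma}).
#' @slot floor positive numeric, the variance floor \eqn{\delta} applied to
#'   zero-count bins.
#' @export
setClass("WeightModel",
  representation(weights = "numeric", floor = "numeric"))

setValidity("WeightModel", function(object) {
  if (any(!is.finite(object@weights)) || any(object@weights <= 0))
    return("weights must be positive and finite")
  if (object@floor <= 0) return("floor must be positive")
  TRUE
})

#' @param object a \code{WeightModel}.
#' @rdname WeightModel-class
#' @export
setGeneric("binWeights", function(object) standardGeneric("binWeights"))

#' @rdname WeightModel-class
#' @export
setMethod("binWeights", "WeightModel", function(object) object@weights)

setMethod("show", "WeightModel", function(object) {
  cat("WeightModel:", length(object@weights), "bins, weight range [",
      format(min(object@weights)), ",", format(max(object@weights)),
      "], floor", object@floor, "\n")
})

# ---------------------------------------------------------------------------
# LinearRegularizer
# ---------------------------------------------------------------------------

#' Signed linear regularization operator with nonnegative splitting
#'
#' A sparse operator \eqn{R} (one row per penalized difference) together
#' with its exact nonnegative splitting \eqn{R = \bar R - \hat R},
#' \eqn{\min(\bar R, \hat R) = 0} elementwise.  The splitting is what lets
#' the multiplicative image update handle the signed operator while staying
#' nonnegative.
#'
#' @slot R sparse \eqn{K \times N} operator.
#' @slot Rpos,Rneg its nonnegative parts \eqn{\bar R}, \eqn{\hat R}.
#' @slot gridSide integer; side of the image grid the operator acts on
#'   (0 when not grid-structured).
#' @export
setClass("LinearRegularizer",
  representation(R = "dgCMatrix", Rpos = "dgCMatrix", Rneg = "dgCMatrix",
                 gridSide = "integer"))

setValidity("LinearRegularizer", function(object) {
  if (!identical(dim(object@R), dim(object@Rpos)) ||
      !identical(dim(object@R), dim(object@Rneg)))
    return("R, Rpos, Rneg must share dimensions")
  if (length(object@Rpos@x) && min(object@Rpos@x) < 0)
    return("Rpos must be nonnegative")
  if (length(object@Rneg@x) && min(object@Rneg@x) < 0)
    return("Rneg must be nonnegative")
  d <- object@Rpos - object@Rneg - object@R
  if (length(d@x) && max(abs(d@x)) != 0)
    return("splitting must satisfy R = Rpos - Rneg exactly")
  TRUE
})

#' @param reg a \code{LinearRegularizer}.
#' @return \code{regOperator}: the sparse matrix \eqn{R}.
#' @rdname LinearRegularizer-class
#' @export
regOperator <- function(reg) reg@R

#' @rdname LinearRegularizer-class
#' @export
regSplit <- function(reg) list(pos = reg@Rpos, neg = reg@Rneg)

setMethod("show", "LinearRegularizer", function(object) {
  d <- dim(object@R)
  cat("LinearRegularizer:", d[1], "rows x", d[2], "pixels,",
      length(object@R@x), "nonzeros",
      if (object@gridSide > 0)
        paste0("(anisotropic TV on ", object@gridSide, "x",
               object@gridSide, " grid)") else "", "\n")
})

# ---------------------------------------------------------------------------
# ReconProblem
# ---------------------------------------------------------------------------

#' Reconstruction problem bundle
#'
#' Bundles the pieces of the penalized WLS problem
#' \deqn{\min_{X \ge 0} \|PX + S - Y\|_\Sigma^2 + \beta \|RX\|_1}
#' (the solver configuration carries \eqn{\beta}, \eqn{\rho} and the
#' iteration schedule separately).
#'
#' @slot P a \code{SystemMatrix}.
#' @slot Y numeric measured counts (clamped nonnegative by default upstream).
#' @slot S nonnegative scatter/randoms estimate.
#' @slot weights a \code{WeightModel}.
#' @slot reg a \code{LinearRegularizer}.
#' @export
setClass("ReconProblem",
  representation(P = "SystemMatrix", Y = "numeric", S = "numeric",
                 weights = "WeightModel", reg = "LinearRegularizer"))

setValidity("ReconProblem", function(object) {
  d <- dim(object@P@entries)
  if (length(object@Y) != d[1] || length(object@S) != d[1])
    return("Y and S must have length nrow(P)")
  if (length(object@weights@weights) != d[1])
    return("weights must have length nrow(P)")
  if (ncol(object@reg@R) != d[2])
    return("regularizer must act on ncol(P) pixels")
  if (any(object@S < 0)) return("S must be nonnegative")
  TRUE
})

#' @param P,Y,S,weights,reg see slots.
#' @rdname ReconProblem-class
#' @export
reconProblem <- function(P, Y, S = numeric(nrow(P@entries)), weights, reg) {
  new("ReconProblem", P = P, Y = as.numeric(Y), S = as.numeric(S),
      weights = weights, reg = reg)
}

setMethod("show", "ReconProblem", function(object) {
  d <- dim(object@P@entries)
  cat("ReconProblem:", d[1], "bins ->", d[2], "pixels,",
      nrow(object@reg@R), "penalty rows, total counts",
      format(sum(object@Y)), "\n")
})

# ---------------------------------------------------------------------------
# SolverConfig
# ---------------------------------------------------------------------------

#' Solver configuration
#'
#' @slot beta positive numeric, L1 penalty weight \eqn{\beta}.
#' @slot rho positive numeric, ADMM penalty \eqn{\rho}.
#' @slot nOuter,nInner integers \eqn{\ge 1}, outer/inner iteration counts
#'   (\code{nInner = 1} with the EM backend is the simplified driver).
#' @slot epsilon nonnegative numeric; outer loop stops early when the
#'   relative-change statistic \eqn{\chi} falls below it (0 disables).
#' @slot xBackend one of \code{"em"}, \code{"projected_landweber"},
#'   \code{"conjugate_gradient"}, \code{"direct"}.
#' @slot alphaOverride optional positive step size for the projected
#'   Landweber backend (length 0 = use the norm-product formula).
#' @slot landweberUseRho logical; use \eqn{\rho} instead of \eqn{\beta} in
#'   the default Landweber step-size formula.
#' @slot cgProjectEachStep logical; project CG iterates at every step rather
#'   than truncating once after the inner loop.
#' @slot squaredChi logical; use the squared-norm-ratio convention for
#'   \eqn{\chi}.
#' @slot clampNegativeCounts logical; clamp negative measured counts to 0.
#' @slot seed integer seed for any stochastic component.
#' @export
setClass("SolverConfig",
  representation(beta = "numeric", rho = "numeric", nOuter = "integer",
                 nInner = "integer", epsilon = "numeric",
                 xBackend = "character", alphaOverride = "numeric",
                 landweberUseRho = "logical", cgProjectEachStep = "logical",
                 squaredChi = "logical", clampNegativeCounts = "logical",
                 seed = "integer"))

setValidity("SolverConfig", function(object) {
  if (object@beta <= 0 || object@rho <= 0)
    return("beta and rho must be positive")
  if (object@nOuter < 1L || object@nInner < 1L)
    return("nOuter and nInner must be >= 1")
  if (object@epsilon < 0) return("epsilon must be nonnegative")
  if (!object@xBackend %in%
      c("em", "projected_landweber", "conjugate_gradient", "direct"))
    return("unknown xBackend")
  if (length(object@alphaOverride) && object@alphaOverride <= 0)
    return("alphaOverride must be positive")
  TRUE
})

#' @param beta,rho,nOuter,nInner,epsilon,xBackend,alphaOverride see slots.
#' @param landweberUseRho,cgProjectEachStep,squaredChi see slots.
#' @param clampNegativeCounts,seed see slots.
#' @rdname SolverConfig-class
#' @export
solverConfig <- function(beta, rho, nOuter, nInner = 1L, epsilon = 0,
                         xBackend = "em", alphaOverride = numeric(0),
                         landweberUseRho = FALSE, cgProjectEachStep = FALSE,
                         squaredChi = TRUE, clampNegativeCounts = TRUE,
                         seed = 1L) {
  new("SolverConfig", beta = as.numeric(beta), rho = as.numeric(rho),
      nOuter = as.integer(nOuter), nInner = as.integer(nInner),
      epsilon = as.numeric(epsilon), xBackend = xBackend,
      alphaOverride = as.numeric(alphaOverride),
      landweberUseRho = landweberUseRho,
      cgProjectEachStep = cgProjectEachStep, squaredChi = squaredChi,
      clampNegativeCounts = clampNegativeCounts, seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# ADMMState
# ---------------------------------------------------------------------------

#' ADMM solver state
#'
#' Final primal/auxiliary/dual variables plus append-only per-outer-iteration
#' traces (costs, \eqn{\chi}, primal residual, matvec count, wall time).
#'
#' @slot X image iterate (strictly positive under the EM backend).
#' @slot V auxiliary variable (shrinkage target \eqn{V \approx RX}).
#' @slot mu scaled dual variable.
#' @slot t number of outer iterations executed.
#' @slot traces data.frame, one row per outer iteration.
#' @export
setClass("ADMMState",
  representation(X = "numeric", V = "numeric", mu = "numeric", t = "integer",
                 traces = "data.frame"))

#' @param state an \code{ADMMState}.
#' @return \code{reconstruction}: the final image vector.
#' @rdname ADMMState-class
#' @export
reconstruction <- function(state) state@X

#' @rdname ADMMState-class
#' @export
solverTraces <- function(state) state@traces

setMethod("show", "ADMMState", function(object) {
  cat("ADMMState:", object@t, "outer iterations,",
      length(object@X), "pixels\n")
  if (nrow(object@traces)) {
    last <- object@traces[nrow(object@traces), ]
    cat("  final primal objective", format(last$primal_objective),
        " chi", format(last$chi), " matvecs", last$matvec_count, "\n")
  }
})
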