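# Phantom generation, parallel-beam system matrix, forward projection,
# measurement noise and plug-in weights.

#' Build a parallel-beam intersection-length system matrix
#'
#' Entry \eqn{P_{ij}} is the length (mm) of ray \eqn{i} inside pixel
#' \eqn{j}: the standard line-intersection parallel-beam model, computed by
#' ray tracing through the pixel grid.  Rays are indexed bin-fastest; ray
#' \eqn{(v, k)} has angle \eqn{\theta_v = (v-1)\pi/nViews} measured from the
#' x axis and signed radial offset \eqn{s_k = (k - (nBins+1)/2)\,binSize}
#' from the rotation axis, which coincides with the image center.  Rays that
#' miss the image support give all-zero rows.
#'
#' @param geometry a \code{\link{scanGeometry}}.
#' @param gridSide image pixels per side.
#' @param pixelSizeMm pixel width in mm (defaults to the bin size).
#' @return a \code{\link{systemMatrix}} with its matvec counter at 0.
#' @export
buildSystemMatrix <- function(geometry, gridSide,
                              pixelSizeMm = geometry@binSizeMm) {
  n <- as.integer(gridSide)
  if (n < 1L) stop("gridSide must be >= 1")
  if (pixelSizeMm <= 0) stop("pixelSizeMm must be positive")
  nb <- geometry@nBins
  nv <- geometry@nViews
  h <- pixelSizeMm
  half <- n * h / 2
  glines <- -half + (0:n) * h
  sOff <- (seq_len(nb) - (nb + 1) / 2) * geometry@binSizeMm
  theta <- (seq_len(nv) - 1) * pi / nv
  eps <- 1e-12

  iAcc <- vector("list", nb * nv)
  jAcc <- vector("list", nb * nv)
  xAcc <- vector("list", nb * nv)
  row <- 0L
  for (v in seq_len(nv)) {
    ct <- cos(theta[v])
    st <- sin(theta[v])
    for (k in seq_len(nb)) {
      row <- row + 1L
      s <- sOff[k]
      ox <- s * ct; oy <- s * st      # ray point closest to the axis
      dx <- -st; dy <- ct             # unit direction along the ray
      # clip the ray against the image bounding box (slab method)
      tmin <- -Inf; tmax <- Inf
      if (abs(dx) > eps) {
        t1 <- (-half - ox) / dx; t2 <- (half - ox) / dx
        tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
      } else if (ox <= -half || ox >= half) next
      if (abs(dy) > eps) {
        t1 <- (-half - oy) / dy; t2 <- (half - oy) / dy
        tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
      } else if (oy <= -half || oy >= half) next
      if (tmax - tmin <= eps) next
      ts <- c(tmin, tmax)
      if (abs(dx) > eps) {
        tx <- (glines - ox) / dx
        ts <- c(ts, tx[tx > tmin + eps & tx < tmax - eps])
      }
      if (abs(dy) > eps) {
        ty <- (glines - oy) / dy
        ts <- c(ts, ty[ty > tmin + eps & ty < tmax - eps])
      }
      ts <- sort(ts)
      len <- diff(ts)
      keep <- len > eps
      if (!any(keep)) next
      tm <- (ts[-length(ts)] + ts[-1])[keep] / 2
      len <- len[keep]
      px <- ox + dx * tm
      py <- oy + dy * tm
      cols <- pmin(pmax(floor((px + half) / h) + 1, 1), n)
      rows <- pmin(pmax(floor((half - py) / h) + 1, 1), n)
      iAcc[[row]] <- rep.int(row, length(len))
      jAcc[[row]] <- (rows - 1L) * n + cols
      xAcc[[row]] <- len
    }
  }
  M <- nb * nv
  ii <- unlist(iAcc, use.names = FALSE)
  if (is.null(ii)) ii <- integer(0)
  ent <- Matrix::sparseMatrix(
    i = ii, j = unlist(jAcc, use.names = FALSE),
    x = unlist(xAcc, use.names = FALSE), dims = c(M, n * n))
  systemMatrix(ent)
}

## Shepp-Logan ellipse geometry (a, b, x0, y0, phi in degrees) on the unit
## square, with emission activity levels assigned per region by layering.
.sheppLoganEllipses <- function() {
  data.frame(
    a   = c(.69, .6624, .11, .16, .21, .046, .046, .046, .023, .023),
    b   = c(.92, .8740, .31, .41, .25, .046, .046, .023, .023, .046),
    x0  = c(0, 0, .22, -.22, 0, 0, 0, -.08, 0, .06),
    y0  = c(0, -.0184, 0, 0, .35, .1, -.1, -.605, -.606, -.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
    activity = c(0.5, 1.0, 0.4, 0.4, 2.0, 1.6, 1.6, 1.6, 1.6, 1.6))
}

.insideEllipse <- function(x, y, e) {
  p <- e$phi * pi / 180
  u <- (x - e$x0) * cos(p) + (y - e$y0) * sin(p)
  v <- -(x - e$x0) * sin(p) + (y - e$y0) * cos(p)
  (u / e$a)^2 + (v / e$b)^2 <= 1
}

#' Generate the emission Shepp-Logan phantom
#'
#' Builds a Shepp-Logan-style activity phantom: the classic ten-ellipse
#' geometry with the CT attenuation levels remapped to a nonnegative
#' emission scale (outer rim 0.5, brain background 1.0, a pair of
#' low-activity ellipses at 0.4, one high-activity ellipse at 2.0, small
#' internal spots at 1.6; zero outside the head).  The image is then scaled
#' so that the total noise-free projection \eqn{\sum_i (PX)_i} equals
#' \code{targetTotalCounts}.  ROI masks \code{"background"} (brain interior
#' minus all inner ellipses), \code{"low_roi"} and \code{"high_roi"} are
#' populated from ellipse membership of pixel centers.
#'
#' @param gridSide pixels per side (\eqn{\ge 8}).
#' @param targetTotalCounts desired total noise-free counts.
#' @param geometry the \code{\link{scanGeometry}} used for scaling.
#' @param projector the matching \code{\link{systemMatrix}}.
#' @return an \code{\link{activityImage}} with ROI masks.
#' @export
makePhantom <- function(gridSide, targetTotalCounts, geometry, projector) {
  n <- as.integer(gridSide)
  if (n < 8L) stop("gridSide must be >= 8")
  d <- dim(projector@entries)
  if (d[2] != n * n || d[1] != nSinogramBins(geometry))
    stop("projector dimensions inconsistent with gridSide/geometry")
  # pixel-center coordinates on the unit square, row-major, row 1 on top
  rc <- expand.grid(col = seq_len(n), row = seq_len(n))[, c(2, 1)]
  x <- (rc$col - (n + 1) / 2) / (n / 2)
  y <- ((n + 1) / 2 - rc$row) / (n / 2)
  ell <- .sheppLoganEllipses()
  inside <- vapply(seq_len(nrow(ell)),
                   function(k) .insideEllipse(x, y, ell[k, ]),
                   logical(n * n))
  act <- numeric(n * n)
  for (k in seq_len(nrow(ell))) act[inside[, k]] <- ell$activity[k]
  highRoi <- inside[, 5]
  # activity layering paints ellipse 5 last, so it wins shared pixels
  lowRoi <- (inside[, 3] | inside[, 4]) & !highRoi
  background <- inside[, 2] &
    !apply(inside[, 3:10, drop = FALSE], 1, any)
  proj <- .fwd(projector, act)
  tot <- sum(proj)
  if (tot <= 0) stop("phantom projects to zero counts; check the projector")
  act <- act * (targetTotalCounts / tot)
  activityImage(act, n, pixelSizeMm = geometry@binSizeMm,
                roiMasks = list(background = background, low_roi = lowRoi,
                                high_roi = highRoi))
}

#' Forward-project an activity image
#'
#' Returns \eqn{PX + S}; counts as one system-matrix product.
#'
#' @param P a \code{\link{systemMatrix}}.
#' @param X an \code{ActivityImage} or nonnegative numeric vector.
#' @param S additive scatter/randoms vector (defaults to zero).
#' @return numeric vector of length \eqn{M}.
#' @export
forwardProject <- function(P, X, S = numeric(nrow(P@entries))) {
  x <- if (is(X, "ActivityImage")) X@pixels else as.numeric(X)
  if (length(x) != ncol(P@entries)) stop("image length must equal ncol(P)")
  if (any(x < 0)) stop("activity must be nonnegative")
  if (length(S) != nrow(P@entries)) stop("S length must equal nrow(P)")
  .fwdCount(P, x) + as.numeric(S)
}

#' Simulate PET measurement noise
#'
#' Draws noisy randoms-precorrected counts per bin by the two-Poisson
#' pseudorandom model
#' \deqn{y_i = c_i \mathrm{Pois}(c_i^{-1}(y_i^* + a_i y_i^*)) -
#'       c_i \mathrm{Pois}(c_i^{-1} a_i y_i^*),}
#' whose mean is \eqn{y_i^*}; \eqn{a_i} is the randoms fraction and
#' \eqn{c_i} the detector efficiency.  The difference can be negative; by
#' default negatives are clamped to zero (which keeps the back-projected
#' data term nonnegative, as the positivity of the multiplicative update
#' requires).  The draw is reproducible for a fixed \code{seed} and leaves
#' the caller's RNG state untouched.
#'
#' @param yStar nonnegative noise-free projection.
#' @param randomsFraction per-bin \eqn{a_i \in [0,1)} (recycled).
#' @param efficiency per-bin \eqn{c_i > 0} (recycled).
#' @param seed integer RNG seed.
#' @param scatter nonnegative additive estimate stored with the sinogram.
#' @param clamp clamp negative counts at zero (default TRUE).
#' @return a \code{\link{sinogram}}.
#' @export
simulateNoise <- function(yStar, randomsFraction = 0.3, efficiency = 1,
                          seed, scatter = numeric(length(yStar)),
                          clamp = TRUE) {
  y <- as.numeric(yStar)
  if (any(y < 0)) stop("yStar must be nonnegative")
  m <- length(y)
  a <- rep_len(as.numeric(randomsFraction), m)
  cc <- rep_len(as.numeric(efficiency), m)
  if (any(a < 0) || any(a >= 1)) stop("randomsFraction must lie in [0, 1)")
  if (any(cc <= 0)) stop("efficiency must be positive")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  prompt <- cc * rpois(m, (y + a * y) / cc)
  delayed <- cc * rpois(m, (a * y) / cc)
  counts <- prompt - delayed
  if (clamp) counts <- pmax(counts, 0)
  sinogram(counts, noiseFree = y, scatter = scatter, randomsFraction = a,
           efficiency = cc, clamped = clamp)
}

#' Data plug-in variance weights
#'
#' The WLS weight of bin \eqn{i} is the plug-in inverse variance for
#' Poisson-like counts, \eqn{\Sigma_{ii} = 1/\max(Y_i, \delta)}, with a
#' floor \eqn{\delta} guarding zero-count bins.
#'
#' @param Y measured counts (a numeric vector or \code{Sinogram}).
#' @param floor positive variance floor \eqn{\delta} (default 1).
#' @return a \code{\link{WeightModel-class}} object.
#' @export
pluginWeights <- function(Y, floor = 1) {
  if (is(Y, "Sinogram")) Y <- Y@counts
  if (floor <= 0) stop("floor must be positive")
  new("WeightModel", weights = 1 / pmax(as.numeric(Y), floor),
      floor = as.numeric(floor))
}
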