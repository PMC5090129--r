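# One-call simulation of the reference study: phantom, projector, noisy
# sinogram, plug-in weights and the assembled reconstruction problem.

#' Simulate a complete phantom study
#'
#' Builds the parallel-beam projector, the emission Shepp-Logan phantom,
#' the noisy randoms-precorrected sinogram and the plug-in weights, and
#' assembles them into a \code{\link{reconProblem}} with the anisotropic TV
#' regularizer.  Defaults reproduce the reference conditions: a 128 x 128
#' grid of 4 mm pixels, 128 radial bins x 128 views over \eqn{\pi},
#' total noise-free counts \eqn{5 \times 10^5}, randoms fraction 30\%,
#' unit detector efficiency, zero scatter estimate.  Pass a smaller
#' \code{gridSide} (bins and views follow it) for scaled-down studies.
#'
#' @param gridSide image/detector side length (default 128).
#' @param totalCounts target total noise-free counts (default 5e5).
#' @param randomsFraction randoms fraction \eqn{a_i} (default 0.3).
#' @param efficiency detector efficiency \eqn{c_i} (default 1).
#' @param seed integer seed for the noise draw.
#' @param pixelSizeMm pixel/bin width in mm (default 4).
#' @param weightFloor variance floor for \code{\link{pluginWeights}}.
#' @param clamp clamp negative simulated counts (default TRUE).
#' @return list with components \code{geometry}, \code{projector},
#'   \code{phantom}, \code{sinogram}, \code{weights}, \code{reg},
#'   \code{problem}.
#' @export
simulateStudy <- function(gridSide = 128, totalCounts = 5e5,
                          randomsFraction = 0.3, efficiency = 1, seed = 1L,
                          pixelSizeMm = 4, weightFloor = 1, clamp = TRUE) {
  geometry <- scanGeometry(gridSide, gridSide, binSizeMm = pixelSizeMm)
  projector <- buildSystemMatrix(geometry, gridSide, pixelSizeMm)
  phantom <- makePhantom(gridSide, totalCounts, geometry, projector)
  yStar <- .fwd(projector, phantom@pixels)
  sino <- simulateNoise(yStar, randomsFraction = randomsFraction,
                        efficiency = efficiency, seed = seed, clamp = clamp)
  weights <- pluginWeights(sino@counts, floor = weightFloor)
  reg <- buildAnisotropicTV(gridSide)
  problem <- reconProblem(projector, sino@counts, sino@scatter, weights, reg)
  list(geometry = geometry, projector = projector, phantom = phantom,
       sinogram = sino, weights = weights, reg = reg, problem = problem)
}
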