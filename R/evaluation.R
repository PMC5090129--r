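# Image-quality metrics, stopping statistic, complexity accounting and the
# penalty-parameter sweep.

#' Mean absolute error
#'
#' \eqn{\mathrm{MAE} = \|X - X_\mathrm{true}\|_1 / N}.
#'
#' @param X,Xtrue image vectors (or \code{ActivityImage}s) of equal length.
#' @return nonnegative scalar.
#' @export
mae <- function(X, Xtrue) {
  x <- .xvec(X)
  xt <- .xvec(Xtrue)
  if (length(x) != length(xt)) stop("X and Xtrue must have equal length")
  mean(abs(x - xt))
}

#' Relative-change stopping statistic
#'
#' \eqn{\chi = \|X^{t+1} - X^t\|_2^2 / \|X^t\|_2^2} under the default
#' squared convention; \code{squared = FALSE} gives the unsquared norm
#' ratio.  The outer loop stops when \eqn{\chi < \epsilon}.  Invariant
#' under joint rescaling of both iterates.
#'
#' @param Xnext,Xcurr successive image iterates.
#' @param squared use the squared-norm-ratio convention (default TRUE).
#' @return nonnegative scalar.
#' @export
stoppingChi <- function(Xnext, Xcurr, squared = TRUE) {
  xn <- .xvec(Xnext)
  xc <- .xvec(Xcurr)
  den <- sum(xc^2)
  if (den == 0) stop("current iterate has zero norm")
  val <- sum((xn - xc)^2) / den
  if (squared) val else sqrt(val)
}

#' NEMA-style contrast and variability
#'
#' Contrast recovery relative to the truth,
#' \deqn{\mathrm{Contrast} = \frac{\mathrm{mean}_{\Omega_1}(X) /
#'   \mathrm{mean}_{\Omega_2}(X)}{\mathrm{mean}_{\Omega_1}(X_\mathrm{true})
#'   / \mathrm{mean}_{\Omega_2}(X_\mathrm{true})} \times 100\%,}
#' and the ROI coefficient of variation
#' \eqn{\mathrm{Variability} = \mathrm{std}_{\Omega_1}(X) /
#' \mathrm{mean}_{\Omega_1}(X) \times 100\%}.
#'
#' @param X reconstructed image (vector or \code{ActivityImage}).
#' @param Xtrue ground-truth image.
#' @param roi logical mask \eqn{\Omega_1} (region of interest).
#' @param background logical mask \eqn{\Omega_2}.
#' @return named numeric: \code{contrast} and \code{variability}, percent.
#' @export
contrastVariability <- function(X, Xtrue, roi, background) {
  x <- .xvec(X)
  xt <- .xvec(Xtrue)
  if (!any(roi) || !any(background)) stop("masks must be nonempty")
  mR <- mean(x[roi]); mB <- mean(x[background])
  tR <- mean(xt[roi]); tB <- mean(xt[background])
  if (mB == 0 || tB == 0 || tR == 0 || mR == 0)
    stop("zero ROI/background mean")
  c(contrast = (mR / mB) / (tR / tB) * 100,
    variability = sd(x[roi]) / mR * 100)
}

#' Total matvec complexity of a solver run
#'
#' Returns the number of system-matrix products consumed by the run, the
#' hardware-independent complexity proxy; equals 2 x (total inner
#' iterations) for the ADMM backends.
#'
#' @param state an \code{\link{ADMMState-class}} object.
#' @return integer count.
#' @export
complexityReport <- function(state) {
  tr <- state@traces
  if (!nrow(tr)) return(0L)
  as.integer(tr$matvec_count[nrow(tr)])
}

#' Full evaluation report for a reconstruction
#'
#' Bundles MAE, contrast for the low- and high-activity ROIs, variability
#' (coefficient of variation of the high-activity ROI), the final primal
#' objective, iteration counts and matvec total.
#'
#' @param state an \code{\link{ADMMState-class}} object.
#' @param phantom the ground-truth \code{\link{activityImage}} with
#'   \code{"background"}, \code{"low_roi"}, \code{"high_roi"} masks.
#' @return named list.
#' @export
evaluationReport <- function(state, phantom) {
  x <- state@X
  xt <- phantom@pixels
  bg <- roiMask(phantom, "background")
  lo <- contrastVariability(x, xt, roiMask(phantom, "low_roi"), bg)
  hi <- contrastVariability(x, xt, roiMask(phantom, "high_roi"), bg)
  tr <- state@traces
  list(mae = mae(x, xt),
       contrast_low = unname(lo["contrast"]),
       contrast_high = unname(hi["contrast"]),
       variability = unname(hi["variability"]),
       final_objective = if (nrow(tr)) tr$primal_objective[nrow(tr)]
                         else NA_real_,
       outer_iters = state@t,
       inner_iters = if (nrow(tr)) sum(tr$inner_iters_used) else 0L,
       matvec_total = complexityReport(state))
}

#' Penalty-parameter sweep
#'
#' Reruns the reconstruction over a \eqn{(\beta, \rho)} grid at a fixed
#' iteration budget and fixed data, and reports the MAE surface; the run is
#' deterministic so repeated sweeps agree exactly.
#'
#' @param problem a \code{\link{reconProblem}} (fixed noisy data).
#' @param phantom ground-truth \code{\link{activityImage}}.
#' @param betas,rhos numeric grids of penalty values.
#' @param config a \code{\link{solverConfig}} whose \code{beta}/\code{rho}
#'   are overridden per grid point.
#' @return data.frame with columns \code{beta}, \code{rho}, \code{mae},
#'   \code{final_objective}, \code{matvecs}; attribute \code{"argmin"}
#'   holds the row index of the smallest MAE.
#' @export
parameterSweep <- function(problem, phantom, betas, rhos, config) {
  grid <- expand.grid(beta = betas, rho = rhos)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    cfg <- config
    cfg@beta <- grid$beta[k]
    cfg@rho <- grid$rho[k]
    st <- runADMM(problem, cfg)
    data.frame(beta = cfg@beta, rho = cfg@rho,
               mae = mae(st@X, phantom@pixels),
               final_objective =
                 st@traces$primal_objective[nrow(st@traces)],
               matvecs = complexityReport(st))
  })
  res <- do.call(rbind, out)
  attr(res, "argmin") <- which.min(res$mae)
  res
}
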