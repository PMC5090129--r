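---
title: "Methods: TV-regularized weighted least squares PET reconstruction with multiplicative EM updates"
author: "petadmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TV-regularized WLS PET reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petadmm)
```

## The reconstruction problem

Positron emission tomography measures projections of an unknown activity
distribution. With $X \in \mathbb{R}^N_{\ge 0}$ the pixelized activity,
$P \in \mathbb{R}^{M \times N}_{\ge 0}$ the system matrix, $S \ge 0$ an
additive scatter/randoms estimate and $Y$ the measured counts, the forward
model is $Y = PX + S$. petadmm reconstructs $X$ by minimizing the
anisotropic-TV ($L_1$) penalized weighted least squares objective

$$\min_{X \ge 0} \; F(X) + \beta\|RX\|_1, \qquad
  F(X) = \|PX + S - Y\|_\Sigma^2 = \sum_i \Sigma_{ii}\,(PX + S - Y)_i^2,$$

where $\Sigma_{ii} = 1/\sigma_i$ is the inverse variance of bin $i$
(`pluginWeights()` uses the data plug-in $\Sigma_{ii} = 1/\max(Y_i,
\delta)$, $\delta = 1$, the Poisson-motivated estimate with a floor for
zero-count bins), $R$ is the anisotropic total-variation difference
operator and $\beta > 0$ trades data fidelity against edge-preserving
smoothness.

## ADMM splitting

Introducing $V = RX$ and a scaled dual $\mu$, the scaled augmented
Lagrangian is

$$L(X, V, \mu) = F(X) + \beta\|V\|_1 +
  \tfrac{\rho}{2}\|RX - V + \mu\|_2^2 - \tfrac{\rho}{2}\|\mu\|_2^2 .$$

`runADMM()` alternates three exact steps:

1. **V-update** — separable soft-thresholding,
   $V_i = (|z_i| - \beta/\rho)_+\,\mathrm{sgn}(z_i)$ with $z = RX + \mu$
   (`vUpdate()`); at the kink the output is exactly 0, which is consistent
   with either subgradient choice.
2. **X-update** — (approximate) minimization of the subproblem cost
   $\Phi(X) = F(X) + \tfrac{\rho}{2}\|RX + C\|_2^2$, $C = -V + \mu$,
   over $X \ge 0$, by one of four backends (below).
3. **Dual ascent** — $\mu \leftarrow \mu + RX - V$ (`dualUpdate()`).

The *greedy* driver runs many inner X-update iterations per outer
iteration; the *simplified* driver (`nInner = 1`) merely decreases $\Phi$
once per outer iteration, which in practice reaches the same primal
objective at a small fraction of the cost.

## The multiplicative EM X-update

The package's core is a multiplicative, step-size-free update for the
nonnegativity-constrained quadratic subproblem. It is a
majorize–minimize scheme built from two separable surrogates that touch
the objective at the current iterate $X^t$ and lie above it elsewhere:

* For $F$, Jensen's inequality with the convex-combination coefficients
  $\lambda_{i*} = S_i/(PX^t + S)_i$, $\lambda_{ij} = P_{ij}X^t_j/(PX^t +
  S)_i$ gives the separable majorizer `surrogateF()`.
* $G(X) = \|RX + C\|_2^2$ contains signed coefficients, so Jensen cannot
  be applied directly. Writing $R = \bar R - \hat R$ and $C = \bar C -
  \hat C$ with nonnegative parts of disjoint support (`splitSigned()`),
  an intermediate half/half surrogate separates the positive and negative
  parts, and a second Jensen step on each half yields the separable
  majorizer `surrogateG()`.

Setting the separable surrogate's gradient to zero gives the closed-form
multiplicative rule (`emXUpdate()`)

$$X^{t+1}_j = X^t_j\,
  \frac{\big(A_1 + \tfrac{\rho}{2}A_2\big)_j}{\big(A_3 + \rho A_4\big)_j},
  \qquad
  \begin{aligned}
  A_1 &= P^T\Sigma Y, &
  A_2 &= (\bar R + \hat R)^T\big[(\bar R + \hat R)X^t + \bar C + \hat C\big],\\
  A_3 &= P^T\Sigma(PX^t + S), &
  A_4 &= (\bar R^T\bar R + \hat R^T\hat R)X^t + \bar R^T\bar C + \hat R^T\hat C.
  \end{aligned}$$

All four terms are nonnegative for nonnegative data, so the update
preserves positivity without a step size, and the MM construction makes
$\Phi$ nonincreasing at every sweep. Because $\Phi$ is strictly convex in
practice, the fixed point satisfies the KKT conditions of
$\min_{X\ge0}\Phi$; the test suite verifies this against an exact
active-set quadratic-programming solve.

Numerical edge cases, resolved once and tested:

* **Zero bins/rows.** Bins with $(PX^t + S)_i = 0$ (or split rows with
  zero denominator) have 0/0 coefficients; their contribution is the
  constant limit of the construction and is added as such.
* **Constant surrogate terms.** The $\lambda_*$ terms of the splitting
  surrogate are constant in $X$ and irrelevant to the minimizer, but they
  are retained in `surrogateG()` so the tangency $g(X^t|X^t) = G(X^t)$
  holds exactly — this is what the majorization tests assert.
* **Absorbing zeros.** A pixel at exactly 0 stays at 0 under a
  multiplicative rule, so initialization must be strictly positive;
  `runADMM()` starts from a uniform image flux-matched so that $\sum PX^0
  = \sum Y$, with $V^0 = RX^0$ and $\mu^0 = 0$.
* **Degenerate denominators.** $(A_3 + \rho A_4)_j = 0$ with a positive
  numerator can only occur for pixels outside the scan support (all-zero
  column of $P$ and of both splits); `emXUpdate()` raises an error rather
  than guessing, and such pixels should be masked at setup.
* **Negative counts.** The randoms-precorrected noise model can produce
  negative $Y_i$; they are clamped to 0 by default (`clampNegativeCounts`)
  because the positivity argument needs $A_1 \ge 0$. The WLS data term
  itself tolerates any sign.

## Comparison backends

* `plXUpdate()` — projected Landweber, $X \leftarrow \max(X -
  \alpha\nabla\Phi, 0)$ with the fixed step $\alpha = 1/(\|P\|_1\|P\|_\infty
  + \beta\|R\|_1\|R\|_\infty)$ by default (`landweberAlpha()`); since the
  subproblem Hessian weights $R^TR$ by $\rho$, a $\rho$-based variant is
  available behind `landweberUseRho`.
* `cgXUpdate()` — conjugate gradient on the quadratic $\Phi$ with a single
  truncation after the inner loop (per-step projection behind
  `cgProjectEachStep`); truncation mid-run breaks the monotonicity that the
  EM update guarantees, which is exactly the behavior the comparisons are
  meant to expose.
* `directXSolve()` — dense solve of the $\Sigma$-weighted normal equations
  $(2P^T\Sigma P + \rho R^TR)X = 2P^T\Sigma(Y-S) + \rho R^T(V-\mu)$ with
  truncation; an oracle for small instances. (The $\Sigma$-weighted form is
  the one consistent with $\nabla\Phi = 0$; the unweighted variant
  coincides with it when $\Sigma = I$.)
* `runIsra()` — the unregularized $\Sigma$-weighted multiplicative
  baseline, $X_j \leftarrow X_j (P^T\Sigma Y)_j/(P^T\Sigma(PX+S))_j$,
  i.e. the $\rho = 0$ specialization of the EM rule (bit-for-bit, which
  the tests check).

## Complexity accounting

Solver cost is reported as the number of system-matrix–vector products,
the hardware-independent proxy: products with the TV operator (two entries
per row) are negligible next to $P$. Every inner iteration of every
backend consumes exactly two counted products (one $P$, one $P^T$), so a
run costs $2 \times n_\mathrm{outer} \times n_\mathrm{inner}$. Run-level
constants — $A_1$, the CG right-hand side, the flux-matching projection —
and diagnostic cost traces are computed once outside this accounting; the
CG backend keeps $HX$ warm across outer iterations so its steps also cost
one $H$-product each, with an extra counted product only when end-of-loop
truncation actually clips.

## The simulator

`simulateStudy()` reproduces the reference conditions end to end:

* **Phantom.** The classical ten-ellipse Shepp-Logan geometry with the CT
  attenuation levels remapped to a nonnegative emission scale (rim 0.5,
  brain background 1.0, two low-activity ellipses 0.4, one high-activity
  ellipse 2.0, small spots 1.6; zero outside), scaled so the total
  noise-free projection matches the target counts — by default $5 \times
  10^5$ on a $128 \times 128$ grid of 4 mm pixels. The exact intensity map
  is a documented package choice; published phantom modifications print no
  values, so absolute error magnitudes are not comparable across
  implementations. ROI masks (background / low / high) come from ellipse
  membership of pixel centers; the high-activity ellipse wins the handful
  of pixels it shares with a low-activity ellipse, mirroring the painting
  order.
* **Projector.** An intersection-length parallel-beam model: $P_{ij}$ is
  the length of ray $i$ inside pixel $j$, computed by ray tracing; 128
  radial bins (4 mm) × 128 views evenly spaced over $\pi$ by default.
  Length weights are the standard reading of an aperture-style projector;
  the tests pin the implementation against an exhaustive ray–pixel
  clipping oracle, and the choice affects absolute MAE values but none of
  the algorithmic properties.
* **Noise.** The two-Poisson randoms-precorrected model $y_i =
  c_i\,\mathrm{Pois}(c_i^{-1}(1 + a_i)y_i^*) -
  c_i\,\mathrm{Pois}(c_i^{-1}a_i y_i^*)$ with randoms fraction $a_i = 0.3$
  and efficiency $c_i = 1$ by default; mean $y_i^*$, variance
  $(1 + 2a_i)y_i^*$ at $c_i = 1$. $S$ is zero during simulation, though
  the solvers accept nonzero $S$.

What the simulator does **not** emulate: attenuation, detector blur and
arc effects, 3-D/list-mode acquisition, realistic scatter. Passing tests
therefore demonstrate the solver's mathematical properties on an idealized
2-D forward model, not clinical image quality.

## Stopping and evaluation

The outer loop stops after `nOuter` iterations or when $\chi =
\|X^{t+1} - X^t\|_2^2 / \|X^t\|_2^2 < \epsilon$ (`stoppingChi()`); the
squared-norm convention is the default, the unsquared ratio is a flag.
`mae()`, `contrastVariability()` (NEMA-style contrast recovery and ROI
coefficient of variation, in percent) and `complexityReport()` implement
the evaluation metrics; `evaluationReport()` reports contrast for both
ROIs and, since the reference tables print a single variability column
without naming its region, variability for the high-activity ROI.
`parameterSweep()` reruns the reconstruction over a $(\beta, \rho)$ grid
at fixed budget and data, and is deterministic for fixed inputs.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the full pipeline at a
scaled-down study size chosen to keep the checks fast while preserving
every property being tested: a $32 \times 32$ phantom with $\sim 5 \times
10^3$ counts for the end-to-end comparisons (greedy 400×120 vs simplified
400×1; penalty sweep over $\beta \in \{10^{-3}, 10^{-2}, 10^{-1}\}$,
$\rho \in \{10^{-5}, 10^{-4}, 10^{-3}\}$ against ISRA at the same matvec
budget), and random instances with $N \le 64$ pixels for the
descent/positivity/KKT sweeps. At this scale and count level the
reconstructions are far from the visual quality of full-size runs —
per-bin counts average about five — so the end-to-end checks compare
methods against each other rather than against absolute reference error
values.

## Known limitations

* The simplified driver has no convergence proof; it is validated
  empirically (its final objective tracks the greedy driver's to well
  under 1%).
* The projected Landweber default step uses the $\beta$-weighted
  norm-product formula; for unusually large $\beta/\rho$ ratios the
  $\rho$-based variant is safer.
* The sweep reports a raw MAE surface; it deliberately asserts nothing
  about unimodality in $(\beta, \rho)$.
* Wall-clock timings are excluded everywhere; matvec counts are the only
  cost measure.
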