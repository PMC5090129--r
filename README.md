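# petadmm

Iterative 2-D PET reconstruction by **L1/TV-regularized weighted least
squares** solved with **ADMM**, where the image subproblem is handled by a
**multiplicative EM-style update** that is monotone, positivity-preserving
and step-size-free. The package is aimed at people studying iterative
emission-tomography algorithms: it ships a complete simulator (emission
Shepp-Logan phantom, intersection-length parallel-beam projector,
randoms-precorrected two-Poisson noise, plug-in weights), four X-update
backends for comparison, an ISRA baseline, and NEMA-style evaluation
metrics, so every algorithmic claim can be exercised without external
data.

## The model

With activity $X \ge 0$, system matrix $P$, scatter/randoms estimate $S$
and measured counts $Y$, the reconstruction solves

$$\min_{X \ge 0}\; \|PX + S - Y\|_\Sigma^2 + \beta\,\|RX\|_1,$$

where $\Sigma_{ii} = 1/\max(Y_i, \delta)$ are plug-in inverse-variance
weights and $R$ is the anisotropic total-variation difference operator.
ADMM splits off $V = RX$ and alternates soft-thresholding in $V$, an
X-update on $\Phi(X) = F(X) + \tfrac{\rho}{2}\|RX + C\|_2^2$
($C = -V + \mu$), and dual ascent in $\mu$. The package's core X-update is
the multiplicative rule

$$X_j \leftarrow X_j\,
  \frac{(A_1 + \tfrac{\rho}{2}A_2)_j}{(A_3 + \rho A_4)_j},\qquad
  A_1 = P^T\Sigma Y,\quad A_3 = P^T\Sigma(PX + S),$$

with $A_2, A_4$ built from the nonnegative splitting $R = \bar R - \hat
R$; it decreases $\Phi$ at every sweep, keeps iterates strictly positive,
needs no step size, and costs exactly two system-matrix products per
iteration. Projected Landweber, conjugate gradient and a direct solve are
provided as comparison backends, plus weighted ISRA as the unregularized
baseline. See `vignettes/petadmm-methods.Rmd` for the full derivation and
the numerical choices.

## Worked example

A scaled-down study — 32 × 32 phantom, ~5 × 10³ counts, 30 % randoms —
reconstructed by ADMM-EM and compared with ISRA at the same matvec budget:

```r
library(petadmm)

study <- simulateStudy(gridSide = 32, totalCounts = 5e3, seed = 1)
cfg   <- solverConfig(beta = 1e-2, rho = 1e-4, nOuter = 400, nInner = 10)
state <- runADMM(study$problem, cfg)
state
#> ADMMState: 400 outer iterations, 1024 pixels
#>   final primal objective 816.4987  chi 7.042114e-12  matvecs 8000

report <- evaluationReport(state, study$phantom)
cat(sprintf("MAE %.5f | contrast low %.1f%% high %.1f%% | matvecs %d\n",
            report$mae, report$contrast_low, report$contrast_high,
            report$matvec_total))
#> MAE 0.04317 | contrast low 165.6% high 125.5% | matvecs 8000

isra <- runIsra(study$problem, 4000)          # same 8000-matvec budget
mae(isra, pixels(study$phantom))
#> [1] 0.0432
```

The MAE is the mean absolute pixel error against the known phantom; the
contrast percentages are NEMA-style contrast recovery of the low/high
activity ROIs relative to the truth (100 % = perfect); `matvecs` counts
system-matrix products, the hardware-independent cost measure — two per
inner iteration. At this (deliberately tiny, very noisy) scale the TV
reconstruction edges out ISRA; the margin widens with size and counts as
the regularization gets more signal to work with.

A thin CLI over the same functions lives at `inst/cli/petadmm`
(`simulate`, `reconstruct`, `evaluate`, `sweep`).

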