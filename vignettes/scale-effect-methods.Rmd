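---
title: "Methods: simulating the scale-effect link between trait mean and environmental variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating the scale-effect link between trait mean and environmental variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalefx)
```

## The question and the model

Many traits show a *scale effect*: the higher the mean, the higher the
standard deviation, the constant-CV case being the extreme. When the residual
variance of a trait is itself partially under genetic control (the
heteroscedastic "double hierarchical" view, where individual $i$ carries an
additive genetic value $v_i$ on the log residual variance), a scale effect
mechanically couples the breeding values for the trait and for its
variability. `scalefx` quantifies that coupling.

One replicate proceeds in three steps.

1. **Homoscedastic base draw.** With mean $\mu$, coefficient of variation
   $CV$ and heritability $h^2$ fixed, the reference variances are
   $\sigma_p^2 = (CV\mu)^2$, $\sigma_u^2 = h^2\sigma_p^2$,
   $\sigma_e^2 = (1-h^2)\sigma_p^2$, and records are
   $y_i = \mu + a_i + e_i$ with independent Gaussian $a_i$, $e_i$.
2. **Per-individual scaling.** The phenotypic standard deviation becomes
   proportional to the record, $\sigma_{pi} = CV\,|y_i|$, and is split with
   the same heritability: $\sigma_{ei} = \sigma_{pi}\sqrt{1-h^2}$,
   $\sigma_{ui} = \sigma_{pi}\sqrt{h^2}$. Scaling the additive part as well
   keeps every individual's residual variance below its phenotypic variance.
3. **Breeding values.** On the exponential model's log-variance scale,
   $v_i = 2r\ln(\sigma_{ei}/\sigma_e)$, and the trait breeding value is
   rescaled to the local variance, $u_i = a_i\,\sigma_{ui}/\sigma_u$. The
   strength $r \in (0, 1]$ attenuates an incomplete determination of the
   variability by the trait level; $r = 1$ is a fully constant CV.

A scenario reports the Pearson correlation $\rho$ of $(u, v)$ and
$GCV = \sqrt{\widehat{\mathrm{Var}}(v)}$, averaged over replicates. Note that
the sample mean of $v$ is *not* zero: the exponential link ties the mean of
$v$ to the geometric rather than arithmetic mean of the residual variances.

Two useful exact consequences, both used as test invariants: $\rho$ is
invariant to $r$ (a positive scaling of $v$) and to $\mu$ (which scales $u$
and leaves $\sigma_{ei}/\sigma_e = |y_i|/\mu$ unchanged); and $v$ depends on
the deviates only through the standardised record, so the GCV is invariant to
$h^2$ *in distribution* — on shared deviate streams two $h^2$ values reweight
the same deviates, so sampled GCVs agree only to Monte-Carlo precision, not
bitwise.

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `mu` | trait mean (trait units) | 100 | reference level of the study design; results are invariant to it |
| `cv` | coefficient of variation | — | scenario axis, 0.05–0.50 in the default grids |
| `h2` | heritability | — | scenario axis, 0.05–0.50 |
| `r` | scale-effect strength | 1 | constant-CV case; grid axis 0.05–1.00 in the strength study |
| `n_individuals` | individuals per replicate | 100,000 | study condition; Monte-Carlo SE of $\rho$ ≈ 0.001 |
| `n_replicates` | replicates per scenario | 10 | study condition; SEs reported as SD/$\sqrt{10}$ |
| `seed` | master RNG seed | 1 | all randomness flows from it |

These defaults are the study conditions; the full 100-cell correlation grid
runs in roughly half a minute on one core and the 200-cell strength grid in
about a minute.

## Negative records

At high CV a small fraction of base records is negative (about 2.3% at
CV = 0.5, the $\Phi(-2)$ tail), which would make $\sigma_{ei}$ negative. The
default convention takes the absolute value at the level of $\sigma_{pi}$,
which keeps all three scaled deviations positive and the elementwise ratios
exact. The alternative — flipping only $\sigma_{ei}$ and letting
$\sigma_{pi}, \sigma_{ui}$ keep the record's sign — is available as
`negative_handling = "residual"` for sensitivity analysis. The two
conventions differ only where records go negative (CV > 0.25), which is also
where printed reference values are least reliable; grid cells there should be
read with that caveat. A record of exactly zero (probability zero under a
continuous draw) is a hard error rather than a silent perturbation, since its
log-scale value is undefined.

## Random-number design

A single master seed initialises a L'Ecuyer-CMRG stream; scenarios advance
whole streams (`parallel::nextRNGStream`) indexed by their grid position, and
replicates advance sub-streams within a scenario. The same
(seed, scenario, replicate) triple always reproduces the same draw, in any
execution order, and a grid's JSON manifest is therefore sufficient to
regenerate its CSV output byte for byte. Global RNG state is saved and
restored around every draw, so package calls never disturb a user's
`set.seed()` context.

## The quadrature oracles

Standardising the construction, with independent standard normals
$(z_a, z_e)$ and $s = \sqrt{h^2} z_a + \sqrt{1-h^2} z_e$:

$$w = 1 + CV\,s, \qquad u \propto z_a\,|w|, \qquad v = 2r\ln|w|.$$

$\rho(CV, h^2)$ and $GCV(CV, r)$ are exact two-dimensional Gaussian
expectations, which `quadrature_correlation()` and `quadrature_gcv()`
evaluate without simulation. The direction orthogonal to $s$ integrates in
closed form (polynomial and folded-normal moments, e.g.
$E[s\,|w|] = CV\,(1 - 2\Phi(-1/CV))$), leaving one-dimensional Gauss–Hermite
quadratures in $s$ for the moments involving $\ln|w|$.

Those integrands are singular at $w = 0$, i.e. $s_0 = -1/CV$, where a plain
Gauss–Hermite rule converges slowly and oscillates (tensor-product errors up
to $5\times10^{-2}$ at $CV = 0.5$ with 128 nodes per axis). The package
removes the singularity by *second-order subtraction*: the Gaussian factor is
expanded to second order around $s_0$ and the subtracted term's integrals are
closed forms in digamma/trigamma values (moments of $\ln|Z|$ such as
$E[\ln|Z|] = -(\gamma + \ln 2)/2$ and
$E[Z^2\ln^2|Z|] = ((\psi(3/2)+\ln 2)^2 + \psi'(3/2))/4$). The regularised
remainder vanishes like $t^3\ln|t|$ at the singular point, restoring fast
convergence.

Accuracy at the default 128 nodes, measured against adaptive
split-at-the-singularity references: machine precision for $CV \le 0.15$,
and absolute error below $4\times10^{-5}$ everywhere up to $CV = 0.5$ —
two orders of magnitude below the Monte-Carlo standard errors it is used to
check. Each oracle call optionally re-evaluates at doubled node count and
warns when the value moves by more than $10^{-6}$ (which it does approaching
$CV = 0.5$, by design of the check). The oracle mirrors the default
absolute-value convention; it is *not* a reference for the `"residual"`
convention.

## Numerical and design choices

* **Variance denominators.** Sample statistics use the conventional $n-1$
  denominator (both inside the correlation and for the GCV); at
  $n = 100{,}000$ the distinction is far below reporting precision.
* **Standard errors.** SD of the replicate point estimates divided by
  $\sqrt{\text{replicates}}$. A single-replicate scenario reports SE = 0 with
  a warning rather than NA, so degenerate runs stay usable.
* **Table serialisation.** Wide CSVs rounded to 4 decimals (the precision of
  the reference tables), with companions for SEs and raw unrounded cells, and
  a JSON manifest. Determinism is tested byte for byte.
* **GCV > 0.69 cells** of the strength grid are flagged, not suppressed:
  values that large are outside anything reported for real populations and
  mark a biologically implausible corner (high strength at high CV), but the
  numbers remain available.
* **Quantile bins.** Sorting is stable (ties keep input order and are split
  by position); when the record count is not divisible by the bin count the
  remainder goes to the lowest-index bins. Both choices are arbitrary and
  documented; bin counts below 2, fewer than 2 records per bin, non-finite
  records and a bin mean of exactly 0 (undefined CV) are errors.
* **Oracle-agreement testing.** Grid cells are compared to the oracle at
  4 SE. With SEs estimated from 10 replicates this comparison has Student-$t_9$
  tails, so about 0.3 cells per 100-cell grid are expected outside the band
  even when simulator and oracle agree perfectly; isolated marginal
  exceedances at a fixed seed are sampling noise, as cross-seed and
  large-$n$ checks in the test suite's development confirmed.

## What the generator emulates — and what it does not

The simulation draws *unrelated* individuals with known true breeding values:
there is no pedigree (no relationship-matrix covariance), no REML or Bayesian
estimation step, no selection, and no skewness-driven correlation mechanism.
Passing tests therefore show that the scale effect alone generates the
reported correlation and variability evolvability under ideal conditions;
they say nothing about estimation error in real heteroscedastic analyses, nor
about populations where selection or residual skewness add further coupling.
The strength $r$ is held constant across the trait range, although in real
data it may vary across levels or even change sign. The quantile-bin
diagnostic is descriptive only: equal-count bins of a single cross-section
have truncation-inflated outer groups, so it separates a constant-CV trait
from a homoscedastic one clearly only when the spread of trait levels
dominates the within-level noise.

## Problem sizes used in the checks

Unit and property tests run on reduced populations (500–50,000 individuals,
2–4 replicates) chosen so the whole suite completes in a few minutes; the
reproduction checks and the acceptance script run the full study conditions
(10 replicates of 100,000 individuals per scenario, including the complete
default correlation grid). The sampling-consistency property (variance of the
replicate estimate halving when $n$ doubles) uses 300 single-replicate trials
at $n = 2{,}000$ vs $4{,}000$, sized so the expected variance ratio of 2 is
resolved within the asserted [1.5, 3] band with high probability.
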