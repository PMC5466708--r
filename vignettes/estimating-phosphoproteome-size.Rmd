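---
title: "Estimating the total size of a phosphoproteome from overlapping detection experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the total size of a phosphoproteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoCensus)
```

## The problem

Mass-spectrometry phosphoproteomics experiments each detect an incomplete
subset of a proteome's phosphorylation sites (p-sites) and phosphoproteins.
Across dozens of published experiments the subsets overlap heavily, and the
overlap structure carries information about how much remains undetected.
`phosphoCensus` estimates the total population size — all discoverable
p-sites or phosphoproteins — from a binary detection matrix: one row per
unit, one column per experiment, 1 where the unit was identified.

Two modelling assumptions frame everything below: the population is
*closed* (a finite, stable set of true units over the time span of the
experiments), and detection is heterogeneous both across experiments
(temporal/contextual effects: different protocols, depths, tissues) and
across units (some proteins are phosphorylated constitutively, others
transiently, so each unit has its own catchability).

## The detection matrix

`DetectionMatrix` extends `SummarizedExperiment` with a single binary
`detections` assay.  Validity enforces 0/1 cells, unique unit and
experiment ids, and no all-zero rows — a unit enters the matrix only by
being detected.  Column order is meaningful: it is read as the
chronological publication order of the experiments and is the default
ordering of every order-sensitive analysis.  CSV round trips
(`readDetectionMatrix()` / `writeDetectionMatrix()`) preserve it exactly;
empty cells are read as 0, and any other value is a parse error naming the
offending row and column.

Site ids follow `"<protein>_<residue><1-based position>"` with residue in
S/T/Y (e.g. `P38712_S14`).  `collapseToProteins()` credits a protein to an
experiment as soon as *one* of its sites is detected there.  The
published compendia do not state how a phosphoprotein should be credited
when only some of its sites pass upstream filters; this union rule is our
choice, and it commutes with merging experiments, which keeps
protein-level results independent of the processing order.

Two quality-control and filtering operations mirror standard practice:
`jaccardQC()` computes pairwise intersection-over-union similarities
between experiments (highly similar experiment pairs would artificially
inflate apparent saturation; the summary reports the mean and maximum
off-diagonal similarity so such pairs can be excluded before estimation),
and `filterMinExperiments(m, 3)` implements the "3X" high-confidence
restriction to units seen in at least three experiments.

## Saturation curves and the exponential recovery model

`buildCurve()` accumulates experiments in a given order and records, per
experiment, the cumulative redundant detection count `x` and the
cumulative non-redundant (distinct) unit count `y`.  If a first experiment
finds 1000 units and a second finds 900 of which 100 were already known,
the curve passes through (1000, 1000) and (1900, 1800).  The final point
is order-invariant; only the path changes.

`fitRecovery()` fits

$$y = a\,(1 - e^{-x/b}) \qquad\text{or}\qquad y = a\,(1 - e^{-x/b}) + c\,x$$

by bounded nonlinear least squares.  Parameters and units:

* `a` (counts) — the asymptote: the estimated total number of
  true-positive non-redundant units.
* `b` (counts of redundant detections) — steepness: the pure-recovery
  component reaches exactly $1 - 1/e = 63.2\,\%$ of `a` at `x = b`.
* `c` (dimensionless, default fixed at 0.01) — average per-detection
  false-positive rate.  False positives drawn from a large pool barely
  overlap between experiments, so they never saturate: they add a linear
  ramp on top of the plateauing true-discovery curve.

Numerical choices.  The optimizer is Levenberg–Marquardt with box bounds
(`minpack.lm::nlsLM`, tolerance 1e-12, 1000 iterations), with an
L-BFGS-B fall-back on the raw SSE surface; failures to meet tolerance are
reported via `converged = FALSE` with parameters still returned.
Initialization: `a0 = 1.2 max(y)`, `b0 = max(x)/3`, `c0 = 0.01` — the
asymptote just above the data, the knee inside the observed range.
Bounds: `b` in `(0, 100 max(x)]`, `c` in `[0, 1]`, and `a ≥ max(y)` for
the pure model, since a total below the observed non-redundant count is
impossible.  For noise fits that lower bound is relaxed (to
`max(max(y) − max(x), 10^{-3} max(y))`): part of the observed final count
is then linear contamination, and the true-positive asymptote may
legitimately sit below it — on data generated with `c = 0.01` the
true `a` is below the final `y` by construction.  The origin (0, 0) is
included as a fit anchor by default (`anchorOrigin`): the model passes
through it exactly, and anchoring stabilizes fits when experiments are
few.  Whether to estimate `c` freely or fix it at a stated contamination
level is genuinely open; fixing (`fixedC`) is the default used by the
reporting functions because the headline "assuming k % noise" analyses
condition on a known rate, and because `c` is weakly identified against
`a, b` when `b` is large (the exponential is then locally linear).  Free
estimation remains available (`noiseTerm = TRUE, fixedC = NULL`).

Order-robustness perturbations (`perturbOrder()`): `best_start` /
`best_end` move the single largest experiment (most detections; ties to
the earliest column) to the front/back of the chronological order;
`half_experiments` keeps the first ⌈t/2⌉ experiments — the extra one is
kept when t is odd, an arbitrary choice fixed here for determinism.

## Closed-population capture–recapture

`captureHistories()` converts the matrix into frequencies of the
$2^t - 1$ observable capture histories.  Because the history space grows
as $2^t$, at most `cap` experiments are used (default 15, hard ceiling
20); when more are available the largest by detection count are kept,
ties resolved toward the earliest column.

`fitLoglinear()` fits a log-link Poisson count model to the history
frequencies by IRLS (`stats::glm`).  The linear predictor at the all-zero
history reduces to the intercept, so `N̂ = n + exp(β₀)` and the delta
method on the fitted covariance gives its SE.  Design columns per model:

| model | columns besides the intercept |
|---|---|
| `M0` | total captures `s` |
| `Mt` | one indicator per occasion |
| `MhChao` | `s` + η_j = 1{s ≥ j}, j = 3..t |
| `MthChao` | occasion indicators + the η columns |

The η terms implement Chao's lower-bound parameterization of individual
heterogeneity: the line through the `s = 1, 2` levels is extrapolated to
`s = 0`, and the η_j (constrained ≥ 0) absorb the heavier-captured
levels.  Starting the η indicators at j = 3 is what makes the model
identifiable — with j = 2 there would be one more parameter than
observable capture-count levels.  Without temporal effects this
reproduces the closed form $\hat N = n + \frac{t-1}{t}\,\frac{f_1^2}{2
f_2}$ exactly (asserted in the tests).  A fitted η that comes out
negative violates the constraint; it is dropped and the model refit, and
the dropped terms are recorded in the estimate.  `selectModel()` fits all
four models and returns the minimum-AIC one (`AIC = -2\ell + 2k` on the
count likelihood), ties broken toward fewer parameters.

`petersenTwoList()` is the two-sample closed form `N̂ = n₁n₂/m`, with the
Chapman correction reported alongside; with two occasions the Mt
log-linear model reduces to it exactly, which the tests verify on random
instances.  It serves the merged-compendium analysis: all HTP experiments
merged into one non-redundant list against a low-throughput (LTP)
gold-standard compendium.  The *detection potential* — the share of the
combined HTP+LTP estimate that HTP-only estimation reaches — is reported
as a half-up-rounded integer percent and is invariant under any common
scaling of the two estimates.

`jackknifeAbundance()` repeats the Chao Mth fit on random subsets
(default 15) of the experiments with at least a minimum number of
detections (default 500), reporting the mean, SD and CV across replicates
(default 100).  Each replicate draws its RNG stream from a seed derived
deterministically from the master seed and the replicate index, so any
single replicate can be reproduced in isolation.

## The noise model

`injectNoise()` adds `round(rate · d)` false detections to each
experiment with `d` detections (base R `round`, i.e. half-to-even —
deterministic and unbiased across experiments), drawn uniformly without
replacement from a shared pool of fake ids sized `poolMultiplier ×` the
real unit count (default 10×; "large" is otherwise unquantified, and the
hypergeometric expected overlap between two experiments' fakes is
negligible at this size, which the tests check by simulation).  Fake ids
carry the reserved `NOISE_` prefix; real detections are never modified,
so stripping the prefix restores the input bit-exactly.

`adjustForNoise()` turns injection into a correction: the estimator is
re-run on `nInjections` independently contaminated copies, and the mean
inflation `δ = mean(N̂_injected) − N̂` is subtracted from the original
estimate.  The correction assumes linearity — injecting k % extra noise
inflates the estimate by the same amount as the k % already present.
That assumption, and its limits, matter: the adjustment removes
*noise-induced inflation*, not estimator bias.  In simulations the
adjusted estimate tracks the estimator's clean-data value closely, but
under strong catchability heterogeneity the Chao Mth estimator is itself
a lower bound whose negative bias can exceed the inflation caused by 1 %
contamination; in that regime the adjusted estimate, while a better
estimate of the clean-data fit, is *not* closer to the true N than the
uncorrected one.  The direction guarantee should therefore only be
expected where the estimator is approximately calibrated (mild
heterogeneity, high saturation), and the tests assert it in exactly that
regime while the unit suite asserts the unconditional
adjusted-recovers-clean property.

## The synthetic generator

`simulateDetectionMatrix()` generates matrices with the statistical
structure the estimators assume: a closed population of `nUnits` true
units with Beta-distributed catchability (default Beta(1.2, 3): mean
0.29, right-skewed — a minority of readily detected units and a long
transient tail), log-normal per-experiment multipliers (default sdlog
0.4) for temporal effects, independent Bernoulli detections given the
clamped product probability (clamp events are counted and reported), and
optional false positives routed through `injectNoise()`.  Units never
detected stay in the ground truth but not in the matrix.
`simulateHtpLtp()` produces the paired merged-compendium setting, with a
correlation knob under which the LTP list degenerates to a subset of the
HTP list (where Petersen collapses to `n₁`, its classic failure mode).
`downsampleMatrix()` keeps an exact uniform fraction of each experiment's
detections, supporting the evaluation protocol below.

What the generator does *not* emulate: correlated false positives (shared
search-engine artifacts), open-population dynamics, peptide-level
phenomena (digestion, localization ambiguity), or dependence between
occasions beyond the shared unit catchability.  Passing tests therefore
validate the estimators under their own assumptions; on real compendia,
violations (especially correlated detection and correlated noise) remain
possible and are exactly what the order perturbations, the 3X filter and
the Jaccard QC are meant to surface.

## Validation harness and problem sizes

The test suite validates each stage against an independent oracle:
closed-form identities (Petersen, the Chao Mh bound, the 63.2 % point),
dense grid search for the least-squares fits, direct likelihood
maximization (BFGS on the Poisson likelihood, bypassing IRLS) for the
log-linear models, and ground-truth recovery on simulated populations.
The simulation scales were chosen to exercise realistic compendium sizes
while keeping the suite quick: populations of 3000 units over 20
experiments (≈ 92 % saturation) for parameter recovery; 3000 units over
12 near-homogeneous experiments for the noise-adjustment direction; five
experiments of ≈ 2700–3300 units with a ≈ 3900-unit union — emulating a
published five-protease yeast proteome survey — for the 50 %-downsampling
evaluation, where both estimators are required to land within 10 % of the
known full union on average.

## Known limitations

* Chao-type estimates are lower-bound-style under heterogeneity; at low
  saturation both estimators degrade, the curve-fit asymptote first (on
  weakly saturated data the bounded fit returns essentially the observed
  count).  Estimates from compendia far from saturation should be read as
  floors, not totals.
* The noise adjustment extrapolates linearly and slightly overcorrects
  when the injected singletons dominate the `f₁` frequency (the Chao
  estimator is quadratic in `f₁`).
* The per-experiment cap discards information in very large compendia;
  the jackknife quantifies, but does not remove, the resulting
  subset-choice variability.
* Exact reproduction of third-party solver output (spreadsheet GRG
  optimizers, other log-linear implementations) is out of scope; fits are
  validated by SSE/likelihood optimality instead.
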