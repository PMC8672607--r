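---
title: "Sparse primal-dual centroid classification with rejection: methods and design"
author: "pdcr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse primal-dual centroid classification with rejection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcr)
```

## The problem

LC-MS metabolomics experiments produce intensity tables with hundreds to
tens of thousands of feature columns (one per detected ion) and far fewer
samples. Classification on such tables must cope with three structural
facts: features are heavily correlated (each metabolite appears as a block
of adducts and isotopologues), only a small subset of features carries
class signal, and the tables contain outliers and detection zeros. On top
of accuracy, clinical use of such classifiers needs a per-sample confidence
measure: a prediction one cannot calibrate a "how sure" statement for is of
limited diagnostic value.

`pdcr` addresses this with a sparse nearest-centroid classifier trained by
a primal-dual scheme, plus a confidence score that supports *classification
with rejection*: the classifier may answer "I don't know".

## Model

Let $X \in \mathbb{R}^{m\times d}$ be the preprocessed intensity matrix
($m$ samples, $d$ features) and $Y \in \{0,1\}^{m\times k}$ the one-hot
label matrix over $k$ classes. The method learns a projection
$W \in \mathbb{R}^{d\times k}$ and a centroid matrix
$\mu \in \mathbb{R}^{k\times k}$ (row $\mu_j$ is the prototype of class $j$
in the projected space) by solving

$$
\min_{W,\mu}\; h_\delta(Y\mu - XW)
  + \frac{\rho}{2}\lVert I_k - \mu\rVert_F^2
\quad\text{s.t.}\quad \lVert W\rVert_1 \le \eta ,
$$

where $h_\delta$ is the Huber function applied entrywise and summed,

$$
h_\delta(t) = \begin{cases} t^2/(2\delta) & |t|\le\delta\\
|t| - \delta/2 & |t|\ge\delta,\end{cases}
$$

$\lVert W\rVert_1$ is the *entrywise* sum of absolute values (this, not the
induced matrix norm, is what produces row-sparsity and hence feature
selection), and the quadratic penalty anchors $\mu$ to the identity,
breaking the homogeneity that would otherwise admit the trivial solution
$(W,\mu) = (0,0)$.

A new sample $x$ is assigned to the class with the nearest centroid in
$\ell_1$ distance, $j^* = \arg\min_j \lVert \mu_j - xW\rVert_1$. The Huber
loss interpolates between the outlier-sensitive squared loss (large
$\delta$) and the equality-enforcing $\ell_1$ loss ($\delta \to 0$) while
staying differentiable; `loss = "squared_l2"` replaces $h_\delta$ by
$\tfrac12\lVert\cdot\rVert_F^2$ for comparison.

### Confidence score and rejection

With two classes and distances $d_1, d_2$ to the centroids, the confidence
score for the prediction (CSP) is

$$ \rho(x) = \frac{d_1 - d_2}{d_1 + d_2} \in [-1, 1], $$

negative when the sample is closer to centroid 1. Given a threshold
$\varepsilon$, predictions with $|\rho(x)| < \varepsilon$ are *rejected*
(strict inequality: the boundary is classified). For $k > 2$ classes the
score generalizes to $\rho(x) = 1 - k\,\min_j d_j / \sum_j d_j \in [0,1]$,
which reduces to $|\rho|$ of the binary score at $k = 2$; rejection then
uses $\rho(x) < \varepsilon$.

Two curves summarize the accuracy/coverage trade-off as functions of
$\varepsilon$: the misclassification load
$\mathrm{FDR}(\varepsilon) = (\mathrm{FP} + \mathrm{FN})/m$ — note the
denominator is **all** samples, a deliberate convention that makes the
curve non-increasing in $\varepsilon$; the conventional rate conditional on
acceptance is emitted alongside as `fdrConditional` — and the rejection
rate $\mathrm{RRS}(\varepsilon) = \text{rejected}/m$.

## Optimization

The criterion is "smooth-loss-of-linear-map plus separable penalties", the
canonical shape for a Chambolle–Pock primal-dual iteration, which we use
with extrapolation:

$$
\begin{aligned}
Z &\leftarrow \mathrm{prox}_{\sigma h^*}\!\big(Z + \sigma(Y\bar\mu - X\bar W)\big)
   &&= \mathrm{clip}\big(\tfrac{Z + \sigma R}{1+\sigma\delta}, -1, 1\big)\\
W^+ &\leftarrow P_{\lVert\cdot\rVert_1\le\eta}\big(W + \tau X^\top Z\big)\\
\mu^+ &\leftarrow \frac{\mu - \tau Y^\top Z + \tau\rho I_k}{1 + \tau\rho}\\
(\bar W, \bar\mu) &\leftarrow 2(W^+, \mu^+) - (W, \mu).
\end{aligned}
$$

Design notes, in decreasing order of consequence:

* **Feasibility by construction.** $W$ is projected onto the $\ell_1$ ball
  at every iteration (exact $O(n\log n)$ sort-based projection with the
  cumulative-sum threshold rule), so every iterate — not only the limit —
  satisfies the constraint. The solver records the largest
  $\lVert W\rVert_1$ it ever produced as a certificate.
* **Step sizes.** Convergence requires $\sigma\tau\lVert A\rVert^2 \le 1$
  for the linear map $A(W,\mu) = Y\mu - XW$. Since $A$ acts column-wise as
  $[-X\; Y]$, $\lVert A\rVert$ is the top singular value of
  $[X\; Y]$, estimated by seeded power iteration; the default
  (`autoSteps`) sets $\sigma = \tau = 0.99/\lVert A\rVert$.
* **Dual prox.** The Huber conjugate is $\delta z^2/2$ on $[-1,1]$, so its
  resolvent is shrink-then-clip; for the squared loss it is plain shrinkage
  $z/(1+\sigma)$ without clipping.
* **Initialization and determinism.** $W = 0$, $\mu = I_k$, $Z = 0$; the
  solver itself contains no randomness, so refits are bit-identical.
* **Stopping.** Relative change of $(W,\mu)$ below `tol` (default $10^{-6}$)
  or `maxIter` (default 2000). Primal-dual objective traces are not
  monotone, so the trace is recorded for diagnostics only and never used as
  the stopping rule.
* **Degenerate cases.** $\eta = 0$ forces $W = 0$ (with a warning at fit
  time); the optimum then decouples and, when all fitted responses stay in
  the Huber knee, has the closed form
  $\mu_{jl} = \rho\,I_{jl}/(n_j/\delta + \rho)$ with $n_j$ the size of
  class $j$ — used as an analytic regression test of the solver. Ties in
  the nearest-centroid argmin go to the lowest class index; two exactly
  zero distances yield CSP 0 (binary) with a degeneracy warning.

### Parameter defaults

| parameter | default | meaning and rationale |
|---|---|---|
| `delta` | 0.3 | Huber knee, on the scale of autoscaled (unit-variance) residuals: residuals under ~0.3 sd are treated quadratically, larger ones linearly. Fixed, not tuned per dataset. |
| `rhoPenalty` | 1 | centroid anchoring weight; order 1 keeps $\mu$ near $I_k$ without freezing it. Fixed. |
| `eta` | 1 | $\ell_1$ budget for $W$; **the one tunable parameter**, set to match the number of features one expects to matter. Our synthetic studies use $\eta = 5$, chosen once on dropout-free generator defaults so the ~30 planted features are all selectable. |
| `sigma`, `tau` | $0.99/\lVert A\rVert$ | auto-derived steps satisfying the convergence condition. |
| `maxIter`, `tol` | 2000, $10^{-6}$ | ample for the study sizes here (typical convergence in a few hundred iterations). |

## Preprocessing

The training pipeline is prevalence filter → log transform → autoscaling,
with every parameter fitted on training samples only and replayed verbatim
on test samples (the model stores them):

* **Prevalence filter**: a feature is "detected" in a sample when its raw
  intensity is strictly positive; features detected in fewer than
  `minFraction` (default 10%) of samples are dropped, with a keep-if-$\ge$
  boundary rule.
* **Log transform**: $\log_{10}(x + 1)$ by default. The pseudocount guards
  dropout zeros; base and pseudocount are configurable.
* **Autoscaling**: per-feature centering and division by the sample
  ($n-1$) standard deviation. Zero-variance features get scale 1 with a
  warning, so constants pass through centered at zero rather than aborting
  a fit.
* **Labels**: class names are ordered lexicographically, so the mapping of
  classes to columns of $Y$ (and to the sign of the binary CSP) is
  deterministic.

Fold-wise refitting of the preprocessing inside cross-validation is a
deliberate leakage guard; the test suite asserts that perturbing held-out
samples cannot change training-fold models.

## The synthetic data generator

`simulateMetabolomics()` emulates the structure that makes real LC-MS
tables hard, with known ground truth:

* lognormal intensities: per-feature log10 means uniform in $[3, 6]$,
  per-sample biological noise sd 0.3 (log10) — multiplicative noise that
  the log transform turns additive;
* `s = 10` informative base metabolites, each observed as
  `adductsPerBase = 3` highly correlated feature columns (shared per-sample
  signal, fixed per-adduct offset, measurement jitter sd 0.05; within-block
  Pearson correlation ≈ 0.97), mirroring adduct/isotopologue blocks;
* a class-2 effect of `log2FoldChange = 1.6` (≈3-fold intensity change) on
  each base metabolite, comparable to fold changes reported for
  discriminative metabolites in real two-class studies;
* detection dropout: each entry zeroed with probability 0.1;
* optional outlier samples (fraction `outlierSampleFrac`) whose noise sd is
  multiplied by `outlierScale` — the mechanism used to probe the
  Huber-vs-$\ell_2$ robustness claim.

Defaults are $m = 100$ balanced samples and $d = 1000$ features. The
generator does **not** simulate retention times, isotope-pattern physics,
batch effects or missing-at-random gaps; conclusions from these studies are
about the algorithm's statistical behaviour, not about any real cohort.

## Study design, sizes, and what the checks show

All studies run on the generator with fixed seeds and are deterministic.

* **Solver correctness** is checked against independent oracles on tiny
  instances ($m \le 10$, $d \le 6$, $k = 2$): a bisection (KKT) oracle for
  the $\ell_1$ projection, numerical prox minimization for the dual
  resolvent, a long-run projected accelerated-gradient oracle for the full
  criterion (agreement to $10^{-4}$; observed agreement is near machine
  precision), and the $\eta = 0$ closed form.
* **Recovery study**: 10 generator datasets at default conditions,
  stratified 4-fold CV (one shuffle seed per dataset) and top-30 feature
  recall against the 30 planted features, summarized by medians.
* **Null control**: 20 datasets ($m = 60$, $d = 200$ for tractability)
  with labels permuted independently of the data; mean CV accuracy is
  compared with the 95% binomial band around the majority-class rate. This
  guards against the overfitting failure mode that high-dimensional
  classifiers are notorious for.
* **Robustness study**: 20 datasets with 10% outlier samples at 5× noise,
  dropout disabled to isolate the outlier mechanism; median CV accuracy of
  the Huber loss must be at least that of the squared loss. At these desk
  sizes the two losses select near-parallel projections and the medians
  typically tie — the check is a non-inferiority guard, not a
  demonstration of a large gap.

## A known limitation: uniform dropout at default conditions

The generator's default 10% uniform dropout interacts destructively with
the standard pseudocount-log-autoscale chain. A zeroed entry of a feature
whose typical log10 intensity is ~4.5 maps to $\log_{10}(0+1) = 0$, i.e. an
outlier at roughly $-3$ standard deviations *after* scaling. Three
consequences, all reproducible with the package itself:

1. per-feature variances are inflated ~5-fold, shrinking the standardized
   class effect from ~1.6 sd to ~0.33 sd;
2. background features acquire spurious class-mean differences of the same
   order as the planted effect (dropout hits the two classes asymmetrically
   by chance), corrupting any weight-based ranking;
3. at prediction time a single dropout in a selected feature shifts the
   projection by several times the per-feature signal.

Under these defaults cross-validated accuracy plateaus near 0.56 and
top-30 recall near 0.2 — and this is not an optimization failure: fitting
on the *true* informative features only (an oracle no selector can beat)
caps at ~0.65, and models trained on clean data also collapse when tested
on dropout data. With dropout disabled and everything else at defaults the
method recovers the ground truth essentially perfectly (CV accuracy ≈
0.97, top-30 recall ≈ 1.0, η = 5). The acceptance suite therefore runs the
recovery study at the stated default conditions and reports the failure
honestly, and the acceptance script reports both the default-condition and
the dropout-free numbers. Handling heavy uniform dropout properly would
need a censoring-aware treatment (per-feature imputation at the detection
limit, or a missing-data likelihood), which is outside the scope of this
classifier's preprocessing contract.

## Worked example

```{r example, eval = FALSE}
sim <- simulateMetabolomics(m = 60, d = 200, s = 5, dropoutProb = 0,
                            log2FoldChange = 3, seed = 1)
fit <- pdcrFit(sim$table, sim$truth$labels, solverConfig(eta = 2))
fit

cv <- pdcrCrossValidate(sim$table, sim$truth$labels, folds = 4, seeds = 0:2,
                        config = solverConfig(eta = 2))
cv

head(featureRanking(fit), 5)

pred <- predict(fit, sim$table, epsilon = 0.2)
head(pred, 3)

curve <- rejectionCurve(cv@predictions, cv@predictions$truth)
curve[curve$epsilon %in% c(0, 0.2, 0.45), ]
```

The same pipeline is scriptable from a shell through the `pdcr` CLI
(`inst/exec/pdcr`): `simulate`, `fit`, `predict`, `cv`, `curve`, with every
resolved parameter logged so per-dataset tuning of η is auditable.
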