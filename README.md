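# pdcr — sparse primal-dual classification with rejection

`pdcr` is an R package for classifying high-dimensional omics intensity
tables — LC-MS metabolomics feature matrices in particular — while
simultaneously selecting the features the decision rests on, and attaching
a confidence score to every prediction so that low-confidence calls can be
*rejected* instead of silently guessed.

## The method

Given a preprocessed sample-by-feature matrix $X \in \mathbb{R}^{m\times d}$
and one-hot labels $Y \in \{0,1\}^{m\times k}$, the classifier learns a
sparse projection $W \in \mathbb{R}^{d\times k}$ and class centroids
$\mu \in \mathbb{R}^{k\times k}$ by solving

$$
\min_{W,\mu}\; h_\delta(Y\mu - XW) + \frac{\rho}{2}\lVert I_k-\mu\rVert_F^2
\quad \text{s.t.} \quad \lVert W\rVert_1 \le \eta,
$$

with $h_\delta$ the Huber loss (robust to outlier samples) and the
entrywise $\ell_1$-ball constraint inducing feature sparsity; $\eta$ is the
single parameter worth tuning and directly controls the feature budget.
The problem is solved with a Chambolle–Pock primal-dual iteration whose
iterates are feasible by construction (exact sort-based projection onto the
$\ell_1$ ball every step).

Prediction is by $\ell_1$ nearest centroid,
$j^* = \arg\min_j \lVert\mu_j - xW\rVert_1$, and each call carries the
confidence score $\rho(x) = (d_1-d_2)/(d_1+d_2) \in [-1,1]$ (binary case).
Samples with $|\rho(x)| < \varepsilon$ can be rejected; the package
computes the resulting FDR-versus-rejection-rate trade-off curves. Feature
importance is read directly off the rows of $W$.

The package also ships the surrounding protocol — prevalence filtering,
log transform, autoscaling (always fitted on training folds only),
stratified k-fold cross-validation with accuracy and Mann–Whitney AUC —
and a synthetic two-class LC-MS-like generator (correlated adduct blocks,
detection dropout, outlier samples) with known ground truth, so everything
is testable at desk scale. See `vignettes/pdcr-methods.Rmd` for the full
model, parameter semantics and study designs.

## Worked example

```r
library(pdcr)

sim <- simulateMetabolomics(m = 60, d = 200, s = 5, dropoutProb = 0,
                            log2FoldChange = 3, seed = 1)
cfg <- solverConfig(eta = 2, maxIter = 10000)
fit <- pdcrFit(sim$table, sim$truth$labels, cfg)
fit
#> PdcrModel: 2 classes (class1, class2)
#>   200 retained features, 59 selected (nonzero weight)
#>   loss=huber eta=2, 6611 iterations, converged

head(featureRanking(fit), 3)
#>    featureId     score selected
#> 1 MET04_ADD3 0.2279908     TRUE
#> 2 MET03_ADD2 0.2191380     TRUE
#> 3 MET01_ADD1 0.1688096     TRUE

cv <- pdcrCrossValidate(sim$table, sim$truth$labels, folds = 4, seeds = 0:2,
                        config = solverConfig(eta = 2))
cv
#> PdcrCVReport: 4-fold CV, 3 seed(s); mean accuracy 1.0000, mean AUC 1.0000

pred <- predict(fit, sim$table, epsilon = 0.2)
pred[1:2, c("sampleId", "d_1", "d_2", "csp", "finalLabel")]
#>   sampleId        d_1        d_2        csp finalLabel
#> 1     S001 0.00990099 1.79374763 -0.9890212     class1
#> 2     S002 1.79365561 0.00990099  0.9890206     class2

curve <- rejectionCurve(cv@predictions, cv@predictions$truth)
curve[curve$epsilon %in% c(0, 0.2, 0.45), ]
#>    epsilon fdr fdrConditional        rrs
#> 1     0.00   0              0 0.00000000
#> 21    0.20   0              0 0.01111111
#> 46    0.45   0              0 0.08333333
```

The fitted model concentrates its weight on the planted adduct-block
features (`MET..`), cross-validated accuracy and AUC on this clean
synthetic dataset are 1.0, and each prediction carries signed distances
and a confidence score: S001 is called `class1` with CSP −0.989, far from
the rejection threshold ε = 0.2. The rejection curve shows the FDR pinned
at 0 while the rejection rate stays below 10%.

A thin command-line interface (`inst/exec/pdcr`) exposes the same pipeline
as `pdcr simulate | fit | predict | cv | curve` subcommands for shell use;
model files are human-inspectable JSON, tabular outputs are CSV.

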