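# smdqsar

Statistical molecular design and reference-model-validated PLS QSAR.

## The problem

Most QSAR models are trained on whatever molecules happen to exist. When
structural features co-vary across those molecules their effects on activity
are confounded, coefficients become uninterpretable, and apparent predictive
power can be an artefact of chance correlation. `smdqsar` implements the
opposite workflow, aimed at medicinal and environmental chemists who get to
choose which compounds to make before modelling:

1. **Statistical molecular design (SMD).** Candidate molecules are
   enumerated as combinations of building blocks at substitution positions
   and encoded as binary fragment indicators ("conditional descriptors").
   A subset of size *n* is selected to maximise `det(Xsel' Xsel)`
   (D-optimality, Fedorov exchange), so fragments recur and vary
   independently. Diagnostics: log-determinant, the condition number of the
   selected design (1 = perfectly orthogonal; below ~3 preferred), and
   per-fragment occurrence counts (every fragment at least twice).
2. **Covariance screening.** For autoscaled descriptors the package reports
   the absolute pairwise correlation matrix `rho = |sum_i x_i1 x_i2 / N|`
   (exactly |Pearson r|), pairs above a redundancy cutoff (default 0.7),
   and the chance-correlation risk `1 - (1 - alpha)^K` for `K` comparisons.
3. **PLS1 regression with full validation.** A NIPALS partial
   least-squares engine provides, in the field's standard notation:
   * `R2Y` and adjusted `R2Y = 1 - (1 - R2Y)(N-1)/(N-1-A)`;
   * `RMSEE = sqrt(sum(y - yhat)^2 / (N - 1 - A))` (training) and
     `RMSEP = sqrt(sum(y - ypred)^2 / N)` (external test);
   * leave-one-out `Q2 = 1 - PRESS/SS` with scaling re-estimated inside
     every fold;
   * jack-knife 90% confidence intervals for the scaled regression
     coefficients from the cross-validation submodels;
   * a 200-fold y-scrambling permutation test;
   * the applicability domain via the normalised distance to the model in
     X (DModX, with DCrit from an F quantile; DModXPS for new compounds).
4. **Reference (null) models.** Training mean and median, nearest
   neighbour (expert map or computed descriptor-space proxy), univariate
   regressions, and a small three-descriptor PLS — the baselines a
   published QSAR should beat in RMSEP.
5. **Statistical comparison of predicted and measured potencies.**
   Anderson-Darling normality screening gates a one-tailed F test and a
   paired t test; two-sample Kolmogorov-Smirnov and Mann-Whitney tests run
   whenever their sample-size rules (n > 10, n > 7) are met.

Activities are handled as pIC50 = −log10(IC50 in M) with IC50 stored in
µM, so `pIC50 = 6 − log10(IC50_µM)`. A synthetic-data generator
(`generate_study()`, `generate_descriptors()`) reproduces the statistical
structure of a designed series — additive fragment effects with Gaussian
noise, correlated descriptor blocks — so the whole chain is testable
without external data.

## Worked example

Design a series, fit and validate a model on simulated activities with
known fragment effects (±1 pIC50 units, noise 0.45):

```r
library(smdqsar)

# the packaged 18-compound designed training set
act <- read_activity_csv(ache_training_path(), role = "train")
mean(act$pic50)    # 3.867
median(act$pic50)  # 4.055

# a four-position library: 6 x 2 x 2 x 6 = 144 candidate molecules
shape <- c(pIa = 6, pIb = 2, pII = 2, pIII = 6)
frag  <- unlist(lapply(names(shape), function(p) paste0(p, ".f", seq_len(shape[[p]]))))
beta  <- setNames(rep(c(1, -1), length.out = length(frag)), frag)
study <- generate_study(shape, beta = beta, sigma = 0.45, seed = 1)

study$selection
#> D-optimal selection: 18 candidates, log det(Xsel'Xsel) = 31.7475, condition number = 3.747
#> Selected: 8 17 21 31 40 44 58 63 67 83 85 96 102 118 119 129 134 144

model <- pls_fit(study$x_reduced, study$activity$pic50, ncomp = 2)
model
#> PLS model: A = 2, N = 18, K = 12
#> R2Y = 0.960, adj R2Y = 0.955, RMSEE = 0.458
#> R2X per component: 0.12, 0.09

cv <- loo_cv(study$x_reduced, study$activity$pic50, 2)
cv
#> Leave-one-out CV: A = 2, Q2 = 0.727 (PRESS = 21.482, SS = 78.722)

permutation_test(study$x_reduced, study$activity$pic50, 2, n_perm = 200, seed = 2)
#> Permutation test (200 scrambles): PASS
#>   original R2Y = 0.960, Q2 = 0.727
#>   intercepts at |cor| = 0: R2Y 0.620, Q2 -1.450; max permuted Q2 0.727
```

The fitted model recovers the design: R2Y ≈ 0.96 with RMSEE ≈ 0.46 (the
noise level injected), honest cross-validated Q2 ≈ 0.73, and a scrambled
response never does better than the real one. Jack-knife intervals
(`jackknife_ci(cv)`) then separate fragments whose effects are resolved
from those that are not, and `predict()` reports each new compound's
DModX against `dmodx_crit()` before its prediction is trusted.

`run_workflow(workflow_config(out_dir = "run1"))` executes the whole chain
and writes per-stage CSV/JSON reports plus a provenance manifest.

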