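---
title: "Methods: statistical molecular design and validated PLS QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical molecular design and validated PLS QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdqsar)
```

This vignette documents the models, conventions and numerical choices
behind `smdqsar`, in the spirit of a chemometrics methods section: what is
computed, under which assumptions, and where a genuinely open convention
had to be fixed.

## The modelling problem

A designed structure-activity study proceeds in stages: choose a diverse
but balanced subset of molecules from a combinatorial library, verify that
the chosen descriptors are not confounded, regress activity on the
descriptors with PLS, validate the model internally (cross-validation,
permutation) and externally (test sets, applicability domain), and demand
that it beats deliberately simple reference models. Activity is
pIC50 = −log10(IC50 in molar); IC50s are stored in µM so the conversion is
pIC50 = 6 − log10(IC50~µM~), with the constant fixed rather than
configurable. Displayed values are rounded to two decimals; stored values
keep full precision.

## Statistical molecular design

Candidates are the Cartesian product of fragments over positions,
enumerated in deterministic lexicographic order. The presence/absence
("conditional") encoding comes in two forms:

* **full** — one indicator per fragment. Each position block sums to 1
  per row, so the blocks are exactly collinear after centering.
* **reduced** — the last fragment per position is the reference level.

D-optimality maximises `det(Xsel' Xsel)` of the centered, unit-variance
scaled indicators. Because the full encoding is singular after centering,
the optimisation and the reported log-determinant use the **reduced**
encoding; reports translate back to full fragment names. Dropping a
reference level is an invertible linear recoding per position, so subset
ranking by determinant is unchanged up to a constant factor. The
condition number — max/min singular value of the autoscaled selected
matrix, 1 for an orthogonal design — is reported for the reduced encoding
by default; a pseudo variant (discarding numerically zero singular
values) serves the full encoding. Which convention a given published
condition number used can only be settled against that study's actual
design matrix, so both are exposed.

The optimiser is classical Fedorov single-swap steepest ascent with
rank-one determinant updates, 50 random restarts by default, and a
deterministic seed. Singular information matrices during the search are
stabilised with a ridge jitter of 1e−8 used for ranking only — reported
log-determinants are ridge-free (−Inf when genuinely singular). Ties
between equally good optima resolve to the lexicographically smallest
index set, making results reproducible across platforms. On libraries
small enough for exhaustive enumeration the exchange recovers the global
optimum essentially always (the test suite requires ≥ 95% over 50 seeded
libraries with 20 restarts).

Design balance is checked as per-fragment occurrence counts with a
minimum-occurrence threshold (default 2): a fragment seen once cannot
have its effect separated from its combination partners.

## Covariance screening

For autoscaled descriptors (population divisor N, which makes the printed
formula `rho = sum x_i1 x_i2 / N` coincide exactly with Pearson's r), the
package reports absolute pairwise correlations, every pair above a
redundancy threshold (default 0.7), counts relative to anchor descriptors,
and the chance-correlation risk `1 − (1 − alpha)^K`. The sample-divisor
variant differs by (N−1)/N and is deliberately not exposed here, so the
reported matrix always satisfies the printed formula. Missing values fail
fast; imputation, if any, must happen upstream and explicitly.

## PLS1 engine

NIPALS with deflation; with a single response the weight vector is
stationary after one pass, but the iterative loop (tolerance 1e−10 on the
weight-vector change, at most 500 iterations per component) is retained
for the general contract and aborts with a named component on
non-convergence. Descriptors and response are centered and scaled to unit
variance before fitting; coefficients are reported in scaled space, where
their relative sizes are comparable across descriptors.

* **Fit statistics.** R2Y, adjusted R2Y = 1 − (1 − R2Y)(N−1)/(N−1−A), and
  RMSEE with the degrees-of-freedom denominator N−1−A. Note that although
  the residual sum of squares can only shrink with extra components,
  RMSEE itself can *rise* when a component adds little, because the
  denominator shrinks too — the error statistic deliberately penalises
  model complexity.
* **Cross-validation.** Leave-one-out, with scaling parameters
  re-estimated inside every fold (predicting a held-out row with
  training-fold scaling is the honest analogue of predicting a genuinely
  new compound). Q2 = 1 − PRESS/SS with SS about the all-rows mean.
  Folds are row order; no randomness. Q2 from total PRESS is the primary
  read-out (a per-component multiplicative variant exists in some
  software; total PRESS is the one computed here). A degenerate column
  inside a fold is a hard error, never a silently skipped fold.
* **Component count.** Accept component a+1 only when it raises Q2 by
  more than 0.05, hard cap 3. A single-response PLS model should rarely
  need more than one component; the limit is a configuration knob
  recorded in provenance, not a hidden heuristic.
* **Jack-knife intervals.** From the N leave-one-out submodels:
  SE_k = sqrt(((N−1)/N) Σ_i (b_k^(−i) − b̄_k)²), interval
  b_k ± t_{0.95, N−1} SE_k for the default 90% level, centred on the
  full-model coefficient. The cited jack-knife admits variants; this one
  is simple, documented, and its realised level is verified by simulation
  in the test suite. A coefficient is "significant" when its interval
  excludes zero.
* **Permutation test.** The response is scrambled n_perm = 200 times
  (dedicated seeded generator); each refit at the same A records
  |cor(y_perm, y)|, R2Y and Q2. Verdict: pass when the intercepts of the
  R2Y and Q2 regression lines versus |cor| lie below the original values
  *and* no permuted Q2 reaches the original. The max rule is strict: on
  small designed sets (N = 18) a permutation that happens to correlate
  strongly with the real response occasionally approaches the original
  Q2, so borderline models legitimately fail it.
* **Applicability domain.** DModX_i = sqrt(Σ_k e_ik²/(K−A)) / s0 with
  s0 = sqrt(ΣΣ e²/((N−1−A)(K−A))); training rows carry the correction
  v = sqrt(N/(N−A−1)) (slightly above 1, compensating for rows that are
  part of the model; with it the mean squared training DModX is exactly
  1), new rows use DModXPS (v = 1). DCrit(α) = sqrt(qF(1−α; K−A,
  (N−A−1)(K−A))). Both the correction and the critical-value recipe are
  software conventions rather than settled theory; they are isolated in
  two small functions.

RMSEP uses divisor N exactly (no degrees-of-freedom correction): test
compounds were never part of the fit. For pooled test sets,
RMSEP(union)² = Σ_s n_s RMSEP_s² / Σ_s n_s.

## Reference models and statistical comparison

Mean, median (even-sized sets: midpoint of the central pair), nearest
neighbour, three univariate regressions and a three-descriptor PLS. An
expert-elicited neighbour map is irreproducible computationally, so the
map is accepted from a file and the computed fallback — nearest training
compound by Euclidean distance in autoscaled descriptor space, ties to
the earlier row — is labelled a proxy in provenance.

Predicted-versus-measured comparisons follow a tiered scheme:
Anderson-Darling normality screening on both samples (composite case,
small-sample adjusted statistic A* = A²(1 + 0.75/n + 2.25/n²) with the
standard piecewise p-mapping — implemented directly because library
implementations typically refuse n < 8, while designed test sets are
often that small; cross-checked against `nortest` where both apply); if
both normal, a one-tailed F test (larger/smaller variance ratio, p = 0.5
at F = 1, never rejected there); if that accepts, a paired two-tailed t
test. Kolmogorov-Smirnov (asymptotic p) and Mann-Whitney (exact for
small untied samples, else tie-corrected normal approximation) run
whenever n > 10 and n > 7 respectively. Inapplicable cells carry codes
(failed F; non-normal; below size rule) rather than numbers. One caveat
is documented rather than hidden: the larger/smaller F convention has
realised size about twice its nominal level, because the direction is
chosen after seeing the data; a classical directional variant
(`direction = "first"`) with exact size is provided, and it is the one
whose type-I error the test suite pins to [0.03, 0.07]. Constant
non-zero paired differences are treated as maximal evidence against
equality (p = 0) since the t statistic is unbounded there. No
multiple-testing correction is applied across the comparison grid — the
grid mirrors reporting practice, and each cell is read marginally.

## Synthetic data: what it does and does not emulate

`generate_study()` reproduces the *statistical* structure the pipeline
assumes: a combinatorial indicator library (default 6×2×2×6 = 144
candidates, 18 selected D-optimally), additive fragment effects
y = intercept + Σ β + ε with homoscedastic Gaussian noise, and stored
truth for recovery tests. Defaults: intercept 4 (a mid-micromolar pIC50),
σ = 0.45 pIC50 units (the half-log-unit estimation error typical of
inhibition assays), random β ~ N(0, 0.75²) unless given explicitly. One
master seed derives per-stage child seeds (linear congruential offsets,
kept below 2³¹), so regeneration is bit-identical. `generate_descriptors()`
adds correlated Gaussian blocks via a PSD square root of the target
correlation matrix — e.g. a two-descriptor block at 0.94 mimicking a
confounded frontier-orbital pair.

Not emulated: any actual chemistry. There is no structure generation, no
descriptor physics, no non-additivity, no heteroscedastic assay error, no
censoring. Tests passing on this generator therefore demonstrate the
correctness of the statistical machinery under its own assumptions — not
that a real assay obeys them. Real-data idiosyncrasies the loader *does*
handle: censored IC50s (a leading `>`; the row keeps its printed pIC50
and is flagged), duplicated protonation states (plain duplicate records),
and IC50/pIC50 inconsistencies (flagged with the row, never silently
corrected).

## Problem sizes and numerical tolerances

The test suite verifies the engine against independent oracles: a
Krylov-subspace closed form for PLS (agreement 1e−8 on 50 seeded problems
with N ≤ 30, K ≤ 20), ordinary least squares at full rank, exhaustive
subset enumeration for D-optimality (9-candidate libraries, C(9,5)
subsets), brute-force ECDF and U-distribution enumeration for the
non-parametric tests, and closed-form RMSEP identities. Simulation-based
properties use 100-seed batches at N between 12 and 24 with 20-50
permutations per run — sizes chosen to mirror the intended use case of
small designed series while keeping the whole suite around half a minute.
Key tolerances: NIPALS weight change 1e−10; ridge jitter 1e−8 (ranking
only); singular-value cutoff 1e−8 relative; correlation-vs-Pearson
agreement 1e−12.

## Known limitations

* Single-response PLS1 only: no PLS2, no OPLS, no kernel variants, no
  VIP scores (scaled coefficients are the interpretation surface).
* The D-optimal search is a local-exchange heuristic; optimality is only
  guaranteed relative to its restarts (ample at the library sizes the
  package targets).
* DModX conventions (correction factor, DCrit) follow common software
  practice and are approximations, not exact distribution theory.
* The Anderson-Darling p-mapping is an approximation; verdicts near
  p = 0.05 should be read with that in mind, and the comparison scheme
  treats normality as a gate, not a conclusion.
* Descriptor computation is out of scope: matrices are consumed as
  given, and the package cannot detect descriptors that are wrong, only
  descriptors that are redundant.
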