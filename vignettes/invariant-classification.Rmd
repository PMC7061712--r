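---
title: "Invariant linear SVMs: models, constraints and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Invariant linear SVMs: models, constraints and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consvm)
library(dplyr)
```

## The problem

A molecular profile $x \in \mathbb{R}^n$ — a vector of expression
measurements — reaches a classifier only after normalization, background
correction and platform-specific transformations. When these differ
between the training cohort and the samples seen at deployment (new
batch, new lab, new platform), a classifier that was accurate in
cross-validation can fail silently. Two artefact families are
ubiquitous: *global scaling* $x \mapsto a\,x$ ($a > 0$), the signature of
normalization differences, and *global transition* $x \mapsto x + b\,\mathbf{1}$,
the signature of reference-point or background shifts. Monotone
nonlinear distortions (e.g. $x^{(i)} \mapsto e^{0.2c\,x^{(i)}}$)
subsume log-scale mismatches.

Rather than estimating and removing such artefacts, this package
restricts the *concept class* of the classifier so that its predictions
are provably unaffected by them. All models are linear decision rules

$$c(x) = \mathbb{1}\left[\langle w, x\rangle \ge t\right],$$

with ties at the boundary assigned to class 1, and the subclasses are
cut out by structural constraints on $(w, t)$:

| class | constraint | invariant to | active features |
|---|---|---|---|
| `lin` | none | — | $[1, n]$ |
| `off` | $t = 0$ | $x \mapsto a x$ | $[1, n]$ |
| `con` | $\sum_i w^{(i)} = 0$ | $x \mapsto x + b\mathbf{1}$ | $[2, n]$ |
| `off_con` | both | $x \mapsto a x + b\mathbf{1}$ | $[2, n]$ |
| `mon` | $w = \alpha(e_i - e_j)$, $t = 0$ | any feature-wise strictly increasing map | exactly 2 |

The invariances are equivalences, not merely sufficient conditions: a
non-constant linear rule is scaling-invariant *iff* $t = 0$, and
shift-invariant *iff* the weights sum to zero (the proof is one line of
algebra on $\langle w, x + b\mathbf{1}\rangle$). The pairwise rule
$\mathbb{1}[x^{(i)} \ge x^{(j)}]$ is the linear form of a
top-scoring-pair classifier: only the order of two measurements
matters, so any monotone re-expression of the data leaves it unchanged.
The classes nest (`mon` $\subset$ `off_con` $\subset$ `off`, `con`
$\subset$ `lin`), and the nesting is mirrored by their
Vapnik–Chervonenkis dimensions: $n+1$, $n$, $n$, $n-1$, and at most
$\max\{m \mid 2^m \le n(n-1)\}$ for the pairwise class, whose classifier
set is finite. Lower complexity means a smaller overfitting risk at
equal empirical fit — the constraints buy both robustness and
generalization headroom.

`vc_lower_bound()` and `vc_upper_falsify()` make these statements
executable: shattering of a candidate point set is decided by linear
feasibility (`realizable()` encodes strict separation as unit-margin
feasibility, valid because every class is closed under positive
rescaling of $(w,t)$), constructed sets (simplex vertices, unit
vectors) certify the lower bounds, and random search attempts to
falsify the upper bounds. For `mon` the classifier set is enumerated,
so its upper-bound check is exact; for the continuous classes a
surviving upper bound is evidence, not proof, and is documented as
such.

## Training under constraints

Two soft-margin criteria are implemented, both subject to
$y_i(w^\top x_i - t) \ge 1 - \xi_i$, $\xi_i \ge 0$ with labels recoded
$1 \mapsto +1$, $0 \mapsto -1$:

* **R2**: $\min \tfrac12\lVert w\rVert_2^2 + C\sum_i \xi_i$ — a convex
  quadratic program, solved with `quadprog` on the primal. A diagonal
  ridge of $10^{-8}$ on the threshold and slack variables makes the
  quadratic form positive definite; at the optimum the slacks equal the
  hinge losses, so the perturbation is orders of magnitude below the
  reported precision.
* **R1**: $\min \lVert w\rVert_1 + C\sum_i \xi_i$ — a linear program via
  the split $w = w^+ - w^-$ (the threshold is not penalized), solved by
  a two-phase dense-tableau simplex implemented in the package
  (`src/simplex.cpp`). Dantzig pricing switches to Bland's rule after a
  burn-in, which rules out cycling; the same routine decides the
  shattering feasibility problems.

Class constraints are imposed *exactly*, not penalized: the threshold
column is eliminated for offset-free classes, and $\sum_i w^{(i)} = 0$
enters as an equality row. Every returned model is re-checked by
`check_membership()`; a model that fails its claimed class is a bug,
not a warning.

For `mon` the feasible set is a union of rays, one per ordered feature
pair, so the problem is not jointly convex; `svm_train()` enumerates
all $n(n-1)$ pairs and solves each one-dimensional convex problem in
the scale $\alpha$ of $w = \alpha(e_i - e_j)$ exactly, walking the
kinks of the piecewise objective (`src/monsearch.cpp`). Ties between
pairs break to the lexicographically smallest $(i, j)$, a convention
chosen for reproducibility. If the optimal scale is $\alpha = 0$ (the
zero vector beats every positive scale, which happens for barely
separable data at small $C$), the fit keeps the pair at $\alpha = 1$
and reports status `"degenerate"`: predictions of a pair rule do not
depend on $\alpha > 0$, but the structural `mon` membership must hold
in the returned model, and the reported objective is the infimum.

**The cost parameter.** $C = 1$ is the package default everywhere,
including the benchmark harnesses. The trade-off it controls is the
usual one; the benchmark's class separations (centroid distances 1–5 at
unit variance) are large enough that the qualitative behaviour of all
five classes is insensitive to $C$ over a wide range. Per-dataset
multi-objective tuning of $C$ is deliberately out of scope.

**Tolerances.** Structural membership uses a relative tolerance
(default $10^{-8}$) against $\max_i |w^{(i)}|$, with an absolute floor
of $10^{-8}$ on that scale so that degenerate near-zero weight vectors
are not rejected on roundoff. `verify_invariance()` uses a per-sample
numerical guard band of $10^{-9}\lVert w\rVert \lVert x\rVert$: a label
flip within the band is floating-point noise at the decision boundary,
reported separately as indeterminate rather than as a counterexample.

## The synthetic benchmark

`simulate_dataset()` draws two classes of 50 samples each from
spherical Gaussians $N(c_y, I)$. The positive centroid has i.i.d.
$U(0, 10)$ coordinates — always positive, as raw expression intensities
would be — and the negative centroid sits at Euclidean distance $d$
along a uniformly random direction. One experiment family varies
$d \in \{1, 1.1, \dots, 5\}$ in noise-free data; the other fixes
$d = 4$ and applies one of five transformation families (identity,
scaling, transition, their combination, exponential) at noise levels
$p \in \{0, \dots, 5\}$, with parameters drawn as $a \sim U(10^{-5}, p)$,
$b \sim U(-p, p)$, $c \sim U(10^{-5}, p)$; $p = 0$ is read as the
identity. Ten repetitions with fresh centroids are run per
configuration, and every invariant model is compared against the
unconstrained SVM with the same regularization.

Two noise regimes differ in what they emulate:

* *sample-wise* (`samplewise_noisify()`): each test profile gets its own
  parameter draw — every sample processed slightly differently; the
  training set is untouched. For a model invariant to the family this
  leaves the per-repetition accuracy trace over $p$ *exactly* constant,
  and the harness keeps the same raw train/test pair across all noise
  levels of a repetition precisely so that this sharp prediction is
  testable. (Fresh data per level would blur an exact invariance into a
  statistical one.)
* *class-wise* (`classwise_noisify()`): one draw per class, independent
  between training and test — a batch-effect caricature in which an
  artefact is confounded with the class label and changes between
  cohorts. Models are retrained on the transformed training set.

"Accuracy loss" under noise is measured against the same model's own
$p = 0$ accuracy within a repetition, the natural reading of a
per-model degradation curve. Summaries pool both regularizations and
report means with interquartile ranges; `summarize_experiment()`
reproduces that convention.

What the generator does *not* emulate: correlated features, non-unit
and non-spherical covariances, heavy-tailed measurement error, class
imbalance, and the count nature of sequencing data. Passing benchmarks
therefore demonstrate the invariance mechanics and the cost of
constraints under controlled geometry — not performance on any real
cohort. For real data the package offers `read_labeled_matrix()` plus
`cross_validate_10x10()` (10 random permutations × 10 stratified folds,
fold sizes within one sample of each other; stratification is a
deliberate choice to keep 13-sample classes represented in every fold,
with a warning when a class is smaller than the fold count).

## Reproducibility and problem sizes

Every experiment function takes a root `seed` and derives an
independent child stream per (distance, repetition) or (repetition,
noise level) cell via a multiplicative congruential step, so any single
cell can be re-run in isolation and CLI runs write a manifest (seed,
configuration, version) next to each result table. The test suite runs
the noise-free protocol at its full size (41 distances × 10 repetitions
× both regularizations, $n \in \{2, 100\}$) and the noise protocols at
$d = 4$ with 10 repetitions; unit tests use miniature instances (tens
of samples, $n \le 8$) chosen so the whole suite stays in the
minutes range. The dense grid-search oracle that cross-checks the
solvers is restricted to $n = 2$, where exhaustive coverage of
$(w, t)$ is feasible.

## Known limitations

* The class-wise noise regime at small $n$ has genuinely high
  run-to-run variance (the interquartile ranges span tens of accuracy
  points); pooled means from 10 repetitions inherit several points of
  seed-to-seed spread.
* The simplex solver is dense and intended for the benchmark scale
  (hundreds of variables); for $n \gg 10^3$ features an interior-point
  or decomposition method would be the right tool.
* `vc_upper_falsify()` cannot prove an upper bound for the continuous
  classes; it only reports that random search failed to break it.
* Only binary classification is supported; the pairwise class is
  restricted to exactly two active features by its definition, which
  caps its accuracy in high-dimensional problems where no single pair
  separates well.
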