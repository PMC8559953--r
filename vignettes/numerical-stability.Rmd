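---
title: "Quantifying numerical uncertainty in connectome pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying numerical uncertainty in connectome pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstab)
```

# The problem

A structural connectome is estimated from diffusion measurements by a long
chain of floating-point computation. Each operation rounds; rounding error
of order one unit-in-the-last-place (ulp) is unavoidable and, in long or
ill-conditioned chains, can amplify into visible differences between two
nominally identical executions. `connstab` measures how much of a
brain-network analysis is robust to that error: it injects controlled
ulp-scale noise into a perturbable reconstruction pipeline, produces a
*distribution* of connectomes per sample, and propagates that distribution
through the standard analytical layers (network comparison, graph
features, phenotype classification).

# The perturbation model

## Monte Carlo Arithmetic

Each instrumented operation is made inexact at a virtual precision $t$:

$$\mathrm{inexact}(x) = x + 2^{e_x - t}\,\xi, \qquad
  \xi \sim \mathcal{U}(-\tfrac12, \tfrac12),$$

where $e_x$ is the base-2 exponent of $x$ under the convention
$2^{e_x-1} \le |x| < 2^{e_x}$, so the perturbation targets the least
significant bit at precision $t$. Exact zeros are preserved: zero has no
exponent, and perturbing it would create spurious edges in sparse
adjacency structures. Two modes exist:

* **RR (random rounding)** — perturb the *result* of each operation,
  exposing accumulated round-off (the default everywhere);
* **PB (precision bounding)** — perturb each *operand* before the exact
  operation, limiting effective input precision.

Draws are i.i.d. per scalar result (RR) or per scalar operand (PB).
Streams are counter-seeded per (simulation index, op), so simulations are
statistically independent yet bit-reproducible: an identical
(profile, seed, index) triple reproduces an identical output.

## Why pipeline simulations default to $t = 52$, not 53

The natural "machine error" precision for doubles is $t = 53$. But in a
carry performed in native double precision, the injected noise
$|2^{e_x-53}\,\xi| < 2^{e_x-54}$ is strictly below half an ulp of every
value in the binade, so round-to-nearest *always* returns the original
value (only exactly at powers of two can the last bit flip, because the
spacing below is half as large). Compiler-level instrumentation escapes
this by adding the noise to the exact, pre-rounding result in extended
precision. An operator-dispatch simulation in R has no extended carry, so
`inexact()` at $t = 53$ is (correctly) a near-fixed-point — the unit tests
pin this behaviour — and pipeline-level simulations default to $t = 52$,
the finest virtual precision whose perturbations survive IEEE-754 double
rounding. This is one simulated bit coarser than compiler-level tooling
with the same last-bit semantics; `mca_profile()` keeps $t = 53$ as its
contract-level default and accepts any $t \ge 1$ (use 24 to model
single-precision storage).

## Dense vs. sparse instrumentation

Operations carry a layer tag. BLAS/LAPACK-style kernels (Gram matrices,
normal-equation solves, predictions, averaging) are `core-numeric`; data
handling (measurement reads, edge accumulation, graph normalization) is
`data-layer`. The **dense** density perturbs everything; the **sparse**
density perturbs only data-layer ops, and models them as *data at rest*:
one frozen ulp perturbation per stored measurement per simulation, reused
coherently at every read, while dense draws fresh noise per call. By
construction the sparse-perturbed op set is a strict subset of the dense
one (a tested invariant, via `mca_trace()`).

**Known limitation.** With nested op sets and independent per-op noise, a
dense execution is distributionally a sparse execution plus extra
independent noise, so dense output variance can never fall below sparse.
Compiler-level studies observe the opposite *magnitude* ranking (dense far
more stable than sparse) because their two instrumentations touch
different library layers with different amplification paths — a
configuration that contradicts literal op-set nesting and is not
representable in this desk-scale model. We measured the gap concretely:
at $t = 52$ the deterministic pipeline gives mean %Dev $1.5\times10^{-13}$
(dense) vs $0.8\times10^{-13}$ (sparse), the probabilistic one
$2.6\times10^{-11}$ vs $0.9\times10^{-11}$. The package therefore makes no
claim about the dense/sparse stability *ordering*; both modes are reported
side by side, and the subset invariant is what the tests assert.

# The synthetic cohort: a stated world

No MRI data enters the package. The generator emulates the statistical
structure the analysis assumes:

* **Design presets.** Repeated measures: 25 subjects × 2 sessions × 2
  subsamples (100 samples); cross-sectional: 100 × 1 × 1; both with 128
  directional + 9 baseline measurements and 20 perturbed simulations per
  execution, so each preset's grid counts
  $100 \times 2\ \text{pipelines} \times 2\ \text{modes} \times 21 = 8400$
  executions. (Source texts disagree between 10 and 20 simulations for the
  repeated-measures arm; the 8,400 total requires 20, which both presets
  adopt.) A `smoke` preset (4 × 2 × 2, 24 + 3 volumes, 2 sims) runs end to
  end in seconds.
* **Hierarchy.** Each subject has a latent 6-dimensional node-factor
  matrix (spread `sigma_subject = 1.0`); each session adds a bias field
  (`sigma_session = 0.3`); each measurement volume adds i.i.d. noise
  (`sigma_subsample = 0.1`). The 1.0 : 0.3 : 0.1 ordering reproduces the
  qualitative subjects > sessions > subsamples deviation ranking; the
  monotone recovery of `sigma_session` is an acceptance criterion.
* **Subsampling.** Odd/even directional measurements plus all baselines,
  so a 128 + 9 session yields two realistic 73-measurement acquisitions
  that partition the directional set.
* **Phenotype.** A scalar latent covariate $z$ is embedded in the factors
  (`signal_scale = 0.5`) and labels are drawn through a logistic link
  (`assoc = 1.5` log-odds per SD of $z$). These defaults put achievable
  5-fold CV accuracy near 0.68 (range ≈ 0.61–0.76 over seeds) — the
  intended 0.65–0.75 regime — and `assoc = 0` makes labels independent of
  connectivity (a null that is also an acceptance criterion).
* **Reconstruction.** A deterministic-given-seed chain stands in for
  tractography: baseline normalization, a 7-parameter per-node signal
  model fit by normal equations, outer-product edge accumulation, a
  residual quality pass, clipping, symmetrization, and sum normalization —
  every step routed through the instrumentation layer. The `det` variant
  fits once; the `prob` variant averages 5 bootstrap resamples of the
  directional volumes with an internal random state that is fixed for all
  analyses, so repeated unperturbed executions are bit-identical (tested
  byte-for-byte on written files).

What a green test does **not** establish: the generator has no diffusion
physics, no streamlines (connection length uses Euclidean node-coordinate
distances as a geometric proxy), no registration or motion artefacts, and
its noise amplification (~$10^2$ instrumented ops) is many orders below a
real pipeline's ~$10^{12}$ flops. Absolute deviation magnitudes are
therefore not comparable to real-data studies; orderings and calibration
properties are the meaningful outputs.

# Stability quantification

* `percent_deviation(A, B)` implements the Frobenius-norm ratio
  $\|A-B\|_F / \|A\|_F$. (A printed variant of this formula omits the
  square roots; the norm-ratio reading matches its verbal definition and
  anchors the 0/1 cases — identical graphs give 0, the empty graph
  gives 1.)
* `significant_digits()` uses the $n-1$-denominator sample standard
  deviation (the common reading of "unbiased"; no $c_4$ correction),
  caps at 15.7, and maps $\sigma = 0 \mapsto 15.7$,
  $\mu = 0, \sigma > 0 \mapsto 0$. Per-edge summaries average over all
  upper-triangle entries including structural zeros (flag
  `include_zero_edges`).
* `group_stability()` enumerates unordered pairs with the reference on the
  A-side: MCA pairs are reference-vs-simulation within one sample;
  subsample/session/subject pairs compare reference executions within one
  pipeline/mode stratum, removing tool noise from acquisition-level
  comparisons.

# Discriminability

`discriminability()` counts, over every (anchor, within-class partner,
cross-class observation) triple, the event
$d_{\text{within}} \le d_{\text{cross}}$; ties count as successes, so
duplicated within-class observations never lower the score, and the
statistic is invariant under any strictly increasing transform of the
distance (both tested, plus equality with an $O(n^3)$ brute-force oracle).
Euclidean distance on vectorized upper triangles is the default.

Hypotheses H1/H2/H3 fix the class variable (subject; session | subject;
subsample | subject, session), assemble observations over the comparison
level (session, subsample, or MCA simulations), evaluate each independent
observation set separately and aggregate the mean. Permutations respect
the exchangeability block (global; within subject; within subject ×
session) and are applied jointly across sets;
$p = (1 + \#\{D_{\pi} \ge D_{\text{obs}}\}) / (1 + n_{\pi})$.

Two chance conventions coexist: the reported `chance` is
$1/\#\text{classes}$ (the convention used in test–retest tables), while
the rank-based statistic's exchangeable null centres at 0.5 regardless of
class count. Both are reported (`chance`, `chance_empirical`), and the
scaled score uses the empirical null:
$(D - \hat c)/(1 - \hat c)$, exposed as a pluggable `scale_fun` because
the original scaling formula for this statistic is not available; raw $D$
is always reported alongside. Cross-condition families use paired Wilcoxon
signed-rank tests with Benjamini–Hochberg correction at $q = 0.05$ (the
correction method is a package choice; all-zero difference pairs return a
degenerate sentinel outside the correction family).

# Graph features

Weighted definitions throughout; path-based measures use edge length
$1/w$ (the standard weighted-connectome convention). Clustering is the
Barrat coefficient; modularity is greedy modularity maximization on the
largest connected component under a stored seed (the community search is
an algorithmic choice — oracle checks recompute the modularity *value* of
the returned partition from the defining formula); assortativity is the
Pearson correlation of endpoint strengths over both edge orientations
(NaN on degree-regular graphs, which is mathematically unavoidable).
Disconnected graphs: unreachable pairs contribute zero efficiency and are
excluded from mean path length. Feature CDFs are evaluated on a fixed
per-feature grid — 0 to the 99.5th percentile of the reference cohort,
100 points — pooled within subject and averaged across subjects with
standard errors; the five moments (sum, mean, variance, skew, *excess*
kurtosis) are computed per simulation and their significant digits across
simulations quantify moment stability. Z-score false-positive rates are
deliberately uncorrected (they measure the perturbation-induced FPR, not
a hypothesis), and zero-variance subjects are flagged perfectly stable
and excluded.

# Phenotype model

PCA with the component count chosen as the smallest $N$ whose cumulative
explained-variance fraction, averaged over the folds' training sets,
exceeds 90% (full rank with a warning if unreachable); a ridge-penalized
logistic classifier (IRLS, fixed $\lambda = 1$, unpenalized intercept) on
the training-fold scores, standardized on the training scale so the
penalty is commensurate with the connectomes' sum normalization.
Stratified $k$-fold CV ($k \in \{2, 5, 10, n\}$) with a fixed assignment
seed; accuracy and F1 (binary positive class; macro-averaging is a flag
away) are pooled over held-out predictions rather than averaged per fold
(the aggregation is unstated in the source convention; pooling is
documented here). `resampled_performance()` redraws one perturbed
connectome per subject per repeat (default 20) with the fold assignment
held fixed, so zero-variance perturbations reproduce the reference run
exactly and performance spread is attributable to the perturbations alone.
No test-fold information reaches a fitted model (asserted by corrupting
held-out rows under a pinned component count).

# Numerical choices and degenerate inputs

* Sub-seeds derive from a 31-bit multiplicative mix (`derive_seed`), so
  all seeds stay below $2^{31}$ and streams never touch the session RNG.
* The normal equations carry a $10^{-8}$ ridge; design rank requires
  $\ge 8$ measurement rows per subsample (the smoke preset uses 24 + 3
  volumes for this reason).
* All-zero measurement sets return an empty graph with a warning;
  all-zero reference matrices make `%Dev` error (undefined reference);
  zero-variance triangles make the Pearson correlation `NA` with a
  warning; digit estimates need $\ge 2$ executions (`NA` per group
  otherwise).
* Elementwise RR noise on the final normalization is not symmetric, so the
  builder re-mirrors the matrix once, uninstrumented: connectome symmetry
  is structural, and holds bitwise for every perturbed execution.

# Orchestration

`experiment_config()` (YAML round-trip, tested bit-stable) drives
`run_experiment()`: cohort → reconstruction → stability →
discriminability grid (6 MCA comparisons × pipelines × modes + 3
reference comparisons × pipelines = 30 tests on the full grid) → feature
moments → phenotype model. Stages are failure-isolated: a failing stage is
logged and its dependents are marked unavailable. Every output file name
carries an FNV-1a hash of the configuration; reference connectome files
are byte-identical across reruns. The CLI (`inst/cli/connstab`, or
`cs_cli()`) exposes `generate | perturb | stability | discrim | features |
model | all`.

# Known limitations

* The dense/sparse *magnitude* reversal observed with compiler-level
  instrumentation is out of reach under op-set nesting (see above); the
  package reports both modes without asserting an ordering.
* $t = 53$ is a near-fixed-point in a double-precision carry; last-bit
  simulations use $t = 52$.
* Real-data headline numbers (test–retest discriminability tables,
  BMI-classification accuracy intervals) depend on MRI data and full
  tractography and are not reproduced; the synthetic cohort covers their
  qualitative structure only.
* The scaled discriminability score is a package definition (empirical
  null anchoring), not the original derivation, and is pluggable.
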