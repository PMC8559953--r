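# connstab

Numerical-uncertainty analysis for brain-network (structural connectome)
pipelines, via simulated **Monte Carlo Arithmetic** (MCA).

Complex neuroimaging pipelines carry machine-precision rounding error whose
downstream consequences are rarely measured: two numerically equivalent
executions can yield measurably different brain graphs, features, and even
study conclusions. `connstab` is for methodologists and pipeline developers
who want to *quantify* that uncertainty. It simulates ulp-scale random
perturbations through a synthetic connectome-reconstruction pipeline and
measures their impact at three levels: the networks themselves, their
graph-theoretic features, and a downstream brain-phenotype classification.

## The model

**Perturbation.** Every instrumented floating-point operation is made
inexact at a virtual precision `t`:

    inexact(x) = x + 2^(e_x - t) * xi,    xi ~ Uniform(-1/2, 1/2)

with `e_x` the base-2 exponent of `x` (`2^(e_x-1) <= |x| < 2^(e_x)`).
*Random Rounding* (RR) perturbs each operation's result; *Precision
Bounding* (PB) perturbs its operands. The *dense* instrumentation perturbs
every operation; the *sparse* one only data-layer operations (data reads,
graph building), modelled as data-at-rest noise — a strict subset of the
dense op set. At `t = 53` a pure double-precision carry rounds all noise
away (it is below half an ulp), so pipeline simulations default to
`t = 52`, the finest precision whose perturbations survive IEEE-754
rounding (see the methods vignette).

**Stability metrics.** For a reference connectome `A` and a perturbed `B`:

* normalized percent deviation `%Dev = ||A - B||_F / ||A||_F`;
* Pearson correlation of the vectorized upper triangles;
* significant digits per edge, `s' = -log10(sigma / |mu|)` across repeated
  executions, capped at 15.7 (the 64-bit bound);
* **discriminability** `D = Pr( ||g_ij - g_ij'|| <= ||g_ij - g_i'j'|| )`,
  the probability that within-class distances rank below cross-class
  distances, with block permutation tests for three hypotheses (H1:
  subjects distinct; H2: sessions distinct within subject; H3: subsamples
  distinct), Wilcoxon signed-rank cross-condition comparisons and
  Benjamini–Hochberg correction;
* univariate/multivariate graph features (edge count, Barrat clustering,
  global efficiency, modularity, assortativity, path length; degree,
  clustering and betweenness distributions), their five moments, and
  Z-score false-positive rates;
* a PCA (+>90% explained variance) + ridge-logistic phenotype classifier
  under perturbation resampling.

No external data is required: a seeded synthetic cohort emulates the
hierarchical design (subjects × sessions × odd/even subsamples, with
subject ≫ session ≫ subsample variance components and a binary
BMI-like phenotype). External connectomes (dense TSV or GraphML) can be
evaluated with the same metrics.

## Worked example

```r
library(connstab)

co  <- generate_cohort(design_preset("smoke"), n_nodes = 8, seed = 2)
set <- reconstruct_cohort(co, base_seed = 2)   # references + RR sims, t = 52
for (cl in c("mca", "subsample", "session", "subject"))
  print(group_stability(set, cl))
run_hypothesis(set, "H1", pipeline = "det", mode = "dense",
               comparison = "session", n_perm = 200, seed = 2)
```

prints

```
<cs_stability> class = mca: 128 pairs, median %Dev = 3.35e-13, mean edge digits = 14.07
<cs_stability> class = subsample: 32 pairs, median %Dev = 0.423, mean edge digits = 6.85
<cs_stability> class = session: 64 pairs, median %Dev = 0.571, mean edge digits = 5.05
<cs_stability> class = subject: 384 pairs, median %Dev = 1.1, mean edge digits = 0.30
<cs_discrim> H1 (session, det/dense, reference): D = 1.000, chance = 0.25 (empirical 0.501), scaled = 1.000, p = 0.004975 [2 sets, 200 perms]
```

Read: tool-induced (MCA) noise sits ten orders of magnitude below
acquisition-level differences (median %Dev 3e-13 vs 0.42), comparisons
lose significant digits as groups become more distinct (14.1 → 0.3 —
across subjects only the order of magnitude of an edge weight is
trustworthy), and subjects remain perfectly discriminable from their
networks (D = 1.0 against a 0.25 chance convention, permutation p ≈ 0.005).

The full experiment grid (both study presets yield
`count_executions(design_preset("repeated")) == 8400` executions and
`count_tests() == 30` hypothesis tests) runs end to end with:

```sh
inst/cli/connstab all --preset smoke --seed 1 --out /tmp/connstab-out
```

(subcommands: `generate`, `perturb`, `stability`, `discrim`, `features`,
`model`, `all`; configuration via `--config experiment.yaml`).

## Documentation

The methods vignette (`vignettes/numerical-stability.Rmd`) documents the
perturbation model and its double-precision subtleties, the synthetic
cohort's stated world and what it does and does not emulate, all tunable
parameters, and known limitations (notably why the nested sparse ⊂ dense
instrumentation model cannot reproduce the dense-more-stable-than-sparse
magnitude reversal seen with compiler-level instrumentation).
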