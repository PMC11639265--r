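---
title: "Metric-driven immune-hybrid training of logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-driven immune-hybrid training of logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csadelr)
```

## The model and why it is trained without gradients

`csadelr` fits a plain binary logistic-regression classifier,
$p_i = \sigma(w \cdot x_i + b)$, but treats training as a derivative-free
search over the full parameter vector $\theta = (b, w)$ inside a box
$[lb, ub]^D$, $D = N + 1$. The point of doing so is that the training
objective no longer needs to be differentiable: candidate vectors can be
scored directly by the quantity one actually reports — F1 or the Matthews
correlation coefficient on the rounded predictions — or by smooth
surrogates (inverse mean residual error $1/(1+e)$, inverse summed
cross-entropy $1/(1+J)$). All four fitnesses are finite and maximized;
the transform $1/(1+\cdot)$ maps an unbounded, minimized cost onto
$(0, 1]$ without changing its ordering.

Two numerical choices make the metric fitnesses total functions: F1 is
defined as 0 when there are no true positives, and MCC as 0 whenever any
factor of its radicand is 0. Degenerate candidates (e.g. constant
predictors) therefore get a well-defined, poor score instead of `NaN`,
which keeps the optimizer's comparisons deterministic. The cross-entropy
cost is the *summed* form (not the mean — the transform is monotone
either way) with probabilities clipped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 10^{-12}$, so saturated predictions keep the cost finite.

## The hybrid search loop

One iteration of `fit_csa_de_lr()` is clonal selection with the
hyper-mutation step replaced by differential evolution:

* **Cloning.** Each of the `P` antibodies is copied `alpha` times into a
  contiguous block, giving `P * alpha` clones.
* **DE/rand/1/bin over clones.** For a clone owned by antibody $j$, three
  *distinct* antibodies other than $j$ are drawn without replacement, and
  one uniformly random clone of each serves as donor. The trial vector
  $c_1 + sf\,(c_3 - c_2)$ replaces the clone's coordinates where a
  per-coordinate uniform satisfies $u \le cr$; replaced coordinates are
  clipped to the box. Two deliberate fidelities to the pseudocode this
  implements: there is **no forced crossover coordinate** (a clone may
  pass through unchanged), and mutation happens **in place**, so clones
  processed later can draw already-mutated donors.
* **Selection.** Each antibody is replaced by its best clone only under
  *strict* fitness improvement; ties keep the parent, and argmax ties
  break toward the lowest index. This makes the per-antibody fitness, and
  hence the population best, non-decreasing.
* **Receptor editing.** The `round(P * B)` worst antibodies (stable
  ascending sort) are replaced by fresh uniform draws and scored
  immediately. Because `round(P * B) < P` is enforced, the incumbent best
  always survives, preserving the monotone best-fitness trace.

Rounding of `P * B` is half-away-from-zero. Base R's `round()` is
banker's rounding, which would make the replaced-count platform-lore
rather than arithmetic; a dedicated helper pins the common-sense reading
(0.5 → 1) and documents it for replication.

### Budget semantics

The loop is governed by a *maximum evaluation number* `MEN`, not an
iteration count. Every scored candidate row advances a counter; the
initial population's scoring is computed and then the counter is reset to
zero, exactly as the procedure this reproduces orders those two steps —
so `MEN` excludes the first `P` evaluations. The guard sits at the top of
the loop: each iteration of the hybrid costs exactly
`P * alpha + round(P * B)` evaluations, and training stops at the first
check where the counter has reached `MEN`. The source material never
states the budget it used for its experiments; the package default is
`MEN = 30000`, which on the benchmark-scale problems is comfortably past
the observed convergence plateau.

### Randomness and determinism

Each fit call seeds one RNG stream from `config$seed` (restoring the
caller's RNG state afterwards) and consumes it in a fixed, documented
order — initialization, then per clone: donor picks, clone offsets,
crossover uniforms, then editing draws. Identical inputs and seed give
bit-identical trained models; the test suite asserts this, and the
cross-validation harness derives per-fold seeds as `seed * 1000 + fold`.

## The ablations

`fit_csa_lr()` is classic CLONALG: each clone attempts a segment-reversal
("inverse") mutation — random positions $j, l$ with $|j - l| > 2$, the
inclusive segment reversed — accepted only under strict improvement,
otherwise a pair-swap mutation under the same rule. Both are coordinate
permutations, so a clone's coordinate multiset is invariant; all movement
through parameter *values* comes from receptor editing and re-selection.
For $D < 4$ the reversal constraint is unsatisfiable and the operator
falls back to the pair swap. Each attempted mutant costs one counted
evaluation; the re-selection assignment is unconditional as printed,
which is equivalent to strict improvement because clones start as parent
copies and only strictly better mutants are accepted.

`fit_de_lr()` is plain generational DE/rand/1/bin with the same
no-forced-coordinate crossover, strict greedy replacement (population
fitness pointwise non-decreasing), and `P` evaluations per generation.

The fitness used by the published ablation rows is not stated in the
source material; the package default for all trainers is `f1`,
configurable per call.

## Preprocessing and evaluation protocol

Loaders parse the four UCI dialects from delimited text, drop any row
containing the literal `'?'` marker (listwise deletion — the stated
instance counts imply no imputation), drop ID columns, and binarize
targets (heart stage 0 vs 1–4; labels 1/2 → 0/1; benign/malignant codes
2/4 and B/M → 0/1). The heart-stage 0-vs-rest binarization is the
standard convention for that table and is documented here because the
source never states it. Categorical heart features (`cp`, `thal`, …)
stay ordinal: the published per-feature weight analyses show exactly 13
weights, which rules out one-hot expansion.

Scaling is fitted on training rows only and applied to both partitions:
min-max to $[0,1]$ for the three integer-coded tables, z-score (with
*population* standard deviation) for the diagnostic breast-cancer table.
Constant features map to 0. Test rows may leave $[0,1]$; they are
deliberately not clamped.

Cross-validation uses 10 folds with sizes within one instance. Folds are
stratified by default — the low fold-to-fold variance of the published
tables suggests balanced folds, and stratification is the conservative
reading — with a flag for plain shuffling. Per-metric summaries use the
population standard-deviation formula (divisor $k$); the source does not
say which convention it used, so the choice is documented rather than
inferred. Table formatting follows the published convention: percentages
to two decimals for accuracy/F1/MCC/ROC-AUC, raw rates to three for
FNR/FPR.

ROC-AUC is rank-based (ties at half credit). It is computed from the
continuous probabilities by default, but a `"hard"` option ranks the
rounded labels instead, because the published ROC-AUC values track
$1 - (FNR + FPR)/2$, suggesting hard labels were used there. Both
readings are supported; neither is silently preferred when reporting.

The error-based fitness defaults to *squared* residuals — the only
formula actually printed in the material this reproduces — even though
that metric is named "MAE" there; `error_mode = "absolute"` provides the
named variant. Which of the two produced the published error-optimized
columns is not decidable, so both are first-class.

## Synthetic data: what a green test establishes

`make_logistic_data()` draws features uniformly on $[0,1]^d$ (mirroring
the post-min-max scale the optimizers see on real tables) and labels
either by Bernoulli draws from $\sigma(b + w \cdot x)$ or
deterministically by thresholding — the latter makes the generating
vector an exact separator, and an optional `margin` discards instances
within a band around $p = 0.5$ to guarantee a fat separator for
convergence tests. The generator does **not** emulate the real tables'
feature distributions, integer coding, class imbalance, or correlation
structure. A green convergence test therefore establishes that the
optimizer can drive a linear decision boundary to a stated training
accuracy on clean, bounded, independent features — not that it reproduces
the published benchmark means, which depend on the real UCI files.

Convergence and invariant tests need a concrete configuration; the
generic choice, made once, is `lb = -16, ub = 16, P = 40, alpha = 3,
B = 0.1, sf = 0.5, cr = 0.9` — mid-range values inside the published
tuning ranges. The parameter-recovery test fixes the generating vector
`(-2, 4, -3, 2)` (a clearly directional separator on $[0,1]^3$) and
measures cosine similarity on the full parameter vector, since the
decision boundary is determined by $(b, w)$ up to positive scaling.

## Tuning and comparison

`random_search_tune()` replaces the Bayesian/TPE tuner used in the source
experiments with seeded uniform random search over the same ranges; the
objective defaults to mean 10-fold CV accuracy (the original tuning
objective is unnamed) and is configurable to any of the six metrics.

`wilcoxon_compare()` implements the two-sided Wilcoxon signed-rank test
with an exact branch for $n \le 25$ after zero-difference removal. The
exact null distribution is built by convolving over the *doubled*
midranks (integers even under ties), so the branch stays exact with tied
absolute differences — the reason this is implemented in-package rather
than delegated to `stats::wilcox.test`, which abandons exactness on
ties. Larger samples use the normal approximation with continuity
correction and the standard tie correction. One property worth noting:
appending a mirrored difference pair $(+d, -d)$ weakens significance
only when $d$ outranks the existing differences; a low-rank mirrored
pair can sharpen the two-sided tail. The tests pin both behaviours to
full $2^n$ enumeration.

The multi-seed comparison protocol runs each algorithm over seeds
$1..30$, pairs the per-seed 10-fold means by seed, and feeds them to the
signed-rank test — the only pairing the published comparison layout
supports.

## Known limitations

* The published benchmark means (e.g. Statlog accuracy 88.15%) are not
  reproduced offline: they require the four UCI downloads. The loaders,
  presets and protocol are in place, so a networked environment can run
  them directly.
* No parallel population evaluation or self-adaptive `sf`/`cr` control.
* Binary targets only; no imputation (rows with missing markers are
  deleted, matching the stated instance counts).
* CLONALG's permutation-only hyper-mutation explores poorly in spaces
  where coordinates have heterogeneous scales; that is a property of the
  reproduced ablation, not a defect of the implementation.
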