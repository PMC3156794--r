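---
title: "Differential C3NET networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential C3NET networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dc3net)
```

## The problem and the model

Given expression matrices for two conditions of the same biological
system — a *test* condition such as tumor tissue and a *control* such as
normal tissue — we want the direct gene-gene dependencies that are
specific to each condition, and those shared by both. "Direct" here
means an expression dependency between two genes that is not mediated by
a third gene in the dataset.

The pipeline has three stages.

**1. Preprocessing.** The two matrices are restricted to their shared
genes (`align_conditions()`; with `keep_all = TRUE` the non-shared genes
are only reported, so they can be highlighted rather than dropped) and
each gene's values are replaced by their empirical-CDF positions
`rank/(n+1)` with average ranks for ties (`copula_transform()`). The
divisor `n + 1` (rather than `n`) keeps every transformed value strictly
inside (0, 1), so the downstream Gaussian machinery never sees a
boundary value; constant genes map to all-0.5 rows and carry zero MI
instead of erroring. Because the transform is per-gene, its order
relative to gene alignment is irrelevant; we transform after aligning.
The package assumes the inputs are already normalized (RMA, TMM, or
whatever fits the platform); raw-array processing is out of scope.

**2. Per-condition network inference.** Mutual information for a gene
pair is estimated parametrically as `MI = -0.5 log(1 - r^2)` nats, with
`r` the Pearson correlation of the copula-transformed rows. On the
copula scale this estimator is invariant to monotone per-gene
transformations of the raw data; its known blind spot is symmetric
non-monotone dependency (a centred quadratic gives `r` near 0 and hence
MI near 0 — see the generator discussion below). `1 - r^2` is clamped
at `1e-12`, so duplicated probes produce a large finite MI
(about 13.8 nats) rather than infinity; the clamp sits far below any
biologically meaningful resolution. A significance threshold comes from
a permutation null (`significance_threshold()`): in each of `B` rounds
every gene's sample order is permuted independently, MI is estimated
for all pairs (all of them when there are at most 100 genes, otherwise a
seeded random subset of 10,000 per round), and the pooled `1 - alpha`
quantile is returned. Pooling across pairs matches the single global
threshold the causal-core step applies; a per-pair threshold would
contradict the method's one-cut-off design. Users who prefer a fixed
cut-off can set `mi_threshold` in `dc3net_params()` and bypass the
permutation test entirely. The conservative causal core rule
(`c3net()`) then keeps, per gene, only the edge to its maximum-MI
significant partner; the union of picks over genes, deduplicated as
unordered pairs, is the condition network. Edge ties at the row maximum
are broken towards the lexicographically smallest partner identifier —
deterministic, reproducible by an independent oracle, and essentially
irrelevant on continuous data where exact ties have measure zero.

**3. The decision filter.** Each MI matrix is ranked row-wise in
descending order (rank 1 = strongest partner of that row; competition
ranking, so tied strong values all count as strong — the conservative
direction for the difnet test). A Tnet edge `(gA, gB)` is *test-specific*
only if, in the control matrices, all four of these hold strictly: the
rank of the pair exceeds `rankdif` in row `gA` **and** in row `gB`, and
its MI falls below `mi_rate` times the row maximum in row `gA` **and**
in row `gB`. It is *common* if the reversed comparisons (rank smaller
than `rankdif_common`, MI greater than `mi_rate_common` times the row
maximum) hold in **at least one** direction. The control difnet applies
the same four-condition test with the roles of the conditions swapped.

Three readings of the filter were genuinely open and are fixed here as
package design choices:

- `mi_rate_common = 0.85` is interpreted as a *rate* of the row-maximum
  MI, consistent with the only definition the filter gives for its MI
  cut-off (`MIdif = MIrate × row max`). A `common_absolute` switch
  provides the absolute-MI reading for users who want it.
- The OR of the common filter joins the two *per-direction (rank AND
  MI) conjunctions*. The alternative — OR across all four atomic
  clauses — would admit edges passing only a rank test with arbitrarily
  low MI, which contradicts the filter's intent.
- The test difnet and the common network are computed independently
  from Tnet rather than sequentially. The per-edge conditions do not
  reference the other output, and with `rankdif_common <= rankdif` the
  two are provably disjoint; Tnet edges satisfying neither land in
  `undecided_test`, realizing the deliberate decision gap around the
  cut-off boundaries.

All comparisons are strict, so boundary equality always fails the test;
this matches the "greater than"/"less than" wording of the filter and
makes the behaviour at ties unambiguous.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `rankdif` | 2000 | minimum (worse-than) rank in the other condition, both directions, for a condition-specific call |
| `mi_rate` | 0.6 | difnet MI cut-off as a fraction of the other row's maximum MI |
| `rankdif_common` | 200 | maximum (better-than) rank for a common call, either direction |
| `mi_rate_common` | 0.85 | common MI cut-off as a fraction of the row maximum |
| `alpha` | 0.01 | significance level of the permutation null |
| `B` | 30 | permutation rounds |

The rank cut-offs are *row positions*, so their natural scale is the
gene count: `rankdif = 2000` was tuned for a dataset of roughly 12,000
genes (a sixth of the genome-wide row length) and is meaningless for a
50-gene matrix whose rows only have 49 positions. When the package's
own synthetic studies run at 50 genes they rescale the same
proportions: `rankdif = 8` (~G/6) and `rankdif_common = 2` (~G/25, the
smallest strict value that still demands rank 1). The MI-rate cut-offs
are already relative and transfer across scales unchanged. Increasing
`rankdif` or decreasing `mi_rate` makes the difnet strictly harder to
enter (the package tests this monotonicity), so the two dials trade
difnet size against confidence in condition-specificity.

## The synthetic generator

`simulate_condition_pair()` provides ground truth the real data cannot:
it plants `n_common` dependencies active in both conditions plus
`n_test_only` and `n_control_only` condition-specific ones, drawn from
a random spanning tree of the gene universe so each condition's active
set is a forest. A forest makes "direct interaction" unambiguous at
generation time — there are no indirect paths among planted edges to
argue about — while shared parents in multi-child trees still produce
the indirect-correlation confounding that makes inference non-trivial.
Every gene starts as standard normal noise; each active edge adds
`effect * f(parent)` plus `N(0, noise_sd)` noise to its child along the
attachment order, with `f` the identity for linear edges and the
centred quadratic `x^2 - mean(x^2)` for a `nonlinear_fraction` of them.
The quadratic is chosen *because* it defeats linear correlation: the
copula-plus-Gaussian estimator largely misses those edges, and the
recovery numbers are meant to show that estimator limitation rather
than hide it.

The reference study conditions are 50 genes, 100 samples per condition,
15 common + 10 test-only + 10 control-only edges, `effect = 1`,
`noise_sd = 0.5`, 20% quadratic edges — small enough that a full
pipeline run takes well under a second and a 20-seed study a few
seconds, yet large enough that the recovery comparisons are not
degenerate. What passing those studies shows is that the filter's logic
separates planted condition-specific from shared dependencies under the
generator's assumptions: independent Gaussian backgrounds, forest-true
structure, equal sample sizes. What it does not show is robustness to
the features of real expression data the generator omits — heavy-tailed
noise, batch effects, co-regulated modules with dense (non-forest)
structure, probe-level artefacts, unequal group sizes — so the numbers
should be read as a verification of the machinery, not a performance
claim for any particular biological dataset.

```{r recovery, eval = FALSE}
rs <- recovery_study(seeds = 1:20)
summary(rs$frac_test_only_in_test_difnet - rs$frac_test_only_in_control_difnet)
```

## Numerical and degenerate-input choices

- MI is reported in natural-log units (nats) throughout; divide by
  `log(2)` for bits.
- Zero-variance genes: correlation is defined as 0, MI as 0; they rank
  last in every row and never form edges.
- The diagonal of an MI matrix is zero by definition (self-interactions
  ignored) and receives the sentinel rank `G` in the rank matrix, so it
  can never outrank an off-diagonal entry.
- Rank ties use competition ("min") ranking; C3NET row-maximum ties
  break lexicographically; `top_edges()` ties break by pair name. Every
  tie rule is deterministic, so identical inputs and seed give
  byte-identical output files (`dc3net_run_dir()` writes MI with
  `%.10g`, which round-trips the comparisons used downstream).
- An empty gene intersection between the conditions is an error; an
  edge set too large for a forest over the requested genes is an error
  in the generator.
- Permutation and simulation randomness is scoped: package functions
  take explicit seeds and restore the caller's RNG state.

## Known limitations

- Exactly two conditions; multi-condition designs require running the
  filter pairwise.
- The C3NET core recovers at most one edge per gene — the strongest
  "causal core" — so dense neighbourhoods are under-called by design.
- The Gaussian estimator misses symmetric non-monotone dependencies
  (see the quadratic edges above); no alternative MI estimators
  (B-spline, k-NN, Miller–Madow) are provided.
- The permutation null is exchangeable across samples; time-series or
  paired designs violate that assumption.
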