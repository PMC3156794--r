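# dc3net

Differential gene-network inference from two expression conditions.

Gene networks inferred separately from, say, tumor and normal expression
data overlap heavily; the biologically interesting part is usually where
they *differ*. `dc3net` infers a direct-interaction network for each
condition with the conservative causal core (C3NET) rule and then applies
a rank/MI decision filter that splits the test-condition network into
three parts:

- **test difnet** — interactions present in the test condition whose
  signal in the control condition is weak (the "disease network"),
- **common network** — interactions strongly supported in both
  conditions,
- **undecided** — interactions near the cut-off boundaries, deliberately
  left out of both calls.

The control-specific difnet is obtained by swapping the roles of the two
conditions. The package is aimed at systems-biology analyses of
two-condition microarray or RNA-seq matrices that have already been
normalized.

## Method

For each condition the genes-by-samples matrix is copula-transformed
(each gene's values replaced by empirical-CDF positions
`rank/(n+1)`), and mutual information is estimated for every gene pair
with the parametric Gaussian estimator

```
MI(x, y) = -1/2 * log(1 - r^2)        [nats]
```

where `r` is the Pearson correlation of the transformed rows. An MI
significance threshold is obtained from a permutation null (each gene's
samples permuted independently; the `1 - alpha` quantile of pooled null
MI values). The C3NET step then keeps, for every gene, only the edge to
its maximum-MI significant partner; the union of these picks is the
condition's network (`Tnet`, `Cnet`), so a network over `G` genes never
has more than `G` edges.

Each MI matrix is also ranked row-wise in descending order (rank 1 = the
row's strongest partner). An edge `(gA, gB)` of `Tnet` enters the **test
difnet** only if all four of these hold in the *control* matrices, with
strict comparisons:

1. rank of `(gA, gB)` in row `gA` is greater than `rankdif`;
2. control MI of `(gA, gB)` is below `MIrate` times row `gA`'s maximum;
3. rank of `(gB, gA)` in row `gB` is greater than `rankdif`;
4. control MI of `(gB, gA)` is below `MIrate` times row `gB`'s maximum.

The **common network** reverses the comparisons (rank *smaller than*
`rankdif_common`, MI *greater than* `mi_rate_common` times the row
maximum) and requires them in only one of the two directions. Default
cut-offs (`rankdif = 2000`, `MIrate = 0.6`, `rankdif_common = 200`,
`mi_rate_common = 0.85`) suit datasets with on the order of 10,000 genes
and should be scaled down with the gene count (see the methods
vignette).

## Worked example

```r
library(dc3net)

# two-condition data with 15 shared, 10 test-only and 10 control-only
# planted direct interactions over 50 genes
sim <- simulate_condition_pair(n_genes = 50, seed = 7)

fit <- run_dc3net(sim$test, sim$control,
  params = dc3net_params(rankdif = 8, rankdif_common = 2, B = 10), seed = 1)
fit
#> Differential C3NET analysis
#>   genes: 50 (shared)
#>   MI thresholds (nats): test 0.0346, control 0.0357
#>   edges: tnet 29, cnet 29 | test difnet 12, control difnet 16, common 11, undecided 6
#>   filter: rankdif 8, mi_rate 0.60 | common: rankdif 2, mi_rate 0.85

score_recovery(fit$test_difnet, dplyr::filter(sim$truth, condition == "test_only"))
#> # A tibble: 1 × 6
#>   true_positive false_positive false_negative precision recall    f1
#>           <int>          <int>          <int>     <dbl>  <dbl> <dbl>
#> 1             6              6              4       0.5    0.6 0.545

head(fit$test_difnet, 3)
#> # A tibble: 3 × 6
#>   gene_a gene_b    mi rank_a rank_b category
#>   <chr>  <chr>  <dbl>  <int>  <int> <chr>
#> 1 g11    g45    0.664      1      1 test_difnet
#> 2 g03    g21    0.551      1      1 test_difnet
#> 3 g20    g44    0.540      1      2 test_difnet
```

The MI thresholds are the permutation-null 99th percentiles for each
condition; every network is a tibble of undirected edges with the MI
weight and the within-row ranks of both directions. Of the 29 `Tnet`
edges, 12 are called test-specific — 6 of them are genuinely test-only
planted edges (recall 0.6) — 11 are called common and 6 are left
undecided. `tidy(fit)` stacks all the networks into one long edge table,
`glance(fit)` gives a one-row summary, and `autoplot(fit)` draws the
decomposition. Subnetwork helpers (`filter_by_gene_list()`, `hubs()`,
`top_edges()`, `connected_components()`) slice any of the edge tables,
and `dc3net_run_dir()` (or the CLI in `inst/cli/dc3net.R`) runs the whole
pipeline on TSV files and writes the six edge lists plus a JSON
run-manifest.

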