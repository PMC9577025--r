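# zeronet

Zero-aware correlation and association networks for microbial abundance
profiles.

Microbiome abundance tables (OTUs × samples) are dominated by zeros — often
more than 85% of all cells — and a zero is ambiguous: the taxon may be truly
absent (a structural zero) or merely undetected at the sequencing depth (a
sampling zero). How those zeros are treated before computing pairwise
correlations changes the inferred co-occurrence and co-exclusion networks
dramatically. `zeronet` makes the zero-treatment step explicit and
comparable: it implements six filtering policies, sequential pairwise
correlation with a minimum-overlap rule, a from-scratch SparCC estimator for
compositional data, signed network construction with topology metrics and
consensus/overlap analysis, and a synthetic generator with known latent
correlations for validation. It is aimed at microbial ecologists building
association networks from count tables, and at methodologists studying how
preprocessing drives network inference.

## The six zero policies

For taxa *x*, *y* observed over the same samples (zeros ≡ missing):

| # | Name | Action |
|---|------|--------|
| 1 | `ZERO_AS_IS` | keep zeros as 0 |
| 2 | `KNN_IMPUTE` | replace zeros by k-nearest-neighbour expectations (profile level) |
| 3 | `FILL_PSEUDO` | replace zeros by a pseudo-value (default 0.01) |
| 4 | `DROP_PAIRED_FILL` | drop samples where *both* are zero; remaining zeros → pseudo-value |
| 5 | `DROP_PAIRED_KEEP` | drop samples where both are zero; unpaired zeros kept as 0 |
| 6 | `COMPLETE_CASE` | drop any sample with a zero in either taxon |

Coefficients (Pearson *r*, mid-rank Spearman ρ, tie-corrected Kendall τ_b)
are computed sequentially per pair, and a pair enters the analysis only with
strictly more than 30 paired valid observations (policies 4–6). Networks
keep an edge when |r| > 0.6 and *p* < 0.001 (both strict): positive edges
form the co-occurrence network, negative edges the co-exclusive network.
SparCC instead ingests the raw zero-containing counts, estimating basis
correlations ρ_ij from log-ratio variances t_ij = var log(f_i/f_j) under a
sparsity assumption, with Dirichlet resampling (pseudocount 1) and iterative
exclusion of strongly correlated pairs.

## Worked example

Everything flows through tibbles and the pipe; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

```r
library(zeronet)

# a 1200-taxon x 139-sample survey-like profile, 39,410 reads per sample
profile <- generate_profile(tara_like_spec(seed = 1))$profile
zero_fraction(profile)
#> [1] 0.8621942

prevalent <- frequency_filter(profile, min_samples = 60)   # 177 taxa remain

res <- correlate_all(prevalent, method = "spearman", policy = 5)
res
#> # A tibble: 15,576 x 7
#>   taxon_i    taxon_j         r        p n_valid method   policy
#>   <chr>      <chr>       <dbl>    <dbl>   <int> <chr>     <int>
#> 1 taxon_0001 taxon_0002 0.596  9.67e-15     139 spearman      5
#> 2 taxon_0001 taxon_0003 0.0832 3.30e- 1     139 spearman      5
#> ...

net <- build_network(res, r_cutoff = 0.6, p_cutoff = 0.001, kind = "co_occurrence")
compute_metrics(net)
#>   n_nodes n_edges avg_neighbors density n_components  ...
#> 1      38      19             1   0.027           19
```

Here 19 strongly supported positive associations survive thresholding among
38 taxa — mostly the latent correlations the generator planted. The policy
benchmark compares every policy's coefficients against policy 5
(paired-zero exclusion) as the standard:

```r
bench <- run_benchmark(prevalent, methods = "spearman",
                       policies = c(1, 2, 3, 5), n_pairs = 2000, seed = 2)
glance(bench)
#>   method   policy n_pairs    mad mean_abs_r n_strong_pos n_strong_neg
#> 1 spearman      1    2000 0.0823     0.0685            1            0
#> 2 spearman      2    2000 0.127      0.0746            3            0
#> 3 spearman      3    2000 0.0823     0.0685            1            0
#> 4 spearman      5    2000 0          0.107             1            0
autoplot(bench)
```

`mad` is the mean absolute deviation from the standard: k-nearest-neighbour
imputation (policy 2) distorts coefficients the most, and pseudo-filled
coefficients (policies 1/3, identical under ranks) sit systematically above
the standard — the behaviours that make the zero-treatment choice matter.

A thin command-line front end covers the same workflow
(`inst/cli/zeronet.R` with subcommands `synth`, `filter`, `correlate`,
`network`, `benchmark`, `run`), and `run_pipeline()` orchestrates a whole
run from a YAML config.

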