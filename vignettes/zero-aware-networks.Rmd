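---
title: "Zero-aware correlation and association networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zero-aware correlation and association networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeronet)
```

# The problem

A taxon-by-sample abundance table from a sequencing survey is mostly zeros,
and each zero is ambiguous: the taxon may be genuinely absent from the
community (a structural zero) or present but missed at the achieved
sequencing depth (a sampling zero). Pairwise correlation — the workhorse of
microbial association network inference — is highly sensitive to how these
zeros enter the computation. Two taxa that share many absences look
strongly positively associated if the shared zeros are retained, and may
look unrelated once they are excluded. `zeronet` treats the zero-handling
step as a first-class, comparable modelling choice rather than a hidden
default.

# Zero policies

Zeros are the missing-value sentinel throughout; there is no separate NA
code. Six policies are implemented, three acting on the whole profile and
three per taxon pair:

1. **ZERO_AS_IS** — zeros stay 0; every sample contributes to every pair.
2. **KNN_IMPUTE** — zeros are replaced by expectations inferred from
   similar taxa (below).
3. **FILL_PSEUDO** — zeros are replaced by a pseudo-value, default 0.01
   (the convention of pipelines that require strictly positive entries).
4. **DROP_PAIRED_FILL** — per pair, samples where *both* taxa are zero are
   dropped; remaining unpaired zeros become the pseudo-value.
5. **DROP_PAIRED_KEEP** — as 4, but unpaired zeros stay 0.
6. **COMPLETE_CASE** — per pair, any sample with a zero in either taxon is
   dropped.

Two structural facts follow directly and are enforced as tested
invariants: `n_valid(6) ≤ n_valid(4) = n_valid(5) ≤ n`, and all six
policies coincide on zero-free pairs. Policy 5 serves as the comparison
standard in the benchmark: paired absences carry no information about
covariation, so excluding exactly those is the most conservative
zero-aware choice.

## k-nearest-neighbour imputation

Policy 2 treats taxa as cases. The distance between two taxa is the
root-mean-square difference of their `log1p` abundances over mutually
observed (both non-zero) samples; a missing value is the
Gaussian-kernel-weighted mean (`w = exp(-d²/2)`) of the values of the `k =
10` nearest donor taxa that are observed at the target sample. The `log1p`
scale keeps the kernel numerically meaningful for heavy-tailed counts —
raw-scale Euclidean distances between abundant taxa underflow the kernel to
zero. Donors must share at least one mutually observed sample; if fewer
than `k` eligible donors exist the available ones are used, and a cell with
no donor at all stays 0 with its taxon listed in the non-imputable report.
This mirrors the practical failure mode for rare taxa: imputation is simply
not applicable to them, which the less-frequent benchmark band makes
visible. `k`, the kernel and the distance are deliberately config-exposed
because nearest-neighbour imputers differ exactly in these choices.

# Sequential pairwise correlation

For every unordered taxon pair, the policy is applied and then the
coefficient computed: Pearson's product-moment *r*, Spearman's ρ as Pearson
on mid-ranks, and Kendall's tie-corrected

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},$$

with `n0 = n(n-1)/2` and `n1`, `n2` the tie corrections of each margin.
P-values are two-sided parametric approximations: `t = r sqrt((n-2)/(1-r²))`
on `n − 2` degrees of freedom for Pearson and Spearman, and the normal
approximation `z = 3S / sqrt(n(n-1)(2n+5)/2)` (with `S = C − D`) for
Kendall. The Kendall variance deliberately omits the tie correction, so
`cor.test()`'s exact/tie-corrected p-values differ slightly; the
coefficients themselves agree to 1e-12 with library and brute-force oracles
in the test suite. No multiple-testing correction is applied by default —
edges are thresholded on raw *p* — matching common practice in this
literature; `p.adjust()` can be applied to the output tibble by the user.

A pair is retained only with **strictly more than** `min_overlap = 30`
paired valid observations, read literally as `n_valid ≥ 31`. By default the
rule binds only the pair-level policies 4–6, where filtering actually
shrinks `n_valid`; a flag extends it to all policies. Coefficients that are
undefined after filtering (a constant vector — frequent under policy 6) are
dropped and tallied in a skip log rather than recorded as 0: a fabricated
zero would silently interact with the `|r|` cutoff downstream.

## Zeros and the centered log-ratio transform

`clr_transform()` computes, per sample column, `y = log x − mean(log x)`
(natural log), the standard compositional CLR. CLR output is legitimately
negative or zero, so "is zero" no longer identifies missingness. The
transform therefore records the pre-transform zero mask in the profile
metadata, and `correlate_all()` uses that mask — not the transformed
values — to drive policies 4–6. On CLR data no pseudo-fill is applied at
pair level (any fill necessarily happened before the log), which makes
policies 4 and 5 coincide there by construction.

# SparCC

SparCC is the comparison arm that ingests the raw zero-containing counts.
Per resampling iteration, per-sample fractions are drawn from a Dirichlet
posterior with a pseudocount prior of 1 on every count; the log-ratio
variance matrix `t_ij = var log(f_i / f_j)` decomposes as

$$t_{ij} = w_i + w_j - 2\rho_{ij}\sqrt{w_i w_j},$$

where `w_i` are basis variances and `ρ_ij` basis correlations. Under the
sparsity approximation (most `ρ_ij ≈ 0`) the row sums of `t` give a linear
system for `w` (diagonal `D − 1`, off-diagonal 1). The most strongly
correlated pair above the exclusion threshold 0.1 (the original SparCC
default) is then removed from the system and the basis re-solved, up to 10
rounds. The "iteration value 20" exposed to users is the number of
Dirichlet resamples, matching the `-i` semantics of SparCC command-line
implementations; resamples are aggregated by the elementwise median
(robust; the mean is available). Estimates are clipped to `[-1, 1]`; a
negative solved basis variance — possible when the sparsity assumption is
badly violated — is clamped to machine epsilon with a warning rather than
aborting, and the exclusion bookkeeping refuses to empty a component's row
of the system. Permutation p-values shuffle each taxon's counts across
samples independently and use the add-one estimator, so the attainable
floor with `B` permutations is `1/(B+1)`.

# Networks

Edges with `p < 0.001` and `r > 0.6` form the co-occurrence network; `r <
−0.6` the co-exclusive network — both inequalities strict, reading "larger
than" literally. Topology metrics follow the NetworkAnalyzer conventions:
density `2E/(N(N−1))`, heterogeneity `sqrt(var deg)/mean deg` (population
variance), centralization `N/(N−2) · (max deg/(N−1) − density)`, mean local
clustering with degree-<2 nodes contributing 0, characteristic path length
averaged over connected node pairs, and diameter/radius on the largest
connected component (association networks here are typically fragmented;
the choice is recorded in provenance). All path metrics ignore edge
weights. Metrics undefined for tiny graphs are reported as `NA`, never an
error. A brute-force oracle (breadth-first search and exhaustive triangle
counting on ≤ 8-node graphs) pins these definitions in the tests.

Hub subnetworks take the ten most connected nodes plus their first
neighbours, with boundary degree ties broken lexicographically by taxon ID
(deterministic, and reported). Consensus networks intersect edge sets
(unordered pair + sign) across member networks; the consensus node set is
the endpoints of the surviving edges, while `overlap_counts()` reports the
bare node-set intersection separately — both readings of "overlapped
nodes" are thus available. Consensus weights are the means of member
weights.

# The synthetic generator

Validation needs profiles with *known* truth, which real surveys cannot
provide. The generator draws, per sample, a latent Gaussian vector with a
target correlation matrix (Gaussian copula; planted entries must leave the
matrix positive definite, checked by eigendecomposition), maps it through
log-normal marginals to basis abundances, masks taxa by per-taxon
occupancy probabilities (structural zeros), closes to fractions and
samples multinomial reads at fixed depth (sampling zeros). The ground
truth reported is the latent copula correlation; observed-count rank
correlations are attenuated by masking and sampling noise, which is
exactly the regime the policies are meant to navigate.

`tara_like_spec()` freezes the survey-like study conditions: 139 samples
at 39,410 reads each, 1200 taxa with `meanlog` declining log-linearly over
roughly 4.8 natural-log decades, `sdlog = 1.5`, occupancy
`0.01 + 0.99·plogis(3.5 − 26·rank)`, and disjoint planted pairs (ρ = +0.8
among the most prevalent taxa, ρ = −0.6 in the next band — disjointness
guarantees positive definiteness). These values were chosen once to match
the intended regime — overall zero fraction above 0.8 (the emulated survey
exceeds 85%) with a few hundred taxa present in ≥ 60 samples — and are not
tuning knobs. What the generator does **not** emulate: phylogenetic
correlation structure, environmental gradients coupling occupancy across
taxa, overdispersion beyond the log-normal, or time-series dynamics.
Passing tests therefore demonstrate correctness of the machinery and the
qualitative policy behaviours, not that any particular real survey is
faithfully modelled.

# Validation design and problem sizes

The test suite runs entirely on generated data at deliberately modest
sizes: oracle equivalence on 10 × 50 profiles, exhaustive
concordance/rank oracles over all permutations of n ≤ 6 plus all 3^5 tied
sequences, SparCC recovery at D = 50, n = 200 with one planted ρ = 0.9
(recovered within ±0.15; null pairs mean |ρ| < 0.1), and the policy
benchmark on the survey-like profile restricted to taxa present in ≥ 60
samples with 3000 subsampled pairs. The benchmark asserts the two
qualitative signatures of zero-handling: pseudo-filled coefficients sit
systematically *above* the paired-exclusion standard under rank
correlation (shared absences masquerade as concordance — under Spearman,
filling with a constant below the detection floor is exactly equivalent to
keeping zeros, so policies 1 and 3 coincide), and nearest-neighbour
imputation produces the largest absolute deviations of any policy. Note
the comparison is signed and per-pair: mean |r| alone also reflects the
smaller `n_valid` of the standard (fewer samples → noisier null
coefficients of larger magnitude), which is a sampling artefact, not the
filling bias.

# Degenerate inputs and numerical choices

- Duplicate taxon/sample IDs, malformed numeric cells, and negative
  abundances are rejected at parse time with the offending location named.
- Rarefaction is without replacement (multivariate hypergeometric),
  delegated to `vegan::rrarefy()`; samples below the target depth are
  dropped with a warning, and a seed makes the draw bit-identical.
- Coefficients are clipped to `[-1, 1]` against floating-point spill;
  `|r| = 1` maps to `p = 0` under the t approximation.
- All randomness (generator, resampling, subsampling, permutations) flows
  through explicit seeds via `withr::with_seed()`, leaving the caller's
  RNG state untouched.
- Pair iteration is canonical (lexicographic taxon IDs), so results are
  independent of input row order.

# Known limitations

- Parametric p-values are approximations; for very small `n_valid` a
  permutation test would be preferable and the Kendall normal
  approximation ignores ties in its variance.
- SparCC assumes sparsity of true correlations; dense interaction
  structures bias the basis solve, surfacing as clamped negative basis
  variances.
- kNN imputation quality degrades sharply for low-prevalence taxa; the
  non-imputable report should always be inspected.
- The consensus operation is a strict intersection; near-threshold edges
  flickering across settings disappear, so consensus networks are
  conservative by construction.
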