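---
title: "Methods: staged profiling of an ordered-condition expression series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged profiling of an ordered-condition expression series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2prof)
```

co2prof implements a complete analysis chain for the classic
three-condition, triplicate-replicate microarray design — for example leaves
sampled under ambient, elevated and high CO~2~ (T0 < T1 < T2) — where the
question is not a single two-group contrast but *which genes change, in what
temporal/dose shape, with what function, and which of them sit at the
center of a regulatory network*. This vignette explains each stage's model,
its assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## 1. Moderated differential expression: the randomized variance model

With three biological replicates per condition, the per-gene residual
variance estimate $s^2$ has only $m = n - k = 6$ degrees of freedom and an
ordinary one-way ANOVA F-test is badly unstable. The randomized variance
model (RVM) treats the residual precision of each gene as random,

$$ 1/\sigma_g^2 \sim \mathrm{Gamma}(a,\ \mathrm{scale} = b), $$

which makes the marginal law of the residual mean square
$s_g^2 \cdot a b \sim F(m,\ 2a)$. We fit $(a, b)$ by maximizing the summed
log marginal density of the observed $s_g^2$ over all genes
(`fit_rvm_prior()`), optimizing on $(\log a, \log b)$ with Nelder–Mead from
a moment start so positivity is structural and the fit deterministic
(relative tolerance $10^{-12}$; a fully degenerate input, all $s^2$ equal,
raises a boundary error rather than chasing $a \to \infty$; $s^2$ below
$10^{-12}$ is floored with a warning).

The moderated test (`rvm_f_test()`) shrinks each gene's variance toward the
prior,

$$ \tilde\sigma_g^2 = \frac{m s_g^2 + 2/b}{m + 2a}, \qquad
   \tilde F_g = \frac{\mathrm{MS}_{\mathrm{between},g}}{\tilde\sigma_g^2}
   \sim F(k-1,\ m + 2a), $$

so the prior contributes $2a$ extra denominator degrees of freedom — the
whole point of the method for triplicate designs. Two limits are worth
keeping straight: as $a \to 0$ the test approaches the per-gene ANOVA, and
as $a \to \infty$ with $ab$ fixed the shrinkage is *complete*
($\tilde\sigma^2 \to 1/(ab)$, the prior mean variance), i.e. every gene is
tested against the common variance. The test suite verifies the second
limit numerically.

Signals are log2-transformed before testing. The normalized chip signals
are positive and linear-scale; the clustering stage below is defined on
log2 ratios, so testing on the same scale keeps one model throughout.
Designs must be complete (no missing values); imputation is out of scope.

P-values get Benjamini–Hochberg adjustment (`bh_fdr()`, delegating to
`stats::p.adjust`), and `select_degs()` applies the raw p and FDR
thresholds *conjunctively* (both < 0.05 by default). Which of the two
conventions (conjunctive vs sequential) to use was an open choice; the
conjunctive rule is the stricter and is recorded in the run manifest.

For phenotype tables (growth, photosynthesis, hormones) the package also
ships `one_way_anova_lsd()`: classic one-way ANOVA plus Fisher's LSD,
$\mathrm{LSD} = t_{1-\alpha/2, df_W}\sqrt{\mathrm{MSW}(1/n_i + 1/n_j)}$,
with a compact-letter display.

## 2. Series-test-of-cluster profile assignment

Each selected gene's trajectory is reduced to an anchored log2-ratio vector
$v_t = \overline{\log_2 x}_{t} - \overline{\log_2 x}_{0}$ (so $v_0 = 0$),
and assigned to one of 16 integer *model profiles* — shapes like $(0,1,0)$
(transient up), $(0,-1,1)$ (down then up), $(0,1,2)$ (sustained rise) —
by maximal Pearson correlation between $v$ and the shape
(`assign_profiles()`). Correlation, not Euclidean distance, is the
STEM-style convention: it makes assignment invariant to positive rescaling
of the trajectory, which the suite property-tests. Flat (zero-variance)
vectors are unassignable and are left out; ties break to the lowest profile
id. No minimum-correlation threshold is applied by default (`min_corr = 0`)
— any exclusion rule beyond flatness would be arbitrary, and the number of
unassigned genes is surfaced rather than hidden. The shipped catalog fixes
one typo a printed version of this table carries: profiles 14 and 15 are
$(0,0,-1)$ and $(0,0,1)$, which would otherwise be duplicates.

The null for "is this profile over-populated?" is permutation of the
condition positions: all $3! = 6$ orderings (identity included), each
gene's vector permuted, re-anchored at its new first position, re-assigned;
the *expected count* of a profile is the mean over the 6 permutations
(`expected_counts()`). Two exact invariants follow and are tested:
every expected count is a multiple of $1/6$, and
$\sum_p \mathrm{expected}_p = \sum_p \mathrm{assigned}_p$ (flatness is
permutation-invariant). These two facts are also what identify this
permutation scheme as the one behind published tables of this kind, whose
expectations are all on the $1/6$ grid and whose two count columns sum
identically.

Profile significance (`profile_significance()`) is the exact binomial upper
tail

$$ p = P(X \ge \mathrm{assigned}), \qquad
   X \sim \mathrm{Binomial}(\mathrm{total},\ \mathrm{expected}/\mathrm{total}), $$

accumulated in log space so tails far below the double-precision underflow
limit ($10^{-300}$) remain meaningful. Published tables of this kind
sometimes label the test "Fisher's exact", but a 2×2 Fisher table cannot
even be built from (assigned, expected, total); recomputing from printed
triples across eleven orders of magnitude matches the binomial tail, which
is what is implemented. `expected = 0` with a positive count returns
$p = 0$ by convention, with a warning.

## 3. Over-representation of annotation categories

Genes of the significant profiles are tested against GMT gene-set
collections (GO biological process, KEGG pathways) with the one-sided
hypergeometric tail and the enrichment ratio
$R_e = (k/n)/(K/N)$ (`hypergeom_enrichment()`). Category gene sets are
intersected with the background before counting. The background defaults to
*all probes on the array* — the defensible universe for chip data — and is
configurable. No multiple-testing correction is applied to enrichment
p-values by default (the conventional raw $p < 0.05$ screen); BH is
available behind a flag, as is the conservative DAVID/EASE convention of
computing the tail at $k - 1$. The dual filter `filter_enriched()` applies
$p < 0.05$ plus $R_e > 5$ for GO-style screens ($R_e > 0$, i.e. p-only, for
pathway-style screens). Under-representation and GO-graph propagation are
out of scope.

## 4. The signal-transduction network

Pairwise Pearson correlations are computed across **all samples** (9
expression points), not across the 3 condition means — 3-point correlations
are $|r| = 1$ almost surely and carry no significance. Significance is the
two-sided t transform $t = r\sqrt{d-2}/\sqrt{1-r^2}$ on $d - 2$ df; the
inclusion cutoff $\alpha = 0.05$ is configurable and recorded in the
manifest, and by default the *magnitude* of $r$ decides inclusion
(anti-correlated regulation is still regulation), with the sign retained.

The network (`build_signal_net()`) is the directed, typed interaction
catalog (SIF; activation, phosphorylation, ...) restricted to significantly
correlated pairs, checked in both orientations. Per node it reports degree
(distinct neighbors, direction-blind), indegree/outdegree (source/target
counts), and betweenness centrality — the fraction of all shortest paths
between node pairs passing through the node — normalized by
$(N-1)(N-2)/2$ (undirected, the default reporting view) or $(N-1)(N-2)$
(directed option). Betweenness is computed by igraph's Brandes algorithm
and verified in the suite against a from-scratch BFS dependency-counting
oracle on hundreds of small random graphs, plus the closed forms (path
interior 1, star hub 1, 4-cycle nodes $1/6$). Networks with fewer than 3
nodes have no possible intermediary and get bc = 0 by convention.
`rank_key_genes()` orders by descending bc, then descending degree, then
gene id — fully deterministic.

## 5. qPCR validation

`ddct_fold_change()` implements plain $2^{-\Delta\Delta C_t}$: technical
replicates averaged first, $\Delta C_t$ differenced against the reference
gene within each biological-replicate block, $\Delta\Delta C_t$ against the
mean control-condition $\Delta C_t$, folds averaged (with SD) over
biological replicates. Amplification efficiency is fixed at 2;
efficiency-corrected variants are out of scope. Because the reference gene
is differenced within every block, a constant Ct shift of any block cancels
exactly — property-tested. `platform_concordance()` correlates array log2
fold changes with log2 qPCR folds over matched (gene, condition) pairs.

## 6. The synthetic-data generator

`generate_expression()` emits data satisfying the stage-1 model *exactly*:
precisions drawn $\mathrm{Gamma}(a, b)$, replicate log2 signals Normal
around condition means, DE genes' means following an integer profile scaled
by `effect_scale`, signals exponentiated to the linear scale. Defaults
describe a desk-scale version of the motivating experiment and were chosen
once:

| parameter | default | why |
|---|---|---|
| `n_genes` | 5000 | desk-scale; a ~61k-probe chip is reachable by config |
| `conditions`, `reps_per_condition` | T0,T1,T2 × 3 | the 3×3 design |
| `rvm_a`, `rvm_b` | 3, 2 | mean residual variance $1/(b(a-1)) = 0.25$ on log2 scale, a realistic chip noise level with a visibly heavy tail |
| `de_fraction` | 0.1 | ~10% of probes responsive, typical of a strong environmental contrast |
| `profile_mix` | the five series shapes (0,1,0), (0,1,−1), (0,−1,1), (0,−1,0), (0,2,1), weighted by their observed prevalence in a published three-point CO~2~ series | plants the profile structure the clustering stage looks for |
| `effect_scale` | 2 log2 units/step | ≥ 4 residual SDs: planted shapes are recoverable with 3 replicates |
| `ct_noise_sd` | 0.1 cycles | typical SYBR technical scatter |

One master `seed` governs everything; the three generators draw from fixed
offsets of it (expression +0, annotations +1000003, qPCR +2000003) so
modules are reproducible independently. The KS property
$s^2 ab \sim F(m, 2a)$ is tested on 10,000 genes.

`generate_annotations()` plants `n_planted_categories` categories whose
members are sampled with odds `planted_enrichment_odds` : 1 in favor of DE
genes (odds 1 = null collection, used for calibration tests). The
interaction catalog plants a known high-betweenness **bridge**: the two
best-populated planted profiles become two communities (anchor clique +
members wired to two anchors each), and the communities communicate *only*
through the bridge gene, making it the ground-truth top-betweenness node of
the catalog; random typed relations are added within communities at
`interaction_density`. Motif roles go to the lowest-residual-variance genes
of their profile so the planted structure survives DEG selection and the
correlation filter essentially always. `generate_qpcr()` inverts the
$2^{-\Delta\Delta C_t}$ model (block shifts shared by all genes of a block,
reference fold ≡ 1), so zero-noise plates recover planted folds exactly.

What the generator does **not** emulate: probe-level Affymetrix artifacts,
normalization residue, correlated gene-gene noise outside the planted
structure, batch effects, or unbalanced/missing designs. Passing tests
therefore demonstrate correctness of the statistical machinery under its
own assumptions, not robustness to violations of them.

## 7. Problem sizes used in the shipped checks

The packaged verification uses 10,000-gene simulations for prior recovery
and null calibration, 100 pipeline runs of the 5,000-gene demo for
end-to-end truth recovery, 500 random ≤ 8-node graphs for the betweenness
oracle, and exhaustive enumeration of all hypergeometric instances with
$N \le 25$ — sizes at which every oracle is exact or the Monte-Carlo error
is far below the tested margins.

## 8. Known limitations

- The clustering stage takes the 16-profile catalog as given (configurable
  via TSV); it does not re-derive candidate profiles by the
  maximal-distance selection used by STEM.
- Enrichment treats categories independently (no term redundancy trimming
  or ontology propagation).
- Correlation edges assume homoscedastic Gaussian log2 signals when
  converting $r$ to a p-value.
- The qPCR module assumes perfect doubling; primer-efficiency calibration
  is not modeled.

## Worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
sim <- generate_expression(cfg)
ann <- generate_annotations(sim$truth, cfg)
run <- run_pipeline(sim$matrix, ann$annotations, ann$catalog,
                    out_dir = "demo_out", seed = 1L)
glance(run)
autoplot(run$profile_stats)
rank_key_genes(run$network, top_k = 5)
```
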