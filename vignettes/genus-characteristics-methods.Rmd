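---
title: "Methods: phylogenetic signal, contrasts and node scans for genus-level characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic signal, contrasts and node scans for genus-level characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amazontraits)
```

## The problem

Tree genera in the Amazon differ enormously in how many species they
contain, how large those species' geographic ranges are, and how abundant
the species are. If those genus-level characteristics are shaped by
heritable traits of the lineages themselves, closely related genera should
resemble each other — the characteristics should carry *phylogenetic
signal* on a time-calibrated genus phylogeny. This package implements the
analysis chain that tests this: signal estimation with Pagel's λ and AIC
model comparison, raw and phylogenetically independent correlations among
the characteristics, a permutation scan for lineages with unusually high or
low values, and a non-phylogenetic ANOVA across major angiosperm clades.
All characteristics are analyzed as log10 values; richness, range and
abundance span orders of magnitude and are strongly right-skewed on the
raw scale.

## Brownian motion, Pagel's λ and the model comparison

Under Brownian motion a continuous trait drifts along the branches with
variance accruing linearly in time, so tip values are jointly multivariate
normal,

$$x \sim \mathcal{N}(\mu \mathbf{1},\; \sigma^2 C),$$

with $C_{ij}$ the branch length shared by tips $i$ and $j$ from the root to
their most recent common ancestor (`vcv_matrix()`). Pagel's λ multiplies
the off-diagonal of $C$ while leaving the diagonal intact
(`lambda_transform()`): λ = 1 keeps the Brownian covariance, λ = 0 erases
it (a star phylogeny). For an ultrametric tree every λ in [0, 1] yields a
valid covariance; λ > 1 is rejected rather than allowing the tree-specific
feasible bound, because the model set under comparison is exactly
{λ̂, 0, 1}.

Given a covariance shape $C_\lambda$, the mean and rate have closed-form
profile (GLS) maximum-likelihood estimates,

$$\hat\mu = \frac{\mathbf{1}^\top C_\lambda^{-1} x}{\mathbf{1}^\top C_\lambda^{-1}\mathbf{1}},
\qquad
\hat\sigma^2 = \frac{(x-\hat\mu\mathbf{1})^\top C_\lambda^{-1}(x-\hat\mu\mathbf{1})}{n},$$

with the ML denominator $n$ (not REML): the full likelihood constants are
retained so AIC is comparable across covariance structures that share the
same mean model. `fit_lambda(mode = "ml")` maximizes the resulting profile
log-likelihood over λ by bounded scalar optimization (absolute tolerance
1e-8) plus explicit endpoint evaluation at 0 and 1, since the profile can
be monotone and the maximum sits on the boundary exactly in those cases.

AIC uses $k = 2$ (μ, σ²) for the fixed-λ models and $k = 3$ when λ is
estimated. The comparison table reports ΔAIC with the best model at 0 and
worse models negative. A consequence of the $k$ convention worth knowing:
when λ̂ lands exactly on a boundary, the estimated-λ model has the same
likelihood as the corresponding fixed model and an AIC exactly 2 larger.

Degenerate input (a constant trait) yields $\hat\sigma^2 = 0$; the fit is
flagged and the unbounded likelihood reported as `Inf` rather than silently
producing a spurious comparison.

## Independent contrasts and correlations

`pic_contrasts()` implements the pruning recursion on a strictly binary
tree: at each internal node the standardized contrast is
$(x_i - x_j)/\sqrt{b_i + b_j}$, the node inherits the branch-length-weighted
average of its children, and its parent branch is lengthened by
$b_i b_j/(b_i+b_j)$. Contrast orientation is fixed deterministically (the
child subtree containing the lexicographically smallest tip label is the
minuend); correlations are orientation-invariant, so this choice only makes
outputs reproducible.

Raw associations use the ordinary centered Pearson correlation with
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Contrast associations are
*uncentered* and the regression is forced through the origin — contrasts
have arbitrary sign, so an intercept is meaningless — with
$r = \sum u_i v_i/\sqrt{\sum u_i^2 \sum v_i^2}$ and df = (number of
contrasts) − 1, one df spent on the slope. The df convention for the
origin-forced p-value is a design choice (the source analyses report only
r and p); it is stated here once and used consistently.

Two zero-length-branch policies exist because consensus trees resolved into
zero-length bifurcations are legitimate inputs: the default adds
1e-8 × tree depth to both siblings of an all-zero contrast (and records how
often), and a strict mode errors instead. Tests verify that the correlation
is invariant to which zero-length resolution of a polytomy was chosen.

## Ancestral reconstruction and the node scan

Under BM the ML estimate of an internal node's state given the tips is the
GLS/BLUP conditional mean

$$\hat a = \hat\mu + C_{at} C_{tt}^{-1}(x - \hat\mu\mathbf{1}),$$

equivalently the GLS mean after re-rooting at that node; the root estimate
is exactly $\hat\mu$, and the estimates do not depend on σ². Because the
map $x \mapsto \hat a$ is linear, `asr_operator()` materializes it once as
a matrix; the randomization scan then reconstructs all permuted datasets
with a single matrix product, which is what makes 1,000 randomizations of a
631-tip tree essentially free.

`permutation_scan()` shuffles the trait-to-tip assignment (the tree is
untouched) over the tips present in the matched dataset, and for each node
reports the fraction of randomizations reconstructing a strictly smaller
value than observed. Classification: `high` if that fraction exceeds
0.975, `low` if the strictly-greater fraction exceeds 0.975, `ns`
otherwise. For continuous traits the `low` rule is identical to
"prob_smaller < 0.025"; phrasing both tails through strict counts makes
ties count toward neither tail, so a constant trait — where every
randomization ties the observation — flags nothing. Reconstructions equal
up to BLAS rounding are treated as ties (absolute tolerance 1e-9 scaled to
the reconstruction magnitude). No multiple-testing correction is applied
across nodes: thresholds are per-node 2.5%/97.5% by design; the report
retains all nodes so users can post-correct, and the
nested structure of the tree means flagged nodes are not independent
discoveries.

## Clade comparison

The across-clade comparison is deliberately non-phylogenetic: one-way
ANOVA of each log10 characteristic with major clade as the grouping
variable, delegated to `stats::aov`, with effect size R² = SSB/SST and
Tukey HSD pairwise comparisons from `stats::TukeyHSD` (Tukey–Kramer
standard errors, appropriate because clade sizes are very unequal — there
are few Magnoliid genera and many Rosid ones). Analyses run on the log10
scale by default, consistent with every other stage; callers can pass raw
columns if they want the untransformed comparison.

## The synthetic-data generator

The generator exists so the full pipeline can be exercised, calibrated and
regression-tested without the external range-size and abundance
compilations an empirical analysis would consume.
`make_study_like_dataset()` emulates realistic conditions for the
Amazonian genus-level setting:

- **Tree:** a birth–death simulation conditioned on the number of extant
  tips (631 by default; `ape::rphylo`, extinct lineages pruned), with
  birth 0.1 and death 0.025 per Myr — a plausible net-diversification
  regime for angiosperm genera; every statistic downstream is invariant to
  the absolute time scale, which the tests verify explicitly.
- **Traits:** three log10-scale characteristics with per-trait Pagel's
  λ = 0.3 (the intermediate-signal regime empirical genus-level estimates
  fall in, λ roughly 0.26–0.37), marginal tip standard deviations (0.6, 0.5, 0.8) log10
  units, root values (0.9, 5.3, 5.5) — a typical genus of ~8 species with
  range ~2×10⁵ and abundance ~3×10⁵ — and innovation correlations
  (richness–range −0.45, richness–abundance −0.40, range–abundance +0.50),
  the sign structure of the observed genus-level correlations. The rate
  σ² is derived per tree as tip_sd²/depth. Traits are drawn with
  covariance σ²_k·C_{λ_k} per trait and cross-correlated innovations
  (exactly the Kronecker structure when the λs are equal, as in the
  defaults).
- **Missingness:** mean abundance is masked for a random 138/631 of
  genera, reproducing realistic per-characteristic sample sizes
  (631 vs 493) and exercising per-trait tree matching.
- **Clades:** three disjoint monophyletic groups greedily matched to
  realistic proportions (0.47/0.37/0.09) plus the paraphyletic remainder,
  labeled by size rank Rosids, Asterids, Monocots, Magnoliids.
- **Back-transformation:** traits are generated on the log10 scale and
  exponentiated, so `log10_transform()` inverts exactly; richness is
  rounded to an integer count ≥ 1, introducing a small discretization that
  the λ-recovery tolerance absorbs.

What the generator does *not* emulate: taxonomic error and synonymy,
spatially structured range geometry, the correlation between missingness
and abundance itself (plot data preferentially miss *rare* taxa; masking
here is random), non-Gaussian tails, and rate heterogeneity across
lineages. Passing tests therefore demonstrate that the pipeline recovers
known structure under its own model assumptions, not that those
assumptions hold for real Amazonian data.

A caution worth stating: under intermediate λ the independent contrasts
computed on the untransformed tree are strongly interdependent, and the
*single-dataset* PIC correlation is far noisier than its raw counterpart —
across generator seeds roughly one dataset in ten shows a sign flip on one
of the weaker pairs. The pooled estimate across replicates converges to the
generating correlation (a tested property). This is a genuine statistical
feature of contrast-based correlation under model misspecification, not a
code artifact.

## Numerical policies

- Covariance solves use Cholesky factorization; on failure a single jitter
  of 1e-10 × mean diagonal is added, otherwise the operation errors with a
  condition-number report. No silent regularization beyond that one step.
- λ optimization: `stats::optimize` on [0, 1], tolerance 1e-8, plus
  endpoint evaluations.
- Polytomy resolution inserts zero-length branches in an order that is a
  deterministic function of a seed, and never changes tip-to-tip path
  lengths (tested to machine precision).
- All simulation and permutation randomness flows through one seeded
  generator per call; the caller's RNG state is saved and restored, and
  identical seeds give byte-identical outputs end to end.

## Problem sizes used by the test suite

The acceptance-style tests run, per design: 50 eight-tip trees against a
brute-force grid oracle for the likelihood machinery; 100 200-tip trees per
λ ∈ {0, 0.3, 0.7, 1} for recovery; 100 300-tip replicates for the AIC
ordering; 200 null datasets (200 tips, 500 permutations) plus 100 shifted
replicates (300 permutations) for node-scan calibration and power; 2,000
null ANOVA datasets; and one full 631-tip end-to-end run with 200
permutations and a byte-identity rerun. These sizes keep the whole suite
around a minute on a single core while leaving Monte-Carlo error well
inside the asserted bounds.

## Known limitations

- λ is bounded to [0, 1]; values above 1 (clumping stronger than Brownian)
  are outside the model set by design.
- The node scan reports marginal per-node quantiles; family-wise error
  across ~630 nested nodes is uncontrolled by design.
- Contrast p-values assume contrasts are iid normal, which holds exactly
  only when the generating process matches the tree (λ = 1).
- The ANOVA ignores phylogeny by construction; it is the intended
  contrast to the phylogenetic analyses, not a replacement.
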