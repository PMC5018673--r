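# amazontraits

Comparative phylogenetic analysis of genus-level characteristics of
Amazonian trees: **species richness**, **mean range size** and **mean
abundance** of the species in each genus. Amazonian tree genera differ by
orders of magnitude in all three, and the question the analysis addresses
is whether that variation is phylogenetically structured — whether closely
related genera resemble each other, which would implicate heritable,
intrinsic traits of lineages (stature, dispersal, generation time) rather
than purely extrinsic factors.

The package is written for comparative biologists and macroecologists. It
provides the complete, tested pipeline as ordinary R functions, a set of
numbered driver scripts under `analysis/`, and a synthetic-data generator
so every stage is exercisable end to end without access to the original
range-size and abundance compilations.

## What it computes

All characteristics are analyzed on the log10 scale on a time-calibrated
genus phylogeny.

1. **Phylogenetic signal (Pagel's λ).** Under Brownian motion, tip values
   are multivariate normal, x ~ N(μ1, σ²C), where C_ij is the shared
   root-to-ancestor branch length of tips i and j. Pagel's λ rescales the
   off-diagonal of C; λ = 1 is pure Brownian covariance, λ = 0 phylogenetic
   independence. The package profiles μ and σ² analytically (GLS), maximizes
   the likelihood over λ ∈ [0, 1], and compares the models {λ̂, λ = 0, λ = 1}
   by AIC with the best model at ΔAIC = 0 and worse models negative
   (k = 3 when λ is estimated, k = 2 otherwise).
2. **Raw and independent-contrast correlations.** Pearson correlations
   among the three characteristics over genera, and again over
   Felsenstein's standardized independent contrasts, where the correlation
   and the best-fit line are forced through the origin
   (r = Σuᵢvᵢ / √(Σuᵢ²·Σvᵢ²), df = n_contrasts − 1).
3. **Node scan.** ML (GLS) ancestral-state reconstruction at every internal
   node, compared against 1,000 reconstructions with trait values shuffled
   across tips: nodes above the 97.5% quantile of the randomizations are
   flagged `high`, below 2.5% `low`.
4. **Clade comparison.** Non-phylogenetic one-way ANOVA of each
   characteristic across the major angiosperm clades (Magnoliids, Monocots,
   Rosids, Asterids), with Tukey HSD pairwise tests.

## Worked example

```r
library(amazontraits)

d <- make_study_like_dataset(seed = 1)          # 631 genera, 493 with abundance
m <- match_tree_and_traits(d$tree, d$traits, "log10_species_richness")
compare_models(m$tree, m$x)
```

```
Evolutionary model comparison (best model has delta AIC = 0):
                      model lambda   loglik     aic delta_aic
           Estimated lambda   0.31  -515.35 1036.70       0.0
 No phylogenetic dependence   0.00  -564.36 1132.71     -96.0
            Brownian motion   1.00 -1089.39 2182.79   -1146.1
```

The estimated λ = 0.31 (the generator's target is 0.3): richness carries
real but intermediate phylogenetic signal — far from both independence and
pure Brownian motion, the regime empirical genus-level estimates for
Amazonian trees fall in (λ roughly 0.26–0.37).

```r
correlation_matrix(d$tree, d$traits)
```

```
                 trait_x               trait_y n_raw  r_raw    p_raw n_contrasts  r_pic    p_pic
1 log10_species_richness log10_mean_range_size   631 -0.480 1.20e-37         630 -0.482 5.23e-38
2 log10_species_richness  log10_mean_abundance   493 -0.408 3.54e-21         492 -0.463 1.68e-27
3  log10_mean_range_size  log10_mean_abundance   493  0.471 1.20e-28         492  0.670 1.94e-65
```

Species-rich genera have, on average, species with smaller ranges and lower
abundance (negative r), while range size and abundance are positively
associated — in the raw data and after removing shared ancestry with
independent contrasts. Note the per-trait sample sizes: genera lacking an
abundance estimate drop out of abundance analyses only.

The numbered scripts run the same stages over files:

```sh
Rscript analysis/01_simulate.R     # writes results/data/{tree.nwk,genus.csv,clades.csv}
Rscript analysis/02_signal.R       # Pagel's lambda + AIC tables
Rscript analysis/03_correlations.R # raw + PIC correlation table
Rscript analysis/04_nodescan.R     # per-node scan TSVs + annotated Newick
Rscript analysis/05_clades.R       # ANOVA / Tukey tables
```

## Layout

- `R/` — implementation: tree handling (`parse_newick`, `vcv_matrix`,
  `lambda_transform`), trait aggregation, BM/λ likelihood (`fit_lambda`,
  `compare_models`), contrasts (`pic_contrasts`, `pearson_pic`), node scan
  (`asr_ml`, `permutation_scan`), clade ANOVA, and the generator
  (`sim_config`, `simulate_tree`, `simulate_traits`,
  `make_study_like_dataset`).
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/genus-characteristics-methods.Rmd` — the methods vignette:
  models, assumptions, numerical policies, generator design, limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
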