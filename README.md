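# clonalGBLUP

Genome-enabled decomposition of quantitative-trait variance in clonally
replicated, multi-site progeny trials — and cross-validation of the genomic
predictions that decomposition supports.

Clonal replication lets a breeding program estimate both a genotype's
breeding value (the additive merit it transmits) and its total genetic
value (additive + dominance + epistasis, which is what the clone itself
delivers in the field). This package implements the full analysis for a
two-site trial of full-sib families genotyped with a SNP array, as used in
apple breeding: fruit-quality phenotypes on up to four clonal replicates
per individual per site over two years.

## The model

Stage one collapses replicate × year records within site to one adjusted
phenotype (BLUE) per individual per site. Stage two fits, by
average-information REML,

```
y = Xb + Z1 a + Z2 d + Z3 i + Z4 t1 + Z5 t2 + Z6 t3 + e
```

with `a ~ N(0, Ga σ²a)`, `d ~ N(0, Gd σ²d)`, `i ~ N(0, Gaa σ²aa)`, site
interactions `t1..t3 ~ N(0, I_s ⊗ G σ²)` and residual `e ~ N(0, I σ²e)`.
The kernels are the VanRaden additive matrix `Ga = MM′/Σ2pᵢqᵢ`, the
dominance matrix `Gd = HH′/Σ2pᵢqᵢ(1−2pᵢqᵢ)` built from heterozygosity
codings, and the additive×additive epistatic matrix `Gaa = Ga # Ga`
(Hadamard square); pedigree `A` and `D` matrices are available for
comparison. Model variants A / AD / ADE drop or keep the nonadditive
kernels. Derived summaries: narrow- and broad-sense heritability
(`h² = σ²a/σ²total`, `H² = σ²G/σ²total`), the between-site genotypic
correlation `rB = σ²G/(σ²G + σ²G×E)`, likelihood-ratio model comparison,
and leave-one-family-out cross-validation of prediction accuracy
(correlation with all-data BLUP genetic values) and bias (regression
slope), under an "untested everywhere" and a "tested at one site"
strategy.

A synthetic clonal-trial generator (`sim_config()`, `simulate_trial()`)
reproduces the study design — 25 interrelated parents, 17 full-sib
families × 15 offspring, 2828 unlinked SNPs, two sites — with known ground
truth for every variance component, and drives the statistical test suite.

## Worked example

Published variance percentages for six apple fruit-quality traits ship
with the package; the heritability and genotypic-correlation ratios
reproduce the published rows exactly:

```r
library(clonalGBLUP)
vc <- apple_fruit_varcomp()
round(rbind(apply(vc, 2, heritabilities),
            rB = apply(vc, 2, genotypic_correlation)), 2)
#>      WT  GRE   FF  CRI  JUI  FIN
#> h2 0.52 0.27 0.50 0.23 0.18 0.11
#> H2 0.77 0.73 0.79 0.66 0.60 0.34
#> rB 0.95 0.87 0.93 0.95 0.93 0.88
```

`h2` is the additive fraction of phenotypic variance (what selection on
parents can exploit), `H2` the total genetic fraction (what a clone
delivers), and `rB` near 1 means genotype rankings are stable across the
two sites.

A small simulated trial, end to end:

```r
cfg <- sim_config(n_parents = 10, n_families = 8, family_size = 12,
                  n_snps = 400, n_reps = 2, n_years = 2, seed = 11)
trial <- simulate_trial(cfg)
Ga <- build_Ga(trial$geno)
kernels <- list(Ga = condition_kernel(Ga),
                Gd = condition_kernel(build_Gd(trial$geno)),
                Gaa = condition_kernel(build_Gaa(Ga)))
blues <- compute_blues(trial$pheno)
fit <- reml_fit(assemble_design(blues, kernels, "ADE"))
fit
#> reml_fit: logL = -59.7640 after 11 iterations (converged)
#>               a      d aa as ds aas      e
#> variance 0.7363 0.0580  0  0  0   0 0.3263
#> fraction 0.6571 0.0518  0  0  0   0 0.2911
#> h2 = 0.657  H2 = 0.709  rB = 1.000

cv <- cv_untested(blues, kernels, trial$families, "ADE")
round(colMeans(cv[c("accuracy", "bias")]), 2)
#> accuracy     bias
#>     0.39     1.04
```

Components printed as 0 are boundary estimates; see the methods vignette
(`vignettes/methods.Rmd`) for why single-replicate fits can shift variance
between the collinear additive and epistatic kernels while `H2` stays
stable.

## The analysis workflow

The numbered scripts under `analysis/` run the full study replica and
write their tables under `results/`:

1. `01_simulate.R` — synthetic trial (six traits, one per published
   variance architecture) and its data files;
2. `02_kernels.R` — marker QC, imputation, genomic + pedigree kernels,
   relatedness summaries, genotype PCA;
3. `03_blues.R` — stage-one BLUEs and per-site trait summaries;
4. `04_variance_components.R` — A/AD/ADE REML per trait, heritabilities,
   `rB`, likelihood-ratio tests;
5. `05_cross_validation.R` — 17-fold family cross-validation under both
   strategies, accuracy/bias tables and their correlates.

Run them in order from the repository root with `Rscript analysis/01_simulate.R`, etc.

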