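---
title: "Decomposing additive and nonadditive variance in clonally replicated trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing additive and nonadditive variance in clonally replicated trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalGBLUP)
```

## The problem

Clonally replicated progeny trials make it possible to separate what a
genotype transmits to offspring (its breeding value, driven by additive
effects) from what the clone itself will do in an orchard (its genetic
value, which also includes dominance and epistatic effects).  This package
implements the full analysis chain for a two-site clonal trial of full-sib
families genotyped with a genome-wide SNP array: stage-one adjustment of
replicate x year records, construction of additive, dominance and
additive-by-additive epistatic genomic relationship matrices, multi-kernel
REML with genotype-by-site interaction, and family-wise cross-validation of
genomic prediction.  A synthetic trial generator with known ground truth
supports all statistical testing.

## The model

Records are first collapsed within site by ordinary least squares on
`value ~ genotype + year + replicate` (all fixed), giving one best linear
unbiased estimate (BLUE) per individual per site.  Stage two stacks the
BLUEs site-major into `y` (length *ns*) and fits

y = Xb + Z1 a + Z2 d + Z3 i + Z4 t1 + Z5 t2 + Z6 t3 + e

where `b` holds the intercept and site effect; `a ~ N(0, Ga sa2)`,
`d ~ N(0, Gd sd2)` and `i ~ N(0, Gaa saa2)` are additive, dominance and
additive-by-additive effects with genomic kernels; `t1..t3` are their site
interactions with covariance `I_s (x) G`; and `e ~ N(0, I se2)`.  Under
site-major ordering each main-effect covariance contribution to `V` is
`(1_s 1_s') (x) G` and each interaction contribution `I_s (x) G` — a
construction asserted by the design tests.  The reduced variants drop the
nonadditive kernels: model A keeps `a` (and its site interaction), model AD
adds `d`, model ADE is the full set.

Kernels follow the VanRaden-style scalings: `Ga = M M' / sum(2 p q)` with
dosages centered at `2p`; `Gd = H H' / sum(2 p q (1 - 2 p q))` with the
heterozygosity coding `1 - 2pq` / `-2pq`; `Gaa = Ga # Ga` (Hadamard
square).  Pedigree counterparts `A` (tabular method) and `D` are provided
for comparison.  Derived quantities are narrow- and broad-sense
heritability, `h2 = sa2 / total` and `H2 = (sa2 + sd2 + saa2) / total`
(total = sum of all components in the model), and the between-site
genotypic correlation computed as the variance ratio

rB = sG2 / (sG2 + sGxE2),  sG2 = sa2 + sd2 + saa2,  sGxE2 = sas2 + sds2 + saas2.

The exact published form of this correlation is not printed in the source
literature; the ratio above is the natural variance-components expression
and reproduces all six published values for the reference trait table to
two decimals, which is how `genotypic_correlation()` is validated.

## REML

`reml_fit()` maximizes the restricted log-likelihood
`-1/2 [log|V| + log|X'V^-1 X| + y'Py]` by average-information updates with
expectation-maximization fallback and step halving, so the objective never
decreases across accepted iterations.  Components are constrained
nonnegative with a floor of `1e-8` of the phenotypic variance; estimates
pinned there are reported as boundary values (printed as 0.00 in the
percentage tables) and are excluded from the AI solve while their gradient
points downhill.  Convergence requires the log-likelihood change below
`1e-6` and relative component change below `1e-4`, with a 200-iteration
cap; non-convergence flags the result rather than erroring.  Starting
values split the sample variance equally across components; a multi-start
test checks insensitivity.  BLUPs of all effects (including individuals
without records, which is how validation families are predicted) come from
the covariance projection `u_hat = s2_u Cov(u, y) P y`.

The nested-model likelihood-ratio test uses the plain chi-square reference
with degrees of freedom equal to the difference in the number of variance
components (4 for ADE vs A).  Because the null places variances on the
boundary, the plain reference is conservative; an equal-mixture
chi-square p-value is reported alongside as a diagnostic, not silently
substituted.

## Allele frequencies and relatedness scale

Genomic kernels default to allele frequencies observed in the analyzed
sample.  A consequence worth stating: with sample frequencies the centered
dosage columns sum to zero, so the grand sum of `Ga` is exactly zero and
the mean off-diagonal relatedness is slightly negative by construction.
Reported mean SNP relatednesses well above zero (such as the 0.34 of the
motivating trial, against 0.19 from its pedigree) therefore imply a
different frequency reference; `build_Ga()`/`build_Gd()` accept an explicit
frequency vector for that reason, and the simulation tests use the known
founder frequencies, under which mean genomic relatedness tracks the mean
pedigree relationship closely.  Kernels are not diagonal-normalized;
variance components are reported as fractions of their sum, which absorbs
overall scale.  Indefinite kernels (possible after subsetting or for the
pedigree `D`) are bent by minimal diagonal inflation and flagged.

## Cross-validation design

Families, not random subsets, are the fold unit: each full-sib family in
turn is the validation population.  Strategy 1 removes the family's rows at
both sites; strategy 2 removes them at the target site only.  Variance
components are re-estimated within every training fold — the source
literature is silent on this point, and re-estimation avoids information
leakage from validation records.  Accuracy is the correlation between the
predicted genetic value (`a + d + i`, `a + d` or `a` by variant) and the
BLUP genetic value from the all-data ADE fit, one common target for all
variants; bias is the slope of the latter regressed on the former.  Family
means are unweighted.  Masking integrity is enforced structurally (masked
rows never enter the design) and verified by sentinel-poisoning tests.

## The synthetic trial generator

`simulate_trial()` emulates the study conditions: 25 parents drawn from a
small grandparental pool (pool size 7, tuned so the mean pedigree
relationship among parents is about 0.15), 17 full-sib families of 15,
2828 unlinked biallelic SNPs with founder frequencies uniform above a 0.05
floor, two sites, up to four clonal replicates and two years.  Loci are
unlinked by design: the covariance structure of the model needs no linkage,
and unlinked loci keep the realized kernels well conditioned.  Additive and
dominance effects are per-locus normal draws on the centered and
heterozygosity codings; epistasis is built from pairwise products of
centered additive codings over `2m` random locus pairs, which generates
variance the Hadamard kernel can capture.  Site-interaction deviations are
drawn per site with covariance proportional to the matching kernel.

Each component is rescaled exactly so that the variance it implies on the
model scale equals its target: the realized population variance is divided
by the kernel's scale factor `tr(K)/n - sum(K)/n^2` before matching.  This
removes Monte-Carlo variation from recovery tests without biasing them
when kernel diagonals differ from one (the epistatic kernel's diagonal
exceeds 1 under inbreeding).  The record-level residual is rescaled so the
per-individual-per-site averages — what survives into the stage-two BLUEs —
hit the residual target.  Year, replicate and site offsets are fixed,
equally spaced constants (0.3, 0.1 and 0.5 trait units); their sizes are
nuisance, present only so stage one has something to remove, and are
documented as arbitrary.  Pollen contamination replaces the transmitting
sire with probability `contamination_rate` while leaving the recorded
pedigree untouched.

What the generator does not emulate: linkage disequilibrium and marker-QTL
LD structure, selection, maternal or permanent environmental effects shared
by sibs, dominance-by-dominance or additive-by-dominance epistasis, and
multi-trait genetic correlations.  Passing recovery tests therefore show
that the estimator is consistent when the data match the model's covariance
assumptions, not that real orchard data meet them.

## Numerical and design choices

* Missing genotypes are mean-imputed (`2p` per SNP) — deterministic and
  standard for kernel construction; haplotype-phasing imputation is out of
  scope for already-called dosage tables.
* QC order: missingness filter, then MAF (thresholds 0.05/0.05), matching
  the trial's published order; QC is idempotent.
* Stage one fits year and replicate as additive fixed main effects within
  site, with no interaction and no precision weighting of the resulting
  BLUEs; heterogeneous replication enters stage two only through residual
  noise.  This is a known simplification.
* "Coefficient of relationship" is read as the off-diagonal relationship
  matrix entry, for both pedigree and genomic summaries; summaries report
  both the off-diagonal and including-diagonal conventions.
* Dosage coding counts the array's alternate allele; the kernels are
  invariant to which allele is counted per SNP, and a test asserts this.

## Known limitations

The additive and epistatic kernels are strongly collinear in
family-structured data (`Gaa` is the square of `Ga`, and within-family
blocks dominate both).  Single-dataset REML fits can therefore swap
variance freely between `a`, `aa` and `d` while barely moving the
likelihood — the analysis scripts print one such replicate where the
additive component collapses to the boundary while the total genetic
variance and `H2` stay stable.  Ratios that pool the genetic components
(`H2`, `rB`, total genetic value) are robust; individual components are
interpretable only on average over replicates, which is how the recovery
tests are framed (20 simulations at study scale, n = 255, m = 2828, s = 2,
each component compared to its target within twice its Monte-Carlo
standard error).  A component whose true value sits on the zero boundary
cannot satisfy a symmetric two-standard-error check: nonnegativity
truncation gives its estimator a strictly positive mean.  The recovery
suite asserts all seven components regardless and documents this one as
the expected exception.

Family-level accuracy correlates (with training-validation relatedness and
with trait heritability) are reported but extremely noisy at 17 folds and
six traits; single-replicate values can take either sign even when the
underlying monotonicity holds, which the dedicated simulation tests verify
directly at higher contrast.

## Problem sizes used by the test suite

Unit tests run on reduced replicas (8-10 families of 12, 300-600 SNPs);
the acceptance-level suite runs the full study design (25 parents, 17 x 15
offspring, 2828 SNPs) for structural checks, 20 study-scale replicates of
the fruit-weight architecture for recovery, and 200 reduced-scale
replicates for the likelihood-ratio null calibration.  These sizes are the
package's chosen balance between statistical resolution and a test suite
that completes in minutes.
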