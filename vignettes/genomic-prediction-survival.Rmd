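---
title: "Methods: multi-component genomic prediction for young-stock survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-component genomic prediction for young-stock survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiblup)
```

# Scope and data model

`multiblup` implements genomic prediction of low-heritability survival
traits in progeny-tested dairy cattle. The observable per bull is a
de-regressed proof (DRP) — a pseudo-phenotype derived from an official
estimated breeding value — with an effective daughter contribution (EDC)
that determines its information content. The package covers: DRP
reliability and residual-weight arithmetic; genotype quality control and
imputation-accuracy metrics; pedigree and genomic relationship matrices;
weighted multi-component REML/BLUP with an optional random regression on
recessive-lethal marker genotypes; forward validation by birth year; and a
gene-drop simulator that creates populations with the statistical structure
the analysis assumes. De-regression itself (running a national evaluation
and back-solving EBVs) is out of scope: DRPs are inputs, or are simulated
directly from true breeding values.

# The mixed model

All prediction models are variants of

$$ y = 1\mu + \sum_k Z g_k + M b + e, $$

* $y$: DRPs of the training bulls; the only fixed effect is the mean $\mu$.
* $g_k \sim N(0, K_k\sigma^2_k)$: one additive genetic component per
  relationship matrix. $K$ is the pedigree numerator matrix $A$ for PBLUP,
  or a VanRaden method-1 genomic matrix $G$ for GBLUP. One-component
  models pool all SNPs into a single $G$; two- and three-component models
  keep the chip and the selected whole-genome-sequencing (WGS) sets as
  separate components.
* $Mb$ (optional): random regression on the raw 0/1/2 genotype codes of
  SNPs tagging recessive lethal haplotypes, $b \sim N(0, I\sigma^2_b)$.
  The codes are deliberately *not* centered (the model regresses on the
  code itself; a centering flag exists and affects only $\hat\mu$).
* $e \sim N(0, D\sigma^2_e)$ with $d_i = (1-r^2_{DRP,i})/r^2_{DRP,i}$:
  bulls with more reliable DRPs carry more weight. Reliability comes from
  $r^2_{DRP} = EDC/(EDC+\lambda)$, $\lambda = (4-h^2)/h^2$. The two
  formulas compose to the exact identity $d_i = \lambda/EDC_i$, which the
  test suite asserts at $10^{-12}$.

A reliability of exactly 1 would give an infinite-information residual
(weight 0); `add_drp_weights()` clamps reliabilities at 0.999 (configurable)
to keep the mixed-model equations well posed.

## Relationship matrices

**Pedigree.** `build_a_matrix()` first prunes the pedigree to the ancestor
closure of the genotyped animals, following parent links at most
`generations_back` (default 5) steps; ancestors at the horizon become
unknown founders. On the closure it applies the tabular method with
inbreeding ($a_{ii} = 1 + 0.5\,a_{sd}$), then restricts to the requested
ids. The tabular recursion is verified against an independently coded
top-down recursive-kinship oracle on hundreds of random pedigrees, plus
textbook anchors (full sibs 0.5; offspring of a parent–offspring mating has
diagonal 1.25).

**Genomic.** `build_grm_vanraden1()` centers codes by twice the allele
frequency computed from the supplied genotypes (training and validation
together — the frequencies describe the genotyped sample, not the training
subset; a caller who wants training-only frequencies can pass that subset)
and scales by $s = 2\sum_j p_j(1-p_j)$. SNPs without genotypic variance in
the data (fixed alleles, or degenerate all-heterozygote columns) carry no
information and are dropped with a warning; an entirely non-segregating set
is an error because $s=0$. For disjoint sets the pooled-set GRM satisfies
$G_{pool} = (s_1 G_1 + s_2 G_2)/(s_1+s_2)$ exactly, which links the one-
and two-component parameterisations; the suite asserts this at $10^{-10}$.

A GRM built from $m \ll n$ SNPs (the 98-SNP set) is rank deficient.
`repair_positive_definite()` adds a ridge of `epsilon * mean(diag)`
(default $10^{-6}$) to the diagonal. A ridge was chosen over blending with
$A$ because it preserves the "G constructed from the SNPs" semantics and
alters no off-diagonal relationship; the perturbation is orders of
magnitude below the sampling noise of any estimate.

## REML estimation

`fit_reml()` maximises the restricted likelihood of
$V = \sum_k \sigma^2_k Z K_k Z' + \sigma^2_b MM' + \sigma^2_e D$ by
average-information (AI) updates with step halving; whenever an AI step
would decrease the log-likelihood or leave the parameter space, the
iteration falls back to the expectation–maximisation update
$\sigma^2_i \leftarrow \sigma^2_i + \sigma^4_i\,(y'PB_iPy - tr(PB_i))/q_i$
(with $q_i$ the dimension of the term), which cannot decrease the
likelihood — so the reported trajectory is non-decreasing, and the suite
checks that. Numerical choices, fixed once:

* starting values: $\sigma^2_e = 0.5\,var(y)$, the remainder split equally
  across random terms (overridable, e.g. to warm-start replicate runs);
* variance floor $10^{-8}\,var(y)$ — boundary estimates are reported at
  the floor rather than as exact zeros;
* convergence when $|\Delta \log L| < 10^{-8}$ *and* the relative
  parameter change is below $10^{-6}$; iteration cap 200, with
  non-convergence raised as an error carrying the likelihood trajectory.

Solutions at the optimum are obtained in the equivalent
generalized-least-squares form: $\hat\mu = (1'V^{-1}1)^{-1}1'V^{-1}y$ and
$\hat g_k = \sigma^2_k K_k[\cdot,obs]\,Py$. Individuals present in a
relationship matrix but absent from the phenotype table (the validation
bulls) receive predictions through this covariance propagation, which is
identical to carrying them as unphenotyped levels in one joint
mixed-model-equation solve. The test suite proves the algebra against an
independently assembled dense Henderson MME for every model variant, and
the GBLUP–SNP-BLUP equivalence ($\hat g = Z_c\hat\alpha$ under per-SNP
variance $\sigma^2_g/s$) against a ridge-regression oracle.

`compute_aic()` returns $-2\log L_{REML} + 2k$ with $k$ the number of
estimated variance parameters ($\mu$ is absorbed by REML). The Gaussian
constant is included, so only AIC *differences between models fitted to
the same data* are meaningful; no attempt is made to reproduce any
externally reported AIC magnitudes.

`variance_proportions()` implements the three-component decomposition
$\%var_i = 100\,\sigma^2_i/\sigma^2_{total}$ with
$\sigma^2_{total} = \sum_{genomic} \sigma^2_i$ — the residual and
lethal-regression variances are excluded from the denominator by
definition.

## Validation

`split_by_birth_year()` assigns bulls with birth year $\ge$ cutoff to
validation. The boundary is inclusive on the validation side because the
marker-discovery data that motivate a forward split typically end the year
before the cutoff; the cutoff is a plain argument, so the exclusive
reading is one integer away. Reliability is
$cor(\widehat{GEBV}, DRP)^2 / \overline{r^2_{DRP}}$ with the mean taken
over validation bulls only; values slightly above 1 can arise from
sampling noise and are reported as-is. Bias is the OLS slope of DRP on
GEBV (1.00 = no dispersion error). For lethal-regression models,
`total_gebv()` adds $M\hat b$ to the summed component GEBVs before
computing either metric. Training solutions are provably independent of
validation DRPs — the suite replaces validation phenotypes with arbitrary
values and asserts bit-identical training fits.

# The synthetic population

`simulate_population()` generates the conditions the analysis assumes:

* **Pedigree**: 200 founders and five discrete generations of 500
  offspring from random sire/dam matings, birth years advancing two years
  per generation. All non-founders are "genotyped bulls" (n = 2,500); the
  last generation (n = 500, exactly 20%) is born at the cutoff year and
  forms the forward-validation set, leaving n = 2,000 for training.
* **Genotypes**: gene drop of unlinked founder SNPs (frequencies uniform
  on [0.05, 0.95]) through the pedigree by Mendelian sampling; 5,000 chip
  SNPs plus 98 YSS-like and 300 DFS-like selected SNPs (the real selected
  sets, ~40K chip and 1,541-SNP DFS set, are scaled down to keep a full
  scenario suite and the replicated tests tractable on one CPU; every
  property tested is size-free). Twenty chip SNPs are designated recessive
  lethals and segregate at founder frequency 0.05.
* **Traits**: four survival sub-traits on the liability scale with
  heritabilities 0.007–0.027. SNP effects are drawn per set and rescaled
  on the realized genotypes so the chip/YSS-like/DFS-like sets carry
  exactly 83/6/11% of the additive variance (the planted mirror of the
  reported decomposition). Homozygous lethal genotypes subtract 0.5
  genetic standard deviations of liability per locus — lethals act on
  survival liability of live-born calves, not as embryonic lethality
  removing individuals. Binary survival is recorded by thresholding
  liability at per-period incidences of 3–8% (configuration values, not
  empirical claims). The index trait is the standardized weighted
  combination of the sub-trait genetic values.
* **DRPs**: EDC ~ Gamma(shape 8, scale calibrated by quadrature so the
  mean reliability hits the per-trait target of 0.611–0.742), then
  $DRP = TBV + \varepsilon_i$ with
  $var(\varepsilon_i) = \sigma^2_a(1-r^2_i)/r^2_i$. The shape was chosen
  by design analysis: with this calibration the population-level
  $cor(DRP, TBV)^2$ equals $1/(1+E[\lambda/EDC])$, and shape 8 keeps that
  within ~0.015 of the target mean reliability for all five traits, so the
  reliability attached to each record is consistent with the noise
  actually injected (a long-tailed shape 2 would overstate it by 6–9
  points). The suite checks the realized calibration within 0.03 at
  n = 5,000.

The synthetic SNP sets are generated disjoint. Real selected sets overlap
(the pooling operation dedupes by SNP id and is tested with overlapping
sets); disjoint planting keeps the realized variance shares auditable.

## What the simulator does not emulate

Founder SNPs are independent, so linkage disequilibrium arises only from
cosegregation within the five simulated generations — there is no
long-range chip-density LD with hidden QTL, no selection across
generations, and no genotyping or imputation error. Passing tests
therefore demonstrate the *estimators and the pipeline* are correct under
the assumed model, and reproduce directional findings (genomic beats
pedigree prediction; a small set carrying 6% of variance barely moves
reliability; planted variance shares are recovered); they do not certify
accuracy levels on real Holstein data, where LD structure, persistent
families and selection shape the achievable reliability.

# Test design and problem sizes

The replicated end-to-end checks use sizes chosen to make Monte-Carlo
error small relative to the asserted tolerances while keeping the default
suite a few minutes on one CPU: parameter recovery with 50 replicates at
n = 800 (mean estimate within two empirical standard errors of the planted
$\sigma^2_g$, plus boundary behaviour at $\sigma^2_g = 0$); variance-share
recovery with 30 replicates at n = 1,000 genotyped and a 1,898-SNP genome
(each share within ±3 points of 83/6/11); and the directional comparison
with 10 replicates at the full default scale (n_train = 2,000, 5,000 chip
SNPs), requiring genomic > pedigree reliability in at least 9 of 10 and a
mean absolute reliability change below 2 points when the 98-SNP set is
added. Replicate REML fits are warm-started from the previous replicate's
estimates — a speed device only; convergence criteria are unchanged.

# Quality-control conventions

* MAF filter: keep when $\min(p, 1-p) \ge 0.05$ — the boundary is
  inclusive by convention, and a `strict` flag flips it.
* Imputation keep rule: correlation **and** concordance strictly greater
  than 0.80, matching the "higher than" phrasing of the rule it
  implements; an undefined correlation (zero variance) fails the rule.
* Missing genotype codes are disallowed downstream; an optional pre-step
  mean-imputes them (rounded to a legal code) before filtering.

# Known limitations

Single-trait analyses only; no standard errors on variance components
beyond the AI matrix; dense matrix algebra throughout (practical to a few
thousand genotyped animals — the intended desk scale — not to national
evaluations); no single-step (combined pedigree–genomic) matrix; and the
simulator's LD limitation above. The file formats are deliberately plain
(CSV/TSV/one-id-per-line) with a PLINK `.raw` reader as the only dialect.
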