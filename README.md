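# multiblup

Multi-component genomic prediction for low-heritability dairy-cattle
survival traits, built around de-regressed proofs (DRP) as pseudo-phenotypes.

## The problem

Young-stock survival (YSS) traits — calf survival in defined rearing
periods (BP1, BP2, HP1, HP2) and the index combining them — have
heritabilities of only 0.007–0.027, so pedigree-based prediction (PBLUP) is
weak and breeders turn to genomic prediction (GBLUP). A natural question is
whether augmenting a standard ~54K SNP chip with small sets of markers
pre-selected from whole-genome sequencing GWAS (tens to a few thousand
SNPs), or with markers tagging recessive lethal haplotypes, improves the
reliability of genomic breeding values for these traits. `multiblup`
implements that complete analysis as a reusable, tested R package, together
with a gene-drop simulator of Holstein-like populations, so every stage can
be exercised without access to restricted industry data.

## The model

The response for bull *i* is its de-regressed proof with reliability

r²_DRP,i = EDC_i / (EDC_i + λ),  λ = (4 − h²)/h²,

where EDC is the effective daughter contribution. All models share the form

y = 1μ + Σ_k Z g_k (+ M b) + e,

with g_k ~ N(0, K_k σ²_k) for each genetic component — K is either the
pedigree numerator relationship matrix **A** (tabular method, genotyped
animals traced five generations back) or a VanRaden method-1 genomic
relationship matrix **G** = ZZ′/s with s = 2Σ p_j(1−p_j) and allele
frequencies taken from the data — an optional random regression b ~
N(0, Iσ²_b) on the raw 0/1/2 codes of recessive-lethal SNPs, and
heteroscedastic residuals e ~ N(0, Dσ²_e) with d_i = (1 − r²_DRP,i)/r²_DRP,i.
Variance components are estimated by average-information REML with an EM
fallback; models are compared by AIC; a three-component model (chip, and
the two selected sets as separate components) decomposes the genomic
variance as %var_i = 100·σ²_i/(σ²_54K + σ²_YSS + σ²_DFS).

Prediction quality is assessed by forward validation at a birth-year
cutoff: reliability = cor(GEBV, DRP)² / mean(r²_DRP) and dispersion bias =
the regression slope of DRP on GEBV, both over validation bulls only, with
lethal-regression effects Mb̂ added to the summed component GEBVs.

## Worked example

Simulate a small Holstein-like population (four generations, 1,150 SNPs,
planted 6%/11% variance shares for the selected sets, 10 recessive-lethal
SNPs) and run four prediction scenarios for the BP1 sub-trait:

```r
library(multiblup)
cfg <- sim_config(n_founders = 100, matings_per_generation = 150,
                  n_generations = 4, n_chip_snps = 1000, n_yss_snps = 60,
                  n_dfs_snps = 90, n_lethal = 10)
sim <- simulate_population(cfg, seed = 2024)
res <- run_scenario_suite(sim, traits = "BP1",
        scenarios = c("PBLUP", "54K", "54K+YSS+DFS", "3c:54K+YSS+DFS"))
round(res$reliability, 3)
#>     PBLUP   54K 54K+YSS+DFS 3c:54K+YSS+DFS
#> BP1  0.34 0.429       0.459          0.457
round(res$bias, 3)
#>     PBLUP   54K 54K+YSS+DFS 3c:54K+YSS+DFS
#> BP1 1.057 1.097        1.06          1.028
res$shares
#>   trait       scenario term percent
#> 1   BP1 3c:54K+YSS+DFS g54K    80.2
#> 2   BP1 3c:54K+YSS+DFS gYSS     9.5
#> 3   BP1 3c:54K+YSS+DFS gDFS    10.3
```

Reading the output: genomic relationships lift validation reliability from
0.34 (pedigree) to 0.43; pooling the planted selected sets into the GRM
adds a further ~3 points on this small simulation; dispersion bias stays
near 1 (neither inflated nor deflated predictions); and the
three-component fit attributes roughly 80/10/10% of the genomic variance
to chip/YSS-like/DFS-like sets, close to the planted 83/6/11 split. The
weighting arithmetic is available directly:

```r
drp_reliability(1000, 0.014)  # EDC = 1000 at h2 = 0.014
#> [1] 0.7784
residual_weight(0.742)        # D-matrix element at r2 = 0.742
#> [1] 0.3477
```

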