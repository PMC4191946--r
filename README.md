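# raveburden

Rare-variant burden testing and exact case–control association for
targeted gene-panel sequencing studies.

## The problem

Sporadic ALS (and heterogeneous diseases like it) rarely yields a single
causative gene: individual rare variants are too infrequent for per-site
tests to have any power. A practical design sequences a panel of
candidate genes (here modelled on a 169-gene panel across four
categories — known ALS genes, GWAS-associated genes, trio-study
candidates, and RNA-recognition-motif genes) in a case–control cohort
(242 cases / 129 controls), and then:

1. hard-filters raw variant calls on site quality
   (DP < 5, QUAL < 30, QD < 2, FS > 50, HaplotypeScore > 13, MQ < 30,
   MQRankSum < −12.5, ReadPosRankSum < −8 fail);
2. classifies each nonsynonymous variant as **novel** (absent from
   dbSNP v137, ESP6500 and 1000 Genomes) or **rare** (ESP6500 frequency
   ≤ 0.000538, the database frequency of the pathogenic SOD1 p.D91A
   allele; or dbSNP-listed without frequency and below 0.01 in
   1000 Genomes), discarding variants seen in both cases and controls;
3. collapses each sample's qualifying variants into one deleteriousness
   score by **PolyPhen-2-weighted allele binning** — by default the
   maximum score, so a sample with score ≥ 0.85 ("probably damaging")
   counts as a deleterious-variant carrier;
4. compares carrier counts between groups with **exact 2×2 inference**:
   two-sided p (minlike or central convention), the conditional
   maximum-likelihood odds ratio (CMLE) under the noncentral
   hypergeometric distribution

   P(X = x | margins; θ) ∝ C(m₁, x) · C(m₂, n₁ − x) · θˣ,

   and a confidence interval obtained by inverting the chosen test;
5. reports per-gene and gene-category carrier prevalence, common-SNP
   association, and APOE ε-diplotype phenotype associations (ε alleles
   called from rs429358 / rs7412 dosages).

Patient-level data from such studies are not redistributable, so the
package ships a synthetic cohort generator (`simulate_study`) that
reproduces the design — cohort sizes, panel structure, the rarity
anchor, Hardy–Weinberg common variation, planted carrier odds ratios
and a two-SNP APOE locus — and the whole pipeline runs end-to-end on
simulated data.

## Worked example

The carrier configuration 10/242 cases vs 1/129 controls:

```r
library(raveburden)
snp_carrier_test(10, 1, 242, 129)
#> Exact 2x2 test (minlike two-sided)
#>      [,1] [,2]
#> [1,]   10  232
#> [2,]    1  128
#> p = 0.1056, conditional MLE OR = 5.5, 95% CI (0.7798, 118.9)
```

The p-value sums all tables (given both margins) no more likely than
the observed one; the odds ratio solves the conditional score equation
E_θ[X] = 10; the interval collects every θ the minlike test would not
reject at 5%. A full simulated study:

```r
st <- simulate_study(seed = 1)
cl <- classify_variants(st$cohort)
cl$counts[c("novel", "rare", "excluded_shared")]
#>           novel            rare excluded_shared
#>             254             407              39
burden_test(cl$cohort, cl$classification, st$panel)
#> Allele-binning burden test over gene set 'known_als+associated' (102 genes)
#> carriers: 62/242 cases vs 14/129 controls
#> Exact 2x2 test (minlike two-sided)
#>      [,1] [,2]
#> [1,]   62  180
#> [2,]   14  115
#> p = 0.000685, conditional MLE OR = 2.822, 95% CI (1.516, 5.596)
```

The planted deleterious-carrier odds ratio in the default generator is
1.93; the run above estimates 2.82 with a CI comfortably covering the
truth. File-based runs go through `run_pipeline()` (or the wrapper
script in `inst/scripts/raveburden.R`), which consumes a VCF +
annotation + manifest + panel set and writes classification, burden,
prevalence, SNP, enrichment and APOE result tables plus a run report.

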