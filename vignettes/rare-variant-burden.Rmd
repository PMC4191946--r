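---
title: "Methods: rare-variant classification, allele-binning burden tests and exact 2x2 inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant classification, allele-binning burden tests and exact 2x2 inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raveburden)
```

## Scope and model

`raveburden` implements the analysis chain of a candidate-gene
case–control sequencing study: site quality filtering, novel/rare
variant classification against population databases, PolyPhen-weighted
allele binning with an exact carrier test, prevalence and enrichment
tables, and APOE ε-diplotype association. Alignment and variant calling
are out of scope — the pipeline starts from a multi-sample VCF plus an
annotation table, and only re-applies the published hard-filter
thresholds to the VCF's site-level fields.

The statistical heart is conditional inference for a 2×2 table. Given
both margins, the top-left cell follows the noncentral hypergeometric
distribution with odds-ratio parameter θ. All tests, estimates and
intervals derive from that one likelihood, so every reported p-value,
odds ratio and confidence limit is mutually consistent.

## Exact 2×2 inference

Two two-sided conventions are exposed, because the literature uses
both and they disagree for asymmetric tables:

* **minlike** (default): p is the total probability of all outcomes no
  more likely than the observed one. This is the convention of
  `stats::fisher.test` and reproduces the study-style p-values. Ties
  are accepted with a relative tolerance of 1e−7, matching
  `fisher.test`, so that floating-point noise cannot drop an exactly
  tied outcome.
* **central**: twice the smaller one-sided tail, capped at 1.

The odds-ratio estimate is always the conditional MLE, the root of
E_θ[X] = x, found by bisection-seeded `uniroot` on the log-odds scale
(tolerance 1e−10). When x sits at the boundary of its support the CMLE
is 0 or ∞ and is reported as such — no continuity corrections.

Confidence intervals invert the selected test, so the 95% interval
excludes 1 exactly when the corresponding two-sided test rejects at
5% (a tested invariant). The central interval solves the two one-sided
tail equations at α/2 (the classical exact interval, as in
`fisher.test`). The minlike p-value function is not monotone in θ —
it has jump discontinuities where outcome probabilities cross — so the
minlike interval is the hull of {θ : p(θ) ≥ α}, located by a coarse
log-scale scan (to step over local dips) followed by bisection on the
inside/outside indicator. Tables with a zero margin carry no
information about θ; they return p = 1, OR = 1 and a degenerate flag
rather than an error, so a pipeline run on pathological data completes
with interpretable output.

Probabilities are computed from log-binomial coefficients, normalised
after subtracting the maximum, so tables far larger than this study's
remain stable.

## Classification rules and their boundaries

A variant is **novel** when absent from all three databases (dbSNP,
ESP6500, 1000 Genomes). Absence means no listing at all: a database
entry with frequency 0 still counts as present, because the novelty
rule is about membership, not magnitude. A database-known variant is
**rare** when its ESP6500 frequency is **at or below** 0.000538
(inclusive — the cutoff is itself the frequency of a known pathogenic
allele, which must classify rare), or when it is dbSNP-listed without a
frequency, absent from ESP6500, and **below** 0.01 (exclusive) in
1000 Genomes. Quality rules use strict comparators (DP < 5 fails,
DP = 5 passes), and absent fields never fail their rule.

Only protein-altering classes (nonsynonymous, stopgain, stoploss,
frameshift) enter the novel/rare analysis; synonymous SNPs remain
visible to the common-SNP association step. A novel or rare variant
carried by at least one case *and* one control is removed
(`excluded_shared`) as a likely benign polymorphism. Whether the
functional restriction runs before or after the shared exclusion does
not change the result — exclusion is decided per variant from its own
carriers — and the suite asserts this commutativity rather than fixing
an order by decree.

Missing genotypes are never treated as reference: a sample with `./.`
at a site is simply not a carrier there, and carrier denominators stay
at the full cohort sizes, matching how the study reports prevalence.

## Allele binning and its open choices

Each sample's qualifying variants in a gene set collapse to one score.
Two aggregation modes are exposed because a per-individual "score" is
not fully pinned down by the description the method follows:

* `max` (default): the score is the best-supported damaging variant;
  "score ≥ 0.85" then means "carries ≥ 1 probably-damaging variant",
  i.e. a carrier-collapsing test. This is the most literal reading of
  thresholding a [0, 1] score per individual.
* `sum`: scores add, so two possibly-damaging variants (0.5 + 0.5) can
  cross the threshold together.

Variants without a PolyPhen score are down-weighted to 0 by default
(the method's declared intent is to down-weight anything not predicted
deleterious), or excluded via `score_missing_policy`. Truncating
variants (stopgain, stoploss, frameshift) are never scored by
PolyPhen; the default policy assigns them 1.0 — a premature stop is at
least as damaging as any missense — with 0 selectable
(`lof_score_policy`). Both behaviours are tested.

The default gene set is the union of the known-ALS and associated
categories: the genes with a high prior for involvement, which is
where a burden signal is interpretable.

## The synthetic cohort generator

`simulate_study()` emulates the study design so the full pipeline runs
without patient data: 242 cases / 129 controls; a 169-gene panel split
22 known / 80 associated / 34 trios / 33 RRM with a few
multi-category genes and stress-granule / hnRNP / chromatin sub-set
tags; per-gene database sites covering every classification rule
(common sites, rare sites below the cutoff, a just-above-cutoff site,
dbSNP-no-frequency sites on both sides of the 1000 Genomes rule,
1000-Genomes-only sites); an anchor pathogenic variant at ESP frequency
exactly 0.000538 carried by two cases; and a two-SNP APOE locus.

Generative assumptions, chosen once:

* Common variants are drawn under Hardy–Weinberg equilibrium from their
  catalog frequencies, identically in both groups (the suite checks
  genotype frequencies against p², 2pq, q²).
* Every planted novel variant is private to one individual — rare
  causal variation is essentially never shared — so the shared-variant
  exclusion fires only on database variants, unless
  `force_shared_variant` plants a shared one for testing.
* Deleterious-carrier status is Bernoulli per sample: probability 0.15
  in controls (a realistic carrier fraction for a panel of this size;
  the study does not print its control carrier count) and the
  odds-scaled probability in cases, with planted odds ratio 1.93 (the
  study's burden estimate) by default. Each carrier receives one
  private novel variant scoring in [0.85, 1] (or an unscored
  truncating variant) inside the known+associated set.
* The two planted signals are kept orthogonal: stress-granule carriage
  (planted odds ratio 5.5, the value implied by 10/242 vs 1/129
  carriers) uses variants scoring strictly below 0.85, and database
  variants lean benign (< 0.85), so the deleterious-carrier odds ratio
  is exactly the quantity the burden test measures and the planted
  stress-granule odds ratio is exactly what the enrichment test
  measures. Without this separation the two planted effects would
  attenuate each other and no planted value would be recoverable
  exactly.
* APOE genotypes come from per-sample allele pairs at frequencies
  ε2/ε3/ε4 = 0.08/0.78/0.14 (typical European values; the study prints
  none), so impossible dosage combinations cannot arise. Onset site is
  drawn per case from a base distribution (bulbar/upper-limb/limb ≈
  1/3 each, mirroring the three case panels) with the ε2 odds on
  upper-limb onset multiplied by 5.22 for carriers and the limb odds
  multiplied by 4.13 for female ε4 carriers (the study's two reported
  effect magnitudes).
* Site quality fields are drawn passing, with a configured 2% of sites
  violating one hard filter; genotypes are masked missing at 1%.

What the generator does **not** model: linkage disequilibrium
(irrelevant for private rare variants, and deliberately absent from
the binning method), gene length variation, population structure,
relatedness, sequencing error, and allelic series within a gene.
Passing simulation tests therefore demonstrates the statistical
machinery — calibration, coverage, monotonicity, determinism — not
robustness to those real-data complications.

## Problem sizes and numerical choices in the test suite

Simulation studies in the suite keep the cohort at the study's
242/129 but use compact panels (8–12 genes) so that coverage runs with
500 replicates per planted odds ratio and the null calibration with
2000 replicates complete in minutes; panel size affects runtime, not
the carrier model. Coverage of the planted odds ratio by the exact
conditional CI is asserted at ≥ 90% (the interval is conservative, so
empirical coverage sits near 97%), and empirical type-I error of the
burden test at α = 0.05 under a null planting is asserted ≤ 0.05 (the
exact test is conservative). The enumeration cross-check compares both
p-value conventions against an independent factorial-formula oracle
for every 2×2 table with N ≤ 60 at 1e−12.

All generator stages are driven by integer seeds through R's default
RNG, with the caller's RNG state saved and restored; identical seeds
give byte-identical files and result tables (tested).

## Known limitations

* No multiple-testing correction is applied anywhere — the analysis
  reports per-test exact p-values, as the original analysis did. With
  dozens of SNP and stratum tests, nominal 0.05 findings are
  hypothesis-generating only.
* Carrier denominators ignore per-sample capture failure; only
  per-genotype missingness is handled.
* The APOE double heterozygote is phase-ambiguous; it is called ε2/ε4
  (the dominant phase in the population), flagged `ambiguous`, and the
  rare ε1 haplotype is not modelled — dosage pairs requiring it are a
  data error.
* The exact intervals are conservative by construction; with very
  sparse tables they can be extremely wide, which is a property of the
  inference, not a defect of the implementation.
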