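---
title: "Orthogonal genetic-effects modelling for small deeply phenotyped cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal genetic-effects modelling for small deeply phenotyped cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiascan)
```

## The problem this package addresses

Diet-challenge studies in non-human primates produce a data shape that is
rare in human genetics: very small cohorts (tens of animals) with extremely
deep, longitudinal phenotyping — dozens of correlated metabolic traits per
animal — and a handful of candidate loci discovered by targeted capture
sequencing of extreme-phenotype animals. `noiascan` implements the analysis
chain for such designs end to end:

1. **Discovery** — multi-caller consensus over candidate variant sites,
   followed by a *homozygous-discordance* filter: a site is a candidate when
   (nearly) all animals of one phenotype group are homozygous for the
   alternate allele while the other group carries no non-reference call at
   all. In a 2×2 carrier table this is an odds ratio diverging to infinity.
   The carrier requirement is relaxed stepwise (all of 4, then 3 of 4, then
   2 of 4) while the zero-tolerance rule for the comparison group is kept.
2. **Annotation gating** — candidates are retained only when nonsynonymous
   *and* called deleterious by SIFT or PROVEAN, and CADD PHRED scores are
   tiered at the conventional bounds (≥ 20: top 1% of substitutions;
   ≥ 10: top 10%).
3. **Association** — allelic case/control tests (chi-square, Fisher exact,
   sample odds ratio) and dosage regressions per quantitative trait, with
   empirical p-values from an adaptive permutation engine.
4. **NOIA modelling** — the core of the package: orthogonal genetic-effects
   models over up to three biallelic loci, screened across the full trait
   panel.

## The NOIA parameterization

For one biallelic locus with observed genotype frequencies
$(p_{11}, p_{12}, p_{22})$ over the classes homozygous-major (code 1),
heterozygous (2) and homozygous-minor (3), the *statistical* formulation of
the NOIA (Natural and Orthogonal InterActions) model builds three scale
vectors over the genotype codes:

* intercept: $(1, 1, 1)$;
* additive: minor-allele dosage centred by its frequency-weighted mean,
  $x_a(g) = d(g) - (p_{12} + 2 p_{22})$ with $d = (0, 1, 2)$;
* dominance:
  $x_d = \left(\dfrac{-2 p_{12} p_{22}}{D},\; \dfrac{4 p_{11} p_{22}}{D},\;
  \dfrac{-2 p_{11} p_{12}}{D}\right)$, where
  $D = p_{11} + p_{22} - (p_{11} - p_{22})^2$.

These satisfy $\sum_g p_g x_a(g) = \sum_g p_g x_d(g) =
\sum_g p_g x_a(g) x_d(g) = 0$ for *any* genotype frequencies — orthogonality
does not require Hardy–Weinberg equilibrium. This matters for small closed
colonies, whose genotype frequencies routinely depart from HWE: orthogonal
columns mean that an effect estimate barely moves when other terms enter or
leave the model, so model screening is stable. Multi-locus designs take
element-wise products of the per-locus columns (the Kronecker construction
restricted to the active terms); under linkage equilibrium the cross-locus
columns are orthogonal in expectation, which the test suite checks at
$n = 10{,}000$.

```{r scales}
g <- rep(1:3, times = c(49, 42, 9))   # frequencies (0.49, 0.42, 0.09)
locus_scales(g)
```

The *functional* formulation (classical $x_a = (-1, 0, 1)$,
$x_d = (-\tfrac12, \tfrac12, -\tfrac12)$ contrasts, orthogonal only at
symmetric frequencies) is available behind `formulation = "functional"`;
the statistical formulation is the default precisely because these cohorts
depart from HWE.

### Model space and screening

Each locus is `absent`, `additive` or `dominance`, giving $3^3 - 1 = 26$
candidate models for three loci. The default space contains main effects
only: the per-locus conclusions this class of study reports are additive or
dominance effects, and an explicit epistatic term is never asserted, so
interaction products (up to the three-way term; 8 columns in the full
design) are a documented opt-in (`include_interactions = TRUE`) rather than
part of the default screen. `screen_models()` fits every (model, trait)
pair by ordinary least squares, reports the whole-model F-test against the
intercept-only model, and keeps fits with $p < \alpha$ (default 0.05,
mirroring the nominal screening convention; no multiple-testing correction
is applied, which users should weigh when interpreting counts). The best
model per trait is the one with the lowest model p; ties go to fewer
terms, then to canonical enumeration order. Genotype frequencies — hence
scales — are re-estimated from the complete cases entering each fit, which
preserves within-fit orthogonality exactly at the cost of slightly
different scales across fits.

Degenerate inputs are handled explicitly: a locus with only two observed
genotype classes has no dominance scale (the fit is skipped and logged,
not fudged); a monomorphic locus is untestable; a constant trait reports
$R^2 = 0$ and model p 1; rank deficiency is an error naming the model.

## The adaptive permutation engine

Empirical p-values permute group labels (or trait values) and count
permutation statistics at least as extreme as the observed one. Two
regimes:

* **Exhaustive** (cohorts of ≤ 10 animals with two-level labels): every
  distinct label arrangement is enumerated — $\binom{8}{4} = 70$ for the
  4 vs 4 discovery design — and the exact permutation p is returned. With
  a symmetric (two-sided) statistic, perfect carrier separation gives
  $p = 2/70 \approx 0.0286$: both perfect relabellings attain the maximal
  statistic. On 2×2 problems with equal group sizes this exactly
  reproduces the Fisher/hypergeometric p, which the acceptance suite
  verifies over all $3^8$ zygosity configurations.
* **Adaptive sampling** (larger cohorts): permutations are drawn in blocks
  with the add-one estimator $p = (1 + b)/(1 + n)$ (never exactly zero),
  stopping once the Clopper–Pearson interval at confidence 0.99 for the
  exceedance probability lies entirely above or below the decision level
  $\alpha$. The interval rule and its confidence are package choices —
  "adaptive permutation" is a procedure family, not a fixed algorithm —
  and both are explicit `permutation_plan()` parameters.

Sidedness is the caller's choice of statistic: the shipped
`allelic_chisq_statistic()` and `carrier_chisq_statistic()` are symmetric
in the groups, hence two-sided.

## The synthetic cohort generator

No individual-level primate data are distributable, so the generator is a
first-class module that emulates the *structure* the analysis assumes, at
the study's scale: 43 genotyped and deeply phenotyped adult females, three
biallelic loci (canonically ordered PLA2G4A, APOB.1, APOB.2), and 37
quantitative traits, six of them named metabolic measures (weight change %,
leptin/body-weight ratio, DXA total fat, insulin/glucose ratio,
triglycerides, free fatty acids) that carry the default injected effects —
APOB.1 additive on the first three, PLA2G4A and APOB.2 jointly additive on
the insulin/glucose ratio, PLA2G4A on triglycerides, APOB.2 on free fatty
acids — mirroring the per-locus conclusions of this study design.

Choices a user should know about:

* **Genetic effects are injected on the NOIA statistical scales computed
  from the realized genotype frequencies**, so recovery tests are
  self-consistent: the estimand of the fit is exactly the injected
  magnitude.
* **Trait correlation enters through the noise only** (a Gaussian copula:
  multivariate normal noise with a configurable correlation matrix,
  default exchangeable 0.3 among the six named traits). Real trait
  correlation also flows through shared genetic effects; the generator
  reproduces that only to the extent that injected effects overlap.
* **Minor-allele frequencies default to 0.30/0.25/0.25** — moderate
  frequencies plausible for segregating variants in a closed breeding
  colony; the study reports no cohort allele frequencies, so these are a
  package default, not an estimate.
* **Missingness is completely at random** at configurable genotype and
  phenotype rates. The partial-data panel of a real study (71 animals, 28
  with partial phenotypes) is not missing at random; MCAR is the neutral
  default absent a stated mechanism.
* Traits are Gaussian on their analysis scale. Real metabolic traits are
  often right-skewed and log-transformed first; the generator does not
  model that, so passing tests demonstrate correctness of the estimators,
  not robustness to distributional misspecification.

Everything is reproducible bitwise from `cohort_config(..., seed = )`.

## Phenotype derivation and classification

Composite traits follow fixed unit conventions: tolerance-test AUCs are
trapezoidal areas of the raw trace from zero (not baseline-subtracted);
HOMA-IR is glucose [mg/dL] × insulin [µU/mL] / 405; weight change is
percent of initial weight; the leptin ratio is ng/ml per kg body weight.
Resistant/sensitive classification is *configuration, not constants*: the
decision boundaries that split such cohorts are study-specific and are
supplied as a `classification_rule()` (per-trait cutoff and direction,
combined by all/any/majority). Trait correlation matrices use
pairwise-complete observations so partial-data animals still contribute,
with the conventional */**/*** stars at 0.05/0.01/0.001. Baseline group
comparisons use Welch's t-test (no equal-variance assumption defensible at
n = 4–20 per group) for numeric traits and Fisher's exact test for
categorical ones such as parity.

## Probe design

Capture probes are selected by sliding an 85 bp window (step 1 by default;
step size is configurable since "sliding" under-determines it) along
multi-species exon alignments and keeping windows whose *columnar*
conservation — the fraction of window columns where every species carries
the identical non-gap base — is at least 0.90. Columnar identity is the
stricter of the plausible readings of percent conservation, and gaps count
as mismatches. Retained windows are then filtered on repetitiveness: every
15-mer of the reference genome is counted once with the two strands folded
together (k-mers containing N are skipped), and a window survives when the
mean count of its 71 constituent 15-mers is below 100. Output coordinates
are 0-based half-open BED.

## Numerical choices and problem sizes

* Orthogonality identities are asserted to 1e-10; OLS agrees with a
  normal-equations oracle to 1e-8; exact permutation p agrees with the
  hypergeometric oracle to 1e-12.
* The test suite's simulation sizes — 1,000 random frequency triples,
  linkage-equilibrium cohorts of 10,000, 200 replicates at n = 2,000 for
  per-model recovery, 200 null-screen replicates at the 43-animal scale —
  were chosen so Monte-Carlo error is several times smaller than each
  asserted tolerance.
* CI coverage in the recovery suite is pooled over the terms of all 26
  models (10,800 intervals), where the ±3-percentage-point band is many
  Monte-Carlo standard errors wide; per-model 200-replicate coverage would
  make the band itself the dominant noise source.
* Ordering conventions are fixed and documented: genotype codes 1/2/3,
  loci ordered PLA2G4A, APOB.1, APOB.2, model ids as per-locus codes
  (`0`/`a`/`d`, e.g. `0a0` = APOB.1 additive only), genotype-effect tables
  enumerating all 27 joint classes with the first locus varying slowest.

## Known limitations

* No kinship or pedigree adjustment: association and NOIA fits assume
  exchangeable animals. Closed colonies have low but nonzero mean kinship;
  estimates are unbiased under the generator but real-data standard errors
  will be slightly optimistic.
* No covariate adjustment or mixed models; no imputation of missing
  genotypes (complete-case per fit).
* The model screen reports nominal p-values; with 26 models × 37 traits,
  ~48 significant fits are expected under the global null at α = 0.05 (the
  calibration test asserts exactly this).
* The VCF dialect is deliberately minimal: single ALT, GT-only FORMAT.
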