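# noiascan

Genotype-phenotype discovery for small, deeply phenotyped cohorts — the
data shape of primate diet-challenge studies: tens of animals, dozens of
correlated metabolic traits, and a handful of candidate SNPs from targeted
capture sequencing of extreme-phenotype individuals.

The package implements the full analysis chain:

* **Discovery** — consensus intersection across variant callers, then a
  homozygous-discordance filter: keep sites where ≥ k animals of one
  phenotype group are homozygous-alternative while the other group carries
  no non-reference call (an "infinite odds ratio" in the 2×2 carrier
  table), with the relaxation ladder k = 4, 3, 2.
* **Annotation gating** — retain nonsynonymous candidates with a
  deleterious SIFT or PROVEAN call; tier CADD PHRED scores at ≥ 20
  (top 1% of substitutions) and ≥ 10 (top 10%).
* **Association** — allelic case/control tests (chi-square, Fisher exact,
  sample odds ratio) and dosage regressions per trait, with empirical
  p-values from an adaptive permutation engine that switches to exhaustive
  enumeration (exact p) on cohorts of ≤ 10 animals.
* **NOIA modelling** — the core. For each biallelic locus with observed
  genotype frequencies (p11, p12, p22), the statistical NOIA formulation
  builds an additive scale x_a = dosage − (p12 + 2 p22) and a dominance
  scale x_d = (−2 p12 p22, 4 p11 p22, −2 p11 p12) / D with
  D = p11 + p22 − (p11 − p22)², so that intercept, additive and dominance
  columns are mutually orthogonal under the observed frequencies — no
  Hardy–Weinberg assumption. Multi-locus designs use products of the
  per-locus columns. All 3³ − 1 = 26 three-locus models are enumerated and
  screened against every trait by OLS with a whole-model F-test.
* **Phenotypes** — composite traits (tolerance-test AUC from zero,
  HOMA-IR, weight change %, leptin/body-weight ratio), configurable
  resistant/sensitive classification, pairwise-complete Pearson
  correlation matrices with significance stars, Welch/Fisher baseline
  comparisons.
* **Probe design** — 85 bp sliding windows over multi-species exon
  alignments at ≥ 90% columnar conservation, filtered to windows whose 71
  constituent 15-mers have mean genome-wide count < 100 (strands folded).
* **Synthetic cohorts** — a generator that emulates the assumed data
  structure (43 animals, 3 loci, 37 correlated traits with injected
  additive/dominance/epistatic effects), so everything above is testable
  without external data.

## Worked example

```r
library(noiascan)

# a study-scale synthetic cohort: 43 animals, 3 loci, 37 traits
cohort <- simulate_cohort(cohort_config(seed = 1))

# orthogonal scales at one locus
locus_scales(cohort$genotypes[, "APOB.1"])

# screen all 26 three-locus NOIA models against all 37 traits
screen <- screen_models(cohort$genotypes, cohort$phenotypes)
screen
#> noia_screen: 962 fits, 116 significant at alpha = 0.05 across 15 traits

head(screen$best[, c("trait", "model_id", "model_p", "r_squared", "n_used")])
#>                     trait model_id  model_p r_squared n_used
#> 1        free_fatty_acids      00a 1.22e-05    0.3762     43
#> 27  insulin_glucose_ratio      ada 3.80e-06    0.5070     43
#> 53        leptin_bw_ratio      0a0 1.64e-03    0.2170     43
#> 79          total_fat_dxa      0a0 7.88e-05    0.3193     43
#> 105              trait_07      0d0 2.12e-01    0.0377     43
#> 131              trait_08      0a0 6.72e-02    0.0794     43
```

Model ids are per-locus codes over (PLA2G4A, APOB.1, APOB.2): `0` absent,
`a` additive, `d` dominance. With the default generator the injected
structure is recovered: `0a0` (APOB.1 additive) is the best model for the
leptin ratio and DXA fat, `00a` (APOB.2 additive) for free fatty acids,
and the insulin/glucose ratio — injected with effects at both PLA2G4A and
APOB.2 — selects a two-locus model (`ada`). The 116 significant fits
across 15 traits include the ~48 expected by chance from screening
962 model × trait pairs at α = 0.05; `screen$significant$n_loci_with_effect`
tabulates how many loci have individually significant terms in each fit.

`fit_model()` returns per-term estimates/SEs/p-values and the predicted
genotypic effect for each of the 27 joint genotype classes
(`genotype_effect_table()`), the data behind genotype-vs-effect panels.

The end-to-end pipeline (simulate → discover → associate → NOIA →
phenotype summaries → probe design) runs as

```r
run_demo("demo_out", seed = 1)   # writes 18 artifacts + manifest.tsv with MD5s
```

or from a shell via the thin dispatcher `inst/cli/noiascan.R`
(`Rscript inst/cli/noiascan.R demo --out demo_out --seed 1`; subcommands
`simulate`, `discover`, `assoc`, `noia`, `phenotypes`, `probes` operate on
files). Identical config and seed give byte-identical outputs.

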