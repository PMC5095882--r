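test_that("cohort simulation has the study-scale shape and is seed-deterministic", {
  cfg <- cohort_config(seed = 7L)
  cohort <- simulate_cohort(cfg)
  expect_identical(dim(cohort$genotypes), c(43L, 3L))
  expect_identical(colnames(cohort$genotypes), c("PLA2G4A", "APOB.1", "APOB.2"))
  expect_equal(ncol(cohort$phenotypes), 38L)  # animal_id + 37 traits
  expect_equal(nrow(cohort$phenotypes), 43L)
  expect_true(all(cohort$genotypes %in% 1:3))

  again <- simulate_cohort(cfg)
  expect_identical(cohort$genotypes, again$genotypes)
  expect_identical(cohort$phenotypes, again$phenotypes)
})

test_that("zero effects and zero noise give traits constant at their intercepts", {
  cfg <- cohort_config(n_animals = 10L, n_traits = 4L,
                       trait_names = paste0("t", 1:4),
                       trait_effects = list(),
                       trait_correlation = diag(4),
                       trait_intercepts = c(1, 2, 3, 4),
                       noise_sd = 0, seed = 3L)
  cohort <- simulate_cohort(cfg)
  Y <- as.matrix(cohort$phenotypes[, -1])
  for (j in 1:4) expect_equal(unname(Y[, j]), rep(j, 10))
})

test_that("an injected additive effect is recovered by an independent least-squares fit", {
  cfg <- cohort_config(
    n_animals = 2000L, n_traits = 1L, trait_names = "t1",
    loci = list(locus_spec("L1", maf = 0.3)),
    trait_effects = list(effect_spec("t1", list(
      list(loci = "L1", types = "additive", magnitude = 2.0)))),
    trait_correlation = matrix(1, 1, 1), noise_sd = 1, seed = 11L)
  cohort <- simulate_cohort(cfg)
  # oracle: plain lm of the trait on the generating additive scale
  sc <- locus_scales(cohort$genotypes[, 1])
  x <- sc$x_a[cohort$genotypes[, 1]]
  slope <- unname(coef(lm(cohort$phenotypes$t1 ~ x))[2])
  expect_lt(abs(slope - 2.0), 0.15)
})

test_that("genotype frequencies converge to the locus specification", {
  cfg <- cohort_config(n_animals = 10000L, n_traits = 1L, trait_names = "t1",
                       loci = list(locus_spec("L1", maf = 0.25)),
                       trait_effects = list(),
                       trait_correlation = matrix(1, 1, 1), seed = 5L)
  g <- simulate_cohort(cfg)$genotypes[, 1]
  expected <- c(0.75^2, 2 * 0.25 * 0.75, 0.25^2)
  gof <- chisq.test(tabulate(g, 3L), p = expected)
  expect_gt(gof$p.value, 0.001)
})

test_that("config validation rejects degenerate inputs", {
  expect_error(locus_spec("L1", maf = 0), "degenerate")
  expect_error(locus_spec("L1", maf = 1), "degenerate")
  expect_error(locus_spec("L1", genotype_freqs = c(0.5, 0.5, 0.5)), "sum to 1")
  bad_R <- matrix(c(1, 2, 2, 1), 2)  # symmetric but indefinite
  expect_error(cohort_config(n_traits = 2L, trait_names = c("a", "b"),
                             trait_effects = list(), trait_correlation = bad_R),
               "positive semidefinite")
  expect_error(cohort_config(missing_rate_genotype = 1.5), "rates")
  expect_error(cohort_config(n_animals = 0), "n_animals")
})

test_that("noiseless callers reproduce the truth and consensus is their intersection", {
  cohort <- simulate_cohort(cohort_config(seed = 2L))
  clean <- simulate_callsets(cohort$genotypes, n_callers = 3L,
                             miss_call_rate = 0, seed = 9L)
  sites <- attr(cohort$genotypes, "sites")
  keys <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  for (cs in clean) {
    truth <- t(cohort$genotypes)[match(callset_keys(cs), keys), , drop = FALSE]
    codes <- matrix(zygosity_to_code(cs$zygosity), nrow(cs$zygosity))
    expect_identical(unname(codes), unname(truth))
  }
  expect_identical(callset_keys(clean[[1]]), callset_keys(clean[[2]]))

  noisy <- simulate_callsets(cohort$genotypes, n_callers = 3L,
                             miss_call_rate = 0.2, seed = 9L)
  consensus <- consensus_intersect(noisy)
  for (cs in noisy) expect_true(all(consensus %in% callset_keys(cs)))

  one <- simulate_callsets(cohort$genotypes, n_callers = 1L,
                           miss_call_rate = 0.1, seed = 4L)
  expect_identical(consensus_intersect(one), callset_keys(one[[1]]))

  expect_error(simulate_callsets(cohort$genotypes, miss_call_rate = 1.2), "\\[0,1\\]")
  expect_error(simulate_callsets(cohort$genotypes, n_callers = 0), ">= 1")
})

test_that("call-set simulation is deterministic under its seed", {
  cohort <- simulate_cohort(cohort_config(seed = 2L))
  a <- simulate_callsets(cohort$genotypes, 3L, 0.2, seed = 13L)
  b <- simulate_callsets(cohort$genotypes, 3L, 0.2, seed = 13L)
  expect_identical(a, b)
})

test_that("mini-genome alignments honour length, rows and divergence", {
  mg <- simulate_mini_genome(100L, n_species = 4L, divergence = 0, seed = 1L)
  expect_length(mg$alignment, 4L)
  expect_true(all(nchar(mg$alignment) == 100L))
  win <- scan_windows(mg$alignment, window_len = 85L, min_conservation = 0.9)
  expect_equal(nrow(win), 16L)            # 100 - 85 + 1 start positions
  expect_true(all(win$conservation == 1))

  div <- simulate_mini_genome(500L, n_species = 3L, divergence = 0.5, seed = 1L)
  expect_false(identical(div$alignment[[1]], div$alignment[[2]]))

  expect_error(simulate_mini_genome(50L), "shorter than window")
  expect_error(simulate_mini_genome(200L, n_species = 1L), "2 species")
})

test_that("missingness is injected at the configured rates", {
  cfg <- cohort_config(n_animals = 2000L, missing_rate_genotype = 0.1,
                       missing_rate_phenotype = 0.2, seed = 21L)
  cohort <- simulate_cohort(cfg)
  expect_lt(abs(mean(is.na(cohort$genotypes)) - 0.1), 0.02)
  expect_lt(abs(mean(is.na(as.matrix(cohort$phenotypes[, -1]))) - 0.2), 0.02)
})
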