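test_that("statistical scales reproduce the closed-form values at known frequencies", {
  # symmetric HWE frequencies (0.25, 0.50, 0.25)
  g <- rep(1:3, times = c(25, 50, 25))
  s <- locus_scales(g)
  expect_equal(s$x_a, c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(s$x_d, c(-0.5, 0.5, -0.5), tolerance = 1e-12)
  # skewed frequencies (0.49, 0.42, 0.09)
  g2 <- rep(1:3, times = c(49, 42, 9))
  s2 <- locus_scales(g2)
  expect_equal(s2$x_a, c(-0.6, 0.4, 1.4), tolerance = 1e-12)
  expect_equal(s2$x_d, c(-0.18, 0.42, -0.98), tolerance = 1e-12)
})

test_that("all three weighted orthogonality identities hold for random frequency triples", {
  set.seed(55)
  for (i in 1:1000) {
    p <- runif(3) + 0.01
    p <- p / sum(p)
    sc <- noiascan:::scales_from_freqs(p)
    expect_lt(abs(sum(p * sc$x_a)), 1e-10)
    expect_lt(abs(sum(p * sc$x_d)), 1e-10)
    expect_lt(abs(sum(p * sc$x_a * sc$x_d)), 1e-10)
  }
})

test_that("two-class and monomorphic loci disable the dominance scale with a flag", {
  s <- locus_scales(c(1L, 1L, 2L, 2L, 1L))
  expect_false(s$dominance_ok)
  expect_identical(s$status, "two_class")
  expect_identical(s$x_d, c(0, 0, 0))
  m <- locus_scales(rep(1L, 5))
  expect_identical(m$status, "monomorphic")
})

test_that("design matrices have the enumerated term structure", {
  G <- gen_genotypes(300, seed = 2L, loci = c("PLA2G4A", "APOB.1", "APOB.2"))
  m1 <- noia_model(c(PLA2G4A = "absent", APOB.1 = "additive", APOB.2 = "absent"))
  X1 <- build_design(G, m1)
  expect_equal(ncol(X1), 2L)  # intercept + one additive scale

  m8 <- noia_model(c(PLA2G4A = "additive", APOB.1 = "additive",
                     APOB.2 = "additive"), include_interactions = TRUE)
  X8 <- build_design(G, m8)
  expect_equal(ncol(X8), 8L)  # 1 + 3 mains + 3 pairwise + 1 three-way
})

test_that("the model space enumerates 3^k - 1 models in stable canonical order", {
  models <- enumerate_models()
  expect_length(models, 26L)
  ids <- vapply(models, `[[`, "", "id")
  expect_identical(ids, vapply(enumerate_models(), `[[`, "", "id"))
  expect_false(anyDuplicated(ids) > 0)
  one <- enumerate_models("L1")
  expect_length(one, 2L)  # additive; dominance
})

test_that("fit_model agrees with a normal-equations oracle on small instances", {
  set.seed(66)
  for (i in 1:20) {
    n <- sample(15:30, 1)
    G <- gen_genotypes(n, seed = i + 100L, loci = c("PLA2G4A", "APOB.1", "APOB.2"))
    # require all three classes at every locus for a full design
    if (!all(apply(G, 2, function(g) length(unique(g))) == 3L)) next
    y <- rnorm(n)
    model <- noia_model(c(PLA2G4A = "additive", APOB.1 = "dominance",
                          APOB.2 = "absent"))
    f <- fit_model(G, y, model)
    X <- build_design(G, model)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(f$estimate), as.vector(beta), tolerance = 1e-8)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (n - ncol(X))
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    expect_equal(unname(f$se), unname(se), tolerance = 1e-8)
  }
})

test_that("a constant trait yields zero effects, R^2 = 0 and model p = 1", {
  G <- gen_genotypes(40, seed = 9L, loci = c("PLA2G4A", "APOB.1", "APOB.2"))
  f <- fit_model(G, rep(4.2, 40), noia_model(c(PLA2G4A = "additive",
                                               APOB.1 = "absent",
                                               APOB.2 = "absent")))
  expect_equal(unname(f$estimate[-1]), 0)
  expect_equal(unname(f$estimate[1]), 4.2)
  expect_equal(f$r_squared, 0)
  expect_equal(f$model_p, 1)
})

test_that("simulated effects are recovered and orthogonality stabilises estimates", {
  set.seed(77)
  G <- gen_genotypes(10000, seed = 42L, loci = c("PLA2G4A", "APOB.1", "APOB.2"))
  sc <- locus_scales(G[, "APOB.1"])
  y <- 3.0 + 2.0 * sc$x_a[G[, "APOB.1"]] + rnorm(10000)
  m_small <- noia_model(c(PLA2G4A = "absent", APOB.1 = "additive",
                          APOB.2 = "absent"))
  m_big <- noia_model(c(PLA2G4A = "additive", APOB.1 = "additive",
                        APOB.2 = "dominance"))
  f_small <- fit_model(G, y, m_small)
  f_big <- fit_model(G, y, m_big)
  expect_lt(abs(f_small$estimate[["APOB.1_a"]] - 2.0), 0.15)
  # adding active terms at other loci barely moves the orthogonal estimate
  expect_lt(abs(f_small$estimate[["APOB.1_a"]] - f_big$estimate[["APOB.1_a"]]),
            0.05)
})

test_that("under linkage equilibrium the design's Gram matrix is near-diagonal", {
  G <- gen_genotypes(10000, seed = 8L, loci = c("PLA2G4A", "APOB.1", "APOB.2"))
  model <- noia_model(c(PLA2G4A = "additive", APOB.1 = "dominance",
                        APOB.2 = "additive"), include_interactions = TRUE)
  X <- build_design(G, model)
  Gm <- crossprod(X) / nrow(X)
  corr <- Gm / sqrt(outer(diag(Gm), diag(Gm)))
  off <- corr[upper.tri(corr)]
  # within-locus pairs are exactly orthogonal; cross-locus within sampling error
  expect_lt(max(abs(off)), 0.05)
})

test_that("R^2 is monotone non-decreasing along nested models", {
  G <- gen_genotypes(500, seed = 3L, loci = c("PLA2G4A", "APOB.1", "APOB.2"))
  set.seed(12)
  y <- rnorm(500) + locus_scales(G[, 2])$x_a[G[, 2]]
  chain <- list(
    noia_model(c(PLA2G4A = "absent", APOB.1 = "additive", APOB.2 = "absent")),
    noia_model(c(PLA2G4A = "additive", APOB.1 = "additive", APOB.2 = "absent")),
    noia_model(c(PLA2G4A = "additive", APOB.1 = "additive", APOB.2 = "additive")))
  r2 <- vapply(chain, function(m) fit_model(G, y, m)$r_squared, 0)
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("genotype-effect tables enumerate all 27 joint classes with model structure", {
  G <- gen_genotypes(400, seed = 14L, loci = c("PLA2G4A", "APOB.1", "APOB.2"))
  set.seed(15)
  y <- rnorm(400) + 2 * locus_scales(G[, "APOB.1"])$x_a[G[, "APOB.1"]]
  f <- fit_model(G, y, noia_model(c(PLA2G4A = "absent", APOB.1 = "additive",
                                    APOB.2 = "absent")))
  tab <- genotype_effect_table(f)
  expect_equal(nrow(tab), 27L)
  # effects depend only on the APOB.1 code: three distinct values
  split_vals <- split(tab$predicted_effect, tab$APOB.1)
  expect_true(all(vapply(split_vals, function(v) diff(range(v)) < 1e-12, TRUE)))
  expect_equal(length(unique(round(tab$predicted_effect, 10))), 3L)
  expect_equal(sum(tab$n), f$n_used)
})

test_that("screening finds the injected locus and respects alpha", {
  cohort <- simulate_cohort(cohort_config(seed = 33L))
  screen <- screen_models(cohort$genotypes, cohort$phenotypes)
  best_wc <- screen$best[screen$best$trait == "weight_change_pct", ]
  expect_match(best_wc$model_id, "^.[ad].$")  # APOB.1 active in the best model
  # alpha = 1 returns every testable pair
  all_pairs <- screen_models(cohort$genotypes, cohort$phenotypes, alpha = 1)
  expect_equal(nrow(all_pairs$significant), nrow(all_pairs$all))
  expect_equal(nrow(all_pairs$all), 26L * 37L)
})

test_that("functional-formulation scales are the classical additive/dominance contrasts", {
  g <- rep(1:3, times = c(49, 42, 9))
  s <- locus_scales(g, formulation = "functional")
  expect_equal(s$x_a, c(-1, 0, 1))
  expect_equal(s$x_d, c(-0.5, 0.5, -0.5))
})
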