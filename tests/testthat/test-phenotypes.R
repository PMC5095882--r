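test_that("tolerance-test AUC is the raw trapezoidal area from zero", {
  expect_equal(auc_from_zero(c(0, 10, 30), c(5, 5, 5)), 150)
  expect_equal(auc_from_zero(c(0, 5, 10), c(0, 10, 0)), 50)
  expect_error(auc_from_zero(c(0), c(5)), "two time points")
  expect_error(auc_from_zero(c(0, 5), c(1, 2, 3)), "same length")
  expect_error(auc_from_zero(c(0, 10, 5), c(1, 2, 3)), "increasing")
  expect_error(auc_from_zero(c(5, 10), c(1, 2)), "start at 0")
})

test_that("AUC is linear in values and additive over time partitions", {
  set.seed(2)
  t_all <- c(0, 5, 10, 20, 30)
  v <- runif(5, 0, 10); w <- runif(5, 0, 10)
  expect_equal(auc_from_zero(t_all, 2 * v + 3 * w),
               2 * auc_from_zero(t_all, v) + 3 * auc_from_zero(t_all, w))
  # additivity over a partition at t = 10
  left <- auc_from_zero(t_all[1:3], v[1:3])
  right <- sum(diff(t_all[3:5]) * (head(v[3:5], -1) + tail(v[3:5], -1)) / 2)
  expect_equal(auc_from_zero(t_all, v), left + right)
})

test_that("composite traits follow the documented formulas", {
  raw <- data.frame(
    animal_id = c("r1", "s1"),
    weight_initial = c(8.0, 9.0),
    weight_final = c(9.784, 14.985),
    weight = c(8.0, 11.4),
    leptin = c(0.64, 7.11),
    glucose_fasting = c(90, 90),
    insulin_fasting = c(4.5, 45),
    glucose_gtt_0 = c(80, 90), glucose_gtt_10 = c(150, 220),
    glucose_gtt_30 = c(100, 180))
  out <- derive_traits(raw)
  expect_equal(out$weight_change_pct[1], 22.3)
  expect_equal(out$leptin_bw_ratio[1], 0.08)
  expect_equal(out$homa_ir[1], 1.0)  # 90 * 4.5 / 405
  expect_equal(out$insulin_glucose_ratio[1], 0.05)
  expect_equal(out$glucose_auc[1],
               auc_from_zero(c(0, 10, 30), c(80, 150, 100)))
})

test_that("zero denominators become missing with a warning and NAs propagate", {
  raw <- data.frame(animal_id = c("a", "b"),
                    weight_initial = c(0, 8), weight_final = c(9, NA),
                    weight = c(9, 10), leptin = c(1, 2))
  expect_warning(out <- derive_traits(raw), "division by zero")
  expect_true(is.na(out$weight_change_pct[1]))
  expect_true(is.na(out$weight_change_pct[2]))
})

test_that("classification labels follow the threshold combination and is monotone", {
  traits <- data.frame(animal_id = paste0("a", 1:5),
                       weight_change_pct = c(10, 70, 40, NA, 20),
                       leptin_bw_ratio = c(0.05, 0.9, 0.5, NA, 0.9),
                       insulin_auc = c(2000, 12000, 5000, NA, 2100))
  rule <- classification_rule(list(
    list(trait = "weight_change_pct", direction = "below", cutoff = 30),
    list(trait = "leptin_bw_ratio", direction = "below", cutoff = 0.4),
    list(trait = "insulin_auc", direction = "below", cutoff = 6000)),
    combination = "all")
  lab <- classify(traits, rule)
  expect_identical(unname(lab[1]), "resistant")   # below all three cutoffs
  expect_identical(unname(lab[2]), "sensitive")   # above all three
  expect_identical(unname(lab[4]), "unclassified")
  expect_identical(unname(lab[5]), "unclassified") # mixed

  # relaxing a cutoff never moves an animal resistant -> sensitive
  relaxed <- classification_rule(list(
    list(trait = "weight_change_pct", direction = "below", cutoff = 50),
    list(trait = "leptin_bw_ratio", direction = "below", cutoff = 0.6),
    list(trait = "insulin_auc", direction = "below", cutoff = 8000)),
    combination = "all")
  lab2 <- classify(traits, relaxed)
  expect_false(any(lab == "resistant" & lab2 == "sensitive"))

  expect_error(classification_rule(list()), "at least one")
})

test_that("correlation matrices match the closed-form Pearson oracle", {
  set.seed(41)
  df <- data.frame(animal_id = paste0("a", 1:30),
                   x = rnorm(30), y = rnorm(30), z = rnorm(30))
  df$y <- df$y + 0.5 * df$x
  cm <- correlation_matrix(df)
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    o <- oracle_pearson(df[[pair[1]]], df[[pair[2]]])
    expect_equal(cm$r[pair[1], pair[2]], o$r, tolerance = 1e-12)
    expect_equal(cm$p[pair[1], pair[2]], o$p, tolerance = 1e-12)
  }
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_identical(cm$r, t(cm$r))

  # exactly linear traits: r = 1 with minimal positive p, not zero
  df2 <- data.frame(animal_id = paste0("a", 1:10), u = 1:10, v = 2 * (1:10) + 3)
  cm2 <- correlation_matrix(df2)
  expect_equal(cm2$r["u", "v"], 1)
  expect_gt(cm2$p["u", "v"], 0)
})

test_that("correlations are invariant to affine transforms up to sign", {
  set.seed(52)
  df <- data.frame(animal_id = paste0("a", 1:25), x = rnorm(25), y = rnorm(25))
  base <- correlation_matrix(df)$r["x", "y"]
  df2 <- transform(df, x = 3 * x + 7, y = -2 * y + 1)
  flipped <- correlation_matrix(df2)$r["x", "y"]
  expect_equal(flipped, -base, tolerance = 1e-12)
})

test_that("star levels follow the 0.05 / 0.01 / 0.001 cutoffs", {
  set.seed(63)
  n <- 40
  x <- rnorm(n)
  df <- data.frame(animal_id = paste0("a", 1:n), x = x,
                   strong = x + rnorm(n, sd = 0.2),
                   none = rnorm(n))
  cm <- correlation_matrix(df)
  expect_identical(cm$stars["x", "strong"], "***")
  expect_true(cm$stars["x", "none"] %in% c("", "*"))
})

test_that("baseline comparisons use Welch t for numeric and Fisher for categorical traits", {
  set.seed(71)
  n1 <- 17; n2 <- 24
  traits <- data.frame(
    animal_id = paste0("a", 1:(n1 + n2)),
    weight_initial = c(rnorm(n1, 7.93, 0.8), rnorm(n2, 9.06, 0.8)),
    parity = c(rep(c("nulliparous", "multiparous"), c(5, 12)),
               rep(c("nulliparous", "multiparous"), c(4, 20))))
  labels <- setNames(rep(c("resistant", "sensitive"), c(n1, n2)),
                     traits$animal_id)
  out <- baseline_comparison(traits, labels)
  wrow <- out[out$trait == "weight_initial", ]
  oracle_t <- t.test(traits$weight_initial[1:n1], traits$weight_initial[-(1:n1)])
  expect_equal(wrow$p, oracle_t$p.value, tolerance = 1e-12)

  prow <- out[out$trait == "parity", ]
  tab <- matrix(c(5, 12, 4, 20), 2, dimnames = list(c("nulli", "multi"), NULL))
  # oracle: full hypergeometric enumeration of the 2x2 table (groups x parity)
  expect_equal(prow$p, oracle_fisher2x2(matrix(c(5, 12, 4, 20), 2, byrow = TRUE)),
               tolerance = 1e-10)
  expect_equal(prow$p, fisher.test(tab)$p.value, tolerance = 1e-12)
})

test_that("two-group rejection rates track analytic power for a 1-sd shift", {
  set.seed(83)
  rejections <- replicate(500, {
    traits <- data.frame(animal_id = paste0("a", 1:40),
                         y = c(rnorm(20, 0), rnorm(20, 1)))
    labels <- setNames(rep(c("g1", "g2"), each = 20L), traits$animal_id)
    baseline_comparison(traits, labels)$p < 0.05
  })
  analytic <- power.t.test(n = 20, delta = 1, sd = 1)$power
  expect_lt(abs(mean(rejections) - analytic), 0.05)
})

test_that("identical groups give t = 0 and Fisher p = 1", {
  traits <- data.frame(animal_id = paste0("a", 1:8),
                       y = rep(c(1, 2, 3, 4), 2),
                       cat = rep(c("u", "v", "u", "v"), 2))
  labels <- setNames(rep(c("g1", "g2"), each = 4L), traits$animal_id)
  out <- baseline_comparison(traits, labels)
  expect_equal(out$statistic[out$trait == "y"], 0, tolerance = 1e-12)
  expect_equal(out$p[out$trait == "cat"], 1)
})
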