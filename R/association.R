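#' Allelic case/control association at one site
#'
#' Builds the 2x2 allelic contingency table (alternate vs reference allele
#' counts by group) from genotype codes, and reports the chi-square
#' statistic with its asymptotic p, the two-sided Fisher exact p (sum of
#' tables at most as probable as the observed one), the one-sided
#' (enrichment in cases) Fisher p, and the sample odds ratio — which
#' diverges to infinity under perfect carrier separation.
#'
#' @param genotypes integer vector of codes 1/2/3/NA for one locus, named
#'   by animal id (or aligned with `labels`)
#' @param labels named character/factor vector with exactly two levels
#'   (e.g. case/control, resistant/sensitive); the first level after
#'   sorting is treated as the case group
#' @return list of class `assoc_result`: `table` (2x2 allele counts),
#'   `statistic` (chi-square), `p_asymptotic`, `p_fisher` (two-sided),
#'   `p_fisher_one_sided`, `odds_ratio`, `untestable`
#' @export
case_control_assoc <- function(genotypes, labels) {
  if (!is.null(names(genotypes)) && !is.null(names(labels)))
    labels <- labels[names(genotypes)]
  keep <- !is.na(genotypes) & !is.na(labels)
  g <- genotypes[keep]; lab <- as.character(labels[keep])
  lvls <- sort(unique(lab))
  if (length(lvls) != 2L || min(table(lab)) < 2L)
    stop_invalid("need two groups with at least 2 genotyped animals each")
  alt_counts <- g - 1L             # minor-allele dosage 0/1/2
  a <- sum(alt_counts[lab == lvls[1L]]); b <- 2L * sum(lab == lvls[1L]) - a
  c_ <- sum(alt_counts[lab == lvls[2L]]); d <- 2L * sum(lab == lvls[2L]) - c_
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(lvls, c("alt", "ref")))
  if (sum(tab[, "alt"]) == 0L || sum(tab[, "ref"]) == 0L) {
    return(structure(list(table = tab, statistic = NA_real_,
                          p_asymptotic = NA_real_, p_fisher = NA_real_,
                          p_fisher_one_sided = NA_real_,
                          odds_ratio = NA_real_, untestable = TRUE,
                          groups = lvls),
                     class = "assoc_result"))
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  ft <- stats::fisher.test(tab)
  ft1 <- stats::fisher.test(tab, alternative = "greater")
  or <- if (b == 0L && c_ == 0L) Inf
        else if (a == 0L && d == 0L) 0
        else (a * d) / (b * c_)
  structure(list(table = tab, statistic = unname(cs$statistic),
                 p_asymptotic = cs$p.value, p_fisher = ft$p.value,
                 p_fisher_one_sided = ft1$p.value,
                 odds_ratio = or, untestable = FALSE, groups = lvls),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  if (isTRUE(x$untestable)) {
    cat("assoc_result: untestable (monomorphic or degenerate)\n")
    return(invisible(x))
  }
  if (!is.null(x$table)) print(x$table)
  cat("statistic =", format(x$statistic, digits = 5))
  if (!is.null(x$p_asymptotic)) cat(", asymptotic p =", format.pval(x$p_asymptotic, digits = 4))
  if (!is.null(x$p_fisher)) cat(", Fisher p =", format.pval(x$p_fisher, digits = 4))
  if (!is.null(x$odds_ratio)) cat(", OR =", format(x$odds_ratio, digits = 4))
  if (!is.null(x$p_empirical)) cat(", empirical p =", format.pval(x$p_empirical, digits = 4),
                                   " (", x$n_permutations_used, " permutations)", sep = "")
  cat("\n")
  invisible(x)
}

#' Quantitative trait association at one site
#'
#' Least-squares regression of the trait on minor-allele dosage (codes
#' 1/2/3 mapped to dosages 0/1/2); the slope is the statistic and the Wald
#' t-test gives the asymptotic p.
#'
#' @param genotypes integer vector of codes for one locus
#' @param trait numeric trait vector aligned with `genotypes`
#' @return list of class `assoc_result`: `statistic` (slope), `se`,
#'   `p_asymptotic`, `r_squared`, `n_used`, `untestable`
#' @export
quantitative_assoc <- function(genotypes, trait) {
  stopifnot(length(genotypes) == length(trait))
  keep <- !is.na(genotypes) & !is.na(trait)
  if (sum(keep) < 3L) stop_invalid("need at least 3 complete (genotype, trait) pairs")
  dose <- genotypes[keep] - 1L
  y <- trait[keep]
  if (stats::var(dose) == 0) {
    return(structure(list(statistic = NA_real_, se = NA_real_,
                          p_asymptotic = NA_real_, r_squared = NA_real_,
                          n_used = sum(keep), untestable = TRUE),
                     class = "assoc_result"))
  }
  X <- cbind(1, dose)
  fit <- ols_fit(X, matrix(y, ncol = 1L))[[1L]]
  structure(list(statistic = unname(fit$estimate[2L]),
                 se = fit$se[2L],
                 p_asymptotic = fit$term_p[2L],
                 r_squared = fit$r_squared, n_used = sum(keep),
                 sigma2 = fit$sigma2, untestable = FALSE),
            class = "assoc_result")
}

#' Plan an adaptive permutation run
#'
#' @param max_permutations ceiling on sampled permutations (>= 1)
#' @param alpha decision level the early-stopping rule targets
#' @param early_stop_confidence confidence of the Clopper-Pearson interval
#'   used for early stopping (default 0.99)
#' @param seed integer seed for the permutation stream
#' @param exhaustive_max_n cohorts of at most this many animals with
#'   two-level labels are enumerated exhaustively instead of sampled
#'   (default 10)
#' @param block permutations drawn between early-stop checks
#' @return object of class `permutation_plan`
#' @export
permutation_plan <- function(max_permutations = 10000L, alpha = 0.05,
                             early_stop_confidence = 0.99, seed = 1L,
                             exhaustive_max_n = 10L, block = 100L) {
  if (max_permutations < 1L) stop_invalid("max_permutations must be >= 1")
  for (lv in c(alpha, early_stop_confidence))
    if (lv <= 0 || lv >= 1) stop_invalid("levels must lie in (0,1)")
  structure(list(max_permutations = as.integer(max_permutations),
                 alpha = alpha, early_stop_confidence = early_stop_confidence,
                 seed = as.integer(seed),
                 exhaustive_max_n = as.integer(exhaustive_max_n),
                 block = as.integer(block)),
            class = "permutation_plan")
}

#' Empirical p-value by adaptive (or exhaustive) permutation
#'
#' Permutes the assignment vector `y` (group labels for case/control tests,
#' trait values for quantitative tests) and compares the statistic on each
#' permutation with the observed one. For small cohorts (at most
#' `plan$exhaustive_max_n` animals with two-level labels) every distinct
#' label arrangement is enumerated and the exact permutation p
#' \eqn{\#\{T_{perm} \ge T_{obs}\} / n_{arrangements}} is returned.
#' Otherwise permutations are sampled in blocks with the add-one estimator
#' \eqn{p = (1 + \#\{T_{perm} \ge T_{obs}\}) / (1 + n)}, stopping early
#' once the Clopper-Pearson interval at `plan$early_stop_confidence` for
#' the exceedance probability lies entirely above or below `plan$alpha`.
#'
#' @param statistic function `statistic(y)` returning a finite scalar;
#'   larger = more extreme (use a two-sided statistic such as chi-square or
#'   an absolute slope for two-sided tests)
#' @param y assignment vector to permute
#' @param plan a [permutation_plan()]
#' @param force_sampling bypass the exhaustive branch (used to test the
#'   sampling path on small cohorts)
#' @return list of class `assoc_result`: `statistic` (observed),
#'   `p_empirical`, `n_permutations_used`, `exact` (TRUE for the
#'   enumeration branch)
#' @export
adaptive_permutation <- function(statistic, y, plan = permutation_plan(),
                                 force_sampling = FALSE) {
  stopifnot(inherits(plan, "permutation_plan"))
  t_obs <- statistic(y)
  if (!is.finite(t_obs)) stop_invalid("observed statistic is not finite")
  n <- length(y)

  two_level <- (is.character(y) || is.factor(y)) &&
    length(unique(as.character(y))) == 2L
  if (!force_sampling && two_level && n <= plan$exhaustive_max_n) {
    lab <- as.character(y)
    lvls <- sort(unique(lab))
    n1 <- sum(lab == lvls[1L])
    arrangements <- utils::combn(n, n1, simplify = FALSE)
    stats_all <- vapply(arrangements, function(idx) {
      perm <- rep(lvls[2L], n)
      perm[idx] <- lvls[1L]
      names(perm) <- names(y)
      statistic(perm)
    }, numeric(1L))
    p <- sum(stats_all >= t_obs) / length(stats_all)
    return(structure(list(statistic = t_obs, p_empirical = p,
                          n_permutations_used = length(stats_all),
                          exact = TRUE),
                     class = "assoc_result"))
  }

  with_seed(plan$seed, {
    exceed <- 0L; used <- 0L
    a_tail <- (1 - plan$early_stop_confidence) / 2
    repeat {
      m <- min(plan$block, plan$max_permutations - used)
      if (m <= 0L) break
      for (i in seq_len(m)) {
        perm <- y[sample.int(n)]
        names(perm) <- names(y)
        if (statistic(perm) >= t_obs) exceed <- exceed + 1L
      }
      used <- used + m
      lo <- if (exceed == 0L) 0 else stats::qbeta(a_tail, exceed, used - exceed + 1L)
      hi <- if (exceed == used) 1 else stats::qbeta(1 - a_tail, exceed + 1L, used - exceed)
      if (hi < plan$alpha || lo > plan$alpha) break
    }
    structure(list(statistic = t_obs,
                   p_empirical = (1 + exceed) / (1 + used),
                   n_permutations_used = used, exact = FALSE),
              class = "assoc_result")
  })
}

#' Chi-square statistic on the allelic 2x2 table, as a permutation statistic
#'
#' Convenience statistic factory for [adaptive_permutation()]: given a
#' fixed genotype vector, returns a function of group labels computing the
#' (uncorrected) chi-square statistic of the allelic contingency table; a
#' degenerate table scores 0. Symmetric in the two groups, hence a
#' two-sided statistic.
#'
#' @param genotypes integer vector of codes 1/2/3/NA
#' @return function(labels) -> numeric
#' @export
allelic_chisq_statistic <- function(genotypes) {
  force(genotypes)
  function(labels) {
    lab <- as.character(labels)
    keep <- !is.na(genotypes) & !is.na(lab)
    g <- genotypes[keep] - 1L; l <- lab[keep]
    lvls <- sort(unique(l))
    if (length(lvls) != 2L) return(0)
    a <- sum(g[l == lvls[1L]]); b <- 2L * sum(l == lvls[1L]) - a
    c_ <- sum(g[l == lvls[2L]]); d <- 2L * sum(l == lvls[2L]) - c_
    nn <- a + b + c_ + d
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
    nn * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2)
  }
}

#' Carrier-status chi-square statistic, as a permutation statistic
#'
#' Like [allelic_chisq_statistic()] but on the animal-level 2x2 table of
#' carrier status (homozygous-alternative vs not) by group.
#'
#' @param genotypes integer vector of codes 1/2/3/NA
#' @return function(labels) -> numeric
#' @export
carrier_chisq_statistic <- function(genotypes) {
  force(genotypes)
  function(labels) {
    lab <- as.character(labels)
    keep <- !is.na(genotypes) & !is.na(lab)
    carrier <- genotypes[keep] == 3L
    l <- lab[keep]
    lvls <- sort(unique(l))
    if (length(lvls) != 2L) return(0)
    a <- sum(carrier[l == lvls[1L]]); b <- sum(!carrier[l == lvls[1L]])
    c_ <- sum(carrier[l == lvls[2L]]); d <- sum(!carrier[l == lvls[2L]])
    nn <- a + b + c_ + d
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
    if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(0)
    nn * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2)
  }
}
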