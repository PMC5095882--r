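#' Area under a tolerance-test curve, from zero
#'
#' Trapezoidal area of the raw concentration trace over \[0, t_max\] —
#' "from zero values", i.e. not baseline-subtracted, the convention used
#' for glucose and insulin tolerance-test AUCs here.
#'
#' @param times strictly increasing sampling times in minutes, starting at 0
#' @param values concentrations at `times` (same length)
#' @return the trapezoidal area (concentration x minutes); NA if any value
#'   is missing
#' @examples
#' auc_from_zero(c(0, 10, 30), c(5, 5, 5))   # 150
#' auc_from_zero(c(0, 5, 10), c(0, 10, 0))   # 50
#' @export
auc_from_zero <- function(times, values) {
  if (length(times) != length(values))
    stop_invalid("times and values must have the same length")
  if (length(times) < 2L) stop_invalid("need at least two time points")
  if (times[1L] != 0) stop_invalid("times must start at 0")
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  if (anyNA(values)) return(NA_real_)
  sum(diff(times) * (utils::head(values, -1L) + utils::tail(values, -1L)) / 2)
}

#' Derive composite metabolic traits
#'
#' Adds the composite traits used throughout the analysis to a raw
#' measurement table:
#' \itemize{
#'   \item `weight_change_pct` = 100 (weight_final - weight_initial) / weight_initial
#'   \item `leptin_bw_ratio` = leptin \[ng/ml\] / weight \[kg body weight\]
#'   \item `insulin_glucose_ratio` = insulin_fasting / glucose_fasting
#'   \item `homa_ir` = glucose_fasting \[mg/dL\] x insulin_fasting \[uU/mL\] / 405
#'   \item `glucose_auc` / `insulin_auc` via [auc_from_zero()] over columns
#'     named `glucose_gtt_<min>` / `insulin_gtt_<min>`
#' }
#' Derivations whose source columns are absent are skipped; missing inputs
#' propagate to missing outputs; division by a zero weight or glucose
#' yields missing with a warning.
#'
#' @param raw data.frame with `animal_id` and raw measurement columns
#' @return the input with derived columns appended
#' @export
derive_traits <- function(raw) {
  stopifnot(is.data.frame(raw), "animal_id" %in% names(raw))
  out <- raw
  safe_div <- function(num, den, what) {
    zero <- !is.na(den) & den == 0
    if (any(zero)) warning("division by zero ", what, " for ",
                           sum(zero), " animal(s); set to missing",
                           call. = FALSE)
    res <- num / den
    res[zero] <- NA_real_
    res
  }
  has <- function(...) all(c(...) %in% names(raw))
  if (has("weight_initial", "weight_final"))
    out$weight_change_pct <- 100 * safe_div(raw$weight_final - raw$weight_initial,
                                            raw$weight_initial, "initial weight")
  if (has("leptin", "weight"))
    out$leptin_bw_ratio <- safe_div(raw$leptin, raw$weight, "body weight")
  if (has("insulin_fasting", "glucose_fasting")) {
    out$insulin_glucose_ratio <- safe_div(raw$insulin_fasting,
                                          raw$glucose_fasting, "glucose")
    out$homa_ir <- raw$glucose_fasting * raw$insulin_fasting / 405
  }
  for (an in c("glucose", "insulin")) {
    cols <- grep(paste0("^", an, "_gtt_\\d+$"), names(raw), value = TRUE)
    if (length(cols) >= 2L) {
      tms <- as.numeric(sub(paste0(an, "_gtt_"), "", cols))
      ord <- order(tms)
      out[[paste0(an, "_auc")]] <- apply(raw[, cols[ord], drop = FALSE], 1L,
                                         function(v) auc_from_zero(tms[ord], as.numeric(v)))
    }
  }
  out
}

#' Define a resistant/sensitive classification rule
#'
#' Each threshold names the trait, a cutoff, and the side (`below`/`above`)
#' that counts toward the resistant phenotype; `combination` sets how many
#' thresholds must agree. Cutoffs are study configuration, not constants of
#' the method.
#'
#' @param thresholds list of `list(trait =, direction = "below"|"above",
#'   cutoff =)`
#' @param combination `"all"`, `"any"` or `"majority"`
#' @return object of class `classification_rule`
#' @export
classification_rule <- function(thresholds,
                                combination = c("all", "any", "majority")) {
  combination <- match.arg(combination)
  if (!length(thresholds)) stop_invalid("need at least one threshold")
  for (th in thresholds)
    stopifnot(is.character(th$trait), th$direction %in% c("below", "above"),
              is.finite(th$cutoff))
  structure(list(thresholds = thresholds, combination = combination),
            class = "classification_rule")
}

#' Classify animals as resistant or sensitive
#'
#' Evaluates every threshold of the rule per animal. An animal is labelled
#' `resistant` when the combination rule holds over the resistant-side
#' indicators, `sensitive` when it holds over their complements, and
#' `unclassified` otherwise (including when every threshold trait is
#' missing).
#'
#' @param traits phenotype data.frame with `animal_id`
#' @param rule a [classification_rule()]
#' @return named character vector of labels, with attribute `counts`
#' @export
classify <- function(traits, rule) {
  stopifnot(inherits(rule, "classification_rule"))
  for (th in rule$thresholds)
    if (!th$trait %in% names(traits))
      stop_invalid("classification trait missing from table: ", th$trait)
  ind <- sapply(rule$thresholds, function(th) {
    x <- traits[[th$trait]]
    if (th$direction == "below") x < th$cutoff else x > th$cutoff
  })
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = nrow(traits))
  combine <- function(m) {
    k <- rowSums(m, na.rm = TRUE)
    avail <- rowSums(!is.na(m))
    switch(rule$combination,
           all = avail > 0L & k == avail & avail == ncol(m),
           any = k >= 1L,
           majority = avail > 0L & k > avail / 2)
  }
  res <- combine(ind)
  sens <- combine(!ind)
  labels <- ifelse(res & !sens, "resistant",
                   ifelse(sens & !res, "sensitive", "unclassified"))
  all_missing <- rowSums(!is.na(ind)) == 0L
  labels[all_missing] <- "unclassified"
  names(labels) <- traits$animal_id
  attr(labels, "counts") <- table(factor(labels, c("resistant", "sensitive", "unclassified")))
  labels
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Pairwise-complete Pearson correlations between traits, with two-sided
#' t-test p-values and the conventional star levels (* p<0.05, ** p<0.01,
#' *** p<0.001). Pairs with fewer than 3 complete observations are marked
#' missing.
#'
#' @param traits phenotype data.frame with `animal_id`
#' @param subset optional character vector of trait names
#' @return list of class `trait_correlations`: matrices `r`, `p`, `n` and
#'   character matrix `stars`
#' @export
correlation_matrix <- function(traits, subset = NULL) {
  Y <- phenotype_matrix(traits)
  if (!is.null(subset)) {
    miss <- setdiff(subset, colnames(Y))
    if (length(miss)) stop_invalid("unknown traits: ", paste(miss, collapse = ", "))
    Y <- Y[, subset, drop = FALSE]
  }
  k <- ncol(Y)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(Y), colnames(Y)))
  nmat <- matrix(0L, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(Y[, i]) & !is.na(Y[, j])
      nn <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- nn
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (nn < 3L) next
      xi <- Y[ok, i]; yj <- Y[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(yj) == 0) next
      rij <- stats::cor(xi, yj)
      r[i, j] <- r[j, i] <- rij
      if (abs(rij) >= 1) {
        pij <- .Machine$double.xmin
      } else {
        tval <- rij * sqrt((nn - 2) / (1 - rij^2))
        pij <- 2 * stats::pt(abs(tval), nn - 2, lower.tail = FALSE)
        if (pij == 0) pij <- .Machine$double.xmin
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  diag(stars) <- ""
  structure(list(r = r, p = p, n = nmat, stars = stars),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("trait_correlations over", ncol(x$r), "traits\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Baseline two-group comparisons
#'
#' Per numeric trait: group means and a Welch (unequal-variance) two-sample
#' t-test. Per categorical column (factor/character with two levels, e.g.
#' parity): Fisher's exact test on the 2x2 count table. Traits with zero
#' variance in both groups are flagged untestable.
#'
#' @param traits phenotype data.frame with `animal_id`
#' @param labels named group-label vector (exactly two levels used;
#'   `unclassified` animals are dropped)
#' @return data.frame: trait, type, group means (or counts), statistic, p,
#'   untestable flag
#' @export
baseline_comparison <- function(traits, labels) {
  lab <- labels[traits$animal_id]
  use <- !is.na(lab) & lab %in% setdiff(unique(lab), "unclassified")
  lab <- factor(lab[use])
  if (nlevels(lab) != 2L) stop_invalid("need exactly two groups")
  if (min(table(lab)) < 2L) stop_invalid("need at least 2 animals per group")
  df <- traits[use, , drop = FALSE]
  lv <- levels(lab)
  rows <- lapply(setdiff(names(df), "animal_id"), function(cn) {
    x <- df[[cn]]
    if (is.numeric(x)) {
      x1 <- x[lab == lv[1L]]; x2 <- x[lab == lv[2L]]
      x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
      if (length(x1) < 2L || length(x2) < 2L ||
          (stats::sd(x1) == 0 && stats::sd(x2) == 0)) {
        return(data.frame(trait = cn, type = "numeric",
                          mean_1 = mean(x1), mean_2 = mean(x2),
                          statistic = NA_real_, p = NA_real_,
                          untestable = TRUE))
      }
      tt <- stats::t.test(x1, x2)   # Welch by default
      data.frame(trait = cn, type = "numeric",
                 mean_1 = mean(x1), mean_2 = mean(x2),
                 statistic = unname(tt$statistic), p = tt$p.value,
                 untestable = FALSE)
    } else {
      tab <- table(factor(x), lab)
      if (nrow(tab) != 2L) {
        return(data.frame(trait = cn, type = "categorical",
                          mean_1 = NA_real_, mean_2 = NA_real_,
                          statistic = NA_real_, p = NA_real_,
                          untestable = TRUE))
      }
      ft <- stats::fisher.test(tab)
      data.frame(trait = cn, type = "categorical",
                 mean_1 = NA_real_, mean_2 = NA_real_,
                 statistic = unname(ft$estimate), p = ft$p.value,
                 untestable = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1L])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2L])
  rownames(out) <- NULL
  out
}
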