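#' Consensus intersection of call sets
#'
#' The sites called by every caller (matching chromosome, position,
#' reference and alternate allele) — the multi-caller agreement filter
#' that precedes all downstream candidate selection.
#'
#' @param callsets non-empty list of [variant_callset()]
#' @return character vector of site keys present in every call set
#' @export
consensus_intersect <- function(callsets) {
  if (!length(callsets)) stop_invalid("need at least one call set")
  keys <- lapply(callsets, callset_keys)
  Reduce(intersect, keys)
}

#' Define a homozygous-discordance rule
#'
#' A variant is a candidate when at least `k` animals of one phenotype
#' group carry it (homozygous-alternative under the default strict
#' reading, or any non-reference call under `carrier = "presence"`) while
#' the other group carries no non-reference call at all — the
#' "odds ratio approximating infinity" seed filter, with `k` relaxed
#' stepwise (4 of 4, then 3 of 4, then 2 of 4) to admit near-perfect
#' discordance.
#'
#' @param k required carrier count in the carrier group (>= 1)
#' @param forbid_other require zero non-reference (het or hom_alt) calls in
#'   the comparison group (default TRUE)
#' @param carrier `"hom_alt"` (default: carriers must be homozygous
#'   alternative) or `"presence"` (het counts toward k)
#' @return object of class `discordance_rule`
#' @export
discordance_rule <- function(k = 4L, forbid_other = TRUE,
                             carrier = c("hom_alt", "presence")) {
  k <- as.integer(k)
  if (k < 1L) stop_invalid("k must be >= 1")
  structure(list(k = k, forbid_other = isTRUE(forbid_other),
                 carrier = match.arg(carrier)),
            class = "discordance_rule")
}

#' Filter a call set for group-discordant variants
#'
#' For each site and each direction (carrier group A vs comparison group B
#' and vice versa): the site is emitted iff at least `rule$k` animals of
#' the carrier group meet the carrier criterion and — when
#' `rule$forbid_other` — no animal of the comparison group has a het or
#' hom_alt call. Missing calls count neither toward `k` nor against the
#' comparison group.
#'
#' @param callset a [variant_callset()]
#' @param groups named character vector mapping every animal in the call
#'   set to one of exactly two group labels
#' @param rule a [discordance_rule()]
#' @return data.frame of candidates: `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `carrier_group`, `k_observed` (carrier count in the carrier group)
#' @export
discordance_filter <- function(callset, groups, rule = discordance_rule()) {
  stopifnot(inherits(callset, "variant_callset"),
            inherits(rule, "discordance_rule"))
  animals <- colnames(callset$zygosity)
  unlabelled <- setdiff(animals, names(groups))
  if (length(unlabelled))
    stop_invalid("unlabelled animals: ", paste(unlabelled, collapse = ", "))
  labels <- groups[animals]
  lvls <- sort(unique(labels))
  if (length(lvls) != 2L) stop_invalid("need exactly two groups, got: ",
                                       paste(lvls, collapse = ", "))
  if (min(table(labels)) == 0L) stop_invalid("a group has zero animals")

  Z <- callset$zygosity
  carrier_ok <- if (rule$carrier == "hom_alt") {
    !is.na(Z) & Z == "hom_alt"
  } else {
    !is.na(Z) & Z %in% c("het", "hom_alt")
  }
  nonref <- !is.na(Z) & Z %in% c("het", "hom_alt")

  rows <- list()
  for (carrier in lvls) {
    other <- setdiff(lvls, carrier)
    in_c <- labels == carrier
    k_obs <- rowSums(carrier_ok[, in_c, drop = FALSE])
    bad_other <- rowSums(nonref[, !in_c, drop = FALSE]) > 0L
    hit <- k_obs >= rule$k & (!rule$forbid_other | !bad_other)
    if (any(hit)) {
      rows[[carrier]] <- data.frame(
        callset$sites[hit, c("chrom", "pos", "ref", "alt"), drop = FALSE],
        key = rownames(Z)[hit],
        carrier_group = carrier,
        k_observed = as.integer(k_obs[hit]),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), key = character(),
               carrier_group = character(), k_observed = integer())
  rownames(out) <- NULL
  out[order(out$key, out$carrier_group), , drop = FALSE]
}

#' Gate candidates on functional annotation
#'
#' A candidate is retained iff it is annotated nonsynonymous and at least
#' one of SIFT or PROVEAN calls it deleterious (missing predictions count
#' as not deleterious). Candidates with no annotation at all pass through,
#' flagged `annotated = FALSE`, so un-annotatable sites are not silently
#' dropped.
#'
#' @param candidates data.frame from [discordance_filter()] (needs a `key`
#'   column)
#' @param annotations data.frame from [read_annotations()]
#' @return the retained candidates with added columns `annotated`,
#'   `nonsynonymous`, `deleterious_prediction`, `cadd_phred`, `cadd_tier`
#' @export
functional_gate <- function(candidates, annotations) {
  idx <- match(candidates$key, annotations$key)
  annotated <- !is.na(idx)
  nonsyn <- annotated & annotations$category[idx] == "nonsynonymous"
  del <- annotated & (
    (!is.na(annotations$sift_deleterious[idx]) & annotations$sift_deleterious[idx]) |
    (!is.na(annotations$provean_deleterious[idx]) & annotations$provean_deleterious[idx]))
  keep <- !annotated | (nonsyn & del)
  out <- candidates[keep, , drop = FALSE]
  out$annotated <- annotated[keep]
  out$nonsynonymous <- nonsyn[keep]
  out$deleterious_prediction <- del[keep]
  out$cadd_phred <- annotations$cadd_phred[idx][keep]
  out$cadd_tier <- rep(NA_character_, nrow(out))
  has_score <- !is.na(out$cadd_phred)
  if (any(has_score)) out$cadd_tier[has_score] <- cadd_tier(out$cadd_phred[has_score])
  rownames(out) <- NULL
  out
}

#' CADD PHRED deleteriousness tier
#'
#' PHRED-scaled CADD scores rank a substitution against all possible
#' substitutions: a score >= 20 places it in the top 1% most likely to be
#' functional, >= 10 in the top 10%, anything lower below both bounds.
#'
#' @param phred non-negative numeric vector of PHRED-scaled CADD scores
#' @return character vector in `c("top1pct", "top10pct", "below")`
#' @examples
#' cadd_tier(c(23.6, 15.07, 9.018))
#' @export
cadd_tier <- function(phred) {
  if (any(is.na(phred))) stop_invalid("missing CADD score")
  if (any(phred < 0)) stop_invalid("negative CADD PHRED score")
  ifelse(phred >= 20, "top1pct", ifelse(phred >= 10, "top10pct", "below"))
}
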