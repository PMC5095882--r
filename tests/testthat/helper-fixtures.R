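# Shared fixtures and independent oracles built in code at test time.

# Genotypes drawn independently per locus under Hardy-Weinberg proportions
# (linkage equilibrium by construction).
gen_genotypes <- function(n, mafs = c(0.3, 0.25, 0.25), seed = 1L,
                          loci = paste0("L", seq_along(mafs))) {
  set.seed(seed)
  G <- vapply(mafs, function(q) {
    p <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    sample.int(3L, n, replace = TRUE, prob = p)
  }, integer(n))
  dimnames(G) <- list(sprintf("a%04d", seq_len(n)), loci)
  G
}

# Build a call set from a genotype-code matrix (animals x sites).
make_callset <- function(codes, caller_id = "caller", chrom = "chr1") {
  n_sites <- ncol(codes)
  sites <- data.frame(chrom = chrom, pos = seq_len(n_sites) * 10L,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  Z <- t(matrix(c("hom_ref", "het", "hom_alt")[codes],
                nrow(codes), ncol(codes), dimnames = dimnames(codes)))
  variant_callset(caller_id, sites, Z)
}

# Independent brute-force oracle for the homozygous-discordance filter:
# per-site loops straight off the rule definition.
oracle_discordance <- function(zyg_row, labels, k, forbid_other = TRUE,
                               carrier = "hom_alt") {
  lvls <- sort(unique(labels))
  hits <- character(0)
  for (grp in lvls) {
    other <- zyg_row[labels != grp]
    mine <- zyg_row[labels == grp]
    n_carrier <- if (carrier == "hom_alt") sum(mine == "hom_alt", na.rm = TRUE)
      else sum(mine %in% c("het", "hom_alt"), na.rm = TRUE)
    other_clean <- !any(other %in% c("het", "hom_alt"))
    if (n_carrier >= k && (!forbid_other || other_clean)) hits <- c(hits, grp)
  }
  hits
}

# All zygosity configurations for n animals over the given states,
# one configuration per row.
all_configs <- function(n, states = c("hom_ref", "het", "hom_alt")) {
  grid <- do.call(expand.grid, c(rep(list(states), n),
                                 list(stringsAsFactors = FALSE)))
  as.matrix(grid)
}

# Closed-form Pearson correlation + two-sided t-test p, as an oracle.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tval), n - 2, lower.tail = FALSE))
}

# Fisher two-sided p for a 2x2 table by full hypergeometric enumeration.
oracle_fisher2x2 <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  a_obs <- tab[1, 1]
  support <- max(0, k - n2):min(k, m)
  pr <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a_obs, m, n2, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
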