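#' Specify a simulated biallelic locus
#'
#' @param name locus name (used as genotype-matrix column name)
#' @param maf minor-allele frequency in (0, 1); under `hwe = TRUE` genotype
#'   frequencies are (1-q)^2, 2q(1-q), q^2
#' @param hwe draw genotypes under Hardy-Weinberg proportions (ignored when
#'   `genotype_freqs` is supplied)
#' @param genotype_freqs optional explicit probabilities (p11, p12, p22) of
#'   the homozygous-major, heterozygous and homozygous-minor classes; must
#'   be positive and sum to 1
#' @param chrom,pos,ref,alt site coordinates and alleles attached to the
#'   locus for call-set and VCF emission
#' @return object of class `locus_spec`
#' @export
locus_spec <- function(name, maf = 0.25, hwe = TRUE, genotype_freqs = NULL,
                       chrom = "chr1", pos = 1L, ref = "A", alt = "G") {
  if (!is.null(genotype_freqs)) {
    stopifnot(length(genotype_freqs) == 3L)
    if (any(genotype_freqs <= 0) || abs(sum(genotype_freqs) - 1) > 1e-8)
      stop_invalid("explicit genotype frequencies must be positive and sum to 1")
  }
  if (maf <= 0 || maf >= 1)
    stop_invalid("degenerate minor allele frequency (must lie strictly in (0,1))")
  structure(list(name = name, maf = maf, hwe = isTRUE(hwe),
                 genotype_freqs = genotype_freqs,
                 chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt),
            class = "locus_spec")
}

#' Specify injected genetic effects for one trait
#'
#' Each term names one or more loci, an effect type per locus
#' (`additive`/`dominance`) and a magnitude. Single-locus terms inject a
#' main effect on that locus's NOIA scale; multi-locus terms inject an
#' epistatic effect on the product of the named scales. Magnitudes are in
#' trait units per unit of the (frequency-weighted) scale.
#'
#' @param trait trait name
#' @param terms list of `list(loci =, types =, magnitude =)`; `loci` and
#'   `types` are parallel character vectors
#' @return object of class `effect_spec`
#' @export
effect_spec <- function(trait, terms) {
  for (tm in terms) {
    stopifnot(length(tm$loci) == length(tm$types),
              all(tm$types %in% c("additive", "dominance")),
              is.finite(tm$magnitude))
  }
  structure(list(trait = trait, terms = terms), class = "effect_spec")
}

# Default loci: the three study loci in canonical order, with moderate
# minor-allele frequencies plausible for a closed breeding colony.
default_loci <- function() {
  list(
    locus_spec("PLA2G4A", maf = 0.30, chrom = "chr1", pos = 101000L, ref = "C", alt = "T"),
    locus_spec("APOB.1",  maf = 0.25, chrom = "chr13", pos = 20932165L, ref = "C", alt = "T"),
    locus_spec("APOB.2",  maf = 0.25, chrom = "chr13", pos = 20940049L, ref = "G", alt = "A")
  )
}

# Default trait panel: six named metabolic traits matching the study's
# headline phenotypes plus generic traits up to n_traits.
default_trait_names <- function(n_traits = 37L) {
  named <- c("weight_change_pct", "leptin_bw_ratio", "total_fat_dxa",
             "insulin_glucose_ratio", "triglycerides", "free_fatty_acids")
  if (n_traits <= length(named)) return(named[seq_len(n_traits)])
  c(named, sprintf("trait_%02d", seq(length(named) + 1L, n_traits)))
}

# Default effect plan mirroring the study's per-locus conclusions:
# APOB.1 additive on weight change %, leptin/body-weight ratio and DXA
# total fat; PLA2G4A + APOB.2 jointly additive on insulin/glucose ratio;
# PLA2G4A additive on triglycerides; APOB.2 additive on free fatty acids.
default_trait_effects <- function(magnitude = 1.2) {
  a <- function(trait, loci) effect_spec(trait, lapply(loci, function(l)
    list(loci = l, types = "additive", magnitude = magnitude)))
  list(
    a("weight_change_pct", "APOB.1"),
    a("leptin_bw_ratio", "APOB.1"),
    a("total_fat_dxa", "APOB.1"),
    a("insulin_glucose_ratio", c("PLA2G4A", "APOB.2")),
    a("triglycerides", "PLA2G4A"),
    a("free_fatty_acids", "APOB.2")
  )
}

# Default trait correlation: exchangeable correlation 0.3 among the six
# named metabolic traits (they index the same obesity/insulin axis),
# independence elsewhere. Positive definite by construction.
default_trait_correlation <- function(n_traits = 37L) {
  R <- diag(n_traits)
  k <- min(6L, n_traits)
  R[seq_len(k), seq_len(k)] <- 0.3
  diag(R) <- 1
  R
}

#' Configure a synthetic cohort
#'
#' Defaults emulate the study design: 43 deeply phenotyped adult females,
#' three biallelic candidate loci, and 37 correlated quantitative traits
#' with additive effects injected at the loci reported to drive them.
#'
#' @param n_animals cohort size (default 43)
#' @param loci list of [locus_spec()] (default the three study loci)
#' @param n_traits number of traits (default 37)
#' @param trait_names trait names (default: six named metabolic traits then
#'   `trait_07`...)
#' @param trait_effects list of [effect_spec()] (default mirrors the
#'   reported per-locus additive effects)
#' @param trait_correlation n_traits x n_traits positive-semidefinite
#'   correlation matrix for the noise component (Gaussian copula on noise
#'   only)
#' @param trait_intercepts per-trait intercepts (recycled; default 0)
#' @param noise_sd per-trait noise standard deviation (recycled; default 1)
#' @param missing_rate_genotype,missing_rate_phenotype probabilities in
#'   \[0,1\] of completely-at-random missingness
#' @param seed integer seed; all generation is reproducible given the config
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_animals = 43L,
                          loci = default_loci(),
                          n_traits = 37L,
                          trait_names = default_trait_names(n_traits),
                          trait_effects = default_trait_effects(),
                          trait_correlation = default_trait_correlation(n_traits),
                          trait_intercepts = 0,
                          noise_sd = 1,
                          missing_rate_genotype = 0,
                          missing_rate_phenotype = 0,
                          seed = 1L) {
  n_animals <- as.integer(n_animals)
  if (n_animals < 1L) stop_invalid("n_animals must be >= 1")
  stopifnot(length(trait_names) == n_traits)
  R <- as.matrix(trait_correlation)
  if (nrow(R) != n_traits || ncol(R) != n_traits)
    stop_invalid("trait_correlation must be ", n_traits, " x ", n_traits)
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
    stop_invalid("trait_correlation must be symmetric with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_invalid("trait_correlation is not positive semidefinite (min eigenvalue ",
                 format(min(ev)), ")")
  for (r in c(missing_rate_genotype, missing_rate_phenotype))
    if (r < 0 || r > 1) stop_invalid("missingness rates must lie in [0,1]")
  locus_names <- vapply(loci, `[[`, "", "name")
  if (anyDuplicated(locus_names)) stop_invalid("duplicate locus names")
  for (ef in trait_effects) {
    if (!ef$trait %in% trait_names)
      stop_invalid("effect references unknown trait: ", ef$trait)
    for (tm in ef$terms)
      if (!all(tm$loci %in% locus_names))
        stop_invalid("effect on trait ", ef$trait, " references unknown loci")
  }
  structure(list(n_animals = n_animals, loci = loci, n_traits = n_traits,
                 trait_names = trait_names, trait_effects = trait_effects,
                 trait_correlation = R,
                 trait_intercepts = rep_len(trait_intercepts, n_traits),
                 noise_sd = rep_len(noise_sd, n_traits),
                 missing_rate_genotype = missing_rate_genotype,
                 missing_rate_phenotype = missing_rate_phenotype,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate a genotyped and phenotyped cohort
#'
#' Genotypes are drawn independently per animal and locus from each locus's
#' genotype frequencies (Hardy-Weinberg from the minor-allele frequency
#' unless explicit frequencies are given). Each trait is the sum of its
#' intercept, the injected genetic terms — evaluated on the NOIA
#' statistical scales computed from the realized genotype frequencies, so
#' downstream recovery is self-consistent — and multivariate Gaussian noise
#' with the configured correlation. Missingness is injected completely at
#' random afterwards. Output is bitwise reproducible for a fixed config.
#'
#' @param config a [cohort_config()]
#' @return list with `genotypes` (integer matrix, animals x loci, codes
#'   1/2/3/NA, site metadata in `attr(, "sites")`) and `phenotypes`
#'   (data.frame: `animal_id` plus one numeric column per trait)
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' dim(cohort$genotypes)                 # 43 x 3
#' dim(cohort$phenotypes)                # 43 x 38 (animal_id + 37 traits)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_animals
    ids <- sprintf("animal_%03d", seq_len(n))
    locus_names <- vapply(config$loci, `[[`, "", "name")

    G <- matrix(NA_integer_, n, length(config$loci),
                dimnames = list(ids, locus_names))
    for (j in seq_along(config$loci)) {
      ls <- config$loci[[j]]
      freqs <- ls$genotype_freqs %||%
        c((1 - ls$maf)^2, 2 * ls$maf * (1 - ls$maf), ls$maf^2)
      G[, j] <- sample.int(3L, n, replace = TRUE, prob = freqs)
    }

    # genetic signal on realized-frequency NOIA scales
    signal <- matrix(0, n, config$n_traits,
                     dimnames = list(ids, config$trait_names))
    scales <- lapply(seq_along(config$loci), function(j) {
      tryCatch(locus_scales(G[, j]), error = function(e) NULL)
    })
    names(scales) <- locus_names
    for (ef in config$trait_effects) {
      for (tm in ef$terms) {
        col <- rep(1, n)
        for (k in seq_along(tm$loci)) {
          sc <- scales[[tm$loci[k]]]
          if (is.null(sc)) stop_invalid("cannot inject effect: locus ",
                                        tm$loci[k], " has no genotypes")
          col <- col * scale_values(sc, tm$types[k], G[, tm$loci[k]])
        }
        signal[, ef$trait] <- signal[, ef$trait] + tm$magnitude * col
      }
    }

    # correlated Gaussian noise (copula on the noise component only)
    L <- chol_psd(config$trait_correlation)
    Z <- matrix(stats::rnorm(n * config$n_traits), n, config$n_traits)
    noise <- Z %*% L
    noise <- sweep(noise, 2L, config$noise_sd, `*`)

    Y <- sweep(signal + noise, 2L, config$trait_intercepts, `+`)

    if (config$missing_rate_genotype > 0) {
      drop <- matrix(stats::runif(length(G)) < config$missing_rate_genotype,
                     nrow(G), ncol(G))
      G[drop] <- NA_integer_
    }
    if (config$missing_rate_phenotype > 0) {
      drop <- matrix(stats::runif(length(Y)) < config$missing_rate_phenotype,
                     nrow(Y), ncol(Y))
      Y[drop] <- NA_real_
    }

    attr(G, "sites") <- data.frame(
      locus = locus_names,
      chrom = vapply(config$loci, `[[`, "", "chrom"),
      pos = vapply(config$loci, function(l) l$pos, 1L),
      ref = vapply(config$loci, `[[`, "", "ref"),
      alt = vapply(config$loci, `[[`, "", "alt"),
      stringsAsFactors = FALSE)

    phenotypes <- data.frame(animal_id = ids, as.data.frame(Y),
                             check.names = FALSE, row.names = NULL)
    list(genotypes = G, phenotypes = phenotypes)
  })
}

# Cholesky-like factor tolerant of semidefinite matrices (pivoted, with
# zeroing of trailing rank-deficient block).
chol_psd <- function(R) {
  out <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(vals), length(vals)))
}

#' Simulate per-caller variant call sets from true genotypes
#'
#' Each caller reports each animal's call at each site; with probability
#' `miss_call_rate` a call is corrupted (half the time dropped to missing,
#' half the time perturbed to another zygosity). A caller's set contains
#' only the sites at which it made at least one non-reference call, so
#' noisy callers yield differing site sets whose consensus is their
#' intersection.
#'
#' @param genotypes genotype matrix from [simulate_cohort()] (site metadata
#'   is taken from `attr(genotypes, "sites")` or synthesised)
#' @param n_callers number of callers (>= 1)
#' @param miss_call_rate per-call corruption probability in \[0,1\]
#' @param seed integer seed
#' @return list of `variant_callset` objects (see [variant_callset()])
#' @export
simulate_callsets <- function(genotypes, n_callers = 3L, miss_call_rate = 0.05,
                              seed = 1L) {
  n_callers <- as.integer(n_callers)
  if (n_callers < 1L) stop_invalid("n_callers must be >= 1")
  if (miss_call_rate < 0 || miss_call_rate > 1)
    stop_invalid("miss_call_rate must lie in [0,1]")
  sites <- attr(genotypes, "sites")
  if (is.null(sites)) {
    sites <- data.frame(locus = colnames(genotypes), chrom = "chr1",
                        pos = seq_len(ncol(genotypes)) * 100L,
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_callers), function(ci) {
      Z <- matrix(code_to_zygosity(genotypes), nrow(genotypes), ncol(genotypes),
                  dimnames = dimnames(genotypes))
      if (miss_call_rate > 0) {
        hit <- which(!is.na(Z) & stats::runif(length(Z)) < miss_call_rate)
        for (i in hit) {
          if (stats::runif(1) < 0.5) {
            Z[i] <- NA_character_
          } else {
            Z[i] <- sample(setdiff(ZYGOSITY_LEVELS, Z[i]), 1L)
          }
        }
      }
      keep <- vapply(seq_len(ncol(Z)), function(j)
        any(Z[, j] %in% c("het", "hom_alt")), TRUE)
      variant_callset(
        caller_id = sprintf("caller_%02d", ci),
        sites = sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE],
        zygosity = t(Z[, keep, drop = FALSE]))
    })
  })
}

#' Simulate a multi-species exon alignment and reference sequence
#'
#' The reference is a uniform random DNA sequence; each other species copies
#' it with independent per-base substitutions at the given divergence. All
#' rows are equal length (no indels), so per-column identity statistics are
#' exact and reproducible under the seed.
#'
#' @param length sequence length in bp (must be at least `window_len`)
#' @param n_species number of aligned species (>= 2); the first row is the
#'   reference
#' @param divergence per-base substitution probability in \[0,1\]
#' @param seed integer seed
#' @param window_len minimum usable length, defaulting to the 85 bp probe
#'   window
#' @return list with `reference` (character scalar) and `alignment` (named
#'   character vector, one sequence per species)
#' @export
simulate_mini_genome <- function(length, n_species = 4L, divergence = 0.02,
                                 seed = 1L, window_len = 85L) {
  length <- as.integer(length)
  if (length < window_len)
    stop_invalid("length (", length, ") shorter than window size (", window_len, ")")
  if (n_species < 2L) stop_invalid("need at least 2 species")
  if (divergence < 0 || divergence > 1)
    stop_invalid("divergence must lie in [0,1]")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ref <- sample(bases, length, replace = TRUE)
    aln <- matrix(rep(ref, n_species), nrow = n_species, byrow = TRUE)
    if (divergence > 0 && n_species > 1L) {
      for (i in 2:n_species) {
        hit <- which(stats::runif(length) < divergence)
        for (j in hit) aln[i, j] <- sample(setdiff(bases, aln[i, j]), 1L)
      }
    }
    seqs <- apply(aln, 1L, paste, collapse = "")
    names(seqs) <- c("reference", sprintf("species_%02d", seq_len(n_species - 1L)))
    list(reference = seqs[[1L]], alignment = seqs)
  })
}
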