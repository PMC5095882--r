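#' Build the default end-to-end pipeline configuration
#'
#' The defaults reproduce the study's data structure: a 43-animal cohort
#' with 37 correlated traits and three candidate loci; an 8-animal
#' (4 resistant vs 4 sensitive) extreme-phenotype discovery subset; three
#' noisy callers; the homozygous-discordance ladder k = 4, 3, 2;
#' association with adaptive permutation; and the 26-model NOIA screen.
#'
#' @param out_dir output directory
#' @param seed base integer seed; stage seeds are derived by fixed offsets
#' @param cohort a [cohort_config()] (its seed is overridden by `seed`)
#' @param n_callers,miss_call_rate call-set simulation parameters
#' @param k_ladder discordance relaxation ladder
#' @param alpha significance level for association and model screening
#' @param max_permutations adaptive permutation ceiling
#' @param genome_length,n_species,divergence probe-design fixture parameters
#' @return list of class `run_config`
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            cohort = cohort_config(seed = seed),
                            n_callers = 3L, miss_call_rate = 0.05,
                            k_ladder = c(4L, 3L, 2L),
                            alpha = 0.05, max_permutations = 10000L,
                            genome_length = 2000L, n_species = 4L,
                            divergence = 0.02) {
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 n_callers = n_callers, miss_call_rate = miss_call_rate,
                 k_ladder = as.integer(k_ladder), alpha = alpha,
                 max_permutations = as.integer(max_permutations),
                 genome_length = as.integer(genome_length),
                 n_species = as.integer(n_species), divergence = divergence),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; unknown
#' keys are rejected. The seed is always explicit in the config.
#'
#' @param path YAML file
#' @param out_dir output directory (overrides any `out_dir` key)
#' @return list of class `run_config`
#' @export
pipeline_config_from_yaml <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "n_animals", "n_traits", "n_callers",
             "miss_call_rate", "k_ladder", "alpha", "max_permutations",
             "genome_length", "n_species", "divergence",
             "missing_rate_genotype", "missing_rate_phenotype")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop_invalid("unknown config keys: ",
                                    paste(unknown, collapse = ", "))
  seed <- as.integer(y$seed %||% 1L)
  cohort <- cohort_config(
    n_animals = y$n_animals %||% 43L,
    n_traits = y$n_traits %||% 37L,
    missing_rate_genotype = y$missing_rate_genotype %||% 0,
    missing_rate_phenotype = y$missing_rate_phenotype %||% 0,
    seed = seed)
  pipeline_config(out_dir = out_dir %||% y$out_dir %||% ".",
                  seed = seed, cohort = cohort,
                  n_callers = y$n_callers %||% 3L,
                  miss_call_rate = y$miss_call_rate %||% 0.05,
                  k_ladder = y$k_ladder %||% c(4L, 3L, 2L),
                  alpha = y$alpha %||% 0.05,
                  max_permutations = y$max_permutations %||% 10000L,
                  genome_length = y$genome_length %||% 2000L,
                  n_species = y$n_species %||% 4L,
                  divergence = y$divergence %||% 0.02)
}

# Convert a call set to a genotype matrix + sites for VCF emission.
callset_to_genotypes <- function(callset) {
  G <- t(matrix(zygosity_to_code(callset$zygosity),
                nrow(callset$zygosity), ncol(callset$zygosity),
                dimnames = dimnames(callset$zygosity)))
  attr(G, "sites") <- data.frame(locus = rownames(callset$zygosity),
                                 callset$sites, stringsAsFactors = FALSE)
  G
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> discover -> associate -> NOIA screen -> phenotype
#' summaries -> probe design, writing every artifact under
#' `config$out_dir` and a `manifest.tsv` listing each output with its MD5
#' checksum. Identical config and seed give a byte-identical manifest.
#'
#' @param config a [pipeline_config()]
#' @return the manifest data.frame, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  seed <- config$seed

  ## stage 1: simulate cohort
  cohort <- simulate_cohort(config$cohort)
  G <- cohort$genotypes
  write_genotypes(G, out("genotypes.vcf"), "vcf")
  write_genotypes(G, out("genotypes.tsv"), "tsv")
  write_phenotypes(cohort$phenotypes, out("phenotypes.csv"))

  ## classification: resistant = below-median weight change, sensitive above
  wc <- cohort$phenotypes$weight_change_pct
  cutoff <- stats::median(wc, na.rm = TRUE)
  rule <- classification_rule(list(list(trait = "weight_change_pct",
                                        direction = "below", cutoff = cutoff)))
  groups <- classify(cohort$phenotypes, rule)
  write_groups(groups, out("groups.tsv"))

  ## discovery subset: 4 + 4 extreme-phenotype animals
  ord <- order(wc)
  disc_animals <- c(rownames(G)[ord[seq_len(4L)]],
                    rownames(G)[rev(ord)[seq_len(4L)]])
  disc_groups <- stats::setNames(rep(c("resistant", "sensitive"), each = 4L),
                                 disc_animals)
  Gd <- G[disc_animals, , drop = FALSE]
  attr(Gd, "sites") <- attr(G, "sites")
  callsets <- simulate_callsets(Gd, n_callers = config$n_callers,
                                miss_call_rate = config$miss_call_rate,
                                seed = seed + 1L)
  for (cs in callsets)
    write_genotypes(callset_to_genotypes(cs),
                    out(paste0("calls_", cs$caller_id, ".vcf")), "vcf")

  ## stage 2: discovery (consensus + discordance ladder + gate)
  consensus <- consensus_intersect(callsets)
  seed_set <- callsets[[1L]]
  keep <- callset_keys(seed_set) %in% consensus
  seed_set <- variant_callset(seed_set$caller_id,
                              seed_set$sites[keep, , drop = FALSE],
                              seed_set$zygosity[keep, , drop = FALSE])
  ladder <- lapply(config$k_ladder, function(k) {
    cand <- discordance_filter(seed_set, disc_groups, discordance_rule(k = k))
    if (nrow(cand)) cand$k_required <- k
    cand
  })
  candidates <- do.call(rbind, ladder[vapply(ladder, nrow, 1L) > 0])
  if (is.null(candidates))
    candidates <- data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             key = character(), carrier_group = character(),
                             k_observed = integer(), k_required = integer())
  annotations <- demo_annotations(attr(G, "sites"))
  write_annotations(annotations, out("annotations.tsv"))
  gated <- functional_gate(candidates, read_annotations(out("annotations.tsv")))
  utils::write.table(gated, out("candidates.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  ## stage 3: association on the full cohort
  sites <- attr(G, "sites")
  plan <- permutation_plan(max_permutations = config$max_permutations,
                           alpha = config$alpha, seed = seed + 2L)
  assoc_rows <- list()
  lab <- groups[groups != "unclassified"]
  for (j in seq_len(ncol(G))) {
    gsub <- G[names(lab), j]
    cc <- case_control_assoc(gsub, lab)
    emp <- if (!cc$untestable)
      adaptive_permutation(allelic_chisq_statistic(gsub), lab, plan)
    else NULL
    assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
      locus = colnames(G)[j], test = "case_control", trait = NA_character_,
      statistic = cc$statistic, p_asymptotic = cc$p_asymptotic,
      p_fisher = cc$p_fisher,
      p_empirical = if (is.null(emp)) NA_real_ else emp$p_empirical,
      n_permutations = if (is.null(emp)) NA_integer_ else emp$n_permutations_used,
      odds_ratio = cc$odds_ratio, untestable = cc$untestable)
  }
  traits <- setdiff(names(cohort$phenotypes), c("animal_id", "group"))
  for (j in seq_len(ncol(G))) {
    for (tr in traits) {
      qa <- quantitative_assoc(G[, j], cohort$phenotypes[[tr]])
      assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
        locus = colnames(G)[j], test = "quantitative", trait = tr,
        statistic = qa$statistic, p_asymptotic = qa$p_asymptotic,
        p_fisher = NA_real_, p_empirical = NA_real_,
        n_permutations = NA_integer_, odds_ratio = NA_real_,
        untestable = qa$untestable)
    }
  }
  assoc <- do.call(rbind, assoc_rows)
  utils::write.table(assoc, out("assoc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  ## stage 4: NOIA model screen
  screen <- screen_models(G, cohort$phenotypes, alpha = config$alpha)
  utils::write.table(screen$all, out("noia_fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(screen$best, out("noia_best.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  best1 <- screen$best[1L, ]
  models <- enumerate_models(colnames(G))
  ids <- vapply(models, `[[`, "", "id")
  bfit <- fit_model(G, cohort$phenotypes[[best1$trait]],
                    models[[match(best1$model_id, ids)]])
  utils::write.table(genotype_effect_table(bfit), out("genotype_effects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")

  ## stage 5: phenotype summaries
  named6 <- intersect(default_trait_names(6L), traits)
  corr <- correlation_matrix(cohort$phenotypes, named6)
  utils::write.table(round(corr$r, 10), out("corr.tsv"), sep = "\t",
                     quote = FALSE, na = "NA", col.names = NA)
  long <- data.frame(
    trait_1 = rep(rownames(corr$r), times = ncol(corr$r)),
    trait_2 = rep(colnames(corr$r), each = nrow(corr$r)),
    r = as.vector(corr$r), p = as.vector(corr$p),
    stars = as.vector(corr$stars), n = as.vector(corr$n))
  long <- long[long$trait_1 < long$trait_2, , drop = FALSE]
  utils::write.table(long, out("corr_long.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  baseline <- baseline_comparison(cohort$phenotypes, groups)
  utils::write.table(baseline, out("baseline.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")

  ## stage 6: probe design on a simulated mini-genome
  mg <- simulate_mini_genome(config$genome_length, config$n_species,
                             config$divergence, seed = seed + 3L)
  write_fasta(mg$alignment, out("exon_alignment.fa"))
  windows <- scan_windows(mg$alignment, exon_id = "exon_01")
  probes <- kmer_filter(windows, mg$reference)
  write_probes_bed(probes, out("probes.bed"))

  ## manifest
  files <- sort(setdiff(list.files(config$out_dir), "manifest.tsv"))
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(sums),
                         seed = seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

# Synthetic annotation table for the simulated candidate loci: the three
# study loci carry nonsynonymous consequences, deleterious predictions and
# CADD PHRED scores spanning the two reporting tiers.
demo_annotations <- function(sites) {
  n <- nrow(sites)
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             alt = sites$alt,
             key = site_key(sites$chrom, sites$pos, sites$ref, sites$alt),
             consequence = rep("missense_variant", n),
             category = rep("nonsynonymous", n),
             sift_deleterious = rep(TRUE, n),
             provean_deleterious = rep(c(TRUE, FALSE), length.out = n),
             cadd_phred = rep(c(23.6, 9.018, 15.07), length.out = n),
             stringsAsFactors = FALSE)
}

#' One-command end-to-end demonstration
#'
#' Runs [run_pipeline()] with the default study-scale configuration
#' (43 animals, 3 loci, 37 traits) under the given seed.
#'
#' @param out_dir output directory
#' @param seed integer seed
#' @return the manifest data.frame, invisibly
#' @export
run_demo <- function(out_dir, seed = 1L) {
  run_pipeline(pipeline_config(out_dir = out_dir, seed = seed))
}
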