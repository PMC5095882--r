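`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a canonical site key
#'
#' Variant sites are identified throughout the package by the tuple
#' (chromosome, 1-based position, reference allele, alternate allele),
#' joined into a single string.
#'
#' @param chrom chromosome name
#' @param pos 1-based position (VCF convention)
#' @param ref reference allele
#' @param alt alternate allele
#' @return character vector of keys, one per site
#' @export
site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs a user's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Reverse complement of plain character DNA (vectorised).
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Genotype codes used throughout: 1 = homozygous major (reference),
# 2 = heterozygous, 3 = homozygous minor (alternate); NA = missing.
GENO_CODES <- 1:3
ZYGOSITY_LEVELS <- c("hom_ref", "het", "hom_alt")

zygosity_to_code <- function(z) {
  match(z, ZYGOSITY_LEVELS)
}

code_to_zygosity <- function(code) {
  ZYGOSITY_LEVELS[code]
}
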