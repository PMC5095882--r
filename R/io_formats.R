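#' Construct a variant call set
#'
#' One caller's per-animal zygosity calls at its candidate sites.
#'
#' @param caller_id caller name
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; the (chrom, pos, ref, alt) tuples must be unique
#' @param zygosity character matrix (sites x animals) with values
#'   `"hom_ref"`, `"het"`, `"hom_alt"` or NA (missing); column names are
#'   animal ids
#' @return object of class `variant_callset`
#' @export
variant_callset <- function(caller_id, sites, zygosity) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (any(sites$pos < 1L)) stop_invalid("positions must be >= 1 (1-based, VCF convention)")
  keys <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(keys))
    stop_invalid("duplicate sites in call set: ",
                 paste(keys[duplicated(keys)], collapse = ", "))
  zygosity <- as.matrix(zygosity)
  if (nrow(zygosity) != nrow(sites))
    stop_invalid("zygosity must have one row per site")
  bad <- !is.na(zygosity) & !zygosity %in% ZYGOSITY_LEVELS
  if (any(bad)) stop_invalid("invalid zygosity values: ",
                             paste(unique(zygosity[bad]), collapse = ", "))
  rownames(zygosity) <- keys
  structure(list(caller_id = caller_id, sites = sites, zygosity = zygosity),
            class = "variant_callset")
}

#' @export
print.variant_callset <- function(x, ...) {
  cat("variant_callset", x$caller_id, ":", nrow(x$sites), "sites x",
      ncol(x$zygosity), "animals\n")
  invisible(x)
}

#' Site keys of a call set
#' @param callset a [variant_callset()]
#' @return character vector of site keys
#' @export
callset_keys <- function(callset) {
  rownames(callset$zygosity)
}

# ---- genotype matrices -----------------------------------------------------

gt_to_code <- function(gt) {
  # GT subfield of a biallelic record -> code 1/2/3 (alt-allele count + 1)
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0L || anyNA(a) || all(a == ".")) return(NA_integer_)
    if (!all(a %in% c("0", "1", "."))) return(-1L)  # sentinel: malformed
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1") + 1L
  }, integer(1L))
}

#' Read a genotype matrix
#'
#' Supports a minimal VCF 4.2 subset (single ALT allele, GT genotype field)
#' and a plain TSV (first column `animal_id`, remaining columns loci with
#' codes 1/2/3 and NA/empty for missing). VCF genotypes are mapped
#' hom_ref -> 1, het -> 2 (phase ignored, so 1/0 and 0/1 both code 2),
#' hom_alt -> 3, missing -> NA. Animal order follows the file header, and
#' coordinates stay 1-based throughout.
#'
#' @param path file path
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension)
#' @return integer matrix animals x loci; for VCF input the site table is
#'   attached as `attr(, "sites")`
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1L]
    stop_invalid("multi-allelic record not supported: ",
                 site_key(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alt[i]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  codes <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  for (i in seq_len(nrow(gt))) {
    ci <- gt_to_code(gt[i, ])
    if (any(ci == -1L, na.rm = TRUE)) {
      stop_invalid("malformed GT at data line ", i, " (",
                   site_key(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alt[i]),
                   "): ", gt[i, which(ci == -1L)[1L]])
    }
    codes[i, ] <- ci
  }
  G <- t(codes)
  sites <- data.frame(locus = rownames(codes) %||% paste0("site_", seq_len(nrow(codes))),
                      chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = alt,
                      stringsAsFactors = FALSE, row.names = NULL)
  colnames(G) <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  attr(G, "sites") <- sites
  G
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!"animal_id" %in% names(df)) stop_invalid("TSV genotypes need an animal_id column")
  if (anyDuplicated(df$animal_id))
    stop_invalid("duplicate animal ids in ", path)
  loci <- setdiff(names(df), "animal_id")
  G <- matrix(NA_integer_, nrow(df), length(loci),
              dimnames = list(df$animal_id, loci))
  for (l in loci) {
    x <- df[[l]]
    ok <- is.na(x) | x %in% c("1", "2", "3")
    if (!all(ok))
      stop_invalid("invalid genotype code in column ", l, ": ", x[!ok][1L])
    G[, l] <- as.integer(x)
  }
  G
}

#' Write a genotype matrix
#'
#' @param genotypes animals x loci genotype matrix (codes 1/2/3/NA); for
#'   VCF output a site table must be present in `attr(genotypes, "sites")`
#' @param path output path
#' @param format `"vcf"` (minimal VCF 4.2, GT-only FORMAT) or `"tsv"`
#' @return the path, invisibly
#' @export
write_genotypes <- function(genotypes, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(animal_id = rownames(genotypes), genotypes,
                     check.names = FALSE, row.names = NULL)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    return(invisible(path))
  }
  sites <- attr(genotypes, "sites")
  if (is.null(sites)) stop_invalid("VCF output needs attr(genotypes, 'sites')")
  gt_strings <- c("0/0", "0/1", "1/1")
  samples <- rownames(genotypes)
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", unique(sites$chrom), ">"),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    g <- genotypes[, i]
    gt <- ifelse(is.na(g), "./.", gt_strings[g])
    paste(c(sites$chrom[i], sites$pos[i], sites$locus[i] %||% ".",
            sites$ref[i], sites$alt[i], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1L))
  writeLines(c(lines, body), path)
  invisible(path)
}

# ---- phenotypes ------------------------------------------------------------

#' Read a phenotype table
#'
#' CSV or TSV with an `animal_id` column, one numeric column per trait, and
#' optionally a `group` column with resistant/sensitive labels. Missing
#' values are the empty string or `"NA"`. Duplicate animal ids and
#' non-numeric trait cells are rejected.
#'
#' @param path file path (separator guessed from the extension; `.csv` ->
#'   comma, otherwise tab)
#' @return data.frame with `animal_id` (character), optional `group`, and
#'   numeric traits
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!"animal_id" %in% names(df)) stop_invalid("phenotype file needs an animal_id column")
  if (anyDuplicated(df$animal_id))
    stop_invalid("duplicate animal id: ",
                 df$animal_id[duplicated(df$animal_id)][1L])
  out <- data.frame(animal_id = df$animal_id, stringsAsFactors = FALSE)
  if ("group" %in% names(df)) out$group <- df$group
  for (cn in setdiff(names(df), c("animal_id", "group"))) {
    x <- df[[cn]]
    num <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(num)
    if (any(bad))
      stop_invalid("non-numeric value in trait column ", cn, ": '",
                   x[bad][1L], "'")
    out[[cn]] <- num
  }
  out
}

#' Write a phenotype table as CSV
#' @param phenotypes data.frame with `animal_id` column
#' @param path output path
#' @return the path, invisibly
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- annotations -----------------------------------------------------------

# Map of variant-consequence terms (VEP vocabulary) to the three categories
# the discovery gate distinguishes; shipped as a documented data file.
consequence_map <- function() {
  path <- system.file("extdata", "vep_consequence_map.tsv", package = "noiascan")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "vep_consequence_map.tsv")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

classify_consequence <- function(term) {
  map <- consequence_map()
  cat <- map$category[match(tolower(term), map$term)]
  ifelse(is.na(cat), "other", cat)
}

parse_deleterious <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("deleterious", "damaging", "true", "yes", "1")] <- TRUE
  out[x %in% c("tolerated", "benign", "neutral", "false", "no", "0")] <- FALSE
  out
}

#' Read a variant annotation table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `consequence`, `sift`,
#' `provean`, `cadd_phred`. Consequence terms are mapped to the categories
#' nonsynonymous / synonymous / other via the shipped synonym table
#' (unknown terms are preserved verbatim and categorised "other"). SIFT and
#' PROVEAN cells accept deleterious/tolerated-style labels; empty means
#' missing. Negative CADD scores are rejected.
#'
#' @param path file path
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `consequence`, `category`, `sift_deleterious`, `provean_deleterious`,
#'   `cadd_phred`
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"))
  need <- c("chrom", "pos", "ref", "alt", "consequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_invalid("annotation file lacks columns: ",
                                 paste(miss, collapse = ", "))
  cadd <- suppressWarnings(as.numeric(df$cadd_phred %||% rep(NA, nrow(df))))
  if (any(!is.na(cadd) & cadd < 0))
    stop_invalid("negative CADD PHRED score: ", min(cadd, na.rm = TRUE))
  data.frame(
    chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref, alt = df$alt,
    key = site_key(df$chrom, as.integer(df$pos), df$ref, df$alt),
    consequence = df$consequence,
    category = classify_consequence(df$consequence),
    sift_deleterious = parse_deleterious(df$sift %||% rep(NA, nrow(df))),
    provean_deleterious = parse_deleterious(df$provean %||% rep(NA, nrow(df))),
    cadd_phred = cadd,
    stringsAsFactors = FALSE)
}

#' Write a variant annotation table
#' @param annotations data.frame as produced by [read_annotations()] (the
#'   `key`/`category` columns are dropped; `sift`/`provean` are written as
#'   deleterious/tolerated labels)
#' @param path output path
#' @return the path, invisibly
#' @export
write_annotations <- function(annotations, path) {
  lab <- function(x) ifelse(is.na(x), NA_character_,
                            ifelse(x, "deleterious", "tolerated"))
  df <- data.frame(chrom = annotations$chrom, pos = annotations$pos,
                   ref = annotations$ref, alt = annotations$alt,
                   consequence = annotations$consequence,
                   sift = lab(annotations$sift_deleterious),
                   provean = lab(annotations$provean_deleterious),
                   cadd_phred = annotations$cadd_phred)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# ---- group labels ----------------------------------------------------------

#' Read animal group labels
#' @param path TSV with columns `animal_id` and `group`
#' @return named character vector (names = animal ids)
#' @export
read_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  stopifnot(all(c("animal_id", "group") %in% names(df)))
  stats::setNames(df$group, df$animal_id)
}

#' Write animal group labels
#' @param groups named character vector (names = animal ids)
#' @param path output path
#' @return the path, invisibly
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(animal_id = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- alignments / sequences ------------------------------------------------

#' Read a multi-FASTA alignment
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @return the path, invisibly
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
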