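#' Scan a multi-species exon alignment for conserved probe windows
#'
#' Slides a fixed-length window along the alignment and keeps windows whose
#' across-species conservation — the fraction of window columns in which
#' every species carries the identical non-gap base — meets the minimum.
#' Gap columns count as mismatches. Coordinates are 0-based half-open on
#' the alignment (BED convention).
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (first row is taken as the reference); or a list with an
#'   `alignment` element as produced by [simulate_mini_genome()]
#' @param exon_id identifier recorded in the output
#' @param window_len window length in bp (default 85)
#' @param min_conservation minimum identity fraction (default 0.90)
#' @param step window step in bp (default 1)
#' @return data.frame of class `probe_windows`: `exon_id`, `start`, `end`
#'   (0-based half-open), `conservation`, `sequence` (reference bases,
#'   gaps stripped)
#' @export
scan_windows <- function(alignment, exon_id = "exon", window_len = 85L,
                         min_conservation = 0.90, step = 1L) {
  if (is.list(alignment) && !is.null(alignment$alignment))
    alignment <- alignment$alignment
  seqs <- toupper(as.character(alignment))
  if (length(seqs) < 2L) stop_invalid("alignment needs at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop_invalid("alignment rows differ in length")
  L <- lens[1L]
  window_len <- as.integer(window_len)
  if (L < window_len) {
    warning("exon ", exon_id, " shorter than window (", L, " < ", window_len,
            "); no windows", call. = FALSE)
    return(empty_windows())
  }
  M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  identical_col <- apply(M, 2L, function(col)
    all(col == col[1L]) && !col[1L] %in% c("-", "."))
  # rolling sum of identical columns over each window
  cum <- c(0L, cumsum(identical_col))
  starts <- seq(0L, L - window_len, by = as.integer(step))
  cons <- (cum[starts + window_len + 1L] - cum[starts + 1L]) / window_len
  keep <- cons >= min_conservation
  refseq <- vapply(starts[keep], function(s) {
    gsub("[-.]", "", substr(seqs[1L], s + 1L, s + window_len))
  }, character(1L))
  out <- data.frame(exon_id = rep(exon_id, sum(keep)), start = starts[keep],
                    end = starts[keep] + window_len,
                    conservation = cons[keep], sequence = refseq,
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_windows", class(out))
  out
}

empty_windows <- function() {
  out <- data.frame(exon_id = character(), start = integer(), end = integer(),
                    conservation = numeric(), sequence = character())
  class(out) <- c("probe_windows", class(out))
  out
}

# Count every k-mer of the genome once, folding the two strands together
# (a k-mer and its reverse complement share one canonical count) and
# skipping k-mers containing N. Returns a named integer vector over
# canonical k-mers.
count_genome_kmers <- function(genome, k = 15L) {
  genome <- toupper(genome)
  if (!nzchar(genome)) stop_invalid("empty genome")
  n <- nchar(genome)
  if (n < k) return(stats::setNames(integer(0), character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(genome, starts, starts + k - 1L)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  tab <- table(canon)
  stats::setNames(as.integer(tab), names(tab))
}

#' Filter probe windows by genome-wide k-mer frequency
#'
#' Counts every k-mer of the reference genome (forward strand and reverse
#' complement folded together; k-mers containing N are skipped) and retains
#' the windows whose constituent k-mers have a mean genome-wide count below
#' the ceiling — removing repeat-prone probes. An 85 bp window contributes
#' 85 - 15 + 1 = 71 15-mers.
#'
#' @param windows data.frame from [scan_windows()] (needs a `sequence`
#'   column)
#' @param genome reference genome as a single character string (or named
#'   vector; concatenated contigs are counted separately)
#' @param k k-mer length (default 15; must not exceed the window length)
#' @param max_mean_freq retain windows with mean k-mer count strictly below
#'   this value (default 100)
#' @return the retained windows with a `mean_kmer_freq` column appended
#' @export
kmer_filter <- function(windows, genome, k = 15L, max_mean_freq = 100) {
  k <- as.integer(k)
  if (nrow(windows)) {
    wl <- nchar(windows$sequence)
    if (any(k > wl)) stop_invalid("k (", k, ") exceeds window length (",
                                  min(wl), ")")
  }
  per_contig <- lapply(as.character(genome), count_genome_kmers, k = k)
  all_kmers <- unique(unlist(lapply(per_contig, names)))
  counts <- stats::setNames(integer(length(all_kmers)), all_kmers)
  for (v in per_contig) counts[names(v)] <- counts[names(v)] + v
  mean_freq <- vapply(windows$sequence, function(s) {
    s <- toupper(s)
    starts <- seq_len(nchar(s) - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    rc <- revcomp(km)
    canon <- ifelse(km <= rc, km, rc)
    cnt <- counts[canon]
    cnt[is.na(cnt)] <- 0L
    mean(cnt)
  }, numeric(1L), USE.NAMES = FALSE)
  out <- windows
  out$mean_kmer_freq <- mean_freq
  out[mean_freq < max_mean_freq, , drop = FALSE]
}

#' Write probe windows as BED
#'
#' 0-based half-open BED with conservation and mean k-mer frequency in the
#' score columns.
#'
#' @param windows data.frame from [scan_windows()] / [kmer_filter()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_probes_bed <- function(windows, path) {
  df <- data.frame(chrom = windows$exon_id, start = windows$start,
                   end = windows$end,
                   name = sprintf("%s_%d", windows$exon_id, windows$start),
                   conservation = signif(windows$conservation, 6),
                   mean_kmer_freq = if (!is.null(windows$mean_kmer_freq))
                     signif(windows$mean_kmer_freq, 6) else NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = ".")
  invisible(path)
}
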