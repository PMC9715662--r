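# Reference genome access, degenerate-motif scanning, and windowed motif densities.
#
# All coordinates handled here are 0-based half-open; conversion to/from the
# 1-based conventions of MAF and GRanges happens at the I/O boundary only.

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
  N = c("A", "C", "G", "T")
)

#' Expand a degenerate IUPAC pattern into fixed-base motifs
#'
#' Expands every degenerate position of an IUPAC-coded nucleotide pattern
#' (e.g. the canonical-AID target `"WRCY"`, where W = A/T, R = purine,
#' Y = pyrimidine) into the full set of fixed-base motifs it matches.
#'
#' @param pattern A single IUPAC string using codes A, C, G, T, W, R, Y, S, K,
#'   M, N.
#' @return Character vector of all fixed motifs matching `pattern`, sorted
#'   lexicographically. Its length is the product of the per-position
#'   degeneracies (8 for `"WRCY"`).
#' @examples
#' expand_motif("WRCY")
#' expand_motif("TCW")
#' @export
expand_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nzchar(pattern))
  chars <- strsplit(toupper(pattern), "")[[1]]
  unknown <- setdiff(chars, names(IUPAC_EXPANSION))
  if (length(unknown) > 0) {
    abort(sprintf("unknown IUPAC code '%s' in pattern '%s'", unknown[1], pattern))
  }
  grid <- expand.grid(IUPAC_EXPANSION[chars], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  sort(do.call(paste0, grid))
}

#' Reverse-complement character motifs
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with names truncated at the first
#'   whitespace and sequences upper-cased.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(as.character(g)))
}

#' Write a genome to FASTA (with .fai index)
#'
#' @param genome A `DNAStringSet`.
#' @param path Output FASTA path.
#' @param index Build a samtools-style `.fai` sidecar index (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, index = TRUE) {
  Biostrings::writeXStringSet(genome, path)
  if (index) Rsamtools::indexFa(path)
  invisible(path)
}

#' Contig lengths of a genome
#'
#' @param genome A `DNAStringSet`.
#' @return Named integer vector of contig lengths in base pairs.
#' @export
contig_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

.check_contig <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    abort(sprintf("contig '%s' not found in genome (has: %s)",
                  contig, paste(head(names(genome), 5), collapse = ", ")))
  }
}

#' Extract genome sequence by 0-based half-open coordinates
#'
#' @param genome A `DNAStringSet`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase sequence string of length `end - start`.
#' @export
seq_slice <- function(genome, contig, start, end) {
  .check_contig(genome, contig)
  len <- length(genome[[contig]])
  stopifnot(start >= 0, end >= start, end <= len)
  as.character(Biostrings::subseq(genome[[contig]], start + 1, end))
}

#' Extract the sequence context centred on a position
#'
#' Returns the `(2 * flank + 1)`-mer centred on each 0-based position. Used for
#' the pentanucleotide (`flank = 2`) and tetranucleotide context lookups.
#'
#' @param genome A `DNAStringSet`.
#' @param contig Contig name.
#' @param pos Integer vector of 0-based positions.
#' @param flank Bases of context on each side.
#' @return Character vector of context strings.
#' @export
extract_context <- function(genome, contig, pos, flank) {
  .check_contig(genome, contig)
  len <- length(genome[[contig]])
  bad <- pos - flank < 0 | pos + flank >= len
  if (any(bad)) {
    abort(sprintf("context out of bounds on %s at 0-based position %s (flank %d, length %d)",
                  contig, pos[which(bad)[1]], flank, len))
  }
  s <- as.character(genome[[contig]])
  stringr::str_sub(s, pos - flank + 1, pos + flank + 1)
}

#' Scan a genome for degenerate-motif occurrences on both strands
#'
#' Finds all plus-strand matches of the expanded motifs and all plus-strand
#' matches of their reverse complements (reported as minus-strand
#' occurrences). Overlapping matches are all reported; windows containing N
#' never match. For the default `"WRCY"` pattern the minus-strand occurrences
#' are plus-strand RGYW matches with the deaminated G at motif offset 1.
#'
#' @param genome A `DNAStringSet`.
#' @param pattern Degenerate IUPAC pattern (default `"WRCY"`).
#' @param contigs Contigs to scan (default: all).
#' @param target_offset 0-based offset of the mutated base within the motif
#'   (2 for the C of WRCY, 1 for the C of TCW).
#' @return Tibble with columns `contig`, `start` (0-based position of the
#'   motif's 5' base on the plus strand), `end`, `strand`, `motif` (reported in
#'   pattern orientation), and `target_pos` (0-based plus-strand coordinate of
#'   the targeted C on `+` / G on `-`), ordered by (contig, start, strand).
#' @export
scan_motifs <- function(genome, pattern = "WRCY", contigs = NULL,
                        target_offset = 2L) {
  motifs <- expand_motif(pattern)
  L <- nchar(pattern)
  stopifnot(target_offset >= 0, target_offset < L)
  rc_motifs <- revcomp(motifs)
  contigs <- contigs %||% names(genome)
  for (ctg in contigs) .check_contig(genome, ctg)

  scan_one <- function(ctg) {
    subj <- genome[[ctg]]
    hit_tbl <- function(pats, str) {
      m <- Biostrings::matchPDict(Biostrings::PDict(pats), subj)
      starts <- unlist(lapply(m, Biostrings::start), use.names = FALSE)
      if (length(starts) == 0) return(NULL)
      idx <- rep(seq_along(pats), lengths(m))
      offset <- if (str == "+") target_offset else L - 1L - target_offset
      tibble(
        contig = ctg,
        start = starts - 1L,         # to 0-based
        end = starts - 1L + L,
        strand = str,
        motif = motifs[idx],
        target_pos = starts - 1L + offset
      )
    }
    bind_rows(hit_tbl(motifs, "+"), hit_tbl(rc_motifs, "-"))
  }

  out <- bind_rows(lapply(contigs, scan_one))
  if (nrow(out) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), motif = character(),
                  target_pos = integer()))
  }
  out %>%
    mutate(contig = factor(contig, levels = contigs)) %>%
    arrange(contig, start, strand) %>%
    mutate(contig = as.character(contig))
}

#' Motif density in tiling windows
#'
#' Counts motif occurrences (by the coordinate of their mutable base) in
#' non-overlapping tiling windows per contig; the last window of a contig is
#' truncated at the contig end. Densities are reported per base pair and, for
#' cross-chromosome comparison, divided by the contig length.
#'
#' @param occurrences Tibble from [scan_motifs()].
#' @param lengths Named vector of contig lengths.
#' @param window Window width in bp (default 20 kb).
#' @return Tibble with `contig`, `start`, `end`, `count`,
#'   `density` (= count / window width) and `chrom_adjusted`
#'   (= count / contig length).
#' @export
motif_density <- function(occurrences, lengths, window = 20000L) {
  stopifnot(window > 0)
  one <- function(ctg) {
    len <- lengths[[ctg]]
    starts <- seq(0L, len - 1L, by = window)
    ends <- pmin(starts + window, len)
    hits <- occurrences$target_pos[occurrences$contig == ctg]
    cnt <- tabulate(findInterval(hits, starts), nbins = length(starts))
    tibble(contig = ctg, start = starts, end = ends, count = cnt,
           density = cnt / (ends - starts),
           chrom_adjusted = cnt / len)
  }
  bind_rows(lapply(names(lengths), one))
}

#' Read a BED file as a 0-based tibble
#'
#' @param path Path to a BED file.
#' @return Tibble with `contig`, `start` (0-based), `end`, plus `name`,
#'   `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals to BED
#'
#' @param df Tibble with `contig`, `start` (0-based), `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if ("name" %in% names(df)) gr$name <- df$name
  if ("score" %in% names(df)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# internal: tibble of 0-based intervals -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}
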