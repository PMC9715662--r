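# MAF-style somatic SNV I/O and reference validation.

#' Default MAF column mapping
#'
#' Maps the package's standard variant column names to the MAF dialect used on
#' disk. Cohorts from heterogeneous sources can remap any entry.
#'
#' @return Named list mapping internal names to MAF header names.
#' @export
maf_cols <- function() {
  list(
    sample_id = "Tumor_Sample_Barcode",
    contig = "Chromosome",
    pos = "Start_Position",
    ref = "Reference_Allele",
    alt = "Tumor_Seq_Allele2",
    gene = "Hugo_Symbol",
    protein_pos = "Protein_position",
    classification = "Variant_Classification",
    t_alt_count = "t_alt_count",
    t_ref_count = "t_ref_count"
  )
}

#' Read somatic SNVs from a MAF-style TSV
#'
#' Reads a tab-separated mutation table, retains single-nucleotide variants
#' (indels and multi-nucleotide records are dropped with a message), converts
#' 1-based inclusive MAF positions to the package's 0-based convention, and
#' normalises chromosome names.
#'
#' @param path Path to the TSV.
#' @param col_map Column mapping, see [maf_cols()]. Entries `sample_id`,
#'   `contig`, `pos`, `ref` and `alt` are mandatory in the file; the rest are
#'   optional.
#' @param chr_prefix One of `"strip"` (default; remove a leading `"chr"`),
#'   `"add"`, or `"keep"`.
#' @param autosomes_only Restrict to contigs named 1-22 after normalisation
#'   (mirrors whole-genome analyses run on somatic chromosomes only).
#' @param strict Error on unparsable rows instead of dropping them.
#' @return Tibble of variants with columns `sample_id`, `contig`, `pos`
#'   (0-based), `ref`, `alt` and, when present in the file, `gene`,
#'   `protein_pos`, `classification`, `t_alt_count`, `t_ref_count`.
#' @export
read_maf <- function(path, col_map = maf_cols(),
                     chr_prefix = c("strip", "add", "keep"),
                     autosomes_only = FALSE, strict = FALSE) {
  chr_prefix <- match.arg(chr_prefix)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  mandatory <- c("sample_id", "contig", "pos", "ref", "alt")
  for (nm in mandatory) {
    if (!col_map[[nm]] %in% names(raw)) {
      abort(sprintf("mandatory column '%s' (mapped to %s) missing from %s",
                    col_map[[nm]], nm, path))
    }
  }
  present <- names(col_map)[vapply(col_map, function(x) x %in% names(raw), logical(1))]
  out <- tibble(.rows = nrow(raw))
  for (nm in present) out[[nm]] <- raw[[col_map[[nm]]]]

  out$pos <- suppressWarnings(as.numeric(out$pos))
  bad <- is.na(out$pos) | is.na(out$sample_id) | is.na(out$contig) |
    is.na(out$ref) | is.na(out$alt)
  if (any(bad)) {
    if (strict) abort(sprintf("%d unparsable row(s) in %s", sum(bad), path))
    inform(sprintf("dropped %d unparsable row(s)", sum(bad)))
    out <- out[!bad, ]
  }

  is_snv <- nchar(out$ref) == 1 & nchar(out$alt) == 1 &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  if (any(!is_snv)) inform(sprintf("dropped %d non-SNV record(s)", sum(!is_snv)))
  out <- out[is_snv, ]

  out$pos <- as.integer(out$pos) - 1L  # MAF is 1-based inclusive
  out$contig <- switch(chr_prefix,
    strip = sub("^chr", "", out$contig),
    add = ifelse(grepl("^chr", out$contig), out$contig, paste0("chr", out$contig)),
    keep = out$contig
  )
  if (autosomes_only) {
    keep <- sub("^chr", "", out$contig) %in% as.character(1:22)
    if (any(!keep)) inform(sprintf("dropped %d non-autosomal record(s)", sum(!keep)))
    out <- out[keep, ]
  }
  for (nm in intersect(c("t_alt_count", "t_ref_count", "protein_pos"), names(out))) {
    out[[nm]] <- suppressWarnings(as.integer(out[[nm]]))
  }
  as_tibble(out)
}

#' Write variants to a MAF-style TSV
#'
#' Inverse of [read_maf()]: positions are written 1-based inclusive under the
#' headers given by `col_map`.
#'
#' @param variants Variant tibble (0-based `pos`).
#' @param path Output path.
#' @param col_map Column mapping, see [maf_cols()].
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path, col_map = maf_cols()) {
  out <- tibble(.rows = nrow(variants))
  for (nm in intersect(names(col_map), names(variants))) {
    out[[col_map[[nm]]]] <- variants[[nm]]
  }
  out[[col_map$pos]] <- variants$pos + 1L
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate variant reference alleles against the genome
#'
#' Checks, for every variant, that the genome base at its position equals the
#' recorded reference allele.
#'
#' @param variants Variant tibble.
#' @param genome A `DNAStringSet` covering all referenced contigs.
#' @param strict Error on any mismatch.
#' @return A list of class `ref_validation` with `n`, `n_match`, `n_mismatch`
#'   and the mismatching records in `mismatches`.
#' @export
validate_against_reference <- function(variants, genome, strict = FALSE) {
  genome_base <- character(nrow(variants))
  for (ctg in unique(variants$contig)) {
    .check_contig(genome, ctg)
    i <- which(variants$contig == ctg)
    s <- as.character(genome[[ctg]])
    genome_base[i] <- stringr::str_sub(s, variants$pos[i] + 1, variants$pos[i] + 1)
  }
  ok <- genome_base == variants$ref
  res <- structure(list(
    n = nrow(variants),
    n_match = sum(ok),
    n_mismatch = sum(!ok),
    mismatches = mutate(variants[!ok, ], genome_base = genome_base[!ok])
  ), class = "ref_validation")
  if (strict && res$n_mismatch > 0) {
    abort(sprintf("%d variant(s) disagree with the reference genome", res$n_mismatch))
  }
  res
}

#' @export
print.ref_validation <- function(x, ...) {
  cat(sprintf("reference validation: %d variants, %d match, %d mismatch\n",
              x$n, x$n_match, x$n_mismatch))
  invisible(x)
}
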