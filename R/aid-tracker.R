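# Canonical-AID mutation tagging, the 768-channel tetranucleotide substitution
# matrix, and per-sample motif-enrichment statistics.
#
# A somatic SNV is tagged c-AID when it is a C>T or C>G change whose cytosine
# sits at the third base of a WRCY tetranucleotide, on either strand: on the
# plus strand the 4-mer [pos-2, pos+2) must be in the WRCY expansion; on the
# minus strand the mutated base is a G and the plus-strand 4-mer [pos-1, pos+3)
# must be in the RGYW expansion (the reverse complement of WRCY).

PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")
BASES <- c("A", "C", "G", "T")

#' Tag variants as canonical-AID mutations
#'
#' Flags each SNV as c-AID or not. A variant qualifies iff it is
#' (ref C, alt T/G) with the plus-strand 4-mer `[pos-2, pos+2)` in the WRCY
#' expansion, or its strand mirror (ref G, alt A/C) with `[pos-1, pos+3)` in
#' the RGYW expansion. The matched motif is reported in WRCY orientation.
#' Variants whose context runs off the contig are flagged `FALSE` with a
#' warning.
#'
#' @param variants Variant tibble (see [read_maf()]).
#' @param genome A `DNAStringSet`.
#' @param pattern Degenerate target motif (default `"WRCY"`).
#' @param target_offset 0-based offset of the deaminated base in `pattern`.
#' @return `variants` with logical `is_aid` and character `aid_motif` columns.
#' @export
classify_aid <- function(variants, genome, pattern = "WRCY", target_offset = 2L) {
  fwd <- expand_motif(pattern)
  rev <- revcomp(fwd)
  L <- nchar(pattern)
  off_fwd <- target_offset              # bases of motif 5' of the target, + strand
  off_rev <- L - 1L - target_offset     # 5' offset of target within the rc motif

  is_aid <- logical(nrow(variants))
  aid_motif <- rep(NA_character_, nrow(variants))
  n_oob <- 0L
  for (ctg in unique(variants$contig)) {
    .check_contig(genome, ctg)
    s <- as.character(genome[[ctg]])
    len <- nchar(s)
    i <- which(variants$contig == ctg)
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]

    fw <- ref == "C" & alt %in% c("T", "G")
    oob_f <- fw & (pos - off_fwd < 0 | pos - off_fwd + L > len)
    kmer_f <- rep(NA_character_, length(i))
    sel <- fw & !oob_f
    kmer_f[sel] <- stringr::str_sub(s, pos[sel] - off_fwd + 1, pos[sel] - off_fwd + L)
    hit_f <- sel & kmer_f %in% fwd

    rv <- ref == "G" & alt %in% c("A", "C")
    oob_r <- rv & (pos - off_rev < 0 | pos - off_rev + L > len)
    kmer_r <- rep(NA_character_, length(i))
    sel_r <- rv & !oob_r
    kmer_r[sel_r] <- stringr::str_sub(s, pos[sel_r] - off_rev + 1, pos[sel_r] - off_rev + L)
    hit_r <- sel_r & kmer_r %in% rev

    is_aid[i] <- hit_f | hit_r
    aid_motif[i[hit_f]] <- kmer_f[hit_f]
    aid_motif[i[hit_r]] <- revcomp(kmer_r[hit_r])
    n_oob <- n_oob + sum(oob_f | oob_r)
  }
  if (n_oob > 0) {
    warn(sprintf("%d variant(s) with out-of-bounds motif context flagged not-AID", n_oob))
  }
  variants$is_aid <- is_aid
  variants$aid_motif <- aid_motif
  variants
}

#' Subset a tagged cohort to its AID mutations
#'
#' @param variants Tibble with an `is_aid` column (see [classify_aid()]).
#' @return The AID-flagged rows, all columns preserved.
#' @export
extract_aid_maf <- function(variants) {
  stopifnot("is_aid" %in% names(variants))
  filter(variants, is_aid)
}

SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G",
                        "A>C", "A>G", "A>T", "G>A", "G>C", "G>T")

#' The 768 tetranucleotide substitution channel labels
#'
#' Twelve uncollapsed substitution types times 64 three-base flanking
#' contexts. Pyrimidine-reference channels use the frame (-2, -1, X, +1) and
#' purine-reference channels the mirrored frame (-1, X, +1, +2), so
#' reverse-complementing a catalogue maps purine channels onto pyrimidine
#' channels one-to-one. Labels look like `"AA[C>T]T"` or `"A[G>A]CT"`.
#'
#' @return Character vector of 768 channel labels.
#' @export
substitution_channels <- function() {
  ctx <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                     stringsAsFactors = FALSE)  # varies fastest on the right
  ctx <- ctx[order(ctx$b1, ctx$b2, ctx$b3), ]
  out <- character(0)
  for (st in SUBSTITUTION_TYPES) {
    ref <- substr(st, 1, 1)
    if (ref %in% PYRIMIDINES) {
      lab <- paste0(ctx$b1, ctx$b2, "[", st, "]", ctx$b3)
    } else {
      lab <- paste0(ctx$b1, "[", st, "]", ctx$b2, ctx$b3)
    }
    out <- c(out, lab)
  }
  out
}

# internal: channel label from ref, alt and the 5-mer context centred on the
# mutated base; NA when the context contains N
.channel_label <- function(ref, alt, context5) {
  ok <- !grepl("[^ACGT]", context5)
  lab <- rep(NA_character_, length(ref))
  pyr <- ref %in% PYRIMIDINES
  lab[ok & pyr] <- paste0(
    substr(context5[ok & pyr], 1, 2),
    "[", ref[ok & pyr], ">", alt[ok & pyr], "]",
    substr(context5[ok & pyr], 4, 4)
  )
  lab[ok & !pyr] <- paste0(
    substr(context5[ok & !pyr], 2, 2),
    "[", ref[ok & !pyr], ">", alt[ok & !pyr], "]",
    substr(context5[ok & !pyr], 4, 5)
  )
  lab
}

#' Per-sample 768-channel substitution matrix
#'
#' Counts every classifiable SNV of each sample into exactly one of the 768
#' tetranucleotide substitution channels (see [substitution_channels()]).
#' SNVs whose +/-2 bp context runs off the contig or contains N are excluded
#' and reported via the `"excluded"` attribute.
#'
#' @param variants Variant tibble.
#' @param genome A `DNAStringSet`.
#' @return Wide tibble: one row per sample, a `sample_id` column and one
#'   integer column per channel (768 columns, zero-filled).
#' @export
build_substitution_matrix <- function(variants, genome) {
  channels <- substitution_channels()
  ctx <- rep(NA_character_, nrow(variants))
  for (ctg in unique(variants$contig)) {
    .check_contig(genome, ctg)
    s <- as.character(genome[[ctg]])
    len <- nchar(s)
    i <- which(variants$contig == ctg)
    inb <- variants$pos[i] - 2 >= 0 & variants$pos[i] + 2 < len
    j <- i[inb]
    ctx[j] <- stringr::str_sub(s, variants$pos[j] - 1, variants$pos[j] + 3)
  }
  lab <- .channel_label(variants$ref, variants$alt, ctx)
  excluded <- variants[is.na(lab), ]
  if (nrow(excluded) > 0) {
    inform(sprintf("%d SNV(s) with unusable context excluded from the matrix",
                   nrow(excluded)))
  }
  keep <- !is.na(lab)
  samples <- sort(unique(variants$sample_id))
  m <- matrix(0L, nrow = length(samples), ncol = length(channels),
              dimnames = list(samples, channels))
  if (any(keep)) {
    tab <- table(factor(variants$sample_id[keep], levels = samples),
                 factor(lab[keep], levels = channels))
    m[] <- as.integer(tab)
  }
  out <- as_tibble(m)
  out <- bind_cols(tibble(sample_id = samples), out)
  attr(out, "excluded") <- excluded
  out
}

# internal: wide spectrum tibble -> numeric matrix (samples x channels)
.spectrum_matrix <- function(tbl) {
  m <- as.matrix(tbl[, setdiff(names(tbl), "sample_id")])
  rownames(m) <- tbl$sample_id
  m
}

#' Cosine similarity of two mutational profiles
#'
#' A value of one means identical profiles, zero completely different
#' (disjoint-support) ones.
#'
#' @param a,b Non-negative numeric vectors of equal length, each with at least
#'   one positive entry.
#' @return Similarity in `[0, 1]`.
#' @export
profile_cosine <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  if (sum(a) == 0 || sum(b) == 0) abort("zero profile vector")
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Per-sample AID motif enrichment
#'
#' Fold-enrichment of mutations at WRCY/RGYW motifs among all strand-symmetric
#' cytosine deamination candidates (C>T/G and G>A/C), normalised by the local
#' abundance of motif target sites versus cytosine/guanine bases counted in a
#' window of `flank` bp around each eligible mutation:
#' `E = (M_motif * C_ctx) / (M_C * Motif_ctx)`. A one-sided Fisher exact test
#' on `[[M_motif, M_C - M_motif], [Motif_ctx, C_ctx - Motif_ctx]]` gives the
#' per-sample p-value, Benjamini-Hochberg-adjusted across samples.
#'
#' @param variants Variant tibble; tagged with [classify_aid()] first if the
#'   `is_aid` column is absent.
#' @param genome A `DNAStringSet`.
#' @param flank Context window half-width in bp (default 20).
#' @param pattern Degenerate motif (default `"WRCY"`).
#' @param target_offset Offset of the deaminated base in `pattern`.
#' @return Tibble with one row per sample: counts (`n_snv`, `n_aid`,
#'   `m_motif`, `m_c`, `motif_ctx`, `c_ctx`), `enrichment`, `p_value`,
#'   `q_value` and `aid_fraction`.
#' @export
compute_enrichment <- function(variants, genome, flank = 20L,
                               pattern = "WRCY", target_offset = 2L) {
  if (!"is_aid" %in% names(variants)) {
    variants <- classify_aid(variants, genome, pattern, target_offset)
  }
  eligible <- (variants$ref == "C" & variants$alt %in% c("T", "G")) |
    (variants$ref == "G" & variants$alt %in% c("A", "C"))

  occ <- scan_motifs(genome, pattern, target_offset = target_offset)
  targets <- split(sort(occ$target_pos), occ$contig[order(occ$target_pos)])

  motif_ctx <- integer(nrow(variants))
  c_ctx <- integer(nrow(variants))
  for (ctg in unique(variants$contig)) {
    s <- as.character(genome[[ctg]])
    len <- nchar(s)
    i <- which(variants$contig == ctg & eligible)
    if (length(i) == 0) next
    lo <- pmax(variants$pos[i] - flank, 0L)
    hi <- pmin(variants$pos[i] + flank, len - 1L)
    tg <- targets[[ctg]] %||% integer(0)
    motif_ctx[i] <- findInterval(hi, tg) - findInterval(lo - 1L, tg)
    win <- stringr::str_sub(s, lo + 1, hi + 1)
    c_ctx[i] <- stringr::str_count(win, "[CG]")
  }

  per_sample <- variants %>%
    mutate(.eligible = eligible, .motif_ctx = motif_ctx, .c_ctx = c_ctx) %>%
    group_by(sample_id) %>%
    summarise(
      n_snv = n(),
      n_aid = sum(is_aid),
      m_motif = sum(is_aid & .data$.eligible),
      m_c = sum(.data$.eligible),
      motif_ctx = sum(.data$.motif_ctx[.data$.eligible]),
      c_ctx = sum(.data$.c_ctx[.data$.eligible]),
      .groups = "drop"
    )

  fisher_p <- function(a, b, c, d) {
    if (b < 0 || d < 0) return(NA_real_)
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                       alternative = "greater")$p.value
  }
  per_sample %>%
    mutate(
      enrichment = if_else(m_c > 0 & motif_ctx > 0 & c_ctx > 0,
                           (m_motif * c_ctx) / (m_c * motif_ctx),
                           if_else(m_motif == 0, 0, NA_real_)),
      p_value = purrr::pmap_dbl(
        list(m_motif, m_c - m_motif, motif_ctx, c_ctx - motif_ctx),
        function(a, b, c, d) if (a + b == 0 || c + d == 0) 1 else fisher_p(a, b, c, d)
      ),
      q_value = p.adjust(p_value, method = "BH"),
      aid_fraction = n_aid / n_snv
    )
}

#' Track AID mutations across a cohort
#'
#' One-call wrapper running [classify_aid()], [build_substitution_matrix()]
#' and [compute_enrichment()], mirroring the usual tag-and-summarise workflow:
#' the result carries the tagged variants, the 768-channel matrix, and the
#' per-sample enrichment table.
#'
#' @inheritParams compute_enrichment
#' @return An object of class `aid_tracking`: a list with `variants` (tagged),
#'   `matrix` (wide spectrum tibble) and `enrichment`. Use [extract_aid_maf()]
#'   on `$variants` for the AID-only MAF; `tidy()` returns the per-sample
#'   table and `glance()` a one-row cohort summary.
#' @export
track_aid <- function(variants, genome, flank = 20L, pattern = "WRCY",
                      target_offset = 2L) {
  tagged <- classify_aid(variants, genome, pattern, target_offset)
  structure(list(
    variants = tagged,
    matrix = build_substitution_matrix(tagged, genome),
    enrichment = compute_enrichment(tagged, genome, flank, pattern, target_offset)
  ), class = "aid_tracking")
}

#' @export
print.aid_tracking <- function(x, ...) {
  cat(sprintf("AID tracking: %d variants in %d samples; %d (%.1f%%) tagged c-AID\n",
              nrow(x$variants), nrow(x$enrichment), sum(x$variants$is_aid),
              100 * mean(x$variants$is_aid)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname track_aid
#' @param x An `aid_tracking` object.
#' @param ... Unused.
#' @export
tidy.aid_tracking <- function(x, ...) x$enrichment

#' @rdname track_aid
#' @export
glance.aid_tracking <- function(x, ...) {
  tibble(
    n_samples = nrow(x$enrichment),
    n_snvs = nrow(x$variants),
    n_aid = sum(x$variants$is_aid),
    aid_fraction = mean(x$variants$is_aid),
    median_enrichment = median(x$enrichment$enrichment, na.rm = TRUE),
    n_significant = sum(x$enrichment$q_value < 0.05, na.rm = TRUE)
  )
}
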