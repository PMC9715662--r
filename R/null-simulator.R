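# Context-preserving mutation shuffling: the null model for the c-AID excess
# test. Every observed mutation is re-placed, within its own chromosome, at a
# uniformly sampled position sharing its reference sequence context; the
# substituted base and the alternate allele are preserved, so per-chromosome
# burden and the context spectrum are identical to the observed data in every
# replicate.
#
# The context half-width is a parameter. The default is +/-1 bp
# (trinucleotide): the widest symmetric window strictly coarser than the WRCY
# 4-mer, so the null re-randomises exactly the W position of the motif. With
# flank = 2 (pentanucleotide) the full motif is contained in the preserved
# window and the shuffle provably preserves every c-AID flag - the simulated
# count then equals the observed count in every replicate. That degeneracy is
# asserted in the test suite; see the methods vignette for the reasoning.

.BASE_LUT <- {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut
}

.decode_kmer <- function(code, k) {
  out <- character(length(code))
  for (j in seq_len(k)) {
    d <- (code %/% 4L^(k - j)) %% 4L
    out <- paste0(out, BASES[d + 1L])
  }
  out
}

#' Build a sequence-context index of a genome
#'
#' For every genomic position with a full non-N `(2 * flank + 1)`-mer context,
#' records the position under its context key, per contig. The index is the
#' sampling frame for [simulate_sample()].
#'
#' @param genome A `DNAStringSet`.
#' @param flank Context half-width in bp. `1` (trinucleotide, default) keeps
#'   the null strictly coarser than the WRCY/RGYW 4-mer; `2` gives the
#'   pentanucleotide (SBS-1536) window.
#' @return Object of class `context_index`: per contig, a named list mapping
#'   each k-mer to the sorted 0-based positions whose centred context equals
#'   that k-mer.
#' @export
build_context_index <- function(genome, flank = 1L) {
  stopifnot(flank >= 1)
  k <- 2L * flank + 1L
  contigs <- lapply(seq_along(genome), function(ci) {
    x <- .BASE_LUT[utf8ToInt(as.character(genome[[ci]]))]
    n <- length(x)
    if (n < k) return(list())
    code <- integer(n - k + 1L)
    for (j in 0:(k - 1L)) code <- code * 4L + x[(1L + j):(n - k + 1L + j)]
    centers <- seq.int(flank, n - flank - 1L)  # 0-based
    valid <- !is.na(code)
    idx <- split(centers[valid], code[valid])
    names(idx) <- .decode_kmer(as.integer(names(idx)), k)
    idx
  })
  names(contigs) <- names(genome)
  structure(list(flank = flank, contigs = contigs), class = "context_index")
}

#' Look up the positions of a context k-mer
#'
#' @param index A `context_index`.
#' @param contig Contig name.
#' @param kmer Context string of width `2 * flank + 1`.
#' @return Sorted integer vector of 0-based positions (empty when absent).
#' @export
context_positions <- function(index, contig, kmer) {
  index$contigs[[contig]][[kmer]] %||% integer(0)
}

#' @export
print.context_index <- function(x, ...) {
  cat(sprintf("context index: flank %d (%d-mers), %d contig(s), %s positions\n",
              x$flank, 2 * x$flank + 1, length(x$contigs),
              format(sum(vapply(x$contigs, function(ct) sum(lengths(ct)), 0)),
                     big.mark = ",")))
  invisible(x)
}

# internal: per-contig logical vectors marking mutable motif target sites
# (C on the plus strand, G on the minus strand)
.aid_target_sites <- function(genome, pattern = "WRCY", target_offset = 2L) {
  occ <- scan_motifs(genome, pattern, target_offset = target_offset)
  lens <- contig_lengths(genome)
  out <- lapply(names(lens), function(ctg) {
    c_site <- logical(lens[[ctg]])
    g_site <- logical(lens[[ctg]])
    oc <- occ[occ$contig == ctg, ]
    c_site[oc$target_pos[oc$strand == "+"] + 1L] <- TRUE
    g_site[oc$target_pos[oc$strand == "-"] + 1L] <- TRUE
    list(c_site = c_site, g_site = g_site)
  })
  names(out) <- names(lens)
  out
}

#' Simulate a sample's mutations under the context-preserving null
#'
#' Each replicate reassigns every mutation of the sample, within its own
#' chromosome, to a uniformly sampled position sharing its reference context
#' (the substituted base and alternate allele are preserved), then counts the
#' c-AID mutations of the replicate. Mutations whose context class offers no
#' alternative position (or whose context is unusable) are kept in place and
#' counted in the report. Deterministic given `seed`.
#'
#' @param variants Variants of one sample (tagged with [classify_aid()] first
#'   if `is_aid` is absent).
#' @param index A [build_context_index()] object for the same genome.
#' @param genome A `DNAStringSet`.
#' @param n_rep Number of replicates (the cohort-scale default is 1000).
#' @param seed Optional integer seed.
#' @param collision_free Sample destination positions without replacement
#'   within each replicate and context class (default `FALSE`:
#'   with-replacement placement, bias-free at genome scale).
#' @param keep_positions Also return the `n_mutations x n_rep` matrix of
#'   simulated positions (for invariant checks; memory-heavy at scale).
#' @param sites Internal cache from repeated cohort calls; leave `NULL`.
#' @param pattern,target_offset Motif definition, as in [classify_aid()].
#' @return Object of class `aid_null` with the observed and per-replicate
#'   simulated c-AID counts.
#' @export
simulate_sample <- function(variants, index, genome, n_rep = 1000L,
                            seed = NULL, collision_free = FALSE,
                            keep_positions = FALSE, sites = NULL,
                            pattern = "WRCY", target_offset = 2L) {
  stopifnot(n_rep >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  if (!"is_aid" %in% names(variants)) {
    variants <- classify_aid(variants, genome, pattern, target_offset)
  }
  sites <- sites %||% .aid_target_sites(genome, pattern, target_offset)
  flank <- index$flank
  n_mut <- nrow(variants)

  # context key and eligibility type of every mutation
  keys <- rep(NA_character_, n_mut)
  for (ctg in unique(variants$contig)) {
    s <- as.character(genome[[ctg]])
    len <- nchar(s)
    i <- which(variants$contig == ctg)
    inb <- variants$pos[i] - flank >= 0 & variants$pos[i] + flank < len
    j <- i[inb]
    km <- stringr::str_sub(s, variants$pos[j] - flank + 1, variants$pos[j] + flank + 1)
    km[grepl("[^ACGT]", km)] <- NA_character_
    keys[j] <- km
  }
  type <- integer(n_mut)
  type[variants$ref == "C" & variants$alt %in% c("T", "G")] <- 1L
  type[variants$ref == "G" & variants$alt %in% c("A", "C")] <- 2L

  sim_aid <- numeric(n_rep)
  pos_mat <- if (keep_positions) {
    matrix(rep(variants$pos, n_rep), nrow = n_mut)
  } else NULL

  n_invalid <- sum(is.na(keys))
  n_single <- 0L
  fixed_aid <- 0L  # AID contribution of kept-in-place mutations

  grp <- paste(variants$contig, keys, type, sep = "\r")
  for (g in unique(grp[!is.na(keys)])) {
    rows <- which(grp == g & !is.na(keys))
    ctg <- variants$contig[rows[1]]
    cand <- context_positions(index, ctg, keys[rows[1]])
    if (length(cand) <= 1) {
      n_single <- n_single + length(rows)
      fixed_aid <- fixed_aid + sum(variants$is_aid[rows])
      next
    }
    ty <- type[rows[1]]
    elig <- if (ty == 1L) sites[[ctg]]$c_site else if (ty == 2L) sites[[ctg]]$g_site else NULL
    n_g <- length(rows)
    if (!collision_free) {
      draws <- cand[sample.int(length(cand), n_g * n_rep, replace = TRUE)]
      if (!is.null(elig)) {
        hits <- elig[draws + 1L]
        dim(hits) <- c(n_g, n_rep)
        sim_aid <- sim_aid + colSums(hits)
      }
      if (keep_positions) pos_mat[rows, ] <- matrix(draws, nrow = n_g)
    } else {
      for (r in seq_len(n_rep)) {
        draws <- if (length(cand) >= n_g) sample(cand, n_g)
                 else cand[sample.int(length(cand), n_g, replace = TRUE)]
        if (!is.null(elig)) sim_aid[r] <- sim_aid[r] + sum(elig[draws + 1L])
        if (keep_positions) pos_mat[rows, r] <- draws
      }
    }
  }
  # invalid-context mutations stay in place: their AID status is fixed
  fixed_aid <- fixed_aid + sum(variants$is_aid[is.na(keys)])
  sim_aid <- sim_aid + fixed_aid

  observed_aid <- sum(variants$is_aid)
  structure(list(
    sample_id = variants$sample_id[1] %||% NA_character_,
    n_rep = n_rep,
    n_mutations = n_mut,
    observed_aid = observed_aid,
    observed_non_aid = n_mut - observed_aid,
    sim_aid = as.integer(sim_aid),
    expected_aid = mean(sim_aid),
    n_kept_in_place = n_single,
    n_invalid_context = n_invalid,
    flank = flank,
    positions = pos_mat,
    variant_order = if (keep_positions) variants else NULL
  ), class = "aid_null")
}

#' @export
print.aid_null <- function(x, ...) {
  cat(sprintf(
    "null simulation for %s: %d mutations, %d replicates; observed c-AID %d, expected %.2f (ratio %.2f)\n",
    x$sample_id, x$n_mutations, x$n_rep, x$observed_aid, x$expected_aid,
    x$observed_aid / max(x$expected_aid, .Machine$double.eps)))
  invisible(x)
}

#' @rdname simulate_sample
#' @param x An `aid_null` object.
#' @param ... Unused.
#' @export
tidy.aid_null <- function(x, ...) {
  tibble(sample_id = x$sample_id, replicate = seq_len(x$n_rep),
         sim_aid = x$sim_aid)
}

#' Simulate every sample of a cohort under the null
#'
#' @inheritParams simulate_sample
#' @param variants Cohort variant tibble with a `sample_id` column.
#' @return Named list of `aid_null` objects, one per sample.
#' @export
simulate_cohort <- function(variants, index, genome, n_rep = 1000L,
                            seed = NULL, pattern = "WRCY", target_offset = 2L) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (!"is_aid" %in% names(variants)) {
    variants <- classify_aid(variants, genome, pattern, target_offset)
  }
  sites <- .aid_target_sites(genome, pattern, target_offset)
  split(variants, variants$sample_id) %>%
    purrr::map(simulate_sample, index = index, genome = genome, n_rep = n_rep,
               sites = sites, pattern = pattern, target_offset = target_offset)
}

#' Per-sample significance of the observed c-AID excess
#'
#' For each replicate, a two-sided Fisher exact test on
#' `[[observed AID, observed non-AID], [simulated AID, simulated non-AID]]`
#' yields a conditional-maximum-likelihood 95% odds-ratio interval. The sample
#' is called significant when the fraction of replicates whose interval
#' contains 1 is below `alpha`; the direction is enrichment when the median
#' odds ratio exceeds 1.
#'
#' @param null An `aid_null` object with at least 20 replicates (fewer:
#'   the call is returned as `NA`).
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble with the overlap fraction, call, direction and the
#'   observed/expected enrichment ratio.
#' @export
test_sample_significance <- function(null, alpha = 0.05) {
  n <- null$n_mutations
  degenerate <- (null$observed_aid + null$sim_aid) == 0 |
    (null$observed_non_aid + (n - null$sim_aid)) == 0
  usable <- which(!degenerate)
  res <- vapply(usable, function(r) {
    ft <- stats::fisher.test(matrix(c(null$observed_aid, null$observed_non_aid,
                                      null$sim_aid[r], n - null$sim_aid[r]),
                                    2, byrow = TRUE))
    c(or = unname(ft$estimate),
      overlap = as.numeric(ft$conf.int[1] <= 1 && ft$conf.int[2] >= 1))
  }, numeric(2))
  prop_overlap <- if (length(usable) > 0) mean(res["overlap", ]) else NA_real_
  med_or <- if (length(usable) > 0) median(res["or", ]) else NA_real_
  tibble(
    sample_id = null$sample_id,
    n_rep_used = length(usable),
    n_degenerate = sum(degenerate),
    prop_or_overlap = prop_overlap,
    significant = if (null$n_rep < 20) NA else prop_overlap < alpha,
    direction = dplyr::case_when(
      is.na(med_or) ~ NA_character_,
      med_or > 1 ~ "enrichment",
      TRUE ~ "depletion"
    ),
    median_or = med_or,
    observed_aid = null$observed_aid,
    expected_aid = null$expected_aid,
    enrichment_ratio = null$observed_aid / max(null$expected_aid, .Machine$double.eps)
  )
}

#' Cohort-level observed/expected c-AID enrichment ratio
#'
#' Ratio of the summed observed c-AID counts to the summed per-sample null
#' expectations, with a seeded bootstrap-over-samples percentile interval.
#'
#' @param nulls List of `aid_null` objects (see [simulate_cohort()]).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return One-row tibble: `ratio`, `ci_low`, `ci_high`, `n_samples`.
#' @export
cohort_enrichment_ratio <- function(nulls, n_boot = 1000L, conf = 0.95,
                                    seed = NULL) {
  stopifnot(length(nulls) >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  obs <- vapply(nulls, function(x) x$observed_aid, numeric(1))
  expd <- vapply(nulls, function(x) x$expected_aid, numeric(1))
  if (sum(expd) == 0) abort("zero expected c-AID count across the cohort")
  ratio <- sum(obs) / sum(expd)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(obs), replace = TRUE)
    sum(obs[i]) / max(sum(expd[i]), .Machine$double.eps)
  }, numeric(1))
  a <- (1 - conf) / 2
  tibble(ratio = ratio,
         ci_low = unname(quantile(boots, a)),
         ci_high = unname(quantile(boots, 1 - a)),
         n_samples = length(obs), n_boot = n_boot)
}
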