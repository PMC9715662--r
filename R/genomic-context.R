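# Genomic-distribution analyses of tagged mutations: chromatin-domain loads,
# TSS-oriented profiles, R-loop overlap tests, inter-mutation distances, and
# expression-mutation correlation.

DOMAIN_CLASSES <- c("heterochromatin", "inactive", "repressed", "low-active",
                    "active")

#' Mutation load across chromatin domain classes
#'
#' Bins mutations into non-overlapping windows, assigns each window to the
#' domain covering the majority of it (ties to the leftward domain), and
#' reports per-class mutation loads normalised by total class length, plus the
#' active/inactive load ratio.
#'
#' @param mutations Variant tibble (`contig`, `pos`).
#' @param domains Tibble `contig`, `start`, `end`, `class` with classes from
#'   `r toString(DOMAIN_CLASSES)`; intervals must not overlap within a contig.
#' @param bin Window width in bp (default 25 kb).
#' @return Object of class `domain_load`: list with `class_loads` (per-class
#'   counts, lengths, load), `bins` (per-window counts and class, for rank
#'   tests), `active_inactive_ratio` and `n_unassigned`. `tidy()` returns
#'   `class_loads`.
#' @export
domain_load <- function(mutations, domains, bin = 25000L) {
  bad <- setdiff(unique(domains$class), DOMAIN_CLASSES)
  if (length(bad) > 0) abort(sprintf("unknown domain class '%s'", bad[1]))
  dom_gr <- .as_granges(domains)
  if (any(GenomicRanges::countOverlaps(dom_gr, dom_gr) > 1)) {
    abort("domain intervals overlap within a contig")
  }

  lens <- domains %>% group_by(contig) %>% summarise(len = max(end))
  bins <- bind_rows(lapply(seq_len(nrow(lens)), function(i) {
    starts <- seq(0L, lens$len[i] - 1L, by = bin)
    tibble(contig = lens$contig[i], start = starts,
           end = pmin(starts + bin, lens$len[i]))
  }))

  # majority-overlap assignment of bins to domains, ties to the leftward one
  bin_gr <- .as_granges(bins)
  ov <- GenomicRanges::findOverlaps(bin_gr, dom_gr)
  ow <- GenomicRanges::width(IRanges::pintersect(
    bin_gr[S4Vectors::queryHits(ov)], dom_gr[S4Vectors::subjectHits(ov)]))
  asg <- tibble(bin = S4Vectors::queryHits(ov),
                dom = S4Vectors::subjectHits(ov),
                w = ow,
                dom_start = domains$start[S4Vectors::subjectHits(ov)]) %>%
    group_by(.data$bin) %>%
    arrange(desc(.data$w), .data$dom_start, .by_group = TRUE) %>%
    slice(1) %>% ungroup()
  bins$class <- NA_character_
  bins$class[asg$bin] <- domains$class[asg$dom]

  # mutation counts per bin
  bins$count <- 0L
  for (ctg in unique(mutations$contig)) {
    bi <- which(bins$contig == ctg)
    if (length(bi) == 0) next
    hits <- mutations$pos[mutations$contig == ctg]
    hits <- hits[hits >= 0 & hits < max(bins$end[bi])]
    bins$count[bi] <- tabulate(findInterval(hits, bins$start[bi]),
                               nbins = length(bi))
  }
  n_unassigned <- sum(bins$count[is.na(bins$class)]) +
    sum(!mutations$contig %in% lens$contig) +
    {  # mutations beyond the last bin of their contig
      m2 <- mutations %>% inner_join(lens, by = "contig")
      sum(m2$pos >= m2$len)
    }

  class_len <- domains %>% group_by(class) %>%
    summarise(class_length = sum(end - start), .groups = "drop")
  class_loads <- bins %>%
    filter(!is.na(class)) %>%
    group_by(class) %>%
    summarise(n_mutations = sum(count), .groups = "drop") %>%
    left_join(class_len, by = "class") %>%
    mutate(load = n_mutations / class_length) %>%
    tidyr::complete(class = DOMAIN_CLASSES,
                    fill = list(n_mutations = 0L)) %>%
    left_join(select(class_len, class, len2 = class_length), by = "class") %>%
    mutate(class_length = dplyr::coalesce(class_length, .data$len2, 0L),
           load = if_else(class_length > 0, n_mutations / class_length, NA_real_)) %>%
    select(class, n_mutations, class_length, load) %>%
    mutate(class = factor(class, levels = DOMAIN_CLASSES)) %>%
    arrange(class)

  active <- class_loads$load[class_loads$class == "active"]
  inactive <- class_loads$load[class_loads$class == "inactive"]
  ratio <- if (isTRUE(inactive == 0)) Inf else active / inactive

  structure(list(class_loads = class_loads, bins = bins,
                 active_inactive_ratio = ratio,
                 n_unassigned = n_unassigned),
            class = "domain_load")
}

#' @rdname domain_load
#' @param x A `domain_load` object.
#' @param ... Unused.
#' @export
tidy.domain_load <- function(x, ...) x$class_loads

#' @export
print.domain_load <- function(x, ...) {
  print(x$class_loads)
  cat(sprintf("active/inactive load ratio: %.3g (%d unassigned mutations)\n",
              x$active_inactive_ratio, x$n_unassigned))
  invisible(x)
}

#' Mutation profile around transcription start sites
#'
#' Places mutations within `span` of each gene's TSS into bins indexed along
#' the transcription direction (negative indices upstream), aggregated
#' separately for plus- and minus-strand genes. The per-bin load is the
#' mutation count normalised by the number of genes in the strand class
#' (`weighting = "gene"`) or the raw pooled count.
#'
#' @param mutations Variant tibble.
#' @param genes Tibble `contig`, `start`, `end`, `strand`, `name`; the TSS is
#'   `start` for plus-strand genes and `end - 1` for minus-strand genes.
#' @param span Half-window around the TSS (default 500 kb).
#' @param bin Bin width (default 10 kb, i.e. 50 bins per side).
#' @param weighting `"gene"` (default) or `"pooled"`.
#' @return Object of class `tss_profile` with `profile` (strand_class,
#'   bin_index, n_mutations, load) and `gene_bins` (per-gene bin counts).
#' @export
tss_profile <- function(mutations, genes, span = 5e5, bin = 1e4,
                        weighting = c("gene", "pooled")) {
  weighting <- match.arg(weighting)
  K <- as.integer(span / bin)
  genes <- mutate(genes, tss = if_else(strand == "+", start, end - 1L))

  per_gene <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    m <- mutations[mutations$contig == g$contig &
                     abs(mutations$pos - g$tss) <= span, ]
    if (nrow(m) == 0) return(NULL)
    rel <- m$pos - g$tss
    if (g$strand == "-") rel <- -rel
    idx <- pmax(pmin(floor((rel + bin / 2) / bin), K), -K)
    tibble(gene = g$name, strand_class = g$strand, bin_index = as.integer(idx)) %>%
      count(gene, strand_class, bin_index, name = "count")
  })
  if (nrow(per_gene) == 0) {
    per_gene <- tibble(gene = character(), strand_class = character(),
                       bin_index = integer(), count = integer())
  }

  n_genes <- genes %>% count(strand, name = "n_genes") %>%
    rename(strand_class = strand)
  grid <- tidyr::expand_grid(strand_class = c("+", "-"),
                             bin_index = seq.int(-K, K))
  profile <- grid %>%
    left_join(
      per_gene %>% group_by(strand_class, bin_index) %>%
        summarise(n_mutations = sum(count), .groups = "drop"),
      by = c("strand_class", "bin_index")) %>%
    mutate(n_mutations = dplyr::coalesce(n_mutations, 0L)) %>%
    left_join(n_genes, by = "strand_class") %>%
    mutate(load = if (weighting == "gene") n_mutations / pmax(n_genes, 1L)
           else as.numeric(n_mutations)) %>%
    select(strand_class, bin_index, n_mutations, load)

  structure(list(profile = profile, gene_bins = per_gene, span = span,
                 bin = bin, K = K, genes = genes),
            class = "tss_profile")
}

#' @rdname tss_profile
#' @param x A `tss_profile` object.
#' @param ... Unused.
#' @export
tidy.tss_profile <- function(x, ...) x$profile

#' Rank-sum contrasts between the TSS bin and the flanking bins
#'
#' Two-sided Wilcoxon rank-sum tests of per-gene mutation counts in the TSS
#' bin against the bins `K` bins up- and downstream (at the profile edges),
#' per strand class.
#'
#' @param x A [tss_profile()] object.
#' @return Tibble `strand_class`, `contrast`, `p_value`.
#' @export
tss_contrasts <- function(x) {
  counts_at <- function(sc, idx) {
    gn <- x$genes$name[x$genes$strand == sc]
    got <- x$gene_bins %>% filter(strand_class == sc, bin_index == idx)
    out <- setNames(rep(0L, length(gn)), gn)
    out[got$gene] <- got$count
    out
  }
  purrr::map_dfr(c("+", "-"), function(sc) {
    tssb <- counts_at(sc, 0L)
    purrr::map_dfr(c(-x$K, x$K), function(edge) {
      p <- tryCatch(
        suppressWarnings(wilcox.test(tssb, counts_at(sc, edge))$p.value),
        error = function(e) NA_real_)
      tibble(strand_class = sc,
             contrast = sprintf("TSS vs %+d kb", as.integer(edge * x$bin / 1000)),
             p_value = p)
    })
  })
}

#' Region overlap labelling and pairwise process contrasts
#'
#' Labels each mutation as inside or outside a region set (half-open interval
#' containment) and runs pairwise two-sided Fisher exact tests between
#' mutational processes on their in/out counts — the construction used to ask
#' whether c-AID mutations localise to R-loop (G-skew) regions differently
#' from APOBEC mutations.
#'
#' @param mutations Variant tibble with a process label column.
#' @param regions Tibble `contig`, `start`, `end` (0-based half-open).
#' @param process_col Name of the label column (default `"process"`).
#' @return Object of class `region_overlap`: `mutations` (with `in_region`),
#'   `counts` (per-process in/out), `tests` (pairwise Fisher p-values).
#' @export
region_overlap_test <- function(mutations, regions, process_col = "process") {
  stopifnot(process_col %in% names(mutations))
  labels <- mutations[[process_col]]
  if (length(unique(labels[!is.na(labels)])) < 2) {
    abort("need at least two process labels")
  }
  reg_gr <- .as_granges(regions)
  mut_gr <- GenomicRanges::GRanges(mutations$contig,
                                   IRanges::IRanges(mutations$pos + 1L, width = 1L))
  mutations$in_region <- GenomicRanges::countOverlaps(mut_gr, reg_gr) > 0

  counts <- mutations %>%
    filter(!is.na(.data[[process_col]])) %>%
    group_by(process = .data[[process_col]]) %>%
    summarise(n_in = sum(in_region), n_out = sum(!in_region), .groups = "drop")

  procs <- counts$process[counts$n_in + counts$n_out > 0]
  pairs <- utils::combn(procs, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- counts[counts$process == pr[1], ]
    b <- counts[counts$process == pr[2], ]
    p <- stats::fisher.test(matrix(c(a$n_in, a$n_out, b$n_in, b$n_out),
                                   2, byrow = TRUE))$p.value
    tibble(process_a = pr[1], process_b = pr[2],
           in_a = a$n_in, out_a = a$n_out, in_b = b$n_in, out_b = b$n_out,
           p_value = p)
  })
  structure(list(mutations = mutations, counts = counts, tests = tests),
            class = "region_overlap")
}

#' @rdname region_overlap_test
#' @param x A `region_overlap` object.
#' @param ... Unused.
#' @export
tidy.region_overlap <- function(x, ...) x$tests

#' Inter-mutation distances
#'
#' Distance between each substitution and the one immediately prior on the
#' same contig (the first mutation of each contig has none), within the given
#' grouping.
#'
#' @param mutations Variant tibble.
#' @param group_col Optional grouping column (e.g. `"sample_id"` or a tumour
#'   type); `NULL` pools all mutations.
#' @return `mutations` sorted by (group, contig, pos) with a `distance`
#'   column.
#' @export
intermutation_distance <- function(mutations, group_col = NULL) {
  grouping <- c(group_col, "contig")
  mutations %>%
    arrange(across(all_of(c(grouping, "pos")))) %>%
    group_by(across(all_of(grouping))) %>%
    mutate(distance = pos - lag(pos)) %>%
    ungroup()
}

#' Mutation counts in megabase windows
#'
#' @param mutations Variant tibble.
#' @param lengths Named contig lengths.
#' @param window Window width (default 1 Mb).
#' @return Tibble `contig`, `start`, `end`, `count`, `density` (per bp).
#' @export
mutation_density <- function(mutations, lengths, window = 1e6) {
  occ <- tibble(contig = mutations$contig, target_pos = mutations$pos)
  motif_density(occ, lengths, window = as.integer(window)) %>%
    select(contig, start, end, count, density)
}

#' Correlate per-gene AID mutation counts with same-gene expression
#'
#' Within each tumour type, Spearman correlation of the number of c-AID
#' mutations in gene i across samples with the expression of the same gene;
#' Benjamini-Hochberg adjustment within tumour type. A gene is called
#' associated when the adjusted p-value is below 0.05 and rho is positive.
#'
#' @param mut_counts Tibble `tumor_type`, `gene`, `sample_id`,
#'   `n_mutations` (samples absent for a gene count as zero).
#' @param expression Long tibble `sample_id`, `gene`, `expression`.
#' @param samples Tibble `sample_id`, `tumor_type` mapping expression samples
#'   to tumour types.
#' @param min_samples Minimum samples with both values per gene (default 3).
#' @return Tibble `tumor_type`, `gene`, `n`, `rho`, `p_value`, `q_value`,
#'   `associated`. Genes with constant counts or expression are skipped.
#' @export
expression_association <- function(mut_counts, expression, samples,
                                   min_samples = 3L) {
  joined <- expression %>%
    inner_join(samples, by = "sample_id") %>%
    left_join(mut_counts, by = c("tumor_type", "gene", "sample_id")) %>%
    mutate(n_mutations = dplyr::coalesce(n_mutations, 0L)) %>%
    semi_join(distinct(mut_counts, tumor_type, gene),
              by = c("tumor_type", "gene"))

  res <- joined %>%
    group_by(tumor_type, gene) %>%
    summarise(
      n = n(),
      constant = sd(n_mutations) == 0 || sd(expression) == 0,
      rho = if (n[1] >= min_samples && !constant[1]) {
        unname(suppressWarnings(cor.test(n_mutations, expression,
                                         method = "spearman",
                                         exact = FALSE)$estimate))
      } else NA_real_,
      p_value = if (n[1] >= min_samples && !constant[1]) {
        suppressWarnings(cor.test(n_mutations, expression,
                                  method = "spearman", exact = FALSE)$p.value)
      } else NA_real_,
      .groups = "drop"
    )
  n_skipped <- sum(is.na(res$p_value))
  if (n_skipped > 0) {
    inform(sprintf("%d gene/tumour-type pair(s) skipped (constant or too few samples)",
                   n_skipped))
  }
  res %>%
    filter(!is.na(p_value)) %>%
    group_by(tumor_type) %>%
    mutate(q_value = p.adjust(p_value, method = "BH")) %>%
    ungroup() %>%
    mutate(associated = q_value < 0.05 & rho > 0) %>%
    select(tumor_type, gene, n, rho, p_value, q_value, associated)
}
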