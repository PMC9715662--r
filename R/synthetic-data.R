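# Synthetic genomes, annotations and cohorts with planted mutational
# processes and full ground truth, so that every pipeline stage is testable
# without external downloads. All generators are deterministic given `seed`.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a random genome
#'
#' I.i.d. bases at a target GC fraction (human-like 0.41 by default).
#'
#' @param lengths Named integer vector of contig lengths (> 10 kb each).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Optional integer seed.
#' @return A `DNAStringSet`; the attribute `"n_wrcy"` reports the realised
#'   WRCY/RGYW target-site count.
#' @export
generate_genome <- function(lengths = c(chr1 = 5e5, chr2 = 5e5), gc = 0.41,
                            seed = NULL) {
  stopifnot(all(lengths > 10000), gc > 0, gc < 1)
  if (!is.null(seed)) withr::local_seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(n) {
    paste(sample(BASES, n, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(lengths)
  attr(g, "n_wrcy") <- nrow(scan_motifs(g, "WRCY"))
  g
}

#' Generate annotations for a synthetic genome
#'
#' Domains tile each contig without gaps or overlaps over the five chromatin
#' classes; genes are placed uniformly with random strand; R-loop (G-skew)
#' regions are short uniform intervals; the gene panel carries composite-test
#' covariates drawn from simple parametric distributions.
#'
#' @param genome A `DNAStringSet`.
#' @param n_genes Number of genes (default 200).
#' @param gene_length Gene body length in bp (default 10 kb).
#' @param mean_domain_length Mean chromatin-domain length (default 100 kb).
#' @param n_rloops Number of R-loop regions (default 200).
#' @param rloop_length R-loop region length (default 600 bp, the scale of
#'   G-skew regions).
#' @param seed Optional integer seed.
#' @return List with `genes`, `domains`, `rloops` and `panel` tibbles.
#' @export
generate_annotations <- function(genome, n_genes = 200L, gene_length = 10000L,
                                 mean_domain_length = 1e5, n_rloops = 200L,
                                 rloop_length = 600L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  lens <- contig_lengths(genome)
  class_probs <- c(heterochromatin = 0.1, inactive = 0.3, repressed = 0.2,
                   `low-active` = 0.2, active = 0.2)

  domains <- bind_rows(lapply(names(lens), function(ctg) {
    len <- lens[[ctg]]
    starts <- 0L
    while (sum(tail(starts, 1)) < len) {
      w <- max(25000L, round(stats::rexp(1, 1 / mean_domain_length)))
      starts <- c(starts, min(tail(starts, 1) + w, len))
    }
    starts <- as.integer(starts)
    tibble(contig = ctg, start = head(starts, -1), end = starts[-1],
           class = sample(names(class_probs), length(starts) - 1,
                          replace = TRUE, prob = class_probs))
  }))

  pick_interval <- function(n, width) {
    ctg <- sample(names(lens), n, replace = TRUE, prob = lens)
    start <- vapply(ctg, function(cc) {
      as.integer(sample.int(lens[[cc]] - width, 1))
    }, integer(1))
    tibble(contig = ctg, start = start, end = start + as.integer(width))
  }
  genes <- pick_interval(n_genes, gene_length) %>%
    mutate(strand = sample(c("+", "-"), n_genes, replace = TRUE),
           name = sprintf("g%04d", seq_len(n_genes)))
  rloops <- pick_interval(n_rloops, rloop_length)

  panel <- tibble(
    gene = genes$name,
    gene_class = sample(c("oncogene", "tsg"), n_genes, replace = TRUE),
    cds_length = pmax(150, round(exp(rnorm(n_genes, log(1500), 0.5)))),
    gc_percent = runif(n_genes, 35, 65),
    replication_time = runif(n_genes, 0, 100),
    chromatin_state = sample(c("active", "repressed", "heterochromatin"),
                             n_genes, replace = TRUE),
    assay_version = sample(c("v1", "v2", "v3"), n_genes, replace = TRUE),
    mean_copy_number = pmax(1, rnorm(n_genes, 2, 0.3))
  )
  list(genes = genes, domains = domains, rloops = rloops, panel = panel)
}

# internal: uniform draws from a motif target-site pool
.draw_sites <- function(pool, n) {
  pool[sample.int(nrow(pool), n, replace = TRUE), c("contig", "target_pos", "strand")]
}

#' Generate a synthetic tumour cohort with planted mutational processes
#'
#' Per sample, a negative-binomial mutation burden is split between planted
#' processes: c-AID mutations (C>T/G, and G>A/C on the minus strand, placed
#' uniformly over WRCY/RGYW target sites), APOBEC-like mutations (TCW
#' targets), and uniform background. Clonality is planted (clonal CCF 1,
#' subclonal CCF uniform on `subclonal_ccf`), read counts are binomial at the
#' expected VAF given purity and diploid copy number, expression is coupled
#' to per-gene AID counts for `coupled_genes` genes by a Gaussian copula at
#' the target Spearman correlation, and neoepitope %rank scores are drawn so
#' that a configured fraction of samples carries at least one immunogenic
#' clonal neoepitope per process.
#'
#' @param genome A `DNAStringSet`.
#' @param annotations Output of [generate_annotations()].
#' @param n_samples Samples in the cohort (default 50).
#' @param mut_mean,mut_dispersion Negative-binomial burden per sample
#'   (default mean 2000, size 10).
#' @param mix Named process fractions (`aid`, `apobec`, `background`),
#'   summing to 1. Default 0.10 / 0.05 / 0.85.
#' @param clonal_fraction Fraction of clonal mutations (default 0.7).
#' @param subclonal_ccf CCF range of subclonal mutations (default 0.2-0.7).
#' @param purity Sample purity range (default 0.5-0.95).
#' @param depth Sequencing depth (default 80; must be >= 20).
#' @param coupled_genes Number of genes whose expression tracks their AID
#'   mutation count (default 10).
#' @param coupled_rho Target Spearman correlation for coupled genes
#'   (default 0.8).
#' @param icn_presence Named per-process probabilities that a sample carries
#'   at least one ICN of that process (default aid 0.30, apobec 0.10,
#'   background 0.05).
#' @param neo_rate Probability that a nonsynonymous gene mutation yields a
#'   neoepitope record (default 0.5).
#' @param tumor_type Tumour-type label for all samples.
#' @param seed Optional integer seed.
#' @return List of class `synthetic_cohort`: `variants` (MAF-style tibble
#'   with read counts, purity, copy number), `samples`, `expression` (long),
#'   `neoepitopes`, `ground_truth` (per-mutation planted labels) and
#'   `truth_samples` (per-sample planted ICN presence).
#' @export
generate_cohort <- function(genome, annotations, n_samples = 50L,
                            mut_mean = 2000, mut_dispersion = 10,
                            mix = c(aid = 0.10, apobec = 0.05, background = 0.85),
                            clonal_fraction = 0.7,
                            subclonal_ccf = c(0.2, 0.7),
                            purity = c(0.5, 0.95), depth = 80L,
                            coupled_genes = 10L, coupled_rho = 0.8,
                            icn_presence = c(aid = 0.30, apobec = 0.10,
                                             background = 0.05),
                            neo_rate = 0.5, tumor_type = "SYN",
                            seed = NULL) {
  stopifnot(abs(sum(mix) - 1) < 1e-8, depth >= 20)
  if (!is.null(seed)) withr::local_seed(seed)
  lens <- contig_lengths(genome)
  strings <- lapply(names(lens), function(ctg) as.character(genome[[ctg]]))
  names(strings) <- names(lens)

  wrcy_pool <- scan_motifs(genome, "WRCY", target_offset = 2L)
  tcw_pool <- scan_motifs(genome, "TCW", target_offset = 1L)
  if (mix[["aid"]] > 0 && nrow(wrcy_pool) == 0) {
    abort("infeasible mix: AID fraction > 0 but the genome has no WRCY site")
  }
  if (mix[["apobec"]] > 0 && nrow(tcw_pool) == 0) {
    abort("infeasible mix: APOBEC fraction > 0 but the genome has no TCW site")
  }

  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    tumor_type = tumor_type,
    purity = runif(n_samples, purity[1], purity[2]),
    depth = as.integer(depth)
  )

  genes <- annotations$genes
  coupled <- head(genes$name, coupled_genes)
  # per-(coupled gene, sample) latent scores drive both AID counts and
  # expression (Gaussian copula; Pearson r chosen to hit the Spearman target)
  r_pearson <- 2 * sin(pi * coupled_rho / 6)
  z_latent <- matrix(rnorm(length(coupled) * n_samples),
                     nrow = length(coupled), ncol = n_samples,
                     dimnames = list(coupled, samples$sample_id))
  coupled_counts <- matrix(qpois(pnorm(z_latent), lambda = 3),
                           nrow = length(coupled), ncol = n_samples,
                           dimnames = dimnames(z_latent))

  # per-gene WRCY target pools for coupled placements
  gene_pools <- lapply(seq_along(coupled), function(i) {
    g <- genes[genes$name == coupled[i], ]
    wrcy_pool %>% filter(contig == g$contig, target_pos >= g$start,
                         target_pos < g$end)
  })
  names(gene_pools) <- coupled

  alt_for <- function(strand) {
    ifelse(strand == "+", sample(c("T", "G"), length(strand), replace = TRUE),
           sample(c("A", "C"), length(strand), replace = TRUE))
  }

  one_sample <- function(si) {
    sid <- samples$sample_id[si]
    n_s <- max(1L, rnbinom(1, mu = mut_mean, size = mut_dispersion))
    n_by <- drop(stats::rmultinom(1, n_s, mix))

    place_pool <- function(pool, n, process) {
      if (n == 0) return(NULL)
      d <- .draw_sites(pool, n)
      tibble(contig = d$contig, pos = d$target_pos,
             ref = if_else(d$strand == "+", "C", "G"),
             alt = alt_for(d$strand), process = process)
    }
    bg <- if (n_by[["background"]] > 0) {
      n <- n_by[["background"]]
      ctg <- sample(names(lens), n, replace = TRUE, prob = lens)
      pos <- vapply(ctg, function(cc) {
        2L + sample.int(lens[[cc]] - 4L, 1L) - 1L
      }, integer(1))
      ref <- vapply(seq_len(n), function(i) {
        substr(strings[[ctg[i]]], pos[i] + 1, pos[i] + 1)
      }, character(1))
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
      tibble(contig = ctg, pos = pos, ref = ref, alt = unname(alt),
             process = "background")
    } else NULL

    extra <- purrr::map_dfr(coupled, function(gn) {
      k <- coupled_counts[gn, sid]
      pool <- gene_pools[[gn]]
      if (k == 0 || nrow(pool) == 0) return(NULL)
      d <- .draw_sites(pool, k)
      tibble(contig = d$contig, pos = d$target_pos,
             ref = if_else(d$strand == "+", "C", "G"),
             alt = alt_for(d$strand), process = "aid")
    })

    bind_rows(
      place_pool(wrcy_pool, n_by[["aid"]], "aid"),
      place_pool(tcw_pool, n_by[["apobec"]], "apobec"),
      bg, extra
    ) %>% mutate(sample_id = sid)
  }

  muts <- purrr::map_dfr(seq_len(n_samples), one_sample)
  muts$mutation_id <- sprintf("m%07d", seq_len(nrow(muts)))

  # gene assignment and protein positions
  gene_gr <- .as_granges(genes)
  mut_gr <- GenomicRanges::GRanges(muts$contig,
                                   IRanges::IRanges(muts$pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(mut_gr, gene_gr, select = "first")
  muts$gene <- ifelse(is.na(ov), NA_character_, genes$name[ov])
  off <- ifelse(genes$strand[ov] == "+", muts$pos - genes$start[ov],
                genes$end[ov] - 1L - muts$pos)
  muts$protein_pos <- ifelse(is.na(ov), NA_integer_,
                             as.integer(off %/% 3L + 1L))
  muts$classification <- ifelse(
    is.na(muts$gene), "IGR",
    sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation"),
           nrow(muts), replace = TRUE, prob = c(0.8, 0.1, 0.1)))

  # planted clonality and binomial read counts (diploid, multiplicity 1)
  muts <- muts %>%
    left_join(select(samples, sample_id, purity, depth), by = "sample_id") %>%
    mutate(
      clonal_true = runif(n()) < clonal_fraction,
      ccf_true = if_else(clonal_true, 1,
                         runif(n(), subclonal_ccf[1], subclonal_ccf[2])),
      cn_tumor = 2L,
      t_alt_count = rbinom(n(), depth, ccf_true * purity / 2),
      t_ref_count = depth - t_alt_count
    )

  # expression: copula-coupled for the chosen genes, lognormal noise otherwise
  expression <- tidyr::expand_grid(sample_id = samples$sample_id,
                                   gene = genes$name) %>%
    mutate(expression = 2^(4 + rnorm(n())))
  for (gn in coupled) {
    i <- expression$gene == gn
    z2 <- r_pearson * z_latent[gn, expression$sample_id[i]] +
      sqrt(1 - r_pearson^2) * rnorm(sum(i))
    expression$expression[i] <- 2^(4 + z2)
  }

  # neoepitopes: records for nonsynonymous gene mutations; per-sample
  # per-process designation plants the ICN presence fractions
  neo_src <- muts %>%
    filter(!is.na(gene), classification != "Silent",
           runif(n()) < neo_rate) %>%
    left_join(expression, by = c("sample_id", "gene"))
  neo <- neo_src %>%
    mutate(
      peptide = vapply(seq_len(n()), function(i) {
        paste(sample(AA_ALPHABET, 9, replace = TRUE), collapse = "")
      }, character(1)),
      hla = "HLA-A*02:01",
      fpkm = expression,
      rank_score = runif(n(), 0.6, 95)
    ) %>%
    select(sample_id, mutation_id, gene, peptide, hla, rank_score, fpkm,
           process, clonal_true)

  designation <- tidyr::expand_grid(sample_id = samples$sample_id,
                                    process = names(icn_presence)) %>%
    mutate(designated = runif(n()) < icn_presence[process])
  for (i in which(designation$designated)) {
    cand <- which(neo$sample_id == designation$sample_id[i] &
                    neo$process == designation$process[i] & neo$clonal_true)
    if (length(cand) == 0) {
      designation$designated[i] <- FALSE  # nothing to plant; truth records it
      next
    }
    k <- min(length(cand), 1L + rpois(1, 0.5))
    pick <- sample(cand, k)
    neo$rank_score[pick] <- runif(k, 0, 0.5)
    neo$fpkm[pick] <- pmax(neo$fpkm[pick], 1.5)
  }
  neo$clonal_true <- NULL

  variants <- muts %>%
    select(sample_id, contig, pos, ref, alt, gene, protein_pos,
           classification, t_alt_count, t_ref_count, cn_tumor, mutation_id)
  ground_truth <- muts %>%
    select(mutation_id, sample_id, contig, pos, ref, alt, gene,
           process, ccf_true, clonal_true)

  structure(list(
    variants = variants,
    samples = samples,
    expression = expression,
    neoepitopes = neo,
    ground_truth = ground_truth,
    truth_samples = designation,
    coupled_genes = coupled,
    mix = mix
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples, %d mutations (planted: %s)\n",
              nrow(x$samples), nrow(x$variants),
              paste(sprintf("%s %.0f%%", names(x$mix), 100 * x$mix),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate per-gene AID-composite counts from the covariate model
#'
#' Draws gene-level observed AID-composite sample counts from a negative
#' binomial whose mean follows the covariate regression used by
#' [fit_expected_counts()] — log link, coefficient `beta_log_cds` on
#' (centred) log CDS length, offset `log(n_mutated)` — with optional planted
#' enriched genes at `fold` times their model rate.
#'
#' @param panel Panel covariate tibble from [generate_annotations()].
#' @param beta_log_cds True coefficient on centred log CDS length (default 1).
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`;
#'   default 0.5).
#' @param base_rate Baseline AID-composite rate per mutated sample
#'   (default 0.05).
#' @param enriched Character vector of genes planted at `fold` times their
#'   expected rate.
#' @param fold Enrichment fold of planted genes (default 5).
#' @param seed Optional integer seed.
#' @return `gene_counts` tibble ready for [fit_expected_counts()]; the
#'   attribute `"truth"` carries the planted parameters.
#' @export
generate_panel_counts <- function(panel, beta_log_cds = 1, dispersion = 0.5,
                                  base_rate = 0.05, enriched = character(),
                                  fold = 5, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  n_mutated <- sample(50:500, nrow(panel), replace = TRUE)
  lcds <- log(panel$cds_length) - mean(log(panel$cds_length))
  mu <- exp(log(base_rate) + beta_log_cds * lcds) * n_mutated
  mu <- mu * ifelse(panel$gene %in% enriched, fold, 1)
  out <- panel %>%
    mutate(n_mutated = n_mutated,
           observed = rnbinom(n(), mu = mu, size = 1 / dispersion)) %>%
    select(gene, observed, n_mutated, cds_length, gc_percent,
           replication_time, chromatin_state, assay_version, mean_copy_number)
  attr(out, "truth") <- list(beta_log_cds = beta_log_cds,
                             dispersion = dispersion, base_rate = base_rate,
                             enriched = enriched, fold = fold, mu = mu)
  out
}

#' Write a synthetic cohort (and its genome/annotations) to disk
#'
#' Emits plain-text artifacts: a MAF, sample/expression/neoepitope/ground
#' truth TSVs, the genome FASTA with index, annotation BEDs and the panel
#' TSV.
#'
#' @param cohort A [generate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @param genome Optional `DNAStringSet` to write alongside.
#' @param annotations Optional annotations list to write alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, genome = NULL, annotations = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_maf(cohort$variants, file.path(dir, "cohort.maf"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(cohort$neoepitopes, file.path(dir, "neoepitopes.tsv"), progress = FALSE)
  readr::write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  if (!is.null(genome)) write_genome(genome, file.path(dir, "genome.fa"))
  if (!is.null(annotations)) {
    write_bed(mutate(annotations$genes, score = 0), file.path(dir, "genes.bed"))
    write_bed(mutate(annotations$domains, name = class),
              file.path(dir, "domains.bed"))
    write_bed(annotations$rloops, file.path(dir, "rloops.bed"))
    readr::write_tsv(annotations$panel, file.path(dir, "panel.tsv"), progress = FALSE)
  }
  invisible(dir)
}
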