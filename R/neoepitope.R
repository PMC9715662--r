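# Neoepitope filtering and immunogenic-clonal-neoepitope (ICN) analysis.
# Immunogenicity %rank scores are consumed, never computed: the upstream HLA
# typing and peptide-MHC predictors sit outside this package.

#' Antigen-presentation gene list used for sample exclusion
#'
#' The genes whose damaging alteration or copy loss disqualifies a sample
#' from neoepitope analysis (HLA enhanceosome, peptide generation,
#' chaperones, and the MHC complex). The family shorthands HSPA/HSPC/CNX are
#' kept as literal configurable tokens.
#'
#' @return Character vector of gene symbols.
#' @export
antigen_presentation_genes <- function() {
  c("HLA-A", "HLA-B", "HLA-C", "CIITA", "IRF1", "PSME1", "PSME2", "PSME3",
    "ERAP1", "ERAP2", "HSPA", "HSPC", "TAP1", "TAP2", "TAPBP", "CALR",
    "CNX", "PDIA3", "B2M")
}

#' Sample-level eligibility filter for neoepitope analysis
#'
#' Excludes samples with (I) incomplete HLA information, (II) microsatellite
#' instability, or (III) a damaging alteration or copy loss in an
#' antigen-presentation gene.
#'
#' @param samples Tibble with `sample_id`, logical `hla_complete` and
#'   `msi_high` columns.
#' @param damaged_genes Optional tibble `sample_id`, `gene` listing
#'   damaging/copy-loss alterations per sample.
#' @param ap_genes Antigen-presentation gene list (default
#'   [antigen_presentation_genes()]).
#' @return Eligible samples tibble; the attribute `"exclusions"` carries the
#'   per-criterion exclusion counts.
#' @export
filter_samples <- function(samples, damaged_genes = NULL,
                           ap_genes = antigen_presentation_genes()) {
  for (nm in c("sample_id", "hla_complete", "msi_high")) {
    if (!nm %in% names(samples)) abort(sprintf("missing column '%s'", nm))
  }
  excl1 <- !samples$hla_complete
  excl2 <- samples$msi_high
  damaged_samples <- if (is.null(damaged_genes)) character(0) else {
    unique(damaged_genes$sample_id[damaged_genes$gene %in% ap_genes])
  }
  excl3 <- samples$sample_id %in% damaged_samples
  out <- samples[!(excl1 | excl2 | excl3), ]
  attr(out, "exclusions") <- tibble(
    criterion = c("incomplete_hla", "msi", "antigen_presentation"),
    n_excluded = c(sum(excl1), sum(excl2), sum(excl3))
  )
  out
}

#' Classify neoepitopes by immunogenicity and clonality
#'
#' Drops records from genes expressed at or below `expression_threshold`
#' FPKM, flags a record immunogenic when its %rank score is lower than or
#' equal to `rank_threshold`, and ICN (immunogenic clonal neoepitope) when it
#' is immunogenic and its source mutation is clonal. Records without a %rank
#' score are dropped and counted; records without a clonality call get an
#' `NA` ICN flag and are excluded from presence counts.
#'
#' @param records Tibble with `sample_id`, `rank_score` (percentage), `fpkm`
#'   (source-gene expression) and either a `clonality` column or a
#'   `mutation_id` joinable to `clonality_calls`.
#' @param clonality_calls Optional tibble `mutation_id`, `clonality`.
#' @param expression_threshold Minimum exclusive FPKM (default 1).
#' @param rank_threshold %rank cut-off, inclusive (default 0.5).
#' @return Filtered records with logical `immunogenic` and `icn` columns.
#' @export
classify_neoepitopes <- function(records, clonality_calls = NULL,
                                 expression_threshold = 1,
                                 rank_threshold = 0.5) {
  if (!is.null(clonality_calls)) {
    records <- left_join(records,
                         select(clonality_calls, mutation_id, clonality),
                         by = "mutation_id")
  }
  stopifnot("clonality" %in% names(records))
  n0 <- nrow(records)
  records <- filter(records, !is.na(rank_score))
  if (nrow(records) < n0) {
    inform(sprintf("%d record(s) without %%rank score dropped", n0 - nrow(records)))
  }
  n1 <- nrow(records)
  records <- filter(records, fpkm > expression_threshold)
  if (nrow(records) < n1) {
    inform(sprintf("%d record(s) from unexpressed genes dropped", n1 - nrow(records)))
  }
  if (anyNA(records$clonality)) {
    inform(sprintf("%d record(s) without clonality: ICN flag unknown",
                   sum(is.na(records$clonality))))
  }
  records %>%
    mutate(immunogenic = rank_score <= rank_threshold,
           icn = if_else(is.na(clonality), NA,
                         immunogenic & clonality == "clonal"))
}

#' Per-sample, per-process ICN presence
#'
#' A sample is `Presence` for a mutational process when it carries at least
#' one ICN attributed to that process, `Absence` otherwise. Records with an
#' unknown ICN flag are ignored; neoepitopes without a process label are
#' grouped as `"other"`.
#'
#' @param records Classified records (see [classify_neoepitopes()]) with a
#'   process label column.
#' @param eligible_samples Tibble of eligible samples (`sample_id`), the
#'   denominator of every proportion.
#' @param process_col Name of the process label column (default `"process"`).
#' @return Tibble `sample_id` x `process` with logical `presence`.
#' @export
neo_presence <- function(records, eligible_samples, process_col = "process") {
  recs <- records %>%
    filter(sample_id %in% eligible_samples$sample_id, !is.na(icn)) %>%
    mutate(process = dplyr::coalesce(.data[[process_col]], "other"))
  procs <- sort(unique(recs$process))
  if (length(procs) == 0) abort("no classified records for eligible samples")
  tidyr::expand_grid(sample_id = eligible_samples$sample_id,
                     process = procs) %>%
    left_join(recs %>% group_by(sample_id, process) %>%
                summarise(presence = any(icn), .groups = "drop"),
              by = c("sample_id", "process")) %>%
    mutate(presence = dplyr::coalesce(presence, FALSE))
}

#' Contrast ICN presence proportions between two processes
#'
#' Two-sided two-proportion z-test (pooled variance) of the fraction of
#' eligible samples with at least one ICN from process A versus process B,
#' with Clopper-Pearson 95% intervals per group.
#'
#' @param status Presence table from [neo_presence()].
#' @param process_a,process_b Process labels to compare.
#' @return One-row tibble with the proportions, intervals, z statistic and
#'   p-value.
#' @export
presence_contrast <- function(status, process_a, process_b) {
  grab <- function(p) {
    s <- filter(status, process == p)
    if (nrow(s) == 0) abort(sprintf("no eligible samples for process '%s'", p))
    c(x = sum(s$presence), n = nrow(s))
  }
  a <- grab(process_a)
  b <- grab(process_b)
  out <- .two_prop_test(a[["x"]], a[["n"]], b[["x"]], b[["n"]])
  mutate(out, process_a = process_a, process_b = process_b, .before = 1)
}
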