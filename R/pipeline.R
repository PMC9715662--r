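# End-to-end pipeline orchestration: simulate (or load) a cohort, tag c-AID
# mutations, run the shuffling null, call clonality, profile the genomic
# distribution, test composite/neoepitope enrichment, and leave every
# intermediate as a plain-text artifact plus a JSON manifest.

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Root seed; every stochastic stage derives its own seed from it.
#' @return Named list of configuration values; any entry can be overridden
#'   and the list (or a YAML file with the same keys) passed to
#'   [run_pipeline()].
#' @export
pipeline_config <- function(out_dir = "aidscape-run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, tag = TRUE, null = TRUE, clonality = TRUE,
                  context = TRUE, composite = TRUE, neoepitope = TRUE),
    genome = list(lengths = c(chr1 = 5e5, chr2 = 5e5), gc = 0.41),
    cohort = list(n_samples = 12L, mut_mean = 400, mut_dispersion = 10),
    flank = 20L,
    context_flank = 1L,
    n_rep = 100L,
    alpha = 0.05,
    n_perm = 2000L,
    inputs = NULL  # named paths (maf, genome, ...) to skip simulation
  )
}

#' Run the full analysis pipeline
#'
#' Runs the stages in dependency order (simulate/load -> tag -> null ->
#' clonality -> context -> composite -> neoepitope), writing per-stage TSV
#' artifacts and a manifest recording the package version, seed, parameters
#' and md5 checksums of every output. Reruns with an identical configuration
#' reproduce identical artifacts.
#'
#' @param config A list from [pipeline_config()] (possibly modified) or the
#'   path of a YAML file with the same keys.
#' @return The manifest list, invisibly; artifacts under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- cfg$stages
  artifacts <- character(0)
  save_tsv <- function(x, name) {
    path <- file.path(cfg$out_dir, name)
    readr::write_tsv(x, path, progress = FALSE)
    artifacts <<- c(artifacts, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- simulate or load ------------------------------------------------
  gl <- unlist(cfg$genome$lengths)
  if (is.null(names(gl))) names(gl) <- paste0("chr", seq_along(gl))
  genome <- annotations <- cohort <- NULL
  if (isTRUE(st$simulate) && is.null(cfg$inputs)) {
    stage("simulate", {
      genome <- generate_genome(gl, cfg$genome$gc, seed = cfg$seed)
      annotations <- generate_annotations(genome, seed = cfg$seed + 1L)
      cohort <- do.call(generate_cohort, c(
        list(genome = genome, annotations = annotations, seed = cfg$seed + 2L),
        cfg$cohort))
      write_cohort(cohort, cfg$out_dir, genome = genome,
                   annotations = annotations)
      artifacts <- c(artifacts,
                     file.path(cfg$out_dir,
                                c("cohort.maf", "samples.tsv", "expression.tsv",
                                  "neoepitopes.tsv", "ground_truth.tsv",
                                  "genome.fa", "genes.bed", "domains.bed",
                                  "rloops.bed", "panel.tsv")))
    })
  } else {
    stage("load", {
      genome <- read_genome(cfg$inputs$genome)
      maf <- read_maf(cfg$inputs$maf, chr_prefix = "keep")
      smp <- readr::read_tsv(cfg$inputs$samples, show_col_types = FALSE)
      cohort <- list(variants = maf, samples = smp)
    })
  }
  variants <- cohort$variants

  # --- tag c-AID mutations ---------------------------------------------
  tracking <- NULL
  if (isTRUE(st$tag)) {
    stage("tag", {
      tracking <- track_aid(variants, genome, flank = cfg$flank)
      variants <- tracking$variants
      save_tsv(tracking$enrichment, "enrichment.tsv")
      save_tsv(tracking$matrix, "substitution_matrix.tsv")
      write_maf(extract_aid_maf(variants), file.path(cfg$out_dir, "aid_only.maf"))
      artifacts <- c(artifacts, file.path(cfg$out_dir, "aid_only.maf"))
    })
  } else {
    variants <- classify_aid(variants, genome)
  }

  # --- context-preserving null -----------------------------------------
  if (isTRUE(st$null)) {
    stage("null", {
      index <- build_context_index(genome, flank = cfg$context_flank)
      nulls <- simulate_cohort(variants, index, genome, n_rep = cfg$n_rep,
                               seed = cfg$seed + 3L)
      sig <- purrr::map_dfr(nulls, test_sample_significance, alpha = cfg$alpha)
      save_tsv(sig, "null_significance.tsv")
      save_tsv(cohort_enrichment_ratio(nulls, seed = cfg$seed + 4L),
               "cohort_enrichment.tsv")
    })
  }

  # --- clonality --------------------------------------------------------
  if (isTRUE(st$clonality) && all(c("t_alt_count", "t_ref_count") %in% names(variants))) {
    stage("clonality", {
      v <- variants
      if (!"purity" %in% names(v)) {
        v <- left_join(v, select(cohort$samples, sample_id, purity),
                       by = "sample_id")
      }
      if (!"cn_tumor" %in% names(v)) v$cn_tumor <- 2L
      v <- compute_ccf(v)
      variants <- v
      save_tsv(select(v, sample_id, contig, pos, ref, alt, vaf, multiplicity,
                      ccf, ccf_low, ccf_high, clonality), "clonality.tsv")
    })
  }

  # --- genomic context --------------------------------------------------
  if (isTRUE(st$context) && !is.null(annotations)) {
    stage("context", {
      aid <- extract_aid_maf(variants)
      dl <- domain_load(aid, annotations$domains)
      save_tsv(dl$class_loads, "domain_loads.tsv")
      tp <- tss_profile(aid, annotations$genes)
      save_tsv(tp$profile, "tss_profile.tsv")
      labelled <- left_join(variants,
                            select(cohort$ground_truth, mutation_id, process),
                            by = "mutation_id")
      ro <- region_overlap_test(labelled, annotations$rloops)
      save_tsv(ro$tests, "rloop_tests.tsv")
      save_tsv(intermutation_distance(aid), "intermutation.tsv")
      counts <- aid %>% filter(!is.na(gene)) %>%
        left_join(select(cohort$samples, sample_id, tumor_type),
                  by = "sample_id") %>%
        count(tumor_type, gene, sample_id, name = "n_mutations")
      ea <- expression_association(counts, cohort$expression, cohort$samples)
      save_tsv(ea, "expression_association.tsv")
    })
  }

  # --- composite --------------------------------------------------------
  if (isTRUE(st$composite) && !is.null(annotations)) {
    stage("composite", {
      events <- detect_composites(variants, annotations$panel)
      save_tsv(select(events, -members), "composite_events.tsv")
      pn <- permutation_expected(variants, n_perm = cfg$n_perm,
                                 seed = cfg$seed + 5L)
      save_tsv(glance(pn), "composite_permutation.tsv")
      hu <- hotspot_utilization(variants, events)
      save_tsv(hu$curves, "hotspot_curves.tsv")
    })
  }

  # --- neoepitope -------------------------------------------------------
  if (isTRUE(st$neoepitope) && !is.null(cohort$neoepitopes)) {
    stage("neoepitope", {
      smp <- mutate(cohort$samples, hla_complete = TRUE, msi_high = FALSE)
      eligible <- filter_samples(smp)
      clon <- select(variants, mutation_id, clonality)
      recs <- classify_neoepitopes(cohort$neoepitopes, clon)
      status <- neo_presence(recs, eligible)
      save_tsv(status, "icn_presence.tsv")
      save_tsv(presence_contrast(status, "aid", "apobec"),
               "icn_contrast.tsv")
    })
  }

  manifest <- list(
    package = "aidscape",
    version = as.character(utils::packageVersion("aidscape")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("stages", "inputs"))],
    stages_run = names(st)[unlist(st)],
    artifacts = lapply(
      setNames(nm = basename(artifacts[file.exists(artifacts)])),
      function(b) unname(tools::md5sum(file.path(cfg$out_dir, b))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
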