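test_that("domain loads conserve counts and reflect uniform placement", {
  domains <- tibble::tibble(
    contig = "c1",
    start = c(0L, 50000L),
    end = c(50000L, 100000L),
    class = c("active", "inactive")
  )
  withr::local_seed(51)
  muts <- tibble::tibble(contig = "c1",
                         pos = sample.int(100000L, 4000L, replace = TRUE) - 1L)
  dl <- domain_load(muts, domains)
  expect_equal(sum(dl$class_loads$n_mutations, na.rm = TRUE) + dl$n_unassigned,
               nrow(muts))
  expect_equal(dl$active_inactive_ratio, 1, tolerance = 0.1)
  expect_s3_class(ggplot2::autoplot(dl), "ggplot")

  # all mutations in active windows with zero inactive load -> infinite ratio
  muts2 <- tibble::tibble(contig = "c1", pos = sample.int(50000L, 100L) - 1L)
  dl2 <- domain_load(muts2, domains)
  expect_true(is.infinite(dl2$active_inactive_ratio))

  expect_error(domain_load(muts, dplyr::mutate(domains, class = "bogus")),
               "unknown domain class")
  expect_error(domain_load(muts, tibble::tibble(contig = "c1", start = 0L,
                                                end = c(60000L, 50000L),
                                                class = c("active", "inactive"))),
               "overlap")
})

test_that("straddling windows are assigned by majority overlap with left ties", {
  muts <- tibble::tibble(contig = "c1", pos = c(26000L, 27000L))
  dom_majority <- tibble::tibble(contig = "c1", start = c(0L, 30000L),
                                 end = c(30000L, 100000L),
                                 class = c("active", "inactive"))
  dl <- domain_load(muts, dom_majority)
  # window [25000, 50000) overlaps active 5 kb, inactive 20 kb -> inactive
  expect_equal(dl$class_loads$n_mutations[dl$class_loads$class == "inactive"], 2L)

  dom_tie <- tibble::tibble(contig = "c1", start = c(0L, 37500L),
                            end = c(37500L, 100000L),
                            class = c("active", "inactive"))
  dl2 <- domain_load(muts, dom_tie)
  # exact 12.5/12.5 kb tie -> leftward (active) domain
  expect_equal(dl2$class_loads$n_mutations[dl2$class_loads$class == "active"], 2L)
})

test_that("TSS profiles orient bins by transcription direction", {
  genes <- tibble::tibble(contig = "c1", start = 400000L, end = 410000L,
                          strand = "-", name = "gm")
  tss <- 410000L - 1L
  # 5 kb downstream of a minus-strand gene = tss - 5000 on the plus axis
  muts <- tibble::tibble(contig = "c1", pos = tss - 5000L)
  tp <- tss_profile(muts, genes)
  prof <- tp$profile
  expect_equal(prof$n_mutations[prof$strand_class == "-" & prof$bin_index == 1L], 1L)
  expect_equal(sum(prof$n_mutations), 1L)

  # no mutations -> all-zero profile with 2K + 1 bins per strand class
  tp0 <- tss_profile(muts[0, ], genes)
  expect_equal(sum(tp0$profile$n_mutations), 0L)
  expect_equal(nrow(tp0$profile), 2 * (2 * 50 + 1))
})

test_that("TSS profiles are symmetric under strand reflection", {
  s <- random_seq(3e5, seed = 52)
  len <- nchar(s)
  genes_f <- tibble::tibble(contig = "c1", start = 120000L, end = 130000L,
                            strand = "+", name = "g1")
  withr::local_seed(53)
  muts <- tibble::tibble(contig = "c1",
                         pos = sample.int(len, 500L) - 1L)
  fwd <- tss_profile(muts, genes_f, span = 1e5, bin = 1e4)

  genes_r <- tibble::tibble(contig = "c1", start = len - 130000L,
                            end = len - 120000L, strand = "-", name = "g1")
  muts_r <- tibble::tibble(contig = "c1", pos = len - 1L - muts$pos)
  rev <- tss_profile(muts_r, genes_r, span = 1e5, bin = 1e4)
  expect_equal(rev$profile$n_mutations[rev$profile$strand_class == "-"],
               fwd$profile$n_mutations[fwd$profile$strand_class == "+"])
})

test_that("region overlap tests agree with exact-test oracles and are symmetric", {
  regions <- tibble::tibble(contig = "c1", start = 0L, end = 1000L)
  mk <- function(process, n_in, n_out) {
    tibble::tibble(contig = "c1",
                   pos = c(sample.int(1000L, n_in, replace = TRUE) - 1L,
                           1000L + sample.int(50000L, n_out, replace = TRUE)),
                   process = process)
  }
  withr::local_seed(54)
  muts <- dplyr::bind_rows(mk("A", 30, 170), mk("B", 10, 190))
  ro <- region_overlap_test(muts, regions)
  expect_equal(ro$counts$n_in[ro$counts$process == "A"], 30L)
  expect_equal(ro$tests$p_value,
               fisher_twosided_oracle(30, 170, 10, 190), tolerance = 1e-7)
  # symmetric under swapping processes
  muts_sw <- dplyr::mutate(muts, process = ifelse(process == "A", "B", "A"))
  ro_sw <- region_overlap_test(muts_sw, regions)
  expect_equal(ro_sw$tests$p_value, ro$tests$p_value)

  # identical proportions: p = 1
  muts_id <- dplyr::bind_rows(mk("A", 20, 80), mk("B", 20, 80))
  expect_equal(region_overlap_test(muts_id, regions)$tests$p_value, 1)

  expect_error(region_overlap_test(mk("A", 5, 5), regions), "two process")
})

test_that("inter-mutation distances match a sorted-difference oracle", {
  m <- tibble::tibble(contig = c("c1", "c1"), pos = c(100L, 250L))
  d <- intermutation_distance(m)
  expect_equal(d$distance, c(NA, 150L))

  m2 <- tibble::tibble(contig = c("c1", "c2"), pos = c(100L, 250L))
  expect_true(all(is.na(intermutation_distance(m2)$distance)))

  withr::local_seed(55)
  m3 <- tibble::tibble(contig = sample(c("c1", "c2"), 200, replace = TRUE),
                       pos = sample.int(1e6, 200))
  d3 <- intermutation_distance(m3)
  oracle <- unlist(lapply(split(m3$pos, m3$contig), function(p) diff(sort(p))))
  expect_setequal(d3$distance[!is.na(d3$distance)], oracle)
  expect_s3_class(plot_rainfall(d3), "ggplot")
})

test_that("expression association flags exactly positive monotone couplings", {
  samples <- tibble::tibble(sample_id = sprintf("s%d", 1:8), tumor_type = "T")
  counts <- tibble::tibble(tumor_type = "T", gene = "g1",
                           sample_id = samples$sample_id,
                           n_mutations = 1:8)
  expr <- dplyr::bind_rows(
    tibble::tibble(sample_id = samples$sample_id, gene = "g1",
                   expression = (1:8) * 2.5),          # proportional
    tibble::tibble(sample_id = samples$sample_id, gene = "g2",
                   expression = 8:1)                    # would be anti, no muts
  )
  counts2 <- dplyr::bind_rows(
    counts,
    tibble::tibble(tumor_type = "T", gene = "g2",
                   sample_id = samples$sample_id, n_mutations = 1:8))
  res <- expression_association(counts2, expr, samples)
  expect_equal(res$rho[res$gene == "g1"], 1)
  expect_true(res$associated[res$gene == "g1"])
  expect_equal(res$rho[res$gene == "g2"], -1)
  expect_false(res$associated[res$gene == "g2"])

  # constant vectors are skipped with a report
  counts3 <- dplyr::mutate(counts, n_mutations = 3L)
  expect_message(res3 <- expression_association(counts3, expr[expr$gene == "g1", ],
                                                samples), "skipped")
  expect_equal(nrow(res3), 0L)
})

test_that("planted expression couplings are recovered at cohort scale", {
  genome <- generate_genome(c(chr1 = 1e6), seed = 401)
  ann <- generate_annotations(genome, n_genes = 300, seed = 402)
  coh <- suppressMessages(generate_cohort(
    genome, ann, n_samples = 40, mut_mean = 150, coupled_genes = 10,
    coupled_rho = 0.8, seed = 403))
  tagged <- classify_aid(coh$variants, genome)
  counts <- dplyr::count(
    dplyr::left_join(extract_aid_maf(tagged),
                     dplyr::select(coh$samples, sample_id, tumor_type),
                     by = "sample_id") |> dplyr::filter(!is.na(gene)),
    tumor_type, gene, sample_id, name = "n_mutations")
  res <- suppressMessages(
    expression_association(counts, coh$expression, coh$samples))
  planted <- coh$coupled_genes
  hits <- res$associated[res$gene %in% planted]
  expect_gte(sum(hits), 8L)
  fp <- res[!res$gene %in% planted & res$associated, ]
  expect_lte(nrow(fp), ceiling(0.05 * sum(!res$gene %in% planted)) + 2L)
})
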