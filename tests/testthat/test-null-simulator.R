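test_that("the context index partitions indexable positions and matches a scan oracle", {
  g <- make_genome(c(c1 = "AACCT"))
  idx <- build_context_index(g, flank = 2)
  expect_equal(names(idx$contigs$c1), "AACCT")
  expect_equal(context_positions(idx, "c1", "AACCT"), 2L)

  s <- random_seq(5000, p_n = 0.005, seed = 31)
  gg <- make_genome(c(c1 = s))
  for (flank in 1:2) {
    idx2 <- build_context_index(gg, flank = flank)
    all_pos <- sort(unlist(idx2$contigs$c1, use.names = FALSE))
    # partition: each indexable position appears exactly once
    expect_false(any(duplicated(all_pos)))
    k <- 2 * flank + 1
    oracle <- lapply(seq(flank, nchar(s) - flank - 1), function(p) {
      km <- substring(s, p - flank + 1, p + flank + 1)
      if (grepl("N", km)) NULL else c(p = p, km = km)
    })
    oracle <- do.call(rbind, oracle[!vapply(oracle, is.null, logical(1))])
    expect_equal(all_pos, sort(as.integer(oracle[, "p"])))
    # every key holds exactly the positions with that context
    for (key in sample(names(idx2$contigs$c1), 10)) {
      expect_equal(sort(context_positions(idx2, "c1", key)),
                   sort(as.integer(oracle[oracle[, "km"] == key, "p"])))
    }
  }
})

test_that("shuffling preserves per-chromosome burden and the sampled context", {
  w <- tiny_world()
  tagged <- classify_aid(w$cohort$variants, w$genome)
  one <- dplyr::filter(tagged, sample_id == "S001")
  idx <- build_context_index(w$genome, flank = 2)
  null <- simulate_sample(one, idx, w$genome, n_rep = 5, seed = 3,
                          keep_positions = TRUE)
  expect_equal(dim(null$positions), c(nrow(one), 5L))
  lens <- contig_lengths(w$genome)
  for (r in 1:5) {
    for (ctg in unique(one$contig)) {
      i <- which(one$contig == ctg)
      # per-chromosome burden: every mutation stays on its contig, within
      # bounds, so per-contig counts equal the observed in every replicate
      expect_true(all(null$positions[i, r] >= 0 &
                        null$positions[i, r] < lens[[ctg]]))
      # sampled positions carry the source pentanucleotide context
      src <- extract_context(w$genome, ctg, one$pos[i], 2)
      dst <- extract_context(w$genome, ctg, null$positions[i, r], 2)
      expect_equal(dst, src)
    }
  }
})

test_that("pentanucleotide-exact shuffling is provably degenerate for WRCY", {
  # the WRCY/RGYW 4-mer sits wholly inside the +/-2 bp window, so a shuffle
  # preserving the exact 5-mer preserves every c-AID flag: simulated counts
  # must equal the observed count in every replicate
  w <- tiny_world()
  tagged <- classify_aid(w$cohort$variants, w$genome)
  one <- dplyr::filter(tagged, sample_id == "S002")
  idx <- build_context_index(w$genome, flank = 2)
  null <- simulate_sample(one, idx, w$genome, n_rep = 40, seed = 4)
  expect_true(all(null$sim_aid == null$observed_aid))
})

test_that("shuffling is deterministic under a seed and varies without one", {
  w <- tiny_world()
  tagged <- classify_aid(w$cohort$variants, w$genome)
  one <- dplyr::filter(tagged, sample_id == "S001")
  idx <- build_context_index(w$genome, flank = 1)
  a <- simulate_sample(one, idx, w$genome, n_rep = 20, seed = 9)
  b <- simulate_sample(one, idx, w$genome, n_rep = 20, seed = 9)
  expect_identical(a$sim_aid, b$sim_aid)
  c <- simulate_sample(one, idx, w$genome, n_rep = 20, seed = 10)
  expect_false(identical(a$sim_aid, c$sim_aid))
})

test_that("mutations without alternative positions stay in place", {
  # a genome where each mutation's 5-mer context is unique forces identity
  g <- make_genome(c(c1 = "TTTTAGCTGGGCATTTT"))
  idx <- build_context_index(g, flank = 2)
  v <- tibble::tibble(sample_id = "s", contig = "c1", pos = c(6L, 11L),
                      ref = c("C", "C"), alt = c("T", "G"))
  v <- classify_aid(v, g)
  null <- simulate_sample(v, idx, g, n_rep = 3, keep_positions = TRUE, seed = 1)
  expect_equal(null$n_kept_in_place, 2L)
  expect_true(all(null$positions == v$pos))
  expect_true(all(null$sim_aid == null$observed_aid))
})

test_that("the simulated c-AID mean matches the per-class analytic expectation", {
  w <- tiny_world()
  tagged <- classify_aid(w$cohort$variants, w$genome)
  one <- dplyr::filter(tagged, sample_id == "S003")
  idx <- build_context_index(w$genome, flank = 1)
  null <- simulate_sample(one, idx, w$genome, n_rep = 400, seed = 5)

  # independent oracle: P(AID) per mutation = fraction of its context class
  # whose positions form a motif target for that substitution type, computed
  # by raw string inspection
  wrcy <- expand_motif("WRCY")
  rgyw <- revcomp(wrcy)
  strings <- lapply(names(w$genome), function(ct) as.character(w$genome[[ct]]))
  names(strings) <- names(w$genome)
  p_aid <- vapply(seq_len(nrow(one)), function(i) {
    ctg <- one$contig[i]
    s <- strings[[ctg]]
    key <- substring(s, one$pos[i], one$pos[i] + 2)  # 0-based +/-1 window
    cand <- context_positions(idx, ctg, key)
    if (length(cand) <= 1) return(as.numeric(one$is_aid[i]))
    if (one$ref[i] == "C" && one$alt[i] %in% c("T", "G")) {
      mean(substring(s, cand - 1, cand + 2) %in% wrcy)
    } else if (one$ref[i] == "G" && one$alt[i] %in% c("A", "C")) {
      mean(substring(s, cand, cand + 3) %in% rgyw)
    } else 0
  }, numeric(1))
  expected <- sum(p_aid)
  sim_se <- stats::sd(null$sim_aid) / sqrt(null$n_rep)
  expect_lt(abs(null$expected_aid - expected), 4 * sim_se + 0.5)
})

test_that("significance calls behave at the extremes", {
  flat <- structure(list(sample_id = "s", n_rep = 50, n_mutations = 200,
                         observed_aid = 20, observed_non_aid = 180,
                         sim_aid = rep(20L, 50), expected_aid = 20),
                    class = "aid_null")
  res <- test_sample_significance(flat)
  expect_false(res$significant)
  expect_equal(res$prop_or_overlap, 1)

  extreme <- structure(list(sample_id = "s", n_rep = 50, n_mutations = 500,
                            observed_aid = 100, observed_non_aid = 400,
                            sim_aid = rpois(50, 5), expected_aid = 5),
                       class = "aid_null")
  res2 <- test_sample_significance(extreme)
  expect_true(res2$significant)
  expect_equal(res2$direction, "enrichment")

  small <- structure(list(sample_id = "s", n_rep = 10, n_mutations = 100,
                          observed_aid = 10, observed_non_aid = 90,
                          sim_aid = rep(10L, 10), expected_aid = 10),
                     class = "aid_null")
  expect_true(is.na(test_sample_significance(small)$significant))
})

test_that("cohort enrichment ratio reduces to arithmetic and rejects zero expectations", {
  mk <- function(obs, expd) {
    structure(list(sample_id = "s", n_rep = 30, n_mutations = 100,
                   observed_aid = obs, observed_non_aid = 100 - obs,
                   sim_aid = rep(as.integer(expd), 30), expected_aid = expd),
              class = "aid_null")
  }
  same <- cohort_enrichment_ratio(list(mk(10, 10), mk(7, 7)), n_boot = 50, seed = 1)
  expect_equal(same$ratio, 1)
  two <- cohort_enrichment_ratio(list(mk(10, 5), mk(20, 5)), n_boot = 50, seed = 1)
  expect_equal(two$ratio, 3)
  expect_true(two$ci_low <= two$ratio && two$ratio <= two$ci_high)
  expect_error(cohort_enrichment_ratio(list(mk(3, 0))), "zero expected")
})
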