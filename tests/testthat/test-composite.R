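mini_cohort <- function() {
  tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    gene = c("A", "A", "B", "B", "C"),
    protein_pos = c(10L, 20L, 5L, 5L, 7L),
    is_aid = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    clonality = c("clonal", "subclonal", "clonal", "clonal", "clonal")
  )
}

test_that("composite detection equals a group-by oracle", {
  ev <- detect_composites(mini_cohort())
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene, "A")
  expect_equal(ev$n_mutations, 2L)
  expect_true(ev$aid_composite)

  none <- tibble::tibble(sample_id = c("s1", "s2"), gene = c("A", "A"),
                         is_aid = FALSE)
  expect_equal(nrow(detect_composites(none)), 0L)

  withr::local_seed(61)
  big <- tibble::tibble(
    sample_id = sample(sprintf("s%d", 1:20), 300, replace = TRUE),
    gene = sample(sprintf("g%d", 1:30), 300, replace = TRUE),
    is_aid = runif(300) < 0.2
  )
  ev2 <- detect_composites(big)
  oracle <- table(paste(big$sample_id, big$gene))
  expect_equal(nrow(ev2), sum(oracle >= 2))
  expect_equal(sort(paste(ev2$sample_id, ev2$gene)),
               sort(names(oracle)[oracle >= 2]))
})

test_that("synonymous records are excluded from composite detection", {
  v <- dplyr::mutate(mini_cohort(),
                     classification = c("Missense_Mutation", "Silent",
                                        "Missense_Mutation", "Missense_Mutation",
                                        "Missense_Mutation"))
  expect_equal(nrow(detect_composites(v)), 0L)  # the A pair loses one member
})

test_that("the permutation null matches exhaustive enumeration on small instances", {
  v3 <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                       gene = c("g1", "g1", "g2"), is_aid = FALSE)
  pn <- permutation_expected(v3, n_perm = 3000, seed = 62)
  # exhaustive: of the 3 distinct arrangements of {g1, g1, g2}, exactly one
  # leaves both g1 labels in s1 -> P(n_i >= 1) = 1/3
  expect_equal(pn$n_pos, 1L)
  expect_equal(pn$p_value, 1 / 3, tolerance = 0.05)

  # all mutations in distinct samples: no composite is ever possible
  v0 <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                       gene = c("g1", "g1", "g2", "g2"), is_aid = FALSE)
  pn0 <- permutation_expected(v0, n_perm = 200, seed = 1)
  expect_equal(pn0$n_pos, 0L)
  expect_equal(pn0$p_value, 1)

  # exhaustive enumeration oracle on a 6-mutation instance
  v6 <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    gene = c("gA", "gB", "gA", "gB", "gB", "gC"), is_aid = FALSE)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (rest in perms(x[-i])) out <- c(out, list(c(x[i], rest)))
    }
    out
  }
  n_pos_of <- function(g) {
    id <- paste(v6$sample_id, g)
    length(unique(v6$sample_id[duplicated(id)]))
  }
  all_n <- vapply(perms(v6$gene), n_pos_of, integer(1))
  exact_p <- mean(all_n >= n_pos_of(v6$gene))
  pn6 <- permutation_expected(v6, n_perm = 4000, seed = 63)
  se <- sqrt(exact_p * (1 - exact_p) / 4000)
  expect_lt(abs(pn6$p_value - exact_p), 4 * se + 1e-3)
  # the p-value respects its add-one bounds
  expect_gte(pn6$p_value, 1 / 4001)
  expect_lte(pn6$p_value, 1)
})

test_that("NB regression recovers degenerate and scaling behaviour", {
  # identical covariates and identical counts: intercept-only fit, n_c = k
  d <- tibble::tibble(
    gene = sprintf("g%02d", 1:25), observed = 4L, n_mutated = 100L,
    cds_length = 1500, gc_percent = 50, replication_time = 50,
    chromatin_state = "active", assay_version = "v1", mean_copy_number = 2
  )
  fit <- suppressWarnings(fit_expected_counts(d))
  expect_equal(fit$fitted$expected, rep(4, 25), tolerance = 1e-6)

  # offset proportionality of the log link: doubling the offset basis
  # doubles the predicted expectation at fixed coefficients
  pred2 <- stats::predict(fit$model,
                          newdata = dplyr::mutate(d, n_mutated = 200L),
                          type = "response")
  expect_equal(unname(pred2), rep(8, 25), tolerance = 1e-6)

  expect_error(fit_expected_counts(d[1:10, ]), "at least 20")
  expect_error(fit_expected_counts(dplyr::select(d, -gc_percent)), "gc_percent")

  # median imputation is reported
  d2 <- d
  d2$replication_time <- runif(25, 0, 100)
  d2$replication_time[3] <- NA
  expect_message(suppressWarnings(fit_expected_counts(d2)), "median-imputed")
})

test_that("gene-level binomial enrichment matches the tail-sum oracle", {
  fitted <- tibble::tibble(gene = c("gA", "gB"), observed = c(10L, 1L),
                           n_mutated = c(20L, 20L), expected = c(1, 1))
  res <- gene_enrichment(fitted)
  oracle <- sum(dbinom(10:20, 20, 0.05))
  expect_equal(res$p_value[1], oracle, tolerance = 1e-10)
  expect_true(res$q_value[1] >= res$p_value[1])

  # observed equal to an integer-mean expectation is never enriched
  fitted2 <- tibble::tibble(gene = "g", observed = 5L, n_mutated = 20L,
                            expected = 5)
  expect_gte(gene_enrichment(fitted2)$p_value, 0.5)

  # BH monotonicity
  withr::local_seed(64)
  fitted3 <- tibble::tibble(gene = sprintf("g%d", 1:30),
                            observed = rpois(30, 3), n_mutated = 50L,
                            expected = 3)
  res3 <- gene_enrichment(fitted3)
  o <- order(res3$p_value)
  expect_true(all(diff(res3$q_value[o]) >= -1e-12))
})

test_that("residue enrichment concentrates where AID composites concentrate", {
  # all AID-composite mutations at one residue, background spread elsewhere
  v <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("s%d", 1:30),
                   gene = "G", protein_pos = 100L, is_aid = TRUE),
    tibble::tibble(sample_id = sprintf("s%d", 1:30),
                   gene = "G", protein_pos = 100L + (1:30), is_aid = FALSE),
    tibble::tibble(sample_id = sprintf("t%d", 1:60),
                   gene = "G", protein_pos = 200L + (1:60) %% 30, is_aid = FALSE)
  )
  ev <- detect_composites(v)
  res <- residue_enrichment(v, ev)
  top <- res[res$residue == 100L, ]
  expect_lt(top$p_value, 0.01)
  expect_equal(res$a_res[res$residue == 100L], 30L)

  # a single-residue gene offers no contrast: p = 1
  v1 <- tibble::tibble(sample_id = c("s1", "s1"), gene = "H",
                       protein_pos = 5L, is_aid = c(TRUE, FALSE))
  res1 <- residue_enrichment(v1, detect_composites(v1))
  expect_equal(res1$p_value, 1)
})

test_that("hotspot-utilization curves equal a cumulative-count oracle", {
  withr::local_seed(65)
  v <- tibble::tibble(
    sample_id = sample(sprintf("s%d", 1:8), 20, replace = TRUE),
    gene = "G",
    protein_pos = sample(c(10L, 20L, 30L), 20, replace = TRUE,
                         prob = c(0.6, 0.3, 0.1)),
    is_aid = runif(20) < 0.4
  )
  ev <- detect_composites(v)
  hu <- hotspot_utilization(v, ev)
  curves <- hu$curves
  expect_true(all(curves$cum_fraction >= 0 & curves$cum_fraction <= 1.0000001))
  # monotone and ending at 1 for every non-empty group
  for (g in unique(curves$group)) {
    cc <- curves$cum_fraction[curves$group == g]
    expect_true(all(diff(cc) >= -1e-12))
    expect_equal(cc[length(cc)], 1)
  }
  # oracle: recompute one group by hand
  flagged <- dplyr::mutate(
    v, in_comp = paste(sample_id, gene) %in% paste(ev$sample_id, ev$gene),
    grp = dplyr::case_when(is_aid & in_comp ~ "aid_composite",
                           is_aid ~ "aid_singleton",
                           in_comp ~ "other_composite",
                           TRUE ~ "other_singleton"))
  rk <- hu$residues$residue
  for (g in unique(flagged$grp)) {
    sub <- flagged[flagged$grp == g, ]
    oracle <- cumsum(vapply(rk, function(r) {
      sum(paste0(sub$gene, ":", sub$protein_pos) == r)
    }, numeric(1))) / nrow(sub)
    expect_equal(curves$cum_fraction[curves$group == g], unname(oracle))
  }

  # single residue: every curve jumps to 1 at k = 1
  v1 <- tibble::tibble(sample_id = c("s1", "s1", "s2"), gene = "G",
                       protein_pos = 9L, is_aid = c(TRUE, TRUE, FALSE))
  hu1 <- hotspot_utilization(v1, detect_composites(v1))
  expect_true(all(hu1$curves$cum_fraction[hu1$curves$k == 1] == 1))
  expect_s3_class(ggplot2::autoplot(hu1), "ggplot")
})

test_that("timing tests reduce to binomial closed forms", {
  mk_pairs <- function(k, n) {
    tibble::tibble(
      residue_first = "G:1", residue_second = "G:2",
      freq_first = c(rep(10L, k), rep(1L, n - k)),
      freq_second = c(rep(1L, k), rep(10L, n - k))
    )
  }
  tt <- timing_test(mk_pairs(10, 10))
  expect_equal(tt$global$p_value, 2 * 0.5^10)
  expect_equal(timing_test(mk_pairs(5, 10))$global$p_value, 1)
  expect_true(is.na(suppressMessages(timing_test(mk_pairs(2, 3)))$global$p_value))
  # per-residue one-sided call: G:2 always second in the 10/10 case
  pr <- tt$per_residue
  expect_equal(pr$p_value[pr$residue == "G:2"], 0.5^10)
})

test_that("clonality-discordant pairs become orderable timing events", {
  v <- mini_cohort()
  ev <- detect_composites(v)
  hu <- hotspot_utilization(v, ev)
  pairs <- composite_timing(ev, hu$residues)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$residue_first, "A:10")   # the clonal member
  expect_equal(pairs$residue_second, "A:20")
})
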