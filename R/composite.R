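# Composite mutations (two or more somatic mutations in the same gene of the
# same tumour) and AID-composite enrichment statistics: the permutation null
# for the cohort-level composite rate, negative-binomial expected counts per
# gene, one-sided binomial gene tests, right-sided residue Fisher tests,
# hotspot-utilization curves, and molecular-timing binomial tests.

NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Splice_Site",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Translation_Start_Site"
)

# internal: restrict to nonsynonymous gene-annotated mutations
.nonsyn <- function(variants) {
  v <- filter(variants, !is.na(gene))
  if ("classification" %in% names(v)) {
    v <- filter(v, is.na(classification) | classification %in% NONSYNONYMOUS_CLASSES)
  }
  v
}

#' Detect composite mutations
#'
#' Groups nonsynonymous mutations by (sample, gene); every pair with two or
#' more mutations is a composite event. An event is an AID composite when at
#' least one member carries the c-AID flag.
#'
#' @param variants Tagged variant tibble (`is_aid` required; rows lacking a
#'   gene symbol are ignored, and `classification` is used to drop synonymous
#'   records when present).
#' @param panel Optional tibble `gene`, `gene_class`
#'   (`"oncogene"`/`"tsg"`) used to label events.
#' @return Tibble with one row per event: `sample_id`, `gene`, `n_mutations`,
#'   `n_aid`, `aid_composite`, `gene_class` (when a panel is given) and a
#'   nested `members` list-column with the member mutations.
#' @export
detect_composites <- function(variants, panel = NULL) {
  stopifnot("is_aid" %in% names(variants))
  v <- .nonsyn(variants)
  ev <- v %>%
    group_by(sample_id, gene) %>%
    filter(n() >= 2) %>%
    tidyr::nest(members = !c(sample_id, gene)) %>%
    ungroup() %>%
    mutate(n_mutations = purrr::map_int(members, nrow),
           n_aid = purrr::map_int(members, ~ sum(.x$is_aid)),
           aid_composite = n_aid >= 1) %>%
    select(sample_id, gene, n_mutations, n_aid, aid_composite, members)
  if (!is.null(panel)) {
    ev <- left_join(ev, select(panel, gene, gene_class), by = "gene")
  }
  ev
}

#' Composite-mutation rates by gene class
#'
#' Fraction of nonsynonymous mutations that are part of a composite event,
#' per gene class, with a two-proportion contrast between tumour suppressors
#' and oncogenes.
#'
#' @param variants Tagged variant tibble.
#' @param events Output of [detect_composites()].
#' @param panel Tibble `gene`, `gene_class`.
#' @return List with `rates` (per class) and `contrast` (two-sided
#'   two-proportion z-test between the first two classes).
#' @export
composite_rates <- function(variants, events, panel) {
  v <- .nonsyn(variants) %>% left_join(select(panel, gene, gene_class), by = "gene")
  comp_keys <- paste(events$sample_id, events$gene)
  v$in_composite <- paste(v$sample_id, v$gene) %in% comp_keys
  rates <- v %>%
    filter(!is.na(gene_class)) %>%
    group_by(gene_class) %>%
    summarise(n_mutations = n(), n_composite = sum(in_composite),
              rate = n_composite / n_mutations, .groups = "drop")
  contrast <- if (nrow(rates) >= 2) {
    .two_prop_test(rates$n_composite[1], rates$n_mutations[1],
                   rates$n_composite[2], rates$n_mutations[2])
  } else NULL
  list(rates = rates, contrast = contrast)
}

#' Permutation null for the composite-sample count
#'
#' Fixes the observed mutations and permutes the gene-to-mutation pairing
#' (shuffling gene labels across all nonsynonymous mutations preserves every
#' sample's burden); each replicate counts the samples carrying at least two
#' same-gene mutations. The p-value uses the add-one convention
#' `p = (1 + #\{n_i >= n_pos\}) / (N + 1)`.
#'
#' @param variants Variant tibble (`sample_id`, `gene`; `classification`
#'   honoured as in [detect_composites()]).
#' @param n_perm Number of permutations. The cohort-scale convention is
#'   100,000; tests use far fewer.
#' @param seed Optional integer seed.
#' @param shuffle `"gene"` (default) permutes gene labels over mutations;
#'   `"sample"` permutes sample labels (the equivalent rewiring).
#' @return Object of class `perm_null` with `n_pos`, replicate counts `n_i`
#'   and `p_value`. `tidy()` gives the replicate counts, `glance()` the
#'   summary row.
#' @export
permutation_expected <- function(variants, n_perm = 10000L, seed = NULL,
                                 shuffle = c("gene", "sample")) {
  shuffle <- match.arg(shuffle)
  if (!is.null(seed)) withr::local_seed(seed)
  v <- .nonsyn(variants)
  stopifnot(nrow(v) >= 2)
  smp <- v$sample_id
  gn <- v$gene

  count_pos <- function(s, g) {
    id <- paste(s, g, sep = "\r")
    length(unique(s[duplicated(id)]))
  }
  n_pos <- count_pos(smp, gn)
  n_i <- vapply(seq_len(n_perm), function(i) {
    if (shuffle == "gene") count_pos(smp, sample(gn))
    else count_pos(sample(smp), gn)
  }, integer(1))
  structure(list(
    n_pos = n_pos, n_i = n_i, n_perm = n_perm,
    p_value = (1 + sum(n_i >= n_pos)) / (n_perm + 1)
  ), class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("composite permutation null: n_pos = %d, mean null = %.2f, p = %.4g (%d permutations)\n",
              x$n_pos, mean(x$n_i), x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname permutation_expected
#' @param x A `perm_null` object.
#' @param ... Unused.
#' @export
tidy.perm_null <- function(x, ...) {
  tibble(replicate = seq_len(x$n_perm), n_samples = x$n_i)
}

#' @rdname permutation_expected
#' @export
glance.perm_null <- function(x, ...) {
  tibble(n_pos = x$n_pos, null_mean = mean(x$n_i), p_value = x$p_value,
         n_perm = x$n_perm)
}

#' Expected AID-composite counts from a negative-binomial covariate model
#'
#' Fits `observed ~ log(cds_length) + gc_percent + replication_time +
#' chromatin_state + assay_version + mean_copy_number` with a log link and an
#' offset of `log(n_mutated)` (the number of tumour samples mutated in the
#' gene), by maximum-likelihood negative-binomial regression
#' ([MASS::glm.nb()]). Missing numeric covariates are median-imputed (and
#' reported); on non-convergence the fit falls back to Poisson with a
#' warning; a singular design is rejected naming the offending covariate.
#'
#' @param gene_counts Tibble with columns `gene`, `observed` (AID-composite
#'   sample count), `n_mutated`, `cds_length`, `gc_percent`,
#'   `replication_time`, `chromatin_state`, `assay_version`,
#'   `mean_copy_number`. At least 20 genes.
#' @return Object of class `composite_fit`: `fitted` (gene, observed,
#'   n_mutated, expected), the `model`, and `family_used`. `tidy()` returns
#'   the coefficient table, `glance()` the model summary.
#' @export
fit_expected_counts <- function(gene_counts) {
  needed <- c("gene", "observed", "n_mutated", "cds_length", "gc_percent",
              "replication_time", "chromatin_state", "assay_version",
              "mean_copy_number")
  miss <- setdiff(needed, names(gene_counts))
  if (length(miss) > 0) abort(sprintf("missing covariate column '%s'", miss[1]))
  if (nrow(gene_counts) < 20) abort("need at least 20 genes to fit the model")

  d <- gene_counts
  num <- c("cds_length", "gc_percent", "replication_time", "mean_copy_number")
  for (nm in num) {
    if (anyNA(d[[nm]])) {
      inform(sprintf("median-imputed %d missing value(s) in %s",
                     sum(is.na(d[[nm]])), nm))
      d[[nm]][is.na(d[[nm]])] <- median(d[[nm]], na.rm = TRUE)
    }
  }
  for (nm in c("chromatin_state", "assay_version")) {
    f <- factor(d[[nm]])
    ref <- names(sort(table(f), decreasing = TRUE))[1]
    d[[nm]] <- stats::relevel(f, ref = ref)
  }

  # drop constant covariates from the formula rather than failing on them
  # (degenerate designs reduce to an intercept-plus-offset fit)
  terms <- character(0)
  num_terms <- c(`log(cds_length)` = "cds_length", gc_percent = "gc_percent",
                 replication_time = "replication_time",
                 mean_copy_number = "mean_copy_number")
  for (i in seq_along(num_terms)) {
    if (sd(d[[num_terms[i]]]) > 0) terms <- c(terms, names(num_terms)[i])
  }
  for (nm in c("chromatin_state", "assay_version")) {
    if (nlevels(droplevels(d[[nm]])) > 1) terms <- c(terms, nm)
  }
  rhs <- if (length(terms) > 0) paste(terms, collapse = " + ") else "1"
  fml <- as.formula(paste("observed ~", rhs, "+ offset(log(n_mutated))"))

  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = d)),
    error = function(e) NULL
  )
  family_used <- "negative binomial"
  if (is.null(fit) || !fit$converged) {
    warn("negative-binomial fit did not converge; falling back to Poisson")
    fit <- glm(fml, data = d, family = poisson())
    family_used <- "poisson"
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(sprintf("singular design: covariate term '%s' is aliased",
                  names(cf)[which(is.na(cf))[1]]))
  }
  structure(list(
    fitted = tibble(gene = d$gene, observed = d$observed,
                    n_mutated = d$n_mutated,
                    expected = unname(stats::fitted(fit))),
    model = fit,
    family_used = family_used
  ), class = "composite_fit")
}

#' @export
print.composite_fit <- function(x, ...) {
  cat(sprintf("%s model over %d genes; mean expected %.3f\n",
              x$family_used, nrow(x$fitted), mean(x$fitted$expected)))
  invisible(x)
}

#' @rdname fit_expected_counts
#' @param x A `composite_fit` object.
#' @param ... Unused.
#' @export
tidy.composite_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4])
}

#' @rdname fit_expected_counts
#' @export
glance.composite_fit <- function(x, ...) {
  tibble(family = x$family_used,
         theta = if (x$family_used == "negative binomial") x$model$theta else NA_real_,
         aic = stats::AIC(x$model),
         n_genes = nrow(x$fitted))
}

#' Gene-level AID-composite enrichment
#'
#' One-sided binomial test, per gene, of the observed AID-composite sample
#' count out of the gene's mutated samples against the model-expected rate
#' `expected / n_mutated`; Benjamini-Hochberg over genes, significant at
#' `q < 0.01`.
#'
#' @param fit A [fit_expected_counts()] object (or its `fitted` tibble).
#' @param fdr Significance threshold on the adjusted p-value (default 0.01).
#' @return Tibble `gene`, `observed`, `expected`, `n_mutated`, `p_value`,
#'   `q_value`, `significant`.
#' @export
gene_enrichment <- function(fit, fdr = 0.01) {
  f <- if (inherits(fit, "composite_fit")) fit$fitted else fit
  rate <- f$expected / f$n_mutated
  if (any(rate >= 1)) {
    warn(sprintf("%d gene(s) with expected >= mutated samples; rate capped",
                 sum(rate >= 1)))
    rate <- pmin(rate, 1 - 1e-9)
  }
  p <- pbinom(f$observed - 1, f$n_mutated, rate, lower.tail = FALSE)
  tibble(gene = f$gene, observed = f$observed, expected = f$expected,
         n_mutated = f$n_mutated, p_value = p,
         q_value = p.adjust(p, method = "BH")) %>%
    mutate(significant = q_value < fdr)
}

# internal: flag variants that are members of composite events
.flag_composites <- function(variants, events) {
  keys <- paste(events$sample_id, events$gene)
  mutate(variants, in_composite = paste(sample_id, gene) %in% keys &
           !is.na(gene))
}

#' Residue-level AID-composite enrichment
#'
#' For each mutated residue of each gene, a right-sided Fisher exact test of
#' whether AID composite mutations concentrate at that residue more than all
#' other mutations of the same gene do:
#' `[[AID-composite at r, AID-composite elsewhere], [others at r, others
#' elsewhere]]`. Benjamini-Hochberg across residues, significant at
#' `q < 0.01`. Mutations without a protein position are excluded and counted.
#'
#' @param variants Tagged variant tibble (`is_aid`, `gene`, `protein_pos`).
#' @param events Output of [detect_composites()].
#' @param fdr Threshold on the adjusted p-value (default 0.01).
#' @return Tibble `gene`, `residue`, the 2x2 counts, `p_value`, `q_value`,
#'   `significant`.
#' @export
residue_enrichment <- function(variants, events, fdr = 0.01) {
  v <- .nonsyn(variants) %>% .flag_composites(events)
  n_missing <- sum(is.na(v$protein_pos))
  if (n_missing > 0) {
    inform(sprintf("%d mutation(s) without protein position excluded", n_missing))
  }
  v <- filter(v, !is.na(protein_pos))
  v$grp_a <- v$is_aid & v$in_composite  # AID composite mutations

  res <- v %>%
    group_by(gene) %>%
    group_modify(function(d, key) {
      tot_a <- sum(d$grp_a)
      tot_b <- sum(!d$grp_a)
      d %>% group_by(residue = protein_pos) %>%
        summarise(a_res = sum(grp_a), b_res = sum(!grp_a), .groups = "drop") %>%
        mutate(a_other = tot_a - a_res, b_other = tot_b - b_res)
    }) %>%
    ungroup()
  res$p_value <- purrr::pmap_dbl(
    res[c("a_res", "a_other", "b_res", "b_other")],
    function(a_res, a_other, b_res, b_other) {
      stats::fisher.test(matrix(c(a_res, a_other, b_res, b_other), 2, byrow = TRUE),
                         alternative = "greater")$p.value
    })
  res %>%
    mutate(q_value = p.adjust(p_value, method = "BH"),
           significant = q_value < fdr) %>%
    arrange(p_value)
}

#' Hotspot-utilization curves
#'
#' Ranks residues by decreasing population-level recurrence (unique samples
#' mutated at the residue) and, for each mutation group (AID-composite,
#' AID-singleton, other-composite, other-singleton), accumulates the fraction
#' of the group's mutations attributable to the top-k residues.
#'
#' @param variants Tagged variant tibble with `gene`, `protein_pos`, `is_aid`.
#' @param events Output of [detect_composites()].
#' @return Object of class `hotspot_curves`: `curves` tibble (`group`, `k`,
#'   `residue`, `cum_fraction`) and the ranked `residues` table.
#' @export
hotspot_utilization <- function(variants, events) {
  v <- .nonsyn(variants) %>% .flag_composites(events) %>%
    filter(!is.na(protein_pos)) %>%
    mutate(residue = paste0(gene, ":", protein_pos),
           group = dplyr::case_when(
             is_aid & in_composite ~ "aid_composite",
             is_aid & !in_composite ~ "aid_singleton",
             !is_aid & in_composite ~ "other_composite",
             TRUE ~ "other_singleton"
           ))
  residues <- v %>%
    group_by(residue) %>%
    summarise(freq = dplyr::n_distinct(sample_id), .groups = "drop") %>%
    arrange(desc(freq), residue) %>%
    mutate(k = row_number())
  curves <- v %>%
    count(group, residue, name = "n_mut") %>%
    left_join(select(residues, residue, k), by = "residue") %>%
    group_by(group) %>%
    arrange(k, .by_group = TRUE) %>%
    tidyr::complete(k = seq_len(nrow(residues)), fill = list(n_mut = 0L)) %>%
    arrange(k, .by_group = TRUE) %>%
    mutate(cum_fraction = cumsum(n_mut) / sum(n_mut),
           residue = residues$residue[k]) %>%
    ungroup() %>%
    select(group, k, residue, n_mut, cum_fraction)
  structure(list(curves = curves, residues = residues),
            class = "hotspot_curves")
}

#' @rdname hotspot_utilization
#' @param x A `hotspot_curves` object.
#' @param ... Unused.
#' @export
tidy.hotspot_curves <- function(x, ...) x$curves

#' Contrasts between hotspot-utilization groups
#'
#' For each pair of groups, compares the proportion of each group's mutations
#' landing in the top `top_frac` most recurrent residues (two-sided
#' two-proportion z-test, Clopper-Pearson 95% CIs) and reports the fold
#' change of the groups' median cumulative fractions.
#'
#' @param x A [hotspot_utilization()] object.
#' @param top_frac Fraction of top-ranked residues defining "hotspots"
#'   (default 0.05).
#' @return Tibble of pairwise contrasts.
#' @export
hotspot_contrasts <- function(x, top_frac = 0.05) {
  k_top <- max(1L, ceiling(nrow(x$residues) * top_frac))
  per_group <- x$curves %>%
    group_by(group) %>%
    summarise(n_total = sum(n_mut),
              n_top = sum(n_mut[k <= k_top]),
              median_cum = median(cum_fraction), .groups = "drop")
  pairs <- utils::combn(per_group$group, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- per_group[per_group$group == pr[1], ]
    b <- per_group[per_group$group == pr[2], ]
    zt <- .two_prop_test(a$n_top, a$n_total, b$n_top, b$n_total)
    mutate(zt, group_a = pr[1], group_b = pr[2],
           fc_median = a$median_cum / b$median_cum, .before = 1)
  })
}

#' Molecular-timing binomial tests for composite pairs
#'
#' Given orderable composite pairs (e.g. one clonal and one subclonal member,
#' the clonal one first), tests globally whether the more recurrent hotspot
#' residue tends to occur first (two-sided binomial against 0.5) and, per
#' residue, whether that residue occurs second more often than chance
#' (one-sided binomial).
#'
#' @param pairs Tibble with one row per orderable event: `residue_first`,
#'   `residue_second`, `freq_first`, `freq_second` (population recurrences).
#'   Ties in recurrence are dropped from the global test.
#' @param min_events Minimum orderable events to run a test (default 5).
#' @return List with `global` (one-row tibble) and `per_residue`.
#' @export
timing_test <- function(pairs, min_events = 5L) {
  ordered <- filter(pairs, freq_first != freq_second)
  k <- sum(ordered$freq_first > ordered$freq_second)
  n <- nrow(ordered)
  global <- if (n >= min_events) {
    tibble(n_events = n, hotspot_first = k,
           prop_hotspot_first = k / n,
           p_value = binom.test(k, n, 0.5)$p.value)
  } else {
    inform(sprintf("only %d orderable event(s); global timing test skipped", n))
    tibble(n_events = n, hotspot_first = k,
           prop_hotspot_first = if (n > 0) k / n else NA_real_,
           p_value = NA_real_)
  }
  res_long <- bind_rows(
    tibble(residue = pairs$residue_first, second = FALSE),
    tibble(residue = pairs$residue_second, second = TRUE)
  )
  per_residue <- res_long %>%
    group_by(residue) %>%
    summarise(n_events = n(), n_second = sum(second), .groups = "drop") %>%
    filter(n_events >= min_events) %>%
    mutate(p_value = purrr::map2_dbl(
      n_second, n_events,
      ~ binom.test(.x, .y, 0.5, alternative = "greater")$p.value))
  list(global = global, per_residue = per_residue)
}

#' Derive orderable composite pairs from clonality
#'
#' Restricts composite events to those with exactly two members of discordant
#' clonality (the clonal member is taken to have arisen first) and attaches
#' population residue recurrences.
#'
#' @param events Output of [detect_composites()]; member tibbles must carry
#'   `protein_pos` and `clonality`.
#' @param residues Ranked residue table from [hotspot_utilization()]
#'   (`residue`, `freq`).
#' @return Tibble of orderable pairs suitable for [timing_test()].
#' @export
composite_timing <- function(events, residues) {
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    m <- events$members[[i]]
    if (nrow(m) != 2 || anyNA(m$protein_pos) || anyNA(m$clonality)) return(NULL)
    if (length(unique(m$clonality)) != 2) return(NULL)
    first <- m[m$clonality == "clonal", ][1, ]
    second <- m[m$clonality == "subclonal", ][1, ]
    tibble(sample_id = events$sample_id[i], gene = events$gene[i],
           residue_first = paste0(events$gene[i], ":", first$protein_pos),
           residue_second = paste0(events$gene[i], ":", second$protein_pos))
  }) %>%
    left_join(rename(residues, residue_first = residue, freq_first = freq),
              by = "residue_first") %>%
    left_join(rename(residues, residue_second = residue, freq_second = freq),
              by = "residue_second") %>%
    select(-any_of("k.x"), -any_of("k.y"))
}

# internal: two-sided two-proportion z-test with pooled variance and
# Clopper-Pearson CIs
.two_prop_test <- function(x1, n1, x2, n2, conf = 0.95) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  ci <- function(x, n) {
    a <- (1 - conf) / 2
    c(low = if (x == 0) 0 else qbeta(a, x, n - x + 1),
      high = if (x == n) 1 else qbeta(1 - a, x + 1, n - x))
  }
  c1 <- ci(x1, n1); c2 <- ci(x2, n2)
  tibble(prop_a = p1, prop_b = p2,
         ci_a_low = c1[["low"]], ci_a_high = c1[["high"]],
         ci_b_low = c2[["low"]], ci_b_high = c2[["high"]],
         statistic = z, p_value = 2 * pnorm(-abs(z)))
}
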