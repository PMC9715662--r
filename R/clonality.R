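# Cancer cell fraction estimation and clonal/subclonal calling.
#
# CCF = VAF * (rho * CNt + (1 - rho) * CNn) / (rho * m), with an exact
# (Clopper-Pearson) binomial 95% interval on the VAF mapped through the same
# linear transform. A mutation is subclonal iff the upper CCF bound is below
# 0.95, clonal otherwise.

#' Estimate mutation multiplicity
#'
#' Nearest-integer estimate of the number of mutated-allele copies per tumour
#' cell: `round(VAF * (rho * CNt + (1 - rho) * CNn) / rho)`, clipped to
#' `[1, CNt]`.
#'
#' @param vaf Variant allele fraction in `[0, 1]`.
#' @param purity Tumour purity rho in `(0, 1]`.
#' @param cn_tumor Tumour total copy number at the locus (>= 1).
#' @param cn_normal Normal copy number (2 for autosomes, 1 for male sex
#'   chromosomes).
#' @return Integer multiplicity vector.
#' @export
estimate_multiplicity <- function(vaf, purity, cn_tumor, cn_normal = 2) {
  stopifnot(all(vaf >= 0 & vaf <= 1), all(purity > 0 & purity <= 1),
            all(cn_tumor >= 1))
  m <- round(vaf * (purity * cn_tumor + (1 - purity) * cn_normal) / purity)
  as.integer(pmin(pmax(m, 1), pmax(cn_tumor, 1)))
}

#' Cancer cell fraction with exact binomial interval and clonality call
#'
#' Data-frame-first CCF computation. Expects per-variant alt/ref read counts,
#' per-sample purity and local tumour copy number; the multiplicity is taken
#' from a `multiplicity` column when present, otherwise estimated with
#' [estimate_multiplicity()]. The Clopper-Pearson interval on the VAF is
#' mapped through the CCF transform; the clonality call uses the (uncapped)
#' upper bound: subclonal iff `ccf_high < clonal_cutoff`.
#'
#' @param data Tibble with columns `t_alt_count`, `t_ref_count`, `purity`,
#'   `cn_tumor` (and optionally `cn_normal`, `multiplicity`).
#' @param cn_normal Normal copy number used when no `cn_normal` column exists.
#' @param conf Confidence level of the binomial interval (default 0.95).
#' @param clonal_cutoff CCF upper-bound threshold for the subclonal call
#'   (default 0.95).
#' @return `data` with added `depth`, `vaf`, `multiplicity`, `ccf`,
#'   `ccf_low`, `ccf_high` and `clonality` (`"clonal"`/`"subclonal"`) columns.
#'   CCF values are left uncapped so that the identity `ccf = 2 * vaf` holds
#'   exactly in the diploid pure-tumour case; values above 1 indicate
#'   multiplicity or copy-number misspecification.
#' @export
compute_ccf <- function(data, cn_normal = 2, conf = 0.95, clonal_cutoff = 0.95) {
  stopifnot(all(c("t_alt_count", "t_ref_count", "purity", "cn_tumor") %in% names(data)))
  alt <- data$t_alt_count
  ref <- data$t_ref_count
  depth <- alt + ref
  if (any(depth == 0)) abort("variant(s) with zero read depth")
  vaf <- alt / depth
  cnn <- if ("cn_normal" %in% names(data)) data$cn_normal else cn_normal
  m <- if ("multiplicity" %in% names(data)) data$multiplicity else
    estimate_multiplicity(vaf, data$purity, data$cn_tumor, cnn)
  stopifnot(all(m >= 1))

  scale <- (data$purity * data$cn_tumor + (1 - data$purity) * cnn) /
    (data$purity * m)
  a <- (1 - conf) / 2
  # Clopper-Pearson in closed beta-quantile form
  v_low <- ifelse(alt == 0, 0, qbeta(a, alt, depth - alt + 1))
  v_high <- ifelse(alt == depth, 1, qbeta(1 - a, alt + 1, depth - alt))

  data$depth <- depth
  data$vaf <- vaf
  data$multiplicity <- m
  data$ccf <- vaf * scale
  data$ccf_low <- v_low * scale
  data$ccf_high <- v_high * scale
  data$clonality <- if_else(data$ccf_high < clonal_cutoff, "subclonal", "clonal")
  data
}
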