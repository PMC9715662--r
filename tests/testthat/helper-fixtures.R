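# Shared in-code fixtures. Everything is generated programmatically; no data
# files are read from disk.

# genome from literal sequences
make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}

# random sequence with optional N content
random_seq <- function(n, p_n = 0, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# regex oracle for degenerate-motif scanning (overlapping matches via
# lookahead), independent of the Biostrings-based scanner
regex_scan_oracle <- function(seq_str, pattern = "WRCY") {
  iupac_re <- c(A = "A", C = "C", G = "G", T = "T", W = "[AT]", R = "[AG]",
                Y = "[CT]", S = "[CG]", K = "[GT]", M = "[AC]")
  to_re <- function(p) paste(iupac_re[strsplit(p, "")[[1]]], collapse = "")
  find <- function(re) {
    m <- gregexpr(paste0("(?=", re, ")"), seq_str, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  rc_pattern <- chartr("ACGTWRYSKM", "TGCAWYRSMK",
                       paste(rev(strsplit(pattern, "")[[1]]), collapse = ""))
  list(plus = find(to_re(pattern)), minus = find(to_re(rc_pattern)))
}

# small deterministic synthetic world reused across files
tiny_world <- function(seed = 101, n_samples = 4, mut_mean = 250) {
  genome <- generate_genome(c(chrA = 5e4, chrB = 3e4), seed = seed)
  annotations <- generate_annotations(genome, n_genes = 25, seed = seed + 1)
  cohort <- suppressMessages(generate_cohort(
    genome, annotations, n_samples = n_samples, mut_mean = mut_mean,
    seed = seed + 2))
  list(genome = genome, annotations = annotations, cohort = cohort)
}

# hypergeometric tail oracle for a one-sided (greater) Fisher test on
# [[a, b], [c, d]]
fisher_greater_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  sum(stats::dhyper(max(a, 0):min(k, m), m, nn, k))
}

# two-sided Fisher oracle: sum of all tables with probability <= observed
fisher_twosided_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  sum(probs[probs <= stats::dhyper(a, m, nn, k) * (1 + 1e-7)])
}
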