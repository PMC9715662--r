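---
title: "Tracking canonical-AID mutations: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking canonical-AID mutations: models, nulls, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aidscape` quantifies the mutational footprint of off-target
activation-induced cytidine deaminase (AID) activity in somatic SNV cohorts.
This vignette is the package's own account of the science behind each stage:
the model, the assumptions, the tunable parameters, and the places where the
design was genuinely open and a choice had to be made.

## The canonical-AID model

AID deaminates cytosine in single-stranded DNA exposed during transcription,
preferentially inside the degenerate tetranucleotide WRCY (W = A/T,
R = A/G, Y = C/T), with the targeted cytosine at the third position.
Error-prone resolution of the uracil leaves C>T and C>G substitutions. DNA
being double-stranded, the same chemistry on the opposite strand appears in
plus-strand coordinates as G>A and G>C changes with the targeted guanine at
the second position of an RGYW 4-mer — RGYW is the reverse complement of
WRCY. A somatic SNV is therefore tagged c-AID iff

* ref C, alt ∈ {T, G}, and the plus-strand 4-mer `[pos-2, pos+2)` is one of
  the eight WRCY motifs (AACC, AACT, AGCC, AGCT, TACC, TACT, TGCC, TGCT), or
* ref G, alt ∈ {A, C}, and the plus-strand 4-mer `[pos-1, pos+3)` is one of
  the eight RGYW motifs (their reverse complements).

Minus-strand motif lists are sometimes written base-by-base-complemented
(TTGG for AACC and so on). We treat that as notation only: the only reading
consistent with double-stranded DNA is the reverse-complement one
implemented here, and `classify_aid()` is property-tested to be exactly
invariant under reverse-complementing the genome and the variants. Matched
motifs are always reported in WRCY orientation.

All internal coordinates are 0-based half-open; 1-based MAF positions are
converted at I/O (`read_maf()` / `write_maf()`), which keeps every piece of
interval arithmetic uniform. Overlapping motif occurrences are all reported
(each genomic C/G is a distinct potential target), motif windows containing
N never match, and variants whose context runs off a contig are tagged
not-AID with a warning.

## The 768-channel substitution matrix

Per-sample catalogues use 768 channels: 12 uncollapsed substitution types ×
64 three-base contexts. Pyrimidine-reference channels use the frame
(−2, −1, X, +1) — the WRCY frame around the mutated C — and
purine-reference channels the mirrored frame (−1, X, +1, +2), so
reverse-complementing a catalogue maps purine channels onto pyrimidine
channels one-to-one. This uncollapsed layout is the unique natural
enumeration reaching 768 while keeping the motif's target base at the
bracketed position; the familiar strand-collapsed spectra (96 or 384
channels) can always be obtained by folding. `profile_cosine()` gives the
standard cosine similarity between any two catalogues.

## The per-sample enrichment score

No single canonical formula exists for motif fold-enrichment, so the package
adopts the construction standard in the APOBEC literature: among
strand-symmetric cytosine-deamination candidates (C>T/G and G>A/C), compare
the fraction at motif sites to the background availability of motif targets
versus cytosines, counted in a ±`flank` window around each eligible
mutation:

$$E \;=\; \frac{M_{motif}\; \cdot\; C_{ctx}}{M_{C}\; \cdot\; Motif_{ctx}}$$

with a one-sided Fisher exact test on
`[[M_motif, M_C − M_motif], [Motif_ctx, C_ctx − Motif_ctx]]` and
Benjamini–Hochberg correction across the samples of a run. `flank` defaults
to 20 bp and is configurable; 20 bp is wide enough to estimate local
composition yet narrow enough to stay local to the mutation. With no
eligible mutations the score is undefined and p = 1; with eligible mutations
but no motif hits, E = 0.

## The context-preserving null, and why its window is ±1 bp

To ask whether a cohort carries more c-AID mutations than its sequence
composition explains, every mutation is re-placed, within its own
chromosome, at a position sampled uniformly among those sharing its local
reference context; the substituted base and the alternate allele travel with
it. Per replicate this preserves each chromosome's burden exactly and the
context spectrum exactly, which is the property the significance test needs.

The half-width of the preserved context is the one genuinely consequential
parameter, and there is a sharp geometric fact behind the default. The WRCY
4-mer around a mutated C spans offsets −2..+1, and the RGYW 4-mer around a
mutated G spans −1..+2: both sit **wholly inside** the ±2 bp
(pentanucleotide) window. A shuffle that preserves the exact 5-mer therefore
preserves every c-AID flag — the simulated count equals the observed count
in every replicate, the odds ratio is identically 1, and the test is vacuous
by construction. This is not a numerical subtlety; it is provable, and the
test suite asserts it (`flank = 2` replicates reproduce the observed count
exactly).

A meaningful null for a motif must randomise at least one motif position.
The package therefore defaults to `flank = 1` (trinucleotide): the widest
symmetric window strictly coarser than the 4-mer, which preserves the R, the
mutated base and the Y while re-randomising exactly the W — the null asks
"given this many mutations in RCY-type contexts, how many would land in a
full WRCY by chance?". Pentanucleotide indexing remains fully supported for
catalogue work and for motifs wider than the window, with its degeneracy
documented and tested rather than hidden. The simulated mean is verified
against a closed-form expectation (the per-context-class motif fraction
computed by raw string inspection), and under pure-background cohorts the
per-sample significance rate stays below its nominal level.

Per-sample significance follows the bootstrap-of-odds-ratios recipe: for
each replicate, a two-sided Fisher exact test of
`[[observed AID, observed non-AID], [simulated AID, simulated non-AID]]`
yields a conditional-maximum-likelihood 95% OR interval, and the sample is
called significant when fewer than 5% of replicates have an interval
containing 1 (direction from the median OR). The replicate count defaults to
1000 at cohort scale; at least 20 are required for a call. Placement is
with-replacement across mutations within a replicate (two mutations may
collide; bias-free at genome scale), with a collision-free mode available.
The cohort-level summary is Σ observed / Σ expected with a seeded
bootstrap-over-samples percentile interval.

## Clonality

The cancer cell fraction is
CCF = VAF · (ρ·CN~t~ + (1−ρ)·CN~n~) / (ρ·m) with purity ρ, local tumour
copy number CN~t~, normal copy number CN~n~ (2 by default; set 1 for male
sex chromosomes or restrict to autosomes at `read_maf()`), and multiplicity
m estimated as the nearest integer of the expected allele count, clipped to
[1, CN~t~] — the standard construction when m is not provided. The 95%
interval is Clopper–Pearson on the VAF (computed in closed beta-quantile
form and tested against `binom.test`) pushed through the same linear map;
exactness was preferred over approximate intervals because the subclonal
rule consumes the bound directly: **subclonal iff the upper CCF bound is
below 0.95**, clonal otherwise. Point estimates are reported uncapped so
that CCF = 2·VAF holds exactly in the diploid pure-tumour case; values above
1 are a useful diagnostic of multiplicity or copy-number misspecification
rather than an error.

## Genomic distribution analyses

**Domain loads.** Mutations are counted in 25-kb non-overlapping windows;
each window is assigned to the chromatin-domain class (heterochromatin,
inactive, repressed, low-active, active) covering the majority of it, with
exact ties going to the leftward domain — a deterministic rule chosen
because straddling windows are unavoidable at fixed width. Per-class loads
are totals divided by total class length; the active/inactive ratio
summarises the transcriptional bias, with a zero inactive load reported as
an infinite ratio rather than an error.

**TSS profiles.** Mutations within ±500 kb of a TSS are placed in 10-kb bins
indexed along the transcription direction (50 bins per side; the TSS of a
minus-strand gene is its rightmost base). Profiles are aggregated per strand
class and normalised by gene count by default — equal-gene weighting stops a
single hypermutated gene from dominating; pooled counts are available by
flag. Contrasts between the TSS bin and the bins 500 kb up/downstream use
two-sided rank-sum tests over per-gene counts. The strand-reflection
symmetry of the construction is exact and property-tested.

**R-loops and expression.** Overlap labelling is half-open interval
containment; pairwise process contrasts are two-sided Fisher tests on in/out
counts. Expression coupling is Spearman correlation of per-gene AID counts
with same-gene expression across samples, within tumour type, BH-adjusted
within tumour type, with "associated" requiring adjusted p < 0.05 *and*
rho > 0; genes with constant counts or expression are skipped and reported,
and at least 3 paired samples are required.

## Composite mutations

A composite event is ≥2 nonsynonymous mutations in one gene of one sample;
it is an AID composite when at least one member is c-AID-tagged.

**Permutation null.** The cohort-level question — do multi-hit samples occur
more often than burden alone predicts? — is answered by shuffling the gene
labels across all m mutations (preserving each sample's burden exactly,
which is the minimal rewiring of the gene–sample pairing; shuffling sample
labels instead is available by flag, and only the per-sample margin is
preserved, not per-gene counts). Each replicate counts samples with ≥2
same-gene mutations, and p = (1 + #{n~i~ ≥ n~obs~}) / (N + 1). The default N
is 10,000 in tests and 100,000 at cohort scale; p-values are verified
against exhaustive enumeration on small instances and are approximately
uniform under label shuffling.

**Expected counts.** Gene-level expectations come from negative-binomial
regression (log link) of observed AID-composite sample counts on log CDS
length, GC percentage, replication time, chromatin state, assay version and
mean copy number, with offset log(mutated samples); dispersion by maximum
likelihood (`MASS::glm.nb`), Poisson fallback on non-convergence, and
constant covariates dropped rather than allowed to break the design (a fully
degenerate design reduces to the intercept-plus-offset fit). Categorical
covariates are coded with the most frequent level as reference. Gene
significance is a one-sided binomial test of observed successes among
mutated samples at rate expected/mutated, BH-corrected, significant at
q < 0.01; residue significance is a right-sided Fisher test of AID-composite
concentration at the residue versus all other mutations of the gene, same
threshold.

**Hotspots and timing.** A hotspot is a gene+protein-position with its
population recurrence (unique mutated samples). Utilization curves
accumulate, per mutation group (AID/other × composite/singleton), the
fraction of the group's mutations attributable to the top-k residues;
contrasts compare the proportion landing in the top 5% of residues
(two-proportion z, Clopper–Pearson CIs) and the fold change of median
cumulative fractions. Timing uses only events whose order is resolvable —
exactly two members with discordant clonality, the clonal member first
(phase, when available, is consumed as an input column, never inferred from
reads) — testing globally whether the more recurrent residue comes first
(two-sided binomial vs 0.5) and per residue whether it comes second
(one-sided), with at least 5 orderable events required.

## Neoepitopes

Immunogenicity %rank scores are inputs, produced upstream; the package
implements the classification layer. Samples are excluded for incomplete
HLA typing, microsatellite instability, or damaging alteration/copy loss in
a 19-gene antigen-presentation list (kept as literal configurable tokens,
including the family shorthands HSPA/HSPC/CNX). Records from genes at
≤1 FPKM are dropped; a record is immunogenic at %rank ≤ 0.5 (inclusive) and
an immunogenic clonal neoepitope (ICN) when additionally its source mutation
is clonal. A sample is "Presence" for a process when it carries ≥1 ICN
attributed to that process; presence proportions over eligible samples are
compared by a pooled-variance two-proportion z-test with Clopper–Pearson
intervals. Records without scores or clonality are excluded from the
corresponding steps and counted, never silently dropped.

## The synthetic generator: what it emulates, and what it does not

`generate_genome()` draws i.i.d. bases at a target GC (0.41, human-like);
`generate_annotations()` tiles each contig with chromatin domains (mean
100 kb, five classes), places genes (10 kb, random strand) and short G-skew
regions (600 bp, the scale of R-loop-associated intervals), and draws panel
covariates. `generate_cohort()` plants, per sample, a negative-binomial
burden (mean 2000, size 10) split 10% c-AID (uniform over WRCY/RGYW
targets), 5% APOBEC-like (TCW targets) and 85% uniform background; 70%
clonal (CCF 1) versus subclonal CCF ~ U(0.2, 0.7); purity U(0.5, 0.95);
binomial read counts at depth 80 under the diploid multiplicity-1 VAF map;
expression coupled to per-gene AID counts for 10 genes by a Gaussian copula
at Spearman ρ = 0.8 (the copula guarantees the rank correlation whatever
the margins); and neoepitope %rank scores drawn so that configured fractions
of samples (AID 30%, APOBEC 10%, background 5%) carry at least one ICN.
These defaults are fixed study conditions, not dials; every generator is
deterministic under its seed, and the emitted MAF always validates against
the emitted genome. A companion generator draws per-gene AID-composite
counts from the same negative-binomial covariate model the fitter assumes
(β = 1 on centred log CDS length, dispersion 0.5), with optional planted
enriched genes.

What the generator deliberately does **not** emulate: real COSMIC signature
catalogues (background is context-uniform, not signature-shaped; a 5-mer
weight table can be supplied), regional covariates of mutation rate
(replication timing, expression-coupled repair), transcriptional strand
bias, indels and MNVs, subclonal population structure beyond a single CCF
draw, and correlated neoepitope biology (peptides and HLA alleles are
decorative). Green tests therefore certify the statistical machinery —
recall of planted motifs, calibration of the nulls, recovery of planted
coefficients and couplings — not robustness to every property of real
tumour data.

## Numerical choices and problem sizes

Tie-breaks and degenerate inputs are handled deterministically: window/
domain ties go left; residues tie-broken lexicographically in hotspot
ranking; degenerate 2×2 replicates are skipped and counted; constant
covariates are dropped; zero expected counts abort with a named reason. All
randomness flows through explicit seeds (`withr::local_seed`), and the
pipeline manifest records seed, parameters and artifact checksums.

The validation suites run at sizes chosen to make their statistical checks
sharp while keeping the whole suite quick on one CPU: oracle equivalences on
100-kb sequences; cohort recovery on a 5-Mb genome with 50 samples × ~2000
SNVs and 100 null replicates per sample; calibration on 200 pure-background
samples (300 mutations, 30 replicates) and 100 null cohorts of 100
permutations; coefficient recovery over 100 simulated 200-gene panels;
clonality power at depth 200 with 1000 planted mutations per class.

## Known limitations

* The enrichment score's context window (±20 bp) is a convention, not a
  measured quantity; cross-cohort comparisons should hold it fixed.
* The shuffling null conditions on trinucleotide context by default; motifs
  whose information lives entirely inside the preserved window need a
  coarser index (and conversely, the ±2 bp index is vacuous for WRCY — see
  above).
* Multiplicity estimation assumes the rounded expected allele count;
  subclonal copy-number states are not modelled.
* The permutation null preserves per-sample burden but not per-gene
  marginals; genes with extreme mutability are partly absorbed by the
  negative-binomial covariate model instead.
* TSS profiles assume one TSS per gene (the gene-body end point); isoform
  structure is out of scope.
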