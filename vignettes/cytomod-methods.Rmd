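---
title: "Methods: models, parameters and design choices in cytomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cytomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomod)
library(data.table)
```

`cytomod` analyzes cytosine DNA modifications (5-methylcytosine and
5-hydroxymethylcytosine) in all three sequence contexts — CG, CHG and CHH
(H = A, T or C) — from whole-genome bisulfite sequencing, and maps 5hmC
independently from PvuRts1I digestion data. This vignette explains the
models, the tunable parameters and the choices made where the design was
genuinely open.

## Coordinates and contexts

All internal coordinates are 0-based half-open; every text report
(methylation TSVs, truth tables) is 1-based inclusive, and BED exports are
0-based half-open as the format requires. A cytosine site is
strand-specific: the reference base is C for a plus-strand site and G for
a minus-strand site. Its context is read 5'→3' on its own strand: CG if
the next base is G, CHG if the base after next is G, CHH otherwise. The
full trinucleotide window is required: a cytosine whose window runs off
the chromosome or contains an N has *undefined* context and enters no
denominator anywhere in the package. CG and CHG contexts are palindromic,
so each such cytosine has a symmetric partner on the opposite strand at
offset ±1 (CG) or ±2 (CHG); CHH has none.

## The region index

Genomic region labels are **non-exclusive sets**: one base can be Exon,
Cds, Gene and Transcript at once, and overlapping genes union their
labels. This matches the arithmetic of published region tables, whose
per-category "analyzed" counts sum to more than the genome-wide totals.
Conventions the source material leaves open, fixed here:

- *Gene* is the union of a gene's transcript spans; *Transcript* is any
  transcript span (for single-transcript genes the two coincide under set
  semantics).
- *Intragenic* marks bases inside a gene span that are in no exon and no
  intron of any transcript (gaps between transcripts of one gene).
- *Intergenic* is everything in no transcript span and no flank.
- Splice sites are the first (`SpliceSiteDonor`) and last
  (`SpliceSiteAcceptor`) `splice_site` bases of each intron in
  transcription order; the default of 2 bases matches the near-universal
  GT/AG motif. Flanks default to 3000 bases and follow transcription
  direction (Upstream of a minus-strand gene lies to its right in genome
  coordinates).

For read- or fragment-level tables (the shape used for
immunoprecipitation and digestion data) an *exclusive* assignment is
needed because the published percentages sum to 100. The default assigns
each interval by its midpoint with the priority SpliceSiteDonor >
SpliceSiteAcceptor > Exon > Intron > Intragenic > Upstream > Downstream >
Intergenic; an any-overlap mode (each overlapped label counted once) is
available.

## The o/e CpG ratio

For a transcript, o/e = observed CG dinucleotides divided by
n~C~·n~G~/L, the count expected if C and G were placed uniformly at
random; genes average transcripts weighted by span length. The sequence
used is the genomic transcript span (introns included) — the published
definition does not resolve spliced vs genomic sequence, and the genomic
span is the quantity that reflects germline CpG depletion by methylation.
A transcript with no C or no G has no expected count and returns `NA`.

## Bisulfite mapping

Bisulfite conversion makes unmodified C read as T, so mapping compares
reads and genome in reduced alphabets: C→T for plus-strand interrogation
(read in sequencing orientation) and G→A for minus-strand interrogation
(read reverse-complemented first). Seeding is exact on the first
`k = 20` reduced bases; extension is ungapped and counts reduced-alphabet
mismatches with a ceiling of 2. A read is reported only when exactly one
location attains the best mismatch count; ties are unmapped. This mapper
is intended for desk-scale genomes (it holds a hash of all genome k-mers
in memory); for production data an external bisulfite aligner's SAM output
can be ingested with `read_sam()`, which takes the interrogated strand
from an `XG`-style tag when present and from flag 16 otherwise. Paired-end
mates are treated as independent single-end reads, and duplicate
collapsing is not performed by default.

## The three-level caller

The caller deliberately restricts methylation levels to
m ∈ {0, 0.5, 1} — unmethylated, hemi-methylated, methylated — trading
continuous-fraction estimates for sensitivity at low depth, the same
trade a genotype caller makes for diploid genotypes. Each pileup
observation at a site is modeled as Bernoulli:

$$P(\mathrm{C} \mid m) = m(1-e) + (1-m)\,\bigl(c(1-e) + (1-c)e\bigr)$$

with `c` the bisulfite non-conversion probability (default 0.005; it is a
configuration constant, not estimated from spike-ins, because library
chemistry that amplifies only fully converted molecules keeps it small
and stable) and `e` the per-base error from the read's phred quality,
floored at 10⁻⁴ so a single miscalled high-quality base cannot dominate a
likelihood. The posterior over the three levels uses a uniform prior and
is computed in log space; ties break toward the lower level
(conservative). Call quality is Q = −10·log₁₀(1 − posterior), capped at
255; a call passes at Q ≥ 20 and depth ≥ `min_depth` (default 1). There is
no base-alignment-quality (BAQ) analogue: the pileup's own
context-mismatch filter plays that role.

Two read-level filters from bisulfite practice are applied in the pileup:
an observation is dropped when the read has a reduced-alphabet mismatch
within ±2 bases of the cytosine, and optionally a whole read is dropped
when three or more consecutive CHH cytosines on it are all C-retained
(`chh_filter`, default off for the unbiased mode — that filter
systematically removes genuinely modified non-CG reads, which is the bias
this package exists to avoid; it is available for the conservative mode).
In the consecutive-run rule only CHH cytosines count: retained cytosines
in other contexts neither extend nor break a run.

The symmetric-methylation summary reports, per context, the share of
modified passing sites whose partner is also a modified passing call; the
denominator is **all** modified sites whether or not the partner is
covered, matching the published table arithmetic (54,120 / 253,041 = 21%).

## Pvu-seq inference

PvuRts1I cuts at a fixed small offset 3′ of a hydroxymethylcytosine:
11–13 nt on the top strand, 9–10 nt on the bottom strand. Inference
inverts this: a top-strand cut at p supports every position p − d
(d ∈ {11,12,13}) whose plus-strand base is C, a bottom-strand cut at p
supports p + d (d ∈ {9,10}) where the minus strand has a C. A cut
supports *all* cytosines in its window — the simplest rule consistent
with a fixed narrow offset range; no probabilistic weighting is
attempted. Sites with support ≥ 2 (default) are called, which suppresses
background singletons. The naive peak caller (sliding-window mean over
base coverage, threshold at `min_fold` × genome-wide mean, merged into
maximal windows) is a stand-in for model-based peak callers, adequate for
synthetic data; peak concordance is the fraction of one peak set
overlapping the other.

## Differential statistics

Per-gene differential modification uses Fisher's exact test on
(modified, unmodified) × (sample A, sample B) with Benjamini–Hochberg FDR
across genes. Gene-set enrichment offers two modes. *Fixed* is the
standard Wilcoxon rank-sum of member vs non-member scores. *Greedy*
interprets the rank-sum-with-cutoff-search idea: scan every prefix cutoff
k of the ranked list and compute the one-sided rank-sum statistic of set
membership against the dichotomized top-k indicator — with binary values
the tie-corrected rank-sum reduces to the standardized hypergeometric
count z(k), so the scan finds the cutoff where members are most
concentrated. Because the cutoff is searched, the naive best-cutoff p is
anti-conservative; significance is therefore assessed by label
permutation (default 10,000 permutations) of the max-z statistic. The
package demonstrates both facts as properties: naive greedy rejections
inflate well above the nominal 5% on null data, and the corrected version
returns to nominal. Quantile normalization follows the classic recipe
(rank-wise mean of sorted columns mapped back through ranks), with tied
values sharing the mean of the reference values their ranks span.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated against:

- **Genome and genes.** Uniform-random background sequence; 2–4-exon
  genes placed without overlap, separated by at least one flank length.
  Genes split into two CpG classes rewritten toward o/e 0.6 and 1.2 — the
  bimodal structure typical of insect genomes where low-o/e genes are the
  historically methylated ones. Thinning keeps each CG with probability
  3t/(4−t) and boosting converts post-C non-G bases with probability
  4(t−1)/(3(4−t)), both solved so the rewritten sequence lands near the
  target t. Intron boundaries receive canonical GT...AG motifs in
  transcription order so splice-junction analyses see realistic
  junctions.
- **Methylome.** Site states (5mC/5hmC) are drawn from a region×context
  rate table whose defaults reproduce the European-honey-bee-like
  pattern: exon CG 6.26%, intron CHH 3.99% (half of it 5hmC), intron CHG
  1.08%, with the remaining cells at their published magnitudes and 5hmC
  concentrated in intronic/intergenic non-CG sites. CHG/CHH sites draw
  independently. Complete CG pairs draw *jointly*: both strands modified
  with probability s·p and each single strand with probability (1−s)·p,
  so each strand-site keeps its marginal rate p while a fraction s
  (default 0.21, the published symmetric share) of modified CG sites sit
  in both-modified pairs. A naive "co-modify the partner afterwards" rule
  would inflate the minus-strand marginal by ~s·p(1−p) and was rejected
  for that reason; when p is so large that the marginals force more
  symmetry (b ≥ 2p−1), the both-probability is clamped to the feasible
  bound. Modified sites take level 1, or 0.5 with probability
  `hemi_fraction` (default 0.1).
- **Reads.** 76-base reads drawn uniformly from both strands at the
  configured coverage. Per cytosine on the origin strand: molecule
  modified with probability = level, unmodified molecules convert with
  probability 1−c (c default 0.005), then every base suffers a symmetric
  miscall with probability e (default 0.001) at a constant phred quality
  (default 30). No indels, no quality profiles, no PCR duplicates — the
  caller's scope is substitution-level evidence.
- **Digestion and pulldown.** Each 5hmC site emits Poisson(10) fragment
  ends at offsets drawn uniformly from the strand's offset set;
  immunoprecipitation fragments are 300–600 bp (uniform), containing
  their site at a uniform internal offset, mirroring sheared-chromatin
  pulldowns. Background rates for both are free parameters (the source
  material does not quantify them; defaults are 0 for digestion tests and
  10⁻⁵ per base where realism matters).

Determinism: every generator stage seeds R's RNG with the configured seed
plus a fixed stage offset (+0 genome, +1 methylome, +2 reads, +3
digestion, +4 pulldown). This makes each stage individually reproducible
given (seed, config) — a property a single shared stream cannot provide,
since re-running one stage would shift all later ones.

What passing tests on this generator do **not** show about real data: the
background sequence has uniform composition (no repeats, no low-complexity
regions, so mapping is easier than in real intronic DNA); bisulfite
non-conversion is homogeneous rather than structure-dependent; base
qualities are constant; and annotation is exact. Results on real genomes
depend on mapping quality in repetitive regions in ways the simulator
cannot probe.

## Numerical choices

- Percentages are rounded half away from zero to 2 decimals (the printed
  table convention), with an epsilon guard against binary representation
  artefacts; `analyzed = 0` yields an `NA` sentinel, never a division
  error.
- Likelihoods are aggregated per (site, quality) count pair and summed in
  log space; posteriors are normalized by the max-shift trick. Levels and
  posteriors match plain-product enumeration to 10⁻¹²; Q agrees to ~10⁻⁴
  relative because −10·log₁₀(1−posterior) amplifies last-ulp differences
  when the posterior is within 10⁻¹⁰ of 1.
- Metagene features shorter than the bin count assign bases by
  proportional rounding; minus-strand genes reverse bin order via
  coordinate reflection.
- The mapper rejects candidate placements spanning chromosome boundaries
  explicitly (chromosomes are concatenated with N spacers for indexing).

## Problem sizes

The test suite validates the end-to-end pipeline on a 1 Mb genome with 60
genes at 20× coverage (~263k reads, ~30 s), chosen as the smallest scale
at which the binomial 3-SD recovery bands around the planted rates are
meaningfully tight; unit tests use 1–100 kb fixtures. The acceptance
script uses the same sizes.

## Known limitations

- The mapper is ungapped and single-seeded; indel-bearing reads are lost.
- Methylation is called per strand-site at three levels only; continuous
  fractions and SNP-aware calling are out of scope by design.
- The greedy enrichment procedure is an interpretation of a
  cutoff-searching rank-sum method whose exact published form is not
  recoverable; it is labelled as such and validated by its own
  permutation calibration, not against an external implementation.
- Per-transcript multi-counting of summary rows (which would make a
  Transcript row exceed a Gene row for single-transcript genes) is not
  reproduced; labels are sets over positions.
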