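---
title: "Methods: assembly-based PAV discovery and population scans in panpav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly-based PAV discovery and population scans in panpav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

panpav implements a desk-scale pangenome analysis workflow for a selfing
crop: structural variants (SVs) are read off whole-genome-alignment synteny
nets, merged into a nonredundant population set of presence/absence
variants (PAVs), annotated against transposable elements (TEs) and gene
models, and carried into population-genetic scans and GWAS post-processing.
This vignette records the models, the operator definitions behind each
step, the tunable parameters, and what the synthetic data generator does
and does not emulate.

## Coordinates and containers

All internal coordinates are 0-based half-open (BED convention); VCF and
GFF3 emission converts to 1-based at the boundary. Genotypes are diploid
ALT-dosage codes 0/1/2 with `NA` for missing; the package targets selfing
material, so the generator emits homozygous calls (`0/0`, `1/1`, `./.`) by
default and heterozygotes only via the `het_rate` option. Heterozygous
calls are tolerated on input everywhere and enter the LD `Het` filter and
the Weir–Cockerham `h` terms.

## SV calling from alignment chains and nets

Anchors are gapless blocks: a PAF record's `cg:Z:` CIGAR is split at every
I/D run (`read_paf`), so downstream calling is pure coordinate arithmetic.
`chain_blocks` runs sparse dynamic programming over colinear same-strand
blocks, scoring `sum(n_matches) - (gap_open + gap_extend * (ref_gap +
query_gap))` per join. Two parameters matter:

* `gap_open = 10`, `gap_extend = 0.01` — kept deliberately small so that
  short anchors (down to tens of bp) between nearby events are retained;
  with a large open penalty the DP skips a small anchor between two
  adjacent deletions and fuses them into one complex call.
* `max_gap = 10000` bp — the largest within-chain gap on either axis. This
  is the net's resolution knob: deletions/insertions up to `max_gap`
  appear as within-chain gaps; larger events split chains and only
  inversions are recovered from between-chain structure.

`build_net` is greedy, kent-style: chains are accepted by descending score
(ties broken by reference chromosome and start for determinism) wherever
their reference span and query span are both unoccupied; partially
overlapping chains are trimmed at block granularity and dropped when the
trimmed reference span falls below `min_span = 10000` bp. The single
10-kb rule is applied uniformly to all accepted chains; consequently an
inversion is only detectable when it is at least `min_span` long, and the
generator draws inversions of 12–40 kb.

`call_svs` classifies each within-chain adjacency by its reference gap
`g_r` and query gap `g_q` against `min_size = 51` (events must *exceed*
50 bp): DEL when only `g_r` passes, INS when only `g_q` passes (sequence
extracted from the query FASTA, reverse-complemented on minus chains), CPX
when both pass. Two operator definitions close gaps the published
tooling leaves unspecified:

* **Tandem duplications.** A duplication carried by the query presents at
  net resolution as an insertion whose sequence tandem-repeats the
  immediately preceding aligned query segment. `call_svs` therefore
  reclassifies an INS as TDUP when the inserted sequence matches that
  segment at `tdup_identity = 0.8` or better, placing the reference
  interval over the duplicated copy. The comparison is staged: Hamming
  identity first (a lower bound on edit identity, so a clear pass or a
  clear miss needs no alignment), exact edit distance only in the
  ambiguous band. A query interval stepping *backward* over already
  aligned territory — impossible in chains built here, but possible in
  externally produced block lists — is likewise reported as TDUP.
* **Inversions.** A minus-strand chain flanked by plus-strand chains over
  colinear query territory (tolerance 100 kb) is an inversion over its
  reference span. Nested or rearranged configurations fall out of this
  definition and surface as complex or unaligned territory.

Filtering removes DEL/INS whose reference footprint (INS: junction point)
touches an assembly gap or centromere interval, and inversions whose
reference interval expanded by 10 bp touches a gap. Both alignment
directions can be called by swapping reference and query — the package's
reciprocity property guarantees each DEL converts into an INS of the
identical sequence — but calls are taken from the reference-vs-query
direction; the swapped direction is a confirmation device, not a second
call set, since no published reconciliation rule exists.

## PAV merging, genotyping and evaluation

Deletions (and inversions) from different accessions are linked when their
reciprocal overlap — `|intersection| / max(len_a, len_b)`, i.e. the
smaller of the two per-length ratios — exceeds 0.90; insertions are linked
when their junctions are < 10 bp apart and their sequences exceed 80%
global identity (`1 - edit_distance / longer_length`: symmetric,
deterministic, no alignment heuristics). Whether the published 90% rule
is reciprocal or one-sided is not stated; reciprocal is the default
because it stops a long deletion from absorbing short ones, and
`merge_params(mode = "one_sided")` exposes the alternative. Clusters are
single-linkage connected components of the link relation; a brute-force
transitive-closure oracle defines correctness on small inputs in the test
suite. The representative is the member linked to the most accessions
(ties: longest, then leftmost) — the selection rule is unstated in the
field's tooling and recorded here as a package convention. Inversions are
clustered but excluded from the PAV genotype matrix, which covers
deletions and insertions only.

Assembly genotyping calls an accession *present* when it contributed a
linked member, *absent* when its net covers the representative interval,
and *missing* when the interval falls in uncovered net territory.
Evaluation against a truth set reuses the merge-link criterion per
subtype with greedy one-to-one matching by overlap quality, reporting
precision, recall and F1.

## Annotation

A PAV is TE-derived when at least 90% of its footprint (union of possibly
overlapping TE intervals, not their sum) is TE sequence; the boundary is
inclusive. A deletion's footprint is its reference interval; an
insertion's TE content is measured on the inserted sequence against the
TE library (the coordinate system the published analysis used is
unstated). Genic context is assigned with precedence coding > intron >
upstream2kb > downstream2kb > intergenic, with strand-aware 2-kb flanks
(strand-awareness is an assumption; the alternative was not described).
Gene impact is an operator definition: *lost* when carried deletions
jointly cover 100% of CDS bases; *pseudogenized* when a complete exon is
deleted, the CDS length change is not divisible by 3, or a start/stop
codon is removed; otherwise intact.

The expression screen substitutes a two-sided Wilcoxon rank-sum test with
Benjamini–Hochberg FDR for a negative-binomial count model, keeping the
decision thresholds (fold change at least 1.5, adjusted P at most 0.05);
fold changes add a 0.1 pseudo-count to group means so silenced genes
(FPKM < 1) produce bounded ratios. Groups below 3 accessions are flagged
untested.

## Gene families and diversity

Occupancy classes over N genomes: core (N), softcore (N−2..N−1),
dispensable (2..N−3), private (1); the thresholds generalize the
32-genome instantiation, and for small N where the windows collide the
documented precedence is core → softcore → private → dispensable.
Rarefaction draws 100 uniform subsamples per size without replacement.
Alignment diversity is `pi = D / L / (N (N - 1) / 2)` with L the count of
gap-free columns ("conserved alignment" is interpreted as gap-free; no
definition is given at the source) and D the total of pairwise mismatches
over those columns — the `/pairs` denominator implies pairwise mismatch
counting rather than segregating sites.

## Windowed scans and the sweep compositor

`windowed_pi` follows the VCFtools convention: per-site `h = 2c(n−c) /
(n(n−1))` summed over the sites in a 20-kb window stepped by 2 kb,
divided by the window length in bp; windows with no usable site are
missing. `windowed_fst` implements the two-population Weir–Cockerham
(1984) variance components with the weighted window estimator
`sum(a) / sum(a+b+c)`; the estimator may be slightly negative under the
null, and fixed differences give exactly 1 (both covered by oracle
tests). The π-ratio track is wild/cultivated per window, flagged missing
(not infinite) on zero or missing denominators.

XP-CLR is consumed, never computed: any per-window score track can be
smoothed over 100-kb windows stepped by 10 kb (mean of input-window
midpoint values) and thresholded. The smooth-then-threshold order is the
default because the source wording is ambiguous; the scan drivers accept
either order by applying `top_quantile_regions` before or after
`smooth_track`. The top-5% threshold is the k-th largest value with
`k = max(1, floor(q n))` — an order-statistic quantile with no
interpolation, inclusive at the threshold, so a constant track
degenerates to selecting everything (intentional and documented).
Selected windows merge into regions, and the sweep set is the base-pair
intersection of all supplied evidence tracks.

LD decay filters sites at MAF ≥ 0.01 and heterozygous fraction ≤ 0.8,
then averages squared dosage correlations (composite LD, appropriate for
unphased data) per distance bin within 500 kb. 4DTv extraction keeps SNPs
at third positions of fourfold-degenerate codon families, strand-aware;
a SNP under multiple CDS must be fourfold in all of them, and genes whose
CDS length is not divisible by 3 are skipped with a warning.

The significance test behind wild/cultivated PAV frequency shifts is not
stated at the source; the package uses a two-sided Fisher exact test on
the called carrier/non-carrier table with BH-FDR at 0.05 and flags PAVs
with fewer than 5 called genotypes per group untested.

## GWAS post-processing

The genome-wide threshold is `0.05 / n_tests`. Variant presets: SNPs at
MAF ≥ 0.05 and missing ≤ 0.1; PAVs at MAF ≥ 0.05 and missing ≤ 0.5.
Candidate regions implement the iterative rule — extend 200 kb from the
last significant variant until no new significant variant appears — via
its single-linkage equivalent (gap ≤ 200 kb), with the literal iterative
scan kept as a test oracle over random layouts; the "from the last
significant SNP" reading was chosen where the wording allows measuring
from the region edge. Mixed-model association is consumed as a
variant→P table; `assoc_scan` is a plain dosage score test used only to
drive synthetic end-to-end runs and corrects for no population structure.
A region is *reliable* when overlapping regions appear in at least two
environment/year result sets.

Gene haplotypes are allele strings over the variant sites within the gene
body ± 2 kb; accessions missing or heterozygous at any site are excluded,
groups are numbered by descending size (the published numbering
convention is unstated), and groups under 10 accessions are flagged
small. Phenotype differences use Kruskal–Wallis with a Nemenyi all-pairs
post-hoc (mean ranks on the Studentized range distribution, tie
correction through the pooled rank variance) and a compact letter display
built from maximal runs of pairwise non-significant groups in mean-rank
order; two groups fall back to a two-sided Wilcoxon rank-sum test. A
constant phenotype short-circuits to H = 0, P = 1. Term enrichment is an
upper-tail hypergeometric test with BH-FDR.

## The synthetic data generator

The generator exists to give every pipeline stage inputs with known
ground truth; all of its parameters are package choices, since no
generative model is published for the system it emulates.

* **Ancestral genome.** Uniform-composition sequence (GC 0.46) with one
  centromere per chromosome (8% of its length), N-run assembly gaps, a TE
  library of 5–20 templates (LTR 1.5–4 kb, DNA 0.3–1.2 kb) whose placed
  copies diverge 1–5% from their template, and 3–6-exon gene models with
  CDS lengths divisible by 3. Features are packed into free segments by
  random slack distribution, so over-dense requests fail with a capacity
  error rather than degrading.
* **Derived accessions.** Implanted events per accession default to 15
  DEL, 15 INS, 3 INV, 4 TDUP, 3 CPX. DEL/INS lengths are log-uniform
  60–8000 bp; 68% of deletions remove an existing TE copy wholesale and
  the same fraction of insertions are fresh TE-library copies (so
  TE-derived variants recur across accessions above the 80% identity
  merge rule, matching the published 68.3% TE-derived share); inversions
  span 12–40 kb (net resolution, see above); events keep 2 kb apart and
  avoid gaps, centromeres and chromosome ends. `simulate_pangenome`
  draws one population pool of events (2.5× the per-accession counts)
  with Beta(0.8, 1.2) frequencies and lets accessions carry pool events
  independently, so shared alleles are identical by descent.
  `truth_alignment_blocks` emits the exact anchors a perfect aligner
  would produce; an external aligner is deliberately not required.
* **Population.** Wild allele frequencies follow a U-shaped Beta(0.5,
  0.5); the SNP count is calibrated so the realized expected
  heterozygosity matches the wild diversity target (6.7e-4 per site),
  and cultivated frequencies derive by Balding–Nichols drift with
  `F = 1 - 4.2e-4/6.7e-4`, so the cultivated panel retains the target
  diversity fraction in expectation. One region (30–40% of chromosome 1)
  receives 5-fold stronger cultivated drift — the ground truth for the
  sweep compositor. PAV frequencies are skewed low, with 40 PAVs set to
  0.10 (wild) versus 0.70 (cultivated). Phenotypes are sums of causal
  effects plus Gaussian noise scaled to the heritability (0.5 default;
  1.0 gives the genetic score exactly). FPKM is log-normal per gene with
  carriers of a linked PAV multiplied by 0.3.
* **Not emulated.** Coalescent genealogies, recombination maps and hence
  genuine LD decay with distance; gene conversion; read-level errors or
  FASTQ output; population structure beyond a single drift parameter per
  subpopulation. Passing tests therefore certify the *operators* —
  coordinate arithmetic, estimator algebra, threshold logic, recovery
  under known truth — not robustness to alignment noise or demographic
  complexity in real data.

## Problem sizes and determinism

The shipped analyses and acceptance checks run on a 5-Mb, 5-accession
pangenome (~200 implanted events) and a 2-Mb, 230-accession population
(~5,000 SNPs, 300 PAVs) — sizes at which every stage completes in seconds
to a couple of minutes on one core while leaving dozens of windows and
events per statistic. All randomness flows from one master seed through
named per-task generators (`with_seed`), so adding a generator never
perturbs another's draws, and identical configurations produce
byte-identical output files.

## Known limitations

Netting is greedy, not optimal interval scheduling; pathological chain
sets can in principle be netted sub-optimally. TDUP/CPX delimitation is
an operator definition, and complex nested rearrangements surface as CPX
or unaligned territory. The expression screen's rank test is less
powerful than a count model at small n. The dosage score test must not
be used for real association scans — it corrects for nothing. LD values
from the generator reflect drift only and should not be read as decay
curves.
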