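---
title: "Models and methods behind srnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`srnapipe` characterizes small RNA sequencing libraries from germline
tissue: it preprocesses and maps reads, profiles them by annotation
category and size, discovers miRNA and mirtron loci de novo, tests
differential expression with a negative-binomial model, and characterizes
piRNAs and endo-siRNAs (clusters, strand bias, positional nucleotide bias,
ping-pong diagnostics, dominant reads, 5' half-tRNAs). This vignette
explains the models, the parameters that matter, the numerical choices, and
what the synthetic-data module does and does not emulate.

## Read preprocessing and mapping

Raw reads are the insert followed by a 3' adapter. The insert is everything
before the leftmost exact occurrence of an adapter prefix of at least
`min_overlap` (default 8) nt; reads with no such occurrence are discarded
rather than kept untrimmed, because a sequencing run longer than the longest
admissible insert must read into the adapter — its absence marks an
artifact. Inserts are kept in the closed 17–36 nt window (the analysis
window; the wider bench-side size selection is irrelevant downstream),
collapsed to unique sequences with per-library counts, and mapped to the
genome with zero mismatches on both strands, reporting *all* placements and
a per-sequence `hit_count`. Downstream stages choose unique-only or all-hit
views explicitly; reads containing N are dropped with a count. Abundances
are normalized as reads per million mapped (RPM): `raw * 1e6 / mapped
total` per library. All internal coordinates are 0-based half-open; GFF3
(1-based inclusive) and BED are converted at I/O boundaries.

## Annotation profiling

Each mapped read receives exactly one category: the highest-precedence
category overlapped (>= 1 nt, either strand) by any of its placements,
under the fixed precedence miRNA > rRNA > tRNA > TE > 3'UTR > 5'UTR >
exon > intron > unannotated. Specific small RNA sources outrank generic
gene structure; each read is counted once regardless of its number of
placements, so category totals sum to the mapped total (the policy is
switchable). Size-by-category profiles, 3'UTR mapping bias per read length
(the fraction of each length's mapped reads with a sense placement on an
mRNA, and fully inside a 3'UTR), and size profiles inside
convergent-transcript overlaps are computed from the same assignment. A
length is called a size peak when its count is at least 1.5x each
neighbour's and at least 5% of the histogram total (both configurable).

## miRNA discovery

The fold is a maximum base-pairing secondary structure (Watson-Crick plus
G-U wobble, minimum hairpin loop 3, no pseudoknots), computed by interval
dynamic programming with a deterministic traceback (pair the 5'-most base
first; among optimal partners take the 3'-most). Base-pair maximization
replaces thermodynamic folding deliberately: it is dependency-free,
deterministic, and exactly checkable against exhaustive enumeration of all
nested structures; every discovery entry point takes the fold as an
internal step, and an external folder can be substituted where needed.

Candidate loci are read stacks: distinct 5' positions of 18–26 nt reads
with at least `min_stack = 5` summed reads across libraries, extended by
`pad = 70` nt. The padded window is folded once; every candidate star read
in the window (disjoint from the mature, with at least `min_star_reads = 2`
supporting reads — one stray read is not star evidence — and at least half
its own arm's modal count, because the duplex should consist of each arm's
dominant product rather than a rare length variant) is tested for the
duplex geometry: in the fold, the partner of the mature 5' end must sit
exactly 2 nt inside the star 3' end and the partner of the star 5' end
exactly 2 nt inside the mature 3' end, and at least 60% of mature bases
must pair with bases inside the star interval ("pairs with the star on the
stem" — the two end conditions alone can be satisfied accidentally by an
unrelated read). A locus is reported iff this duplex exists, the 5' ends
are homogeneous (modal 5' fraction >= `tau5 = 0.9`, and at least the modal
3' fraction) on the anchor arm — and on the star arm whenever it carries at
least 25 reads, enough depth to judge raggedness — and at least two
libraries support it. Windows overlapping known precursors are excluded and
one locus is kept per precursor span. `tau5 = 0.9` reflects the very tight
5' ends Dicer/Drosha products show in practice; raising it never reports
more loci.

Mirtrons are evaluated on introns shorter than 100 nt: the intron span is
folded, the 5'-arm mature stack must pass homogeneity and multi-library
support, and a star with valid duplex geometry completes the locus; a
missing star is tolerated when at least `tau_u = 50%` of mature reads end
in an untemplated 3' U (terminal read U where the genomic continuation on
the read strand is not T). Discovered loci are chained into genomic
clusters at <= 10 kb, flagged for repeat-track overlap (>= 1 nt), and
partitioned against a prior catalog (previously reported iff the precursor
overlaps a prior precursor on the same strand or the mature sequence
matches exactly).

## Differential expression

Size factors follow the median-of-ratios rule: per sample, the median over
all-positive loci of the ratio of the sample count to the locus geometric
mean (library-size ratios as fallback). The two-group test is exact-style
negative binomial. Per locus with summed condition counts $k_A, k_B$ and
$T = k_A + k_B$:

* dispersion $\alpha$ is estimated by method of moments from the pooled
  *within-condition* variance of size-factor-normalized counts (so a real
  between-condition difference cannot inflate its own dispersion), with the
  chi-square median correction $\mathrm{df}/\chi^2_{0.5,\mathrm{df}}$ and a
  floor of $10^{-8}$;
* each condition total is modelled as negative binomial with mean
  $\mu_c = \hat q \sum_{s \in c} f_s$ (where $\hat q = T / \sum_s f_s$) and
  variance $\sum_{s \in c} (\mu_s + \alpha \mu_s^2)$, reducing to Poisson
  at the floor;
* the two-sided p-value sums the probabilities of all splits $(a, T-a)$
  whose joint probability does not exceed the observed split's, normalized
  by the total over splits.

No information is shared across loci (no dispersion trend or shrinkage).
The price is documented honestly: with plug-in per-locus dispersions the
test is anti-conservative at low replication (about 4% rejections at
nominal 1% with 3 replicates per group in our null simulations). The
calibration experiment in the test suite therefore uses 10 replicates per
condition, where the rejection rate sits near 1.5–2%; the median
correction keeps the extreme tail (which drives false discoveries after
Benjamini–Hochberg adjustment) controlled. Multiple testing uses
Benjamini–Hochberg; "strong" sex bias is operationalized as adjusted
p < 0.01 with fold >= 4 (both configurable, since the source analyses leave
"strong" undefined). Expression classes come from average-linkage
hierarchical clustering of log10(normalized + 1) values over loci with a
raw count strictly above 20 in at least one library, cut at k = 3.
Chromosomal enrichment of biased loci uses a two-sided Fisher exact test
computed by explicit hypergeometric enumeration of all tables with the
observed margins.

## piRNA and endo-siRNA characterization

Reads with a 5' U or an A at position 10 (read space, 1-based) form the
piRNA-enriched fraction. Clusters are called from unique-mapping selected
reads: 5' positions supported by at least `min_pos_reads = 2` reads seed
chains, consecutive seeds within `max_gap = 500` nt are linked, and
terminal seeds more than 10x the median intra-chain spacing from the chain
body are trimmed. Seeding and trimming are needed because a uniform
degradation background at realistic depth would otherwise percolate entire
chromosomes at a 500-nt gap; recurrent 5' ends are the signature of
genuine piRNA production. A chained locus is reported iff its span exceeds
100 bp, the mean length of its distinct supporting sequences lies in
[26, 27] nt, and the mean per-sample read count exceeds 50. Two
interpretive choices are deliberate: the span threshold follows the
"larger than 100 bp" reading (kilobase-scale clusters are the object of
interest), and the abundance gate operates on read counts, which the
sub-threshold wording ("30 reads") implies — at modest library depth a
normalized-abundance gate degenerates (one read in a 28k-read library is
already ~35 RPM). Mean read length is taken over distinct sequences rather
than read copies so that a single hyper-abundant sequence (see dominant
reads below) does not move a locus out of the window.

TE profiles count reads per family, length and orientation relative to the
TE strand, weighting each placement by `count / hit_count`; the 29:27
ratio uses a pseudocount of 1. Positional nucleotide bias is scored per
position and base as the signed `-log10` exact binomial tail against a
background probability (over-representation positive, under-representation
negative, computed in log space so extreme tails do not underflow); the
background defaults to uniform 0.25 and should be set to the source feature
space's composition when that is known. The ping-pong histogram weighs
every opposite-strand pair on a chromosome by the product of normalized
counts at offsets 1–20, where the offset is `five_minus - five_plus + 1`
(the 5' end of a minus-strand alignment is its rightmost coordinate), so a
perfect ping-pong pair scores 10; `z10` compares the offset-10 mass with
the mean and standard deviation of the other offsets. A caveat worth
knowing: U1 and A10 composition biases alone enrich offset-10 coincidences
(a sense A10 and an antisense U1 read anchor the same genomic base), so
`z10` should be read as evidence of 5'-overlap structure only relative to
an appropriate composition null. Dominant reads are sequences at least
100x more abundant than the next distinct sequence at their locus. 5'
half-tRNAs are 32-nt reads whose 5' end coincides (± 1 nt) with a tRNA 5'
end on the tRNA strand; fold changes contrast two named conditions on
normalized counts.

## The synthetic-data module

`blueprint_germline()` + `build_genome()` + `simulate_library()` emulate
the *structure* of a seven-library germline study on a three-chromosome
genome (two autosomes and an X, ~390 kb): known and novel miRNA hairpins
(a quarter of the novel ones X-linked and testes-enriched), decoy hairpin
loci whose reads violate either 5' homogeneity or the 2-nt overhang
geometry, mirtron host genes with sub-100-nt hairpin introns, TE families
with two diverged copies each (one family 29-nt-dominant on the antisense
strand), convergent cis-NAT pairs producing exactly-21-nt siRNAs from the
overlap, tRNA genes producing 32-nt 5' halves (30-fold down in
pre-vitellogenic ovaries), mRNAs with 3'UTR-biased sense piRNAs, piRNA
cluster regions averaging 26–27 nt with planted dominant 29-mers, and a
uniform random degradation background. All randomness flows from one
integer seed through deterministic per-component sub-seeds; identical
inputs give byte-identical FASTA/FASTQ/TSV outputs.

Hairpins are synthesized as 5' arm + loop + 3' arm with the 3' arm the
reverse complement of the 5' arm at a 10% interior mismatch rate (at least
two mismatches — perfectly complementary arms would make arm reads map to
both strands and create mirror loci; ends are protected so the duplex
register is anchored; loop bases are drawn from A/C so the loop cannot
extend the stem and appended U tails stay untemplated). Because flanking
genomic sequence can tie-break a maximum-pairing fold into a shifted
register, `build_genome()` verifies each planted hairpin's duplex geometry
in the same padded window discovery folds, re-synthesizing (from derived
seeds) until it holds. Sequence biases are planted exactly: each read's
flag combination (U1/A10 on either strand) is realized by sampling the 5'
position from the set of genomic positions carrying exactly those bases,
so a planted fraction of 0.85 is the realized expectation, not a lower
bound. Ping-pong partners are planted by construction — a secondary sense
read's 5' end sits exactly 10 nt inside its antisense partner's 5' end —
which also makes the partner's position-10 base an A automatically,
mirroring the biology of the amplification loop.

What the generator does **not** emulate: sequencing errors and quality
variation (qualities are constant), real genome composition and repeat
structure, nested or fragmented TE copies, transcription-level coupling
between classes, and per-class abundances of any real library (the source
material gives none; the defaults — roughly 29k reads per library across
the eight classes — are round numbers chosen to exercise every stage at
desk scale). Passing the planted-truth suites therefore demonstrates that
the *computations* are correct and that the discovery criteria separate
compliant from non-compliant loci under controlled conditions; it does not
certify performance on real libraries, where adapter chemistry, annotation
quality and abundance skew dominate.

## Numerical and design notes

* Folding: window <= 400 nt; ties broken deterministically as above;
  discovery folds each padded stack window once (~165 nt, O(n^3) in
  compiled code).
* Exact tails: binomial and hypergeometric tail sums use log-space
  accumulation; two-sided sums include ties with the customary
  (1 + 1e-7) tolerance.
* Degenerate inputs: empty libraries yield empty (typed) results;
  all-zero loci get p = 1; zero biased loci give an undefined percentage
  with p = 1; families or lengths with no reads are reported missing, not
  zero.
* The problem sizes in the test and acceptance runs (~390 kb genome, ~29k
  reads per library, 2000-locus null simulations, 10 replicates per
  condition in calibration experiments) were chosen as the smallest scales
  at which every planted signal is comfortably detectable by the stated
  criteria.
* The pipeline (`run_pipeline()`) caches stage state on disk, records
  every effective parameter, input checksums and the seed in
  `run_log.yaml`, and is byte-identical across reruns with the same
  configuration.
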