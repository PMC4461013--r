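---
title: "Models and methods behind spliceops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceops)
```

`spliceops` detects and compares splice junctions, polyadenylation sites and
cassette exons from short-read RNA-Seq data. This vignette explains the
models each stage implements, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the simulator
does and does not emulate.

## Coordinates and the annotation model

All internal coordinates are 0-based half-open; GTF input (1-based
inclusive) is converted at the I/O boundary and converted back on write.
This makes interval arithmetic (lengths, splits, unions) free of ±1
adjustments. Exons are ranked 1..k in transcript 5'→3' order — ascending
genomic order on `+`, descending on `-` — and all junction, trio and
flank definitions are expressed in ranks, so minus-strand transcripts need
no special-casing downstream. Transcripts with overlapping exons are
rejected outright rather than merged: the skipping combinatorics below
assume disjoint exons, and silently repairing a malformed model would change
its junction set. Both attribute dialects found in the wild
(`key "value";` and `key=value`) are accepted.

## Junction library

For a transcript with k exons, the k−1 adjacent exon pairs give the known
junctions. Novel junctions are produced by skipping every contiguous run of
inner exons: all pairs (i, j) with j ≥ i+2, which is C(k−1, 2) =
(k−1)(k−2)/2 junctions, k−2 of them single-skip. Enumeration is strictly
per transcript — exons of different isoforms are never combined — and
deduplication is positional: the key (chrom, strand, donor, acceptor)
identifies a junction globally, records merge accumulating their source
transcripts, and a key that is adjacent in *any* transcript is categorised
`known` even when it arises as a skip in another, so novel counts are never
inflated by annotated introns.

Flank extraction takes up to L bases from each side of the junction
(L ∈ {50, 75, 100, 150} by default, chosen to bracket common read lengths).
A flanking exon shorter than L yields a truncated flank of the whole exon;
because the two flank lengths are carried in each record, the fusion point
(local position `up_len`) stays recoverable for truncated records, and
record-local positions map bijectively back to genomic coordinates.
Sequences are emitted in transcript (sense) orientation; aligning an
unstranded library against both strands is the aligner's concern, not the
library's.

## Junction quantification

A read supports a junction when its aligned span crosses the fusion point
with at least `min_anchor` aligned bases on each side. The default of 8 bp
is the conventional spliced-alignment anchor: long enough that a random 8-mer
match is unlikely, short enough to keep sensitivity near read ends. Reads
whose alignment has an insertion or deletion exactly at the fusion point are
rejected as non-spanning, since their breakpoint position would be
ambiguous. Multi-mapped reads (one read spanning several library records)
count once per record by default — the junction is the unit of the
downstream test — with the multi-hit fraction reported and a `unique_only`
mode available. Secondary and supplementary alignments are excluded from the
examined total and tallied separately, so the conservation identity
`counted + rejected + unmapped = examined` holds exactly.

## Poly(A) sites and PAS annotation

A read is a poly(A) tag when its maximal *uninterrupted* terminal A-run is
at least `min_tail` (default 6) and the remaining prefix is at least
`min_trimmed` (default 15) bases. An exact run is the simplest reproducible
rule; allowing mismatches inside the tail would make tag boundaries
parameter-dependent in ways that are hard to audit. Trimming is lossless:
trimmed sequence + `A`×tail_len reconstructs the read.

Cleavage positions (strand-aware 3'-most aligned base of each trimmed tag)
are clustered by single-linkage within `cluster_window` (default 10 bp,
reflecting the micro-heterogeneity of cleavage); the representative is the
modal position, ties resolved 3'-ward. PAS annotation scans the
transcribed-strand genomic sequence — not the read, which is robust to
sequencing errors — over the `search_window` (default 40 bp, comfortably
covering the canonical 10–30 nt upstream placement) for the table hexamers
in *rank* order: the canonical AATAAA beats any variant regardless of
proximity, and among occurrences of the winning hexamer the
cleavage-proximal one is reported. The default table (AATAAA + 10 variants,
ordered by published human frequency) is packaged as a replaceable TSV.
Sites whose 10 downstream genomic bases are >70% A are flagged as potential
internal-priming artifacts but not removed: filtering is a judgement the
analyst should make with the flag in view.

## Exon trios and inclusion

The TXdb holds every consecutive exon triple of every transcript (k−2 per
transcript), merged across transcripts when the three intervals coincide.
The inclusion ratio uses length-normalised supporting counts,

IR = (n_inc/len_inc) / (n_inc/len_inc + n_skip/len_skip),

a point estimate with a binomial delta-method standard error on the
effective counts. It replaces Bayesian posterior machinery deliberately:
with the support definitions exposed (a read supports inclusion if it
overlaps the middle exon body or an inclusion-only junction, skipping if it
spans the skip junction) the ratio is transparent and consistent for the
true mixing fraction under length-proportional sampling. Poorly covered
trios are flagged by the exon-size-dependent cutoff
`max(n_min, ceiling(rho * middle_exon_len / read_len))` with defaults
n_min = 4, ρ = 2 — an estimate from four reads is the bare minimum for a
two-isoform ratio, and ρ = 2 demands about 2× read coverage of the middle
exon before an IR is trusted. Failing estimates keep their IR but carry
`passes_cutoff = FALSE`.

## Gene counting

`assign_read()` implements the intersection-nonempty rule on interval
arithmetic: per-position gene sets are intersected over the positions that
have features, so a read wholly inside gene A and partially overlapping B
goes to A, partial overlap of a single gene still assigns, and positions
without features are ignored unless the whole read is feature-free. The
implementation never enumerates positions (it compares per-gene overlap
widths with the union overlap); the test suite checks it against a literal
per-position oracle on randomized fixtures. Paired mates are combined into
one fragment (union of blocks) and counted once, matching the
one-observation-per-fragment assumption of the count test downstream.

## Differential testing

Inclusion tables are compared with Pearson's chi-square without continuity
correction; tables with any expected cell below 5 are tested but flagged
`low_count` rather than silently corrected, and replicates are pooled by
summing counts within condition before testing. Counts (genes, junctions,
poly(A) sites) are normalised by median-of-ratios size factors and tested
per feature under a negative-binomial model whose variance decomposes into
shot noise plus overdispersion: Var = μ + αμ².

The dispersion α is estimated per feature by method of moments across
replicates within each condition and pooled with features of similar
expression: features are binned by normalised mean (≥ 20 per bin where
possible), the bin trend is the mean of the *unfloored* per-feature
estimates — flooring each estimate at zero before averaging would bias the
trend upward exactly when the true dispersion is near zero — and the final
α is the maximum of the feature's own estimate and the trend. The maximum
rule is deliberately conservative: at 2–3 replicates the per-feature
estimate is noisy, and letting it fall below the trend is what inflates
false discovery. Without replicates, α is pooled across conditions from the
cross-condition estimate, which confounds real differences with dispersion
and correspondingly (and intentionally) reduces power — single-sample
designs are supported but discouraged.

The p-value conditions on the feature's total count K: the two condition
sums follow NB laws with means and variances assembled from the size
factors and α, and the two-sided p doubles the smaller tail of the
conditional split distribution with a mid-p correction (half weight on the
observed split). Mid-p offsets the discreteness that makes exact conditional
tests conservative at moderate totals, while the doubled-tail form keeps the
exact identity p = 1 for a perfectly balanced split. BH adjustment is
applied separately per analysis family (genes, junctions, sites, trios),
mirroring the pipeline's independent differential steps. Note that the BH
step-up map is not idempotent on arbitrary adjusted vectors — only constant
vectors and step-up plateaus are fixed points — so adjusted q-values should
never be re-adjusted.

## The simulator

`sim_config()` / `simulate_annotation()` / `simulate_reads()` generate a
random genome carrying single-transcript genes (default 20 genes, 2–6 exons
of 90–300 bp, introns 60–200 bp, alternating strands), then emit three read
classes at exactly known placements — unspliced single-exon reads
(Poisson-distributed per gene, default mean 30), junction-spanning reads
(5–20 per junction with anchors ≥ 8), and poly(A) reads carrying a 12 bp
untemplated tail with a canonical PAS planted 15–30 bp upstream of the
cleavage base. SAM records are synthesised directly from the known
placements; no aligner runs, so alignment artifacts are out of scope by
design and exercising a real aligner remains an integration concern.

Two generator details are deliberate. Every third genome base is forced to
C/G, capping templated A/T homopolymers at two bases, so the only terminal
A-runs reaching the tag threshold are the planted tails (even across a
junction fusion) and the only canonical AATAAA occurrences are the planted
ones — making planted sites, hexamers and offsets exactly recoverable in
error-free mode, which is what the recovery tests assert. And the
differential power simulation plants fold changes balanced in direction:
median-of-ratios normalisation assumes changes are mostly absent or
balanced, and a simulation with 20% one-directional DE measurably biases
the size factors rather than the test.

What passing these tests shows — and does not. Exact recovery on simulator
output validates the coordinate arithmetic, the counting rules and the
conservation identities. It does not validate behaviour under alignment
error, soft-clipping, coverage bias, intron retention or genomic A-rich
internal priming, none of which the generator emulates (the A-richness flag
exists precisely because real genomes violate the scrubbed-homopolymer
assumption).

## Problem sizes

The test suite and the acceptance script run on deliberately small
instances: 6–20 genes, a single ~10–40 kb chromosome, hundreds to ~1,500
reads, 200–1,000 features × 6 samples in the differential simulations, and
n = 2,000 reads per trio for inclusion recovery — sizes at which every
check is exact or has well-characterised Monte-Carlo error, and the whole
suite completes in about a minute.

## Known limitations

* Junction enumeration covers exon skipping only; alternative donor/acceptor
  shifts and intron retention are out of scope.
* The NB test is a simplified two-condition exact-style test; no multi-factor
  designs, no empirical-Bayes dispersion machinery beyond binned pooling.
* PAS search uses genomic sequence; a read-sequence search (sensitive to
  untemplated variation) is a documented alternative, not implemented.
* Whether junction counting should exclude reads that also align contiguously
  to the genome is the caller's pre-filtering decision; the package counts
  whatever is aligned to the library.
* Transcripts sharing identical exon chains are not collapsed before
  enumeration; deduplication happens at the junction level, which yields the
  same library.
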