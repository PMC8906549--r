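---
title: "Calling full-length RNA scaffolds from cap-adapted nanopore reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling full-length RNA scaffolds from cap-adapted nanopore reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Direct RNA nanopore sequencing reads single poly(A) RNA molecules 3'-to-5',
but the observed 5' end of a read is unreliable: strand breaks in vivo and in
vitro, signal-processing artifacts and motor-enzyme slippage all truncate
reads before the biological 5' end, and nothing in the standard chemistry
marks the m7G cap. A read therefore cannot, by itself, witness a
transcription start site (TSS) or a full-length isoform.

Cap-exchange chemistry addresses this by replacing the biological cap with a
modified cap that is click-ligated to a 45-nt RNA oligomer. A read whose
basecalled sequence begins with that oligomer is known to start at a bona
fide capped 5' end. `capscaffold` implements the computational half of this
design: it detects the cap-adapter on basecalled reads, cross-checks the
detection against genomic alignments, and cascades the surviving reads
through poly(A)-tail and poly(A)-site evidence to produce *full-length RNA
scaffolds* — single reads that run from a capped 5' end to a documented
polyadenylation site. On top of the cascade it discovers unannotated TSS by
clustering read 5' ends, quantifies their support in orthogonal marker data
(CAGE, DNase, ChIP), and scores candidate TSS with a 5' RACE treated /
untreated ratio.

## The cascade and its parameters

Stages apply in fixed order; a read is a full-length scaffold iff it passes
all of them.

| stage | rule | default | notes |
|---|---|---|---|
| quality gate | mean read quality >= `min_q` | 7 | error-probability averaging (below) |
| cap-adapter | barcode identity >= threshold | 74 (human), 70 available | semi-global alignment, first 150 nt |
| true-positive check | untrimmed 5' clip >= 15 | 15 | adapter must *not* align to the genome |
| clip filter | trimmed 5' clip < 15 | 15 | removes misaligned 5' ends |
| poly(A) tail | tail-caller QC tag equals `PASS` | closed world | absent read = fail |
| poly(A) site | 3' end within [-60, +10] nt of a site | inclusive | negative = gene-internal |

Other tunables: novel-TSS distance gate 300 nt (inclusive), single-linkage
gap 50 nt, minimum cluster support 2 reads; 5'-end merging window 25 nt;
full-length-by-annotation windows 25 nt (5') and 50 nt (3'), both inclusive;
RACE counting window 100 nt two-sided inclusive with validation requiring
ratio > 0.5 *strictly* and at least one treated read.

### Mean read quality

The pass gate averages per-base *error probabilities* and converts back to
the Phred scale (`-10*log10(mean(10^(-q/10)))`), the convention of the
standard read-filtering tools for this platform; low-quality bases dominate,
so two bases at Q10 and Q20 average to 12.6, not 15. The arithmetic mean of
Phred values is available as a configuration alternative because published
descriptions of the Q >= 7 gate name the tool rather than the formula.

### Adapter detection

The 22-nt barcode `TCCCTACACGACGCTCTTCCGA` (a sub-sequence of the DNA form
of the 45-nt cap-adapter) is aligned semi-globally against the first 150 nt
of each U-to-T-converted read: the barcode aligns end to end, gaps before
and after the aligned read segment are free, internal gaps are affine.
Scoring is match +3, mismatch -6, gap open -5, gap extend -2, with a gap of
length L costing `open + (L-1)*extend`. Ties in score resolve to the
leftmost match start, then to the alignment with most matched bases, so
results are reproducible to the byte.

Percent identity is matched bases over *alignment columns* — barcode length
plus read insertions. For ungapped alignments this is exactly
`matches/22` (five substituted bases give 17/22 = 77.3%), and a terminally
truncated adapter still loses identity because deleted barcode columns count
in the denominator. Counting insertion columns matters: scoring against the
barcode length alone would let gap-padded alignments on random sequence
reach the low 80s in percent identity, and detection at threshold 74 would
fire on several percent of adapter-free reads. With column counting the
false-positive rate on random sequence is negligible, which is what makes
the downstream true-positive filter's job well defined.

Detected reads are trimmed through the end of the full adapter (the barcode
ends three bases before the adapter's 3' end), leaving a genuine
cap-adapted read with exactly its transcript sequence.

### The true-positive cross-check

A barcode hit can be genomic: transcript sequence that happens to resemble
the adapter. These calls are rejected by aligning each read twice — with and
without trimming. For a genuine cap, the adapter cannot align, so the
untrimmed alignment soft-clips it (5' clip >= 15); for a genomic mimic the
"adapter" aligns and the untrimmed clip is small. A detected read is
confirmed only if its untrimmed alignment clips >= 15 bases *and* its
trimmed alignment passes the < 15 clip filter. The same constant (15) is
used at both stages; the published description implies but does not
separately state the untrimmed constant, and we adopt the single value.

### Distances, clustering, and sign conventions

All internal coordinates are 0-based, half-open; GTF input is shifted on
read, BED taken as is, and all emitted BED is 0-based half-open. A read's
5' end is its alignment start on the plus strand and `end-1` on minus;
clips are counted at the strand-appropriate CIGAR end. Distances to TSS and
poly(A) sites are signed in the annotated gene's frame: negative means
upstream of a TSS, or upstream (gene-internal) of a cleavage site. Nearest
features are same-strand only, per transcript (not collapsed per gene), with
exact-distance ties broken toward the first feature in sorted order. The
compatibility question of downstream-preferring nearest-feature semantics is
resolved in favour of simple signed nearest, because the two-sided distance
distributions that motivate the gate retain both signs.

Novel-TSS discovery keeps reads at least 300 nt (inclusive — the "300 or
more" reading of the two published phrasings) from any same-strand annotated
TSS, single-links their 5' ends per chromosome and strand with a 50-nt
maximum gap, and reports clusters of at least two reads. The cluster
representative is the 5'-most member: the statistic is deterministic and
conservative, where a mode would depend on arbitrary tie-breaking at small
cluster sizes. Reads on chromosomes absent from the annotation count as
infinitely far, hence eligible.

### Marker matrices

Reference-point matrices mirror the usual promoter-heatmap layout: rows are
5'-end reference points (first merged within 50 bp, optionally down-sampled
under a seed), columns are strand-oriented offsets over +/-1 kb, and cells
carry the interval signal covering each genomic position. Signal tracks are
assumed non-overlapping per chromosome, as in a bedGraph. Rendering is out
of scope; the matrix is the product.

## The synthetic-data generator

The generator builds a toy reference (multi-exon genes on both strands of
random-sequence chromosomes, 2-4-kb intergenic gaps, one poly(A) site per
TES) and draws reads from five classes that mirror the failure modes the
cascade is designed to separate:

* **capped** — adapter + full spliced transcript + poly(A) tail (14% by
  default, the observed cap-adaptation rate);
* **truncated** — 5'-truncated at a uniform internal breakpoint, no adapter
  (60%, the dominant strand-break population);
* **uncapped** — full-span but adapter-free (remainder);
* **decoy** — from genes whose first exon genuinely begins with the adapter
  sequence planted in the genome (2%), exercising the true-positive filter;
* **degradation-tailed** — adapter + transcript cut at least 100 nt before
  the TES, then tailed (4%), exercising the poly(A)-site window.

Optionally it plants novel-TSS clusters: cap-adapted reads whose first exon
extends a fixed 400 nt (plus small per-member offsets of at most 25 nt)
upstream of a distinct gene's TSS, plus isolated singletons that must never
be reported.

Errors are substitution-only at a default rate of 0.13, matching the ~87%
median identity of direct-RNA basecalls; substituted bases are always
changed, so simulated identity is 1 minus the rate by construction. Indels
are deliberately not modelled: they would complicate the truth CIGARs
without changing what the identity thresholds test. Alignments are emitted
as truth-based SAM (spliced `N` operations, strand-aware soft-clips for
adapter and tail, for both the untrimmed and adapter-trimmed reads), so the
test suite never invokes an external aligner. Mapping qualities are drawn
from a fixed mixture (72.3% Q60, 6.8% Q0, remainder uniform) so MAPQ
summaries have realistic mass at both ends. Tails are written into the read
sequence and, in parallel, into a tail table whose entries are tagged
`PASS`; the pipeline consumes only the table, mirroring how signal-domain
tail callers are used in practice.

Two generator properties are load-bearing for the planted-truth tests.
First, everything is deterministic under the seed — same seed, byte-identical
files. Second, the background is screened: after laying out the genome the
generator re-randomizes any gene whose spliced transcript contains a
spurious barcode look-alike (any 150-nt window reaching identity 70, the
lower of the two published operating points), so adapter-like sequence
occurs only where planted and zero-error recovery of stage counts is exact
rather than approximate. Without screening, chance look-alikes fire the
detector on roughly half a percent of adapter-free reads.

What the simulator does **not** emulate: homopolymer-biased and indel
errors, raw-signal artifacts, coverage biases, multi-isoform genes,
overlapping genes, or real promoter structure. Passing tests therefore
demonstrate the correctness of the decision logic and its boundary
semantics under controlled conditions, not recovery of published counts
from real nanopore data, which additionally depend on basecaller version,
reference annotation and sequencing depth.

## Problem sizes and numerical choices

The test suite and acceptance script run the cascade on 5,000 simulated
reads over 40 genes (planted-truth recovery), 200 reads over 30 genes with
20 planted clusters and 5 singletons (novel-TSS recovery), 2,000 reads at
substitution rate 0.13 (detection sensitivity, measured ~0.93-0.95 at
threshold 74), 1,000 random reads of up to 60 nt against an exhaustive-DP
oracle, and 10,000 fuzzed CIGARs against brute-force expansion. These sizes
give exact planted-truth checks and stable stochastic characterizations at
interactive runtimes.

Degenerate inputs are defined rather than accidental: empty FASTQ yields an
empty table; a chromosome with no same-strand annotation flags the read
instead of erroring; an empty marker set gives overlap 0; down-sampling
beyond the available rows keeps everything; a zero-read RACE window is "not
validated" rather than a division by zero.

## Known limitations

* Identity semantics reproduce the modelled detector's thresholds but are
  not guaranteed to be bit-identical to any particular release of it.
* Gene assignment for expression counting uses closest same-strand TSS plus
  span overlap; published per-gene counts may use other assignment tools,
  so cross-tool CPM comparisons carry that caveat.
* The poly(A)-site atlas is consumed as single-base cleavage coordinates;
  cluster-shaped atlas entries should be reduced to representative sites
  upstream of this package.
* Alignment itself is delegated: the pipeline consumes splice-aware SAM/BAM
  produced externally (or truth-based SAM from the simulator) and never
  realigns soft-clipped tails.
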