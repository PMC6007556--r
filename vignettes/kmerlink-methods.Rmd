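---
title: "Methods: unique k-mer indexing, alignment-free pair placement, and scaffold-join evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unique k-mer indexing, alignment-free pair placement, and scaffold-join evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kmerlink places paired reads on assembled contigs without computing a single
base-level alignment, and turns the cross-contig pairs into a scaffolding
graph. This vignette is the package's own account of the method: the model
and its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The unique k-mer dictionary

The central object is a static dictionary over the set $S$ of *unique*
k-mers: canonical k-mers that occur exactly once, counting both strands,
across the contig set. Uniqueness is what substitutes for alignment: a hit
on a unique k-mer is, up to the dictionary's false-positive rate, an
unambiguous statement about where a read came from. Repetitive sequence
contributes no keys, so reads from repeats are silently unplaceable rather
than misplaced.

Each key stores a 32-bit contig id, a 32-bit coordinate, and a strand bit.
Canonicalisation is the lexicographic minimum of a k-mer and its reverse
complement; the strand bit records whether the canonical form equals the
contig's forward k-mer. For $k \le 32$ the k-mer is packed 2 bits/base
(most significant base first, so integer order is lexicographic order) and
both strand codes are maintained by a rolling update, giving amortised
constant work per position; the packed canonical value is finalised through
splitmix64, which is a 64-bit bijection, so at these k the key hash is
collision-free. For $32 < k \le 256$ the canonical string is hashed with
FNV-1a per window (correct, but no longer amortised constant — all routine
use sits at $k \in [15, 32]$).

Membership queries are *fingerprint-verified*: every key stores the low 16
bits of an xor-shift remix of its hash, and a query for an absent key is
routed to a pseudo-random slot (an independent splitmix64 remix, modulo
$N = |S|$) where its fingerprint is compared against the resident key's.
Stored keys are always found; an absent key is spuriously accepted with
probability $\approx 2^{-16} = 1.5 \times 10^{-5}$, in which case an
arbitrary stored record is returned. This reproduces the query contract of
a minimal-perfect-hash dictionary with fingerprint control while using an
exact map as the slot assignment, a deliberate trade at desk scale: the
lookup semantics (including the false positives, which the test suite
measures against a $3\sigma$ binomial band at $10^7$ queries) are
faithful, but the memory budget of a true MPHF is not emulated.
K-mers containing any non-ACGT symbol are neither counted, indexed, nor
queried. Construction aggregates counts over chunks of contig sequence and
sorts keys by hash before slot assignment, so the result is bit-identical
under any chunking — `--threads` on the command line is accepted and may
be ignored precisely because nothing is allowed to depend on it.

## Alignment-free pair placement

For a read pair (QF, QR), the mapper:

1. scans QF's k-mers left to right, querying each canonically, and stores
   hits until the *hit capacity* is reached (default 10 for short reads,
   20 for synthetic long-read pairs — the noisier the reads, the more
   chances to collect evidence);
2. projects each hit to an inferred read start (strand-adjusted) and
   window-scores the collection: the score is the maximum number of hits
   inside any window whose width equals the read length. Two maximal
   windows at distinct genomic locations make the read *ambiguous*, which
   is treated as score 0; overlapping maximal windows at one location are
   not ambiguity;
3. applies a strict forward gate: unless QF's score is greater than 3, the
   pair is abandoned before QR is examined (a cheap rejection of
   repeat-derived and junk pairs);
4. reports the pair when both reads score strictly above the report
   threshold (5 for short reads, 15 for synthetic long-read pairs);
5. otherwise attempts *pair rescue*: the better-scored read (which must
   itself clear the report threshold) is fixed, and the mate's hits are
   re-scored keeping only those whose implied placement falls within
   $\mu \pm 3\sigma$ of the library insert and matches the library
   orientation; a rescued mate is accepted at score $\ge 4$.

Threshold comparisons are strict ("larger than") for the forward gate and
the report threshold, and inclusive for rescue ("a minimum score of 4") —
the asymmetry is kept exactly as the defaults are stated. The $3\sigma$
distance window covers $>99\%$ of a Gaussian insert distribution; it is
the reason the library sd estimate must target the true $\sigma$ (below).
The reported position uses a single representative unique k-mer — the hit
with the smallest read offset inside the winning window — and positions
are clamped into contig bounds, which only matters for reads straddling
contig ends. Scores are hit counts, not derived quantities.

Placements are emitted as SAM 1.x with 1-based positions (coordinates are
0-based everywhere else), a full-length `M` placeholder CIGAR (no base
alignment exists), MAPQ 60 for score-reported reads and 30 for rescued
mates, an `XR:i:1` tag on rescued mates, and TLEN as the signed outer
distance. Unplaced pairs are not emitted; scaffolders consume mapped pairs
only.

## Synthetic mate-pairs from long reads

A long read is turned into mate-pair libraries by cutting, for each
nominal insert $D$ and each start $s \in \{0, 100, 200, \dots\}$ with
$s + D$ inside the read, a forward 200-mer at $s$ and the reverse
complement of the 200-mer ending at $s + D$. $D$ is the *outer* distance
(first base of QF to last base of QR inclusive), chosen so that an
error-free pair maps with observed insert exactly $D$; the second read is
reverse-complemented at extraction so every emitted pair is physically
forward-reverse. Pair ids are `<read>:<s>:<D>`, so provenance survives SAM
round trips. The pair count per read has the closed form
$\lfloor (L - D)/\mathrm{step} \rfloor + 1$ for reads of length $L \ge D$.

Because deletions shrink read coordinates relative to the genome, a
deletion-dominant error process (ONT-like) makes the *genomic* span of a
fixed read-coordinate distance $D$ larger than $D$ — the observed insert
distribution of ONT-like synthetic libraries sits above the nominal
insert, while substitution-dominant (PacBio-like) errors leave it centred.
The acceptance suite checks both directions.

## Library parameter estimation

Insert parameters are estimated from a subsample mapped with a report
threshold of 8 and rescue disabled (rescue needs the very parameters being
estimated). Only pairs with both reads on one contig are used; the
observed outer inserts are sorted and exactly $\lfloor 0.1 n \rfloor$
values removed from each tail before computing mean and sd. Orientation is
a majority vote over {FR, RR, FF, RF} across all within-contig pairs (ties
break in that fixed order); synthetic libraries are FR by construction and
skip the vote. Defaults: 100,000 pairs for short-read libraries, 1,000
long reads per synthetic library, and at least 50 usable pairs before the
estimator refuses to answer.

One numerical choice deserves emphasis: the sd of the central 80% of a
Gaussian is $0.662\sigma$, so an sd computed naively on the trimmed sample
would systematically shrink the $\mu \pm 3\sigma$ rescue window and the
join-distance tolerance. The estimator therefore divides the trimmed-sample
sd by the truncated-normal factor
$\sqrt{1 - 2 b \varphi(b) / (1 - 2t)}$ (with $b = \Phi^{-1}(1-t)$ at trim
fraction $t$), making it consistent for the library $\sigma$ while keeping
the outlier-robust trimmed scope. Two caveats are documented rather than
hidden: the correction assumes an approximately Gaussian core, and heavy
contamination biases the trimmed *mean* — a 10% trim cannot remove a 20%
contaminant mass, and short-insert contaminants are over-represented among
within-contig pairs because genuine long inserts span contigs more often.
The orientation vote, not the mean, is what survives such libraries.

Library QC follows the same observed-insert distributions: a library is
flagged low-quality when more than 30% of observations fall outside
$\mu \pm 3\sigma$ or when the sd exceeds 30% of the mean; flagged
libraries should be excluded from scaffolding.

## Scaffolding graph and join evaluation

Pairs whose reads map uniquely to *different* contigs carry the linking
information. Each supports an edge recording the contig pair, their
relative orientation, the support count (weight), and a gap estimate
$\mu - d_u - d_v$, where $d$ is the distance from each read's start to the
contig end it points at; the edge keeps the mean over supporting pairs and
edges with weight below 3 (configurable) are dropped. Construction assumes
a forward-reverse library and refuses others. Edges are canonicalised on
contig id, reverse-complementing the implied layout when the contigs swap.

Scaffold joins are scored against a known true layout with bit-wise error
flags: 0 correct; 1 wrong relative orientation; 2 contigs from different
references; 4 wrong distance; 8 wrong order; composites 5 = 4+1 and
12 = 8+4. Two decisions fill gaps the flag vocabulary leaves open. First,
order is judged in the traversal direction shared by the join's two
contigs, so a wholly reverse-complemented scaffold is correct; when the
two contigs disagree in orientation (flag 1) the direction is undefined
and order is not additionally penalised — which is exactly why 1+8
composites do not occur. Second, the distance check accepts a claimed gap
within $\max(1000, 3\sigma)$ bases of the true gap, a configurable default
in line with common evaluation practice. With $P$ potential joins (truly
adjacent contig pairs in the layout), recall is $TP/P$, precision
$TP/(TP+FP)$, and the F-score their harmonic mean, defined as 0 when no
join is correct. The package evaluates scaffolds; it deliberately does not
build them — path selection through the graph is the scaffolder's job, and
external layouts (or truth perturbations from the simulator) are the
expected input.

## The synthetic-data generator

`simulate_genome()` draws i.i.d. uniform bases and plants each repeat
family as one random block copied verbatim to non-overlapping positions —
the sharpest possible repeat structure, which is the right stress test for
a uniqueness-based index (repeat interiors provably contain no unique
k-mers). `fragment_genome()` tiles the genome into contigs and writes the
layout that later serves as evaluation truth. `simulate_illumina_pairs()`
draws outer inserts from a truncated normal, emits FR pairs, applies
per-base substitutions, and can mix in a contamination fraction of
short-insert (normal, mean 300, sd 50) reverse-forward pairs emulating
mate-pair circularisation failures. `simulate_long_reads()` applies a
total per-base error rate split 60/25/15 between deletion, substitution
and insertion for the ONT-like profile, and 60/25/15 between substitution,
insertion and deletion for the PacBio-like profile — the split magnitudes
are the package's own settings (the direction of each technology's bias is
the established fact being emulated), and they are configurable. All
generators are deterministic under a seed via R's default Mersenne-Twister
stream.

What the generator does *not* emulate: quality-score models (qualities are
constant placeholders and the method never reads them), coverage and GC
biases, chimeric long reads, inexact (diverged) repeats, and heterozygosity.
Passing tests therefore demonstrate the algorithmic contracts — uniqueness
filtering, window scoring, rescue geometry, graph and evaluation logic —
on clean ground truth, not calibrated performance on real libraries.

## Reference study conditions and problem sizes

The package's tests and the acceptance script run one fixed scenario,
chosen once as a realistic desk-scale stand-in: a 1 Mb genome with one
5 kb repeat family in 3 copies, fragmented into 10 contigs (9 potential
joins); 10,000 FR pairs of 100 bp reads at insert $3000 \pm 300$; long
reads of mean length 10 kb at 15% error; $k = 21$ for short-read mapping
and $k = 15$ for raw long reads; $10^7$ random queries for the
false-positive measurement. Library recovery is checked at $n = 10{,}000$
pairs across 10 seeds (trimmed mean within 2%, corrected sd within 15%,
orientation FR even at 20% contamination).

## Known limitations

- The index is an exact map plus fingerprint emulation: query behaviour
  matches a fingerprinted MPHF, memory does not (roughly 40 bytes/key here
  versus the 87 bits/key of a production structure).
- CIGARs are placeholders; nothing downstream should interpret them as
  base-level alignments.
- Graph construction assumes FR libraries; RF/FF data must be
  re-oriented upstream.
- For $k > 32$ hashing falls back to per-window work and the
  false-positive experiment is not offered (packed decoding is
  unavailable).
- The per-join error flags cannot express order errors across joins with
  inconsistent orientation (see above); whole-scaffold metrics beyond
  join counting (e.g. reference-alignment-based validation) are out of
  scope.
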