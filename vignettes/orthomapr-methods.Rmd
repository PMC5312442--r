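---
title: "Methods: global best-reciprocal-hit assignment of transcripts to ortholog groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global best-reciprocal-hit assignment of transcripts to ortholog groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomapr)
```

## The problem and the model

Given (i) reference proteomes ("reference gene sets", RGS) of several
species, (ii) a clustering of part of those proteins into ortholog groups
(OGs), and (iii) a de novo transcriptome assembly of a target species, the
task is to decide, for every transcript, which OG (if any) it is
orthologous to — without ever assigning the same transcript region twice.

orthomapr implements the graph-based best-reciprocal-hit (BRH) strategy as
a *global* assignment problem rather than a per-group one:

1. Each OG's member proteins are aligned and summarized as a profile HMM.
2. Every profile is searched against all six reading-frame translations of
   every transcript (*forward search*); hits are local alignments with a
   bit score, an E-value, and envelopes on both the translated frame and
   the profile.
3. For each forward hit, *only* the matched amino-acid subsequence is used
   as a query against the complete reference protein database — including
   proteins that belong to no OG, which act as decoys (*reverse search*).
4. All candidates are collated into a single list ordered by descending
   forward bit score (reverse results subordinated, also by bit score) and
   consumed greedily: a candidate is accepted iff its rank-1 reverse hit is
   a member of the OG whose profile found it (the BRH criterion) *and* its
   transcript region has not already been claimed. Accepted regions are
   recorded in a region ledger.

Step 4 is the essential difference from per-group ("memoryless")
implementations, in which each OG independently grabs its best transcript
and one transcript can end up in several OGs. Here the ledger makes
non-redundancy a structural invariant: the test suite asserts, on every
fixture it generates, that no nucleotide position belongs to two
assignments.

Accepted regions are then post-processed into open reading frames by a
frameshift-aware protein-to-DNA alignment against the most similar OG
member, extended outward in frame, and emitted as exactly corresponding
amino-acid and nucleotide FASTA records.

## The forward scorer

The profile HMM is the classical match/insert/delete architecture. Match
columns are alignment columns with residue occupancy ≥ 0.5 (tunable);
emissions are Laplace-smoothed frequencies, `(n_a + w·q_a) / (n + w)` with
pseudocount weight `w = 1` and background `q` uniform at 1/20; transitions
are estimated from the per-row state paths with the same smoothing.
Scoring is local Viterbi in log2-odds units: insert states emit at
background (log-odds 0), entry into and exit from any match state are
free, so the bit score is the best-scoring contiguous local state path.
Rare I→D and D→I transitions in the source alignment are folded into the
neighbouring I→M / D→M counts; the Plan7-style architecture does not model
them and they carry negligible mass at this smoothing level.

Two deliberate simplifications relative to a full profile-search engine:

* **E-values are naive**, `E = N · 2^(−S)` with `N` the residue count of
  the translated library. They are used only for reporting and optional
  thresholding. The candidate ordering — the part of the algorithm where
  statistics could change results — uses bit scores exclusively.
* **No forward-algorithm posteriors or glocal modes.** The scorer is
  self-contained and oracle-testable; `score_sequence()` is pluggable, so
  an external profile-search backend returning the same tuple shape can
  replace it.

Stop symbols in a translated frame are emitted at a mild fixed log-odds
penalty (`stop_lod = −4` bits) instead of −∞: assemblies contain errors,
and a spurious in-frame stop should reduce, not void, an otherwise strong
hit. Frameshift correction deals with it downstream.

Multiple non-overlapping hits of one profile on one frame are found by
recursive envelope splitting: after the best local hit is recorded, the
flanking subsequences (if ≥ `min_hit_aa = 10` residues) are rescored,
up to `max_hits_per_frame = 4` hits.

## The reverse search

The reverse query is restricted to the forward envelope; a longer query
would dilute the reciprocal test. Two modes share one scoring model
(affine Smith–Waterman, BLOSUM62, gap open 11 / extend 1, raw scores
converted to bits by the Karlin–Altschul transform
`S' = (λS − ln K) / ln 2`, λ = 0.267, K = 0.041 — the conventional gapped
BLOSUM62 parameters):

* `exact` (default): every database protein is fully aligned, like a
  non-heuristic Smith–Waterman scan. At desk scale this is fast and free
  of seeding artifacts.
* `heuristic`: BLAST-like screening — proteins sharing two length-3 seed
  words on one diagonal within a 40-residue window (one word suffices for
  short queries) are fully aligned, the rest skipped. By construction the
  exact mode's score dominates the heuristic mode's for every pair.

Ties at equal reverse bit score are broken by longer alignment, then
lexicographic protein id, making ranks total and deterministic. A rank-1
tie is accepted if any tied protein is an OG member; `strict_brh = TRUE`
demands all of them, for users who prefer conservative calls when
near-identical reference isoforms slipped into the database (the manager
flags same-taxon pairs above 95% identity for exactly this reason, but
deliberately does not auto-remove them — reference curation is the user's
call; a `collapse_isoforms` switch keeps the longest member per taxon and
group when asked).

## Assignment semantics

Candidates are processed once, in a total deterministic order: descending
forward bits, then lower E-value, longer envelope, transcript id, OG id.
Input row order can never influence results. Rejections are kept with one
of three reasons (`no_reverse_hit`, `best_hit_outside_og`,
`region_already_claimed`) and persisted for audit.

The ledger claims nucleotide intervals (`ledger = "section"`), so a
genuinely chimeric transcript may legitimately host two non-overlapping
assignments; they are flagged in the report. Users who want the stricter
one-transcript-one-OG guarantee switch to `ledger = "transcript"`. The
overlap tolerance is 0 amino acids by default: any overlap blocks.

One property worth stating precisely: re-evaluating a stored run with
*tightened* thresholds shrinks the assignment set on fixtures where each
region has a single reciprocal-positive candidate (the common case, and
the one the test grid checks). It is not a theorem in adversarial cases —
removing a winning candidate can free a region for a previously blocked
one — which is an inherent property of greedy global assignment, not of
this implementation.

## Frameshift-corrected ORFs

For each assignment the most similar OG member (highest Smith–Waterman
score against the assigned region, ties by id) guides a local
protein-to-DNA dynamic program over the strand-resolved transcript with
five move families: codon match (BLOSUM62 on the translated codon; an
emitted stop scores `−stop_penalty`), affine codon gaps in either
sequence, and frameshift moves that excise one or two nucleotides at a
fixed penalty — either extra bases between codons or the remnant of a
codon that lost bases. Frameshifted bases are excised and *nothing is
emitted for them*, which is what makes the headline guarantee structural:
the emitted nucleotide sequence is a concatenation of whole codons, so
its translation equals the emitted amino-acid sequence, codon for codon.
This is asserted for every record the package ever writes.

Penalty defaults: `frameshift_penalty = 15` and `stop_penalty = 20`
half-bits. The frameshift penalty is set so that a single indel inside an
otherwise well-matching region is accepted (a handful of downstream
matches outweigh it) while isolated spurious shifts at alignment edges
are not; note the converse: around a very short flank the optimal path
correctly prefers dropping the flank over paying the penalty.
An adapter (`orf_skeleton_from_segments()`) accepts segments from an
external protein-to-DNA aligner in place of the built-in DP.

The ORF is then extended codon-by-codon in the established frame until a
stop codon or the transcript end, on both sides. Coverage is measured in
amino acids as (BRH region length) / (ORF length); if it falls below
`min_orf_coverage` (default 0.5) the ORF is trimmed from its ends —
alternating, longest overhang first, never inside the BRH region — until
the bound holds. Trimming rather than rejection keeps partially covered
but reciprocal-confirmed regions in the output, logged via the reported
coverage; measuring in amino acids keeps the bound independent of
frameshift bookkeeping.

## What the fixture generator emulates

`sim_generate()` plants a fully known truth: ancestral proteins drawn
uniformly over residues (length 40–100 aa by default — short genes keep
desk-scale runs fast while leaving profiles ~40+ match states); reference
taxa and the target species derived by i.i.d. per-site substitutions
(default 5% per branch, a moderate divergence at which profile and
reverse searches should both succeed comfortably); coding sequences
back-translated with uniform synonymous codons, embedded in random UTR
flanks on a random strand. Optional plants: inparalog copies (extra
divergence), isoforms (central deletion, default 30%), single-nucleotide
frameshifts, chimeric fusions of two genes, unrelated decoy proteins in
the RGS and decoy transcripts in the library.

What it does *not* emulate: codon-usage bias, realistic indel processes,
sequencing-error profiles beyond isolated frameshifts, expression-level
effects, alternative splicing beyond simple deletions, or real ortholog
databases' curation errors. Perfect recovery on clean fixtures therefore
shows algorithmic correctness — the search finds what is there and the
assignment never duplicates it — not field performance on real
assemblies, which depends on reference quality and assembly quality in
ways the generator deliberately sidesteps.

The short-isoform failure mode known for this class of methods is
reproduced by arithmetic, not tuning: with the default E-value cutoff of
1e-5 and a translated library of ~2·10^4 residues, a forward hit needs
roughly 30 bits, i.e. ~8 well-aligned residues at the ~4 bits/residue a
small-sample profile provides. An isoform retaining only ~10% of a
40–60 aa gene falls below that and is missed, while 30%-deleted isoforms
are found.

## Numerical and determinism choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  reports; negative-strand hits are reported on the forward strand with a
  strand flag, so FASTA slicing stays trivial.
* All alignment tracebacks break ties in a fixed order (diagonal, then
  gap-up, then gap-left), and every sort used anywhere has a total key,
  so the whole pipeline is bit-deterministic; the only randomness in the
  package is the fixture generator's seeded RNG.
* The group MSA is deterministic center-star: the member with the
  maximal summed pairwise global-alignment score is the center (ties:
  first in id order); others are merged through their pairwise alignment
  with the center. For the within-group divergences the pipeline targets
  this is adequate; `align_og(precomputed = ...)` accepts an external
  MSA when users prefer a full aligner.
* The run store is a directory of TSV tables and JSON metadata with a
  schema version; floating-point columns are written at 15 significant
  digits, enough for stored-vs-in-memory assignment decisions to agree.

Test problem sizes: oracle-equivalence batches use queries ≤ 10 residues
against models ≤ 8 states and protein/DNA pairs ≤ 6 aa / 24 nt (with true
path enumeration at micro scale and an independent plain-R dynamic
program beyond it); the non-redundancy sweep runs 100 generated fixtures
of 2–4 groups plus adversarial near-duplicate-group cases; the benchmark
fixture uses 20 groups × 4 reference taxa.

## Limitations

The package maps transcripts of one species onto reference OGs; it does
not delineate orthology de novo between genomes, model splice sites or
introns (transcripts are assumed spliced), or classify overlapping
same-group transcripts into isoform vs artifact — they are flagged, with
coordinates, for downstream judgment. E-values are uncalibrated and
should not be compared across databases of different composition.
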