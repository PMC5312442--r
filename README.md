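# orthomapr

Assigns coding nucleotide sequences — typically transcripts from a de novo
assembly — to known clusters of orthologous genes (ortholog groups, OGs),
for researchers building phylogenomic or comparative-genomic matrices from
RNA-seq data of species without an annotated genome.

## The method

Reference-based orthology assignment by a *globally sorted*
best-reciprocal-hit (BRH) strategy:

1. **Profiles.** Each OG's member proteins (from reference proteomes plus
   an OrthoDB-style membership table) are aligned; the MSA becomes a
   profile HMM with match/insert/delete states.
2. **Forward search.** Every profile is scored by local Viterbi against
   all six reading frames of every transcript. A hit is a local alignment
   with bit score *S* = log₂ of the odds of the best state path versus the
   background null, E-value *E* = *N*·2⁻ˢ, and envelopes on frame and
   profile.
3. **Reverse search.** The matched amino-acid subsequence — nothing more —
   is aligned by affine-gap Smith–Waterman against *all* reference
   proteins (including those in no OG). Raw scores become bits via the
   Karlin–Altschul transform *S′* = (λ*S* − ln *K*)/ln 2 (λ = 0.267,
   *K* = 0.041).
4. **Global BRH assignment.** All candidates are sorted by descending
   forward bits (reverse hits subordinated, also by bits) and consumed
   greedily: accept iff the rank-1 reverse hit belongs to the originating
   OG and the transcript region is unclaimed; accepted regions are claimed
   in a ledger. No nucleotide position is ever assigned twice — unlike
   per-group ("memoryless") BRH implementations, where one transcript can
   end up in several OGs.
5. **ORF refinement.** Each assignment is aligned to its most similar OG
   member by a frameshift-aware protein-to-DNA dynamic program, extended
   in frame to the surrounding stop codons under a coverage constraint,
   and written as per-OG amino-acid and nucleotide FASTA whose records
   correspond codon for codon.

Searches are persisted in a file-based run store, so assignment parameters
can be changed and results re-evaluated (`og_report`, `brh_reevaluate`)
without re-running the searches. A synthetic fixture generator
(`sim_generate`) plants orthologs, inparalogs, isoforms, frameshifts,
chimeras and decoys with known truth for validation
(`score_against_truth`).

## Worked example

```r
library(orthomapr)

fx <- sim_generate(sim_config(seed = 7, n_ogs = 5, n_ref_taxa = 3), "demo")
og_manage("demo/store", fx$og_table, fx$proteomes)
#> manage: 5 groups, 25 proteins, 3 taxa
og_analyze("demo/store", fx$transcripts)
#> analyze: 10 transcripts, 5 forward hits, 125 reverse hits
res <- og_report("demo/store", "demo/out")
#> report: 5 assignments in 5 groups, 0 rejections ()

res$report[, c("og_id", "transcript_id", "strand", "nt_start", "nt_end",
               "fwd_bits", "rev_protein_id", "coverage")]
#>   og_id transcript_id strand nt_start nt_end fwd_bits rev_protein_id coverage
#>  OG0001     tr_OG0001      +       26    268 271.3193 taxon01_OG0001   0.9101
#>  OG0002     tr_OG0002      +       54    299 268.8751 taxon03_OG0002   0.8283
#>  OG0003     tr_OG0003      +       37    180 154.5083 taxon03_OG0003   0.8000
#>  OG0004     tr_OG0004      +       42    332 311.2451 taxon01_OG0004   0.9700
#>  OG0005     tr_OG0005      +       36    191 182.1869 taxon03_OG0005   0.8254

score_against_truth(res$assignments, fx$truth)[c("sensitivity", "FP")]
#> $sensitivity
#> [1] 1
#> $FP
#> [1] 0
```

Each report row is one accepted transcript region: its OG, 1-based
forward-strand coordinates, the forward profile bit score that ordered it,
the reference protein its reverse search hit (a member of the same OG —
that is the BRH criterion), and the fraction of the final ORF covered by
the reciprocal region. `demo/out/fasta/` holds the paired FASTA, e.g.
`>OG0001|target|tr_OG0001|2-268|+`, where translating each nucleotide
record reproduces its amino-acid partner exactly.

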