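---
title: "Models and methods behind hml2tx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hml2tx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hml2tx)
```

# The biological model

HERV-K(HML-2) proviruses share one splicing anatomy. A full-length
transcript runs from the R region of the 5' LTR to the R region of the 3'
LTR. Splicing of intron 1 (SD1 to SA1) produces the `env` mRNA; a second
splicing event inside `env` produces the doubly spliced mRNAs: `rec` from
type 2 proviruses (donor SD2_rec to the acceptor SA2 just upstream of the
3' LTR) and `np9` from type 1 proviruses. The two provirus types are
distinguished by a 292-bp sequence located about 50 bp into the `env`
coding sequence: type 1 loci lack it, and with it SD2_rec, so they use a
donor just upstream of the deletion point instead; splicing from that donor
to SA2 shifts the reading frame in exon 3, which is why Np9 and Rec share
only their N-terminus.

`hml2tx` encodes this anatomy as a single canonical type 2 reference
(`hml2_anatomy()`), a synthetic ~9.5-kb sequence built deterministically in
code. Its geometry is what carries the science; the base-level sequence is
arbitrary. The placements that matter:

* SD2_rec is 220 nt downstream of SD2_np9 and inside the discriminator, so
  the `rec` and `np9` PCR products (ca. 580 and ca. 360 bp between the
  multiplex primer pools) differ by 220 nt. Both products share the forward
  primer (overlapping the common Env/Rec/Np9 start codon) and the exon 3
  portion, so the product size difference equals the donor-to-donor offset
  — not the full 292 bp, of which 72 nt remain downstream of SD2_rec.
* An alternative donor sits 252 nt downstream of SD2_np9 (in type 1
  coordinates) and an alternative acceptor 7 nt downstream of SA2. A
  transcript using both carries 252 − 7 = 245 nt extra relative to `np9`.
  The SA2 region is planted as the composite 17-mer `TGTTAGTCTGCAGGTGT`:
  the canonical acceptor AG inside `TGTTAGTCTG` and, 7 nt downstream, the
  alternative acceptor AG inside `CTGCAGGTGT`. Mutating the first AG to GG
  (as in proviruses absent from the reference assembly) kills SA2 and
  forces the +7 acceptor.
* The Rec frame stops 106 triplets after the start codon (105 aa), the Np9
  frame 75 triplets (74 aa), matching the canonical protein sizes.

One deliberate artificiality: the `env`/exon 3 background sequence is drawn
over {A, C, G} only. Since every stop codon and every GT donor begins with
T, a T-free background guarantees that stops and donor motifs exist exactly
where planted, making all reading-frame and splice-motif ground truth of
the synthetic anatomy provable rather than probabilistic. Real proviral
sequence is not T-free; none of the algorithms depend on this property.

# Coordinate and site conventions

External files (catalog TSV, GFF3) are 1-based inclusive; everything
internal is 0-based half-open. A splice donor position is the first intron
base (the G of GT), an acceptor position the last intron base (the G of
AG). Minus-strand loci are reverse-complemented on load so that all
downstream modules see provirus-forward sequence only.

# Locus annotation

Each locus is projected onto the canonical anatomy by global pairwise
alignment (match 1, mismatch −1, gap open 4, extend 1 — Biostrings). Two
verified shortcuts handle the dominant colinear cases (equal-length
substitution-only paralogs, and type 1 loci that are exactly the anatomy
minus the 292-bp discriminator); both are accepted only when the implied
hamming distance is below 5%, and tests check them against the full
alignment path. Classification reads the discriminator columns of the
projection: at least 90% aligned means type 2; a clean deletion (at most
10% aligned, both 30-nt flanks aligned) means type 1; anything else —
solo LTRs, large truncations, retrocopies — is undetermined. Splice-site
motifs are always read from the locus's own bases; sites falling in
deleted or N-masked regions are reported as unlocatable, never dropped.

# In-silico PCR

Primer matching is an ungapped sliding-window comparison with at most 2
mismatches per primer and the 3'-terminal 3 nt required exact (polymerase
extension is intolerant of 3' mismatches; no standard matching rule exists
for this assay, so this is the package's choice). The degenerate pool ratios
(85/5/5/5 forward, 95/5 reverse) are used only by the read simulator;
matching treats all pool members equally. The primer-excluded insert is
the unit of read assignment.

# Read assignment

A read is compared with every insert by ends-free pairwise alignment;
differences are substitution columns plus one event per indel run (a
per-base policy is available for sensitivity analysis). A read is assigned
when a unique locus achieves the minimum difference count at or below
`max_mismatch = 2` ("less than three mismatches"); ties form an ambiguity
group that is reported, never broken heuristically. Two guards matter in
practice:

* masking of the short (23 nt) `np9` exon 2 applies to substitution
  columns only. The 252-nt alternative exon of the +245 variant begins at
  that exon boundary; masking structural indel events there would erase
  the variant's signature and cause false assignments.
* a comparison must cover at least 90% of the longer of read and insert.
  Ends-free alignment would otherwise let a read that shares only one exon
  with an insert pass with few counted differences.

Reads failing assignment are compared with the predicted inserts of
non-reference proviruses; "identical to X" requires zero differences over
the comparable region (overlaps under half the insert length are flagged).
Reads identical to several entries are labelled `ambiguous_nonref`, so the
partition identical-to-X / ambiguous / unmatched is disjoint and conserves
the routed total.

# Alternative splice variants

Variant detection aligns a read against the unspliced genomic window
between the primer sites of each candidate locus, using intron-friendly
gap costs (open 8, extend 0.05) so that an intron-scale deletion beats a
mismatch-dense ungapped alignment. Deletion boundaries are snapped to the
nearest GT..AG-consistent placement within ±3 nt (alignment gaps slide
inside repeats), then classified: canonical intron (no call), the +252/+7
alternative pattern (reported with both offsets), or a novel GT..AG intron
(such as the 334-nt intron spliced from transcripts of the intron-less
chromosome-10-style locus). Equally scoring interpretations are all
returned, flagged as tied.

# Coding capacity

The start codon is located by homology projection of the shared
Env/Rec/Np9 start. Capacity is `full_length` when both LTRs are present,
the required splice sites are intact, and the protein is within 9 aa of
the canonical reference length (shorter variants are reported as "about
ten or more" aa short, so 9 is the widest slack consistent with that);
`short_variant` down to 25% of the reference length (covering both
truncated proteins and those similar to the canonical protein only over
the N-terminus, whose identity length is reported); `none` below that or
when any gating feature is missing. "Stop N triplets into the coding
sequence" is interpreted as: the Nth codon is the stop, so the protein has
N − 1 aa. Protein variants are compared by a center-star multiple
alignment against the longest sequence (BLOSUM62 pairwise alignments,
merged insertion-wise); this is exact for the near-identical variants it
is used on and avoids a dependency no installed package provides. Chimera
detection scores every split point of the translated variant as local
identity of the prefix to Rec plus the suffix to Np9 and reports the best
split — robust to ±1 codon around a planted breakpoint.

# Retrocopy detection

The three hallmarks of L1-mediated retrotransposition of a spliced mRNA
are scored independently and combined only at the end: a target site
duplication (longest exact duplicated word, 6–25 nt, ending at the 5'
insertion point and restarting after the poly-A), a 3' poly-A tail
(max-score suffix with +1 per A and a penalty tuned to a 0.8 break-even
purity, at least 8 nt, with the AATAAA signal reported but not required —
the evidence for it in the motivating case is suggestive, not load-bearing),
and exon-junction coincidence. Junctions are verified by probing the
candidate with the spliced 40-mer around each expected exon-exon join
(up to 4 mismatches, absorbing ~1% lineage divergence; shifts up to ±3 nt
are tried and reported as the offset error). A retained intron means the
join sequence does not exist genomically, so the probe fails. This
probe-based check replaces a full 9.5-kb global alignment per candidate,
which costs seconds each and is unnecessary when the expected junctions
are known. The 5' truncation is the offset at which the candidate's
30-mer prefix locates on the model mRNA. Verdicts: all three hallmarks →
retrocopy; exactly two → inconclusive; fewer → not a retrocopy. Detection
retries the reverse complement when forward k-mer coverage of the model is
poor, making it strand-invariant.

# The synthetic data generator

`generate_panel()` derives all loci from the canonical ancestor by seeded
substitutions (defaults: 10 cataloged loci at 1% divergence, half type 1,
one rec-mRNA retrocopy with a 10-nt TTAAAAATGT TSD, 30-nt poly-A and
250-nt 5' truncation, three non-reference SA2-mutated loci of which two
are in the non-reference database). Functional elements — primer sites,
splice dinucleotides, the SA2 block, start and stop codons, poly-A
signals — are protected from substitution, emulating the purifying
selection that keeps the assay's targets recognisable in real loci and
keeping the truth table exact. `simulate_reads()` draws, per tissue, 41
reads (a realistic Sanger survey depth) multinomially over a gamma-distributed
activity matrix, plants substitution errors at 0.3% per base, and draws 5%
of reads from the unspliced genomic sequence of retrocopy loci — which is
identical to their cDNA product, so this contamination is indistinguishable
by construction and only the truth table tells it apart.

What the generator does not emulate: indel sequencing errors and PCR
chimeras (substitution-only divergence keeps the mismatch metric
analysable; an indel policy exists for stress tests), chromatogram quality
values, real per-tissue activity profiles (unknown; the activity matrix is
user-suppliable), and real HML-2 sequence content. Passing tests therefore
demonstrate the correctness of the algorithms under the stated error
model, not performance on real Sanger traces.

At the default error rate a 539-nt `rec` read carries three or more errors
about 22% of the time and is then unassignable *by the assignment rule
itself*; recovery statements are therefore made over reads carrying at
most `max_mismatch` planted errors (the truth table makes this exact), and
the unconditional rate is reported alongside.

# Problem sizes and determinism

The test suite runs the full 16-tissue × 41-read simulation (656 reads, 13
loci), a 100-retrocopy / 100-intact-provirus detection experiment, and a
5,000-read single-tissue draw for the multinomial fidelity check — sizes
chosen so the whole suite completes in a few minutes on one CPU while
preserving realistic sampling depth where it matters. All randomness
flows through `simulation_config(seed)`; panels and read sets are
byte-identical under a fixed seed, and the multinomial check uses
simultaneous exact binomial bands (Bonferroni-split to a family-wise 99%
level, so the check itself has a ~1% seeded failure probability rather
than the ~10% that per-locus 99% bands would give).

# Known limitations

* Site projection assumes loci are globally colinear with the canonical
  anatomy; heavily rearranged proviruses come back undetermined rather
  than annotated.
* The "identical" criterion for non-reference matching tolerates no
  mismatches, so sequencing errors push true non-reference reads into the
  unmatched bin — the same conservative behaviour the zero-difference rule
  has on real data.
* Quality values are not modelled; reads are consumed as FASTA.
* Thresholds that the source material does not state numerically (ORF
  slack, poly-A purity, junction tolerance, TSD bounds) are configuration
  defaults chosen once and documented above, not fitted quantities.
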