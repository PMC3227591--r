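---
title: "Methods: discovering gene fusion transcripts from RNA-Seq with fusionfindR"
author: "fusionfindR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering gene fusion transcripts from RNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A gene fusion joins parts of two genes into one chimeric transcript, most
often through a chromosomal translocation; several recurrent fusions are
oncogenic drivers. In bulk RNA-Seq, a fusion transcript betrays itself in two
independent ways:

* **junction-spanning reads** — single reads that cross the fused exon–exon
  boundary and therefore align to neither the reference genome nor any
  ordinary splice junction;
* **discordant read pairs** — paired-end mates that each align cleanly, but
  to two different genes (different chromosomes, or implausibly far apart on
  one chromosome).

`fusionfindR` implements both discovery routes at desk scale, together with
the supporting machinery: junction sequence libraries, a candidate score, an
in-frame call, exon-level expression profiling, and a seeded simulator that
provides ground truth for every stage.

# Junction sequence libraries: the x − 5 rule

Reads that span a splice junction cannot match the genome because an intron
interrupts the alignment. The remedy is a library of junction sequences: for
read length $x$, each junction record joins up to $x-5$ bases from the 3'
end of the upstream exon with up to $x-5$ bases from the 5' start of the
downstream exon (the whole exon when it is shorter than $x-5$). The arithmetic
guarantees that any read of length $x$ fully contained in a junction sequence
overlaps *each* exon by at least 5 bases — enough to anchor the read on both
sides. The package asserts this guarantee by exhaustive placement enumeration
in its test suite.

The same construction, applied to *every* exon pair of a candidate 5'/3'
partner combination (`buildFusionJunctionLibrary`), yields the search space
for fusion-junction-spanning reads. Because all $n_5 \times n_3$ exon pairs
are enumerated, alternate fusion isoforms (different donor exons feeding the
same acceptor) are found in the same pass, and swapping the partner roles
gives the disjoint library for the reciprocal product of a balanced
translocation.

# Single-end route: gene fusion candidate reads (GFCRs)

Reads that fail both genomic and splice-junction alignment are realigned
*locally* against mRNA sequences. A retained partial hit (group A) must

* cover 20–70 % of the read (`partialMinFrac`/`partialMaxFrac`),
* touch one end of the read, so that an unaligned remainder exists,
* end within 5 bp of an exon boundary (`boundaryTol`), and
* belong to a read that partially hits at most 5 distinct genes
  (`maxPartialGenes`); more promiscuous reads are discarded as ambiguous.

The unaligned remainder is then matched **exactly** against exon sequences
and kept only when it lands within 5 bp of an exon's 5' or 3' end (group B).
A group-A and a group-B hit on the *same* read but *different* genes form a
GFCR: the two blocks jointly account for the entire read, with the junction
at their meeting point. Gene pairs with ≥ 3 *unique* GFCRs (distinct partial
alignment start coordinates; identical starts collapse as likely PCR
duplicates) become candidates. Two false-positive patterns are annotated but
never silently removed: remainders hitting many loci (repeats) and partner
names that look like one gene family. We chose flags over deletion because
the original screening step here is a manual judgement that an automated
pipeline should expose, not emulate silently.

Interpretation note: the partial-alignment window ("20–70 %") is implemented
as the aligned block covering 20–70 % of the read length with the block
itself near-exact, which is what a local alignment of a chimeric read
produces; the alternative reading (percent identity of the whole read) is
not distinguishable at these read lengths. Both bounds are configurable.

# Paired-end route: discordant pairs and the PEFS

Only pairs whose mates both map *fully and uniquely* to the genome are
considered. A pair is discordant when its mates map to different chromosomes
or ≥ 1 Mb apart on one chromosome; the 1 Mb floor (`minIntraDistance`)
guards against large introns masquerading as rearrangements. Discordant
mates are realigned to mRNA sequences and grouped by the (5', 3') gene pair.
The 5' partner is inferred from transcript-alignment strand: a fragment of a
fusion transcript yields one mate matching the 5' partner's mRNA forward and
one matching the 3' partner's mRNA in reverse complement. When both mates
align on the same strand the orientation is ambiguous and both orientations
are emitted, letting the junction-spanning search adjudicate.

Each candidate gene pair is scored with the paired-end fusion score

$$\mathrm{PEFS} = 2P - D - 0.5M$$

where $P$ counts supporting read pairs, $D$ counts duplicate supporting
reads (a read with the same start coordinate as another supporting read —
the signature of a PCR amplification artifact), and $M$ counts mismatches
across the supporting reads. $P$ counts *all* identified pairs; duplication
is penalized only through $D$, which is the only accounting consistent with
the score's own worked example (three clean pairs score exactly 6).
Mismatches are taken from the genomic pair alignments by default
(`mismatchSource = "genomic"`); a configuration switch uses the transcript
realignment instead, since the defining description does not name the
alignment.

Candidates with $P \ge 3$ and $\mathrm{PEFS} \ge 5$ are prioritized, then
confirmed by aligning the still-unmapped reads against the pairwise
fusion-junction library of the two partners. The junction with the most
spanning reads becomes the predicted junction; every junction with at least
one read is reported as an isoform; zero spanning reads leave the candidate
flagged unconfirmed rather than dropped.

# The in-frame call

With CDS annotation for both partners, the fusion is **in frame** when the
number of coding bases upstream of the donor boundary (5' partner) and the
number of coding bases upstream of the acceptor boundary (3' partner) are
congruent modulo 3 — the downstream codon frame is preserved. When the donor
boundary lies inside the 5' partner's 5' UTR the call is `UTR-truncation`:
the product is a (possibly N-terminally truncated) 3'-partner protein driven
by the 5' partner's promoter. A donor inside the CDS joined to an acceptor
outside the 3' partner's CDS is called `N`, and missing CDS annotation gives
`unknown` with a warning. The phase arithmetic is validated in the tests
against a manual translation of a constructed fusion transcript.

# Exon-level expression discordance

A fusion leaves a quantitative footprint: exons of the 3' partner retained
in the fusion gain expression from the 5' partner's promoter, while exons
lost from either partner do not. For each exon, reads that uniquely map to
the exonic region are counted (a read overlapping an exon by ≥ 1 base counts
for that exon, so a straddling read counts for both neighbours — the
counting rule is stated here because the choice is not forced) and
normalized to RPKM:

$$\mathrm{RPKM} = \frac{\text{count}}{(\text{exon length}/10^3)\,
(\text{mapped reads}/10^6)}$$

The fold change of each exon compares the fusion-bearing sample against the
arithmetic mean of fusion-negative reference samples,
$FC = \mathrm{RPKM}(e_S)/\mathrm{RPKM}(e_R)$, stabilized by an RPKM
pseudocount $\varepsilon = 0.1$ in numerator and denominator (zero reference
denominators are otherwise undefined; affected exons are flagged).
`breakpointDiscordance` summarizes the log2-FC profile as upstream-block
mean, downstream-block mean and their difference — the step visible at the
breakpoint. No significance test is attached; with a handful of reference
samples a formal test would suggest precision the design does not have.

# The simulator and what passing tests mean

`simulationSpec`/`generateReference`/`injectFusion`/`simulateReads` build a
deterministic toy experiment from a single seed: random multi-chromosome
genomes packed with non-overlapping multi-exon genes on both strands (each
with a CDS placed so in-frame, out-of-frame and UTR-breakpoint fusions are
all constructible), fusion transcripts joining exons 1..e5 of the 5' partner
to exons e3..last of the 3' partner (with reciprocal products on request),
and SE or PE reads with i.i.d. substitution errors, uniform fragment starts,
and a fraction of fragments re-emitted at identical coordinates as PCR
duplicates. Abundance multipliers implement 3'-partner overexpression: a
fusion at multiplier $m$ over a wild-type background of 1 raises the
retained 3' exons to $1+m$ fold, so the expected log2-FC step is
$\log_2(1+m)$. For controlled experiments an event can request an *exact*
number of junction-flanking pairs, placed so that both mates lie wholly
inside single exons (and therefore survive the full/unique genomic mapping
filter).

Defaults emulate the data regime the method targets: 50 bp reads (SE or PE),
~250 ± 25 bp fragments, substitution error rate 0.005, duplicate fraction
0.05, and a 2 × 30 kb genome with 6 genes of 3–6 exons (80–220 bp). The
test suites run at depths 4–20×; the expression-recovery suite uses 20×, the
end-to-end recovery and negative-control suites 10 seeds each at 4×. These
problem sizes are the package's own choice of a desk-scale experiment that
still exercises every filter.

What the simulator does *not* model — indels, quality-score structure, GC
and positional bias, intronic/pre-mRNA reads, multi-isoform wild-type genes,
sequence homology between gene families — bounds what green tests prove:
they validate the logic of the filters, the score arithmetic, orientation
inference and frame calls on reads whose only corruptions are substitutions
and PCR duplication. On real libraries the alignment stage should come from
a production aligner (imported via SAM/BAM), and repeat- or homology-driven
false positives will be more common than in random sequence.

# Numerical and design choices

* **Coordinates.** 1-based closed intervals internally (the R/Bioconductor
  idiom, `IRanges`); all reports are 1-based inclusive.
* **One model per transcript.** Junction libraries are built per transcript
  and results collapse to gene level by gene id, matching annotation inputs
  in which each mRNA record is a transcript.
* **Minus-strand genes** are handled entirely in transcript orientation;
  exon 1 of a minus-strand model is the rightmost genomic exon and all
  sequences are reverse-complemented on access.
* **"Unique" mapping** means exactly one placement at the best mismatch
  count (built-in aligner) or MAPQ ≥ 1 and not secondary (SAM import);
  the mismatch budget of the built-in aligner is 2 by default.
* **Local alignment surrogate.** Match +1, mismatch −1, gap −2, minimum
  block score 16; equivalent to a textbook Smith–Waterman on small
  instances, which the tests verify against an independent dynamic-programming
  oracle. The scoring stands in for an external local aligner whose exact
  internals are not part of the method.
* **Exact-match floor.** Remainders shorter than 8 bp are not searched;
  below that length exact hits are dense enough to be meaningless.
* **GFCR coverage.** The two blocks must partition the read exactly (gap
  tolerance 0, configurable); uniqueness of a GFCR is keyed on the partial
  alignment's start coordinate, mirroring the paired-end duplicate rule.
* **Tie-breaks.** Prioritized candidates sort by PEFS, then pair count,
  then lexicographic gene pair; the predicted junction breaks spanning-read
  ties toward the lowest exon ordinals.
* **Degenerate inputs.** Empty read sets, fusion-free libraries, zero
  spanning reads, zero-expression references and breakpoints at terminal
  exons all return well-defined empty/NA results rather than errors.

# Limitations

The built-in aligner is exact-seed based and intended for toy genomes — its
role on real data is taken by SAM/BAM import. Genomic (DNA-level) breakpoint
inference, copy-number integration, cohort recurrence screening and
gene-level differential expression are out of scope. The in-frame call uses
the first transcript model per gene when several exist.
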