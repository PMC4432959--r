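---
title: "Tailoring gene models in compact genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tailoring gene models in compact genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txtailor)
```

`txtailor` implements the post-assembly computations of a
transcriptome-based genome reannotation: refining transcript 3' ends
with 3'-end-tag evidence, classifying alternative-splicing (AS) events
among isoforms, comparing competing annotation sets, and profiling
transcription-terminal sequence signals. This vignette explains the
procedures, the parameters that matter, the design decisions taken where
the methods were genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## The data model

An annotation is four tibbles — genes, transcripts, exons, CDS — with
1-based, closed coordinates on the forward genomic axis and orientation
carried by a strand column. We chose 1-based closed (rather than
0-based half-open) coordinates because the entire R/Bioconductor
interval stack (IRanges, GenomicRanges, Biostrings, rtracklayer) uses
that convention; with it, GFF3 I/O needs no coordinate conversion and
every library call is convention-free. UTRs are never stored: they are
derived on demand as the exonic bases 5'/3' of the CDS on the transcript
strand, which keeps the model normalised and makes the GFF3 round trip
an identity.

## 3' end extension

CEL-Seq-style protocols sequence transcript 3' ends, so read pileups mark
true termination sites. The procedure:

1. **Clustering** (`cluster_reads`): single-linkage merge of reads
   overlapping by at least 1 bp, per scaffold, strand and sample.
   "Overlapping" is taken literally — abutting reads (gap 0) do not
   merge. Clusters with fewer than `min_cluster_reads = 10` reads are
   discarded as noise. Filtering precedes cross-sample merging, so the
   threshold applies within each sample.
2. **Merging** (`merge_sample_clusters`): same-strand overlapping
   clusters from different samples are union-merged, counts summed and
   sample sets unioned. A merged cluster may therefore exceed any single
   sample's count; whether the original study pooled or merged across
   samples is not recoverable from its description, so merging is our
   documented choice (it is idempotent and order-free).
3. **Extension** (`extend_three_prime`): a transcript is eligible if it
   has an annotated (derivable) 3' UTR; a cluster qualifies if it is
   same-strand and overlaps the transcript's last exon by at least
   `min_overlap_bp = 10`. The 3' end moves out to the farthest
   qualifying cluster boundary — farthest because the evidence supports
   termination at least that far, and any smaller choice would be
   arbitrary. 5' ends, internal exons and CDS are untouched; extension
   past a scaffold end is clamped with a warning. Applied per
   transcript, which subsumes the single-isoform ("per gene") case.

The operation is monotone (no coordinate moves inward) and idempotent;
both properties are asserted in the test suite, together with exact
recovery of simulated true ends and strand-mirror symmetry.

## Alternative-splicing classification

The seven event classes are standard names, but their operational
definitions are rarely written down; ours are as follows, all
strand-aware, with "donor" the intron boundary nearer the transcript 5'
end. The canonical isoform is the gene's representative — the isoform
with the longest ORF (ties: longer transcript, then smallest id).

* **IntRt** — a canonical intron every base of which is exonic in the
  alternative isoform, the covering exon also overlapping both flanking
  canonical exons. Footprint: the intron.
* **ExSk** — a canonical *internal* exon lying entirely inside one
  alternative intron whose outer boundaries match the flanking canonical
  introns' outer splice sites. Footprint: the skipped exon.
* **AltAc / AltDo** — an alternative intron sharing its donor (resp.
  acceptor) with a canonical intron but not the other boundary. We
  additionally require the exons distal to the differing boundary to
  overlap between the isoforms: without this, an alternative *terminal*
  exon (which shares the donor of the canonical last intron but lies
  beyond the canonical terminal exon) would always be absorbed by
  AltAc/AltDo and the AltTEx class could never fire. Footprint: the
  alternative intron.
* **AltTEx** — the alternative isoform's first or last exon overlaps
  neither the corresponding canonical terminal exon nor the interior of
  a canonical intron, while at least one intron is shared exactly.
  Footprint: the alternative terminal exon.
* **IntSt / IntEnd** — the alternative transcript's start (end), in
  transcript orientation, lies strictly inside a canonical intron.
  Footprint: that intron.

A single structural difference never receives two labels: exon-skipping
introns are excluded from donor/acceptor comparison and intron-interior
termini from AltTEx, which realises the precedence
IntRt > ExSk > AltAc/AltDo > AltTEx > IntSt/IntEnd deterministically.

**Support.** An event's support is the number of transcripts exhibiting
the *alternative* form; events from different isoforms with identical
(class, footprint) merge and union their supporters. "Supported by at
least three transcripts" could also be read as counting either form or
assembly-level alignments; counting the minority structure is the
conservative reading and is what `filter_events(min_support = 3)`
implements. The summary reports, per class, event and transcript counts
and three percentages (of AS events, of AS transcripts, of all
transcripts), rounded to one decimal. Transcript-based percentages can
sum above 100 because one transcript can carry several event classes.
When the summariser is fed pre-aggregated per-class counts, the
distinct-AS-transcript denominator is not derivable and that column is
`NA` unless supplied.

## Annotation comparison and structure statistics

Coverage of a gene by another set is the fraction of its *exonic* bases
covered by same-strand exonic bases of any target gene (the 80 %
criterion is meant to tolerate missing UTRs, i.e. it concerns transcribed
structure; a span-based mode is provided as an option). Hierarchical
assignment walks the precedence order: every reference gene lands in the
region named by which lower-precedence sets cover it at threshold; each
non-reference set contributes only its genes not covered by any
higher-precedence set, assigned among the remaining sets by the same
rule. Only the reference therefore keeps its cardinality — the invariant
the tests assert. One-to-many correspondences (fragmented or merged
loci) are reported separately rather than double-counted.

Structure statistics count distinct exons and introns per gene (identical
intervals shared by isoforms count once), use gene spans (introns
included) for lengths, and measure genome coverage as the union of gene
spans over total genome length. Intergenic distances sort gene spans per
scaffold by start irrespective of strand and clamp overlaps to zero.
Every statistic is checked against an independent naive recount.

## Terminal signals

Strict sets restrict signal analyses to anchors with reliable context:
3' UTRs overlapping a tag cluster on scaffolds longer than 50 kb
(strict inequality), and TSSs whose promoter (100 bp upstream, 50 bp
downstream) overlaps no other gene, again on > 50 kb scaffolds — short
scaffolds would depress motif frequencies purely through missing
flanking sequence.

Motif scanning is IUPAC-consensus matching (every base compatible;
overlapping matches all reported) or PWM log-odds scanning against a
uniform background, with the threshold expressed as a fraction of the
motif's maximum score (default 0.6 — the converted-matrix scanning
threshold of the original toolchain is not documented, so this is a
package default, tunable per motif). MEME minimal-format files are
parsed directly.

Positional profiles extract ± `window` (2,000 bp) around each anchor in
transcript orientation on the coding strand, scan, and bin match starts
into 20 bp bins. Sequences truncated by scaffold edges contribute only to
the bins they fully cover, so each bin's frequency is hits per
contributing sequence — denominators are explicit per bin rather than
assuming equal flank availability. Cumulative PAS curves count, for each
offset 1..500, matches within that many bp upstream (resp. downstream)
of the TSS, normalised per TSS; scanning is coding-strand only, which is
what makes the upstream/downstream contrast meaningful (a double-strand
flag exists).

## The synthetic-data generator

The generator's defaults emulate a compact, gene-dense genome: median
intergenic gap 587 bp (log-normal, sdlog 0.7), mean intron length
~327 bp (log-normal around a 280 bp median, sdlog 0.55), 1 + Poisson(4.2)
exons per gene (mean 5.2), exon lengths around 220 bp, 80 % of genes with
a 3' UTR. Background sequence is i.i.d. uniform ACGT, which makes motif
nulls closed-form (AWTAAA rate 2·(1/4)^6 per position) — a property the
profile tests exploit.

Coding sequence is *designed*: each gene's CDS is ATG, stop-free random
codons, then a stop, written into the exon positions (reverse-complement
on the minus strand), and the last three 5'-UTR bases are a stop codon so
no chance upstream ATG can extend the frame. The designed ORF is thus
the longest ORF of the canonical isoform, making representative
selection well-defined.

`spawn_isoforms` adds isoforms differing from the canonical by exactly
one event (truth labels stay unambiguous; a gene hosts at most one event
class), each replicated `n_support` times, optionally with a fraction of
genes given only two supporters to exercise the support filter. Two
guards keep the truth table consistent with the pipeline's canonical
rule: retained introns are preferentially chosen with lengths that are
not codon multiples (so retention frameshifts the ORF), and any gene
where the structural edit would still hand the alternative isoform the
longest ORF — e.g. terminal-exon replacement deleting the stop codon and
reading through into a longer chance ORF — is skipped. Noise tag
pileups carry at most 9 reads (one below threshold) and are placed away
from genes so they can never merge with a true pile and shift its
boundary.

What the generator does **not** emulate: read-level error and coverage
variation, expression levels, multi-class isoforms, overlapping genes,
alternative polyadenylation heterogeneity, and non-uniform (isochore or
repeat) sequence composition. Passing the recovery tests therefore shows
the *logic* of clustering, extension and classification is exact under
clean evidence; it does not certify performance on noisy real libraries.

## Numerical and testing choices

Problem sizes were chosen to make every property measurable while
keeping the default suite fast: 200-gene genomes (four ~250 kb
scaffolds) for end-recovery and classification recovery, a 500-gene
genome for distribution-recovery (realised median intergenic gap within
10 % of the configured 587 bp), and ≥ 100 random instances per
brute-force oracle comparison (ORF enumeration, sliding-window motif
scan, per-base coverage bitmaps, union-find read clustering, naive
structure recounts). Degenerate inputs are defined, not errors: empty
annotations summarise to zeros, single-exon transcripts have no introns,
scaffolds with one gene contribute no intergenic distance (median `NA`),
and zero-event summaries divide nothing.

## Limitations

* Classification is structural only — no read-support quantification
  (PSI) and no splice-site sequence scoring.
* Extension never creates new exons: a cluster disjoint from the last
  exon (a potential unannotated terminal exon) is ignored.
* The AltAc/AltDo versus AltTEx boundary cases and the support-counting
  semantics follow the package's documented definitions above; other
  readings exist and would shift class counts on real data.
* Coverage-threshold comparison is exon-base by default; span-based
  comparison (also provided) can differ for genes with long introns.
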