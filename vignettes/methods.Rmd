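---
title: "Detecting and filtering indel RNA-DNA differences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and filtering indel RNA-DNA differences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA editing by insertion or deletion of single nucleotides is well
documented in kinetoplastids, paramyxoviruses and *Physarum*, but evidence
for it in human is essentially absent.  Searching for it genome-wide means
looking for single-base indel differences between RNA-seq reads and the
matching genome of the same individual — and such call sets are dominated by
artifacts.  Four mechanisms account for nearly all of them:

1. **Diploid alleles.**  Reads are mapped against one haplotype (here
   called "maternal").  A heterozygous indel makes reads transcribed from
   the other haplotype look edited.
2. **Splice junctions.**  A non-splice-aware aligner forces exon-junction
   reads onto the genome; when the intron start resembles the downstream
   exon, the best full-length alignment contains a small gap (often with
   extra mismatches) near the junction.
3. **Paralogs.**  When a transcribed copy of a locus is absent from the
   assembly used for mapping, its reads land on the sibling locus and
   consistently exhibit the copy's divergence, including its indel.
4. **Known genomic variants / misassemblies.**  Real homozygous indels
   missing from the assembled haplotypes show up in (nearly) all reads and
   sit in the variant databases.

`indelrdd` implements the full pipeline: a synthetic diploid genome and
spliced-read simulator that plants each mechanism with truth labels, a
seed-and-extend gapped aligner, a pileup-based indel caller with the
standard initial filters, the four-way classification cascade, and a
sensitivity analysis.  Everything is deterministic given a master seed.

## The synthetic study conditions

The default configuration (`default_config()`) emulates a compressed
version of a lymphoblastoid RNA-seq experiment against a personal diploid
genome:

* one 200 kb contig at 41% GC;
* 20 spliced genes (2–6 exons of 150–300 bp, GT..AG introns of 70–140 bp),
  a quarter of which carry a *decoy* first intron whose prefix copies the
  downstream exon with one extra base — the construction that reproduces
  the splice-junction indel artifact;
* 10 heterozygous single-base indels and 60 SNPs planted in exon cores,
  plus 10 "misassembly" indels (present in the transcribed molecules,
  absent from both assembled haplotypes, always database-annotated) — the
  mechanism behind database-matched false positives;
* 5 paralog pairs (500 bp, 2% divergence, exactly one single-base indel),
  modelled as assembly gaps: the copy exists only in the reference contig
  and is transcribed from it, while both assembled haplotypes keep their
  original sequence, so the copy's reads can only map to the source locus;
* 200,000 single-end 33 bp reads with 1% substitution errors and a
  two-state quality profile (Q37/Q10; error bases are low-quality with
  probability 0.9), drawn uniformly from transcripts of both haplotypes;
* optionally, single-base editing events planted in transcripts at a
  configurable molecule fraction (default 0.5), at least 40 bp from
  transcript ends and junctions and outside homopolymer runs longer than 5.

Two deliberate departures from purely random placement: planted variant
sites are separated by at least 40 bp and kept at least 45 bp away from
every internal exon boundary.  At this compressed scale (10 indels in
~24 kb of exonic sequence, roughly forty-fold denser than heterozygous
indels in a real exome), unconstrained placement regularly superimposes two
mechanisms inside a single read window — e.g. a heterozygous indel riding
along in junction-spanning reads — which produces compound candidates that
no single-mechanism filter can claim.  Real genomes exhibit such compounds
at negligible rates, so the generator keeps one mechanism per candidate
column; the same separation rule governs editing placement.  Consequently,
a pass on synthetic data says nothing about how the cascade handles
overlapping mechanisms, read lengths other than 33/54 bp, realistic
error-cycle profiles, paired-end data, or non-canonical splicing — all out
of scope here.

Read length 33 bp mirrors the first-round data this class of experiment
used; 54 bp runs are a configuration change (`config$reads$read_length`).

## Alignment

Mapping is seed-and-extend: a contiguous k-mer index (k = 14 by default,
valid range 4–20) over the target haplotype; lookups returning more than
K = 8 locations are *repetitive* and contribute no candidates; candidate
locations per read are capped at M = 1280.  Each candidate is aligned with
affine-gap local Smith-Waterman (match +1, mismatch −3, gap open 5, gap
extend 2, gap of length L costing `open + L*extend`).  Under this scheme a
single 1 bp gap (−7) beats three mismatches, the regime in which gapped
short-read aligners report indels, and a terminal mismatch is cheaper to
clip than to keep — which is why error bases near read ends leave reads
unmapped rather than misaligned.

Only alignments covering the read end-to-end are reported; a best alignment
that soft-clips any base leaves the read unmapped, so that downstream
counting only sees reads mapped over their entire length.  Ties resolve
deterministically (higher score, full-length before clipped, fewer gaps,
leftmost coordinate, plus strand).  MAPQ is a contract rather than a
reproduction of any aligner's formula: 0 on a score tie, 60 with no
full-length runner-up, otherwise `min(60, 6 * margin)` under default
scoring.  Indels are left-aligned (anchored on the base before the event)
before any counting, so representations are comparable across reads and
with the variant database.

The aligner's correctness is anchored by a dual oracle: an exhaustive
enumeration of every gapped alignment of every substring pair validates an
independently written R dynamic program on tiny strings, and that oracle
checks the C++ implementation on all pairs up to length 6 over {A,C}.

## Initial filtering

Candidates are called from pileup columns at (left-aligned) indel anchors.
Read-level rules remove entries with base quality below 20 at the column or
mapping quality below 20, and indel-carrying reads whose event lies within
2 bp of either read end or that carry more than 3 mismatches.  Site-level
rules then require: at least 2 indel-containing non-duplicated reads
(duplicates = identical contig/start/strand/CIGAR, a definition the source
criteria leave open); at least 5 covering reads; at least 5% supporting
fraction (deliberately far below the 50% a genotype-caller would demand,
because editing can be a minority species); variant quality at least 0.01;
a single non-reference allele; no Ns; indel size exactly 1; homopolymer run
at most 5.

Variant quality is defined self-containedly as the Phred-scaled probability
that all supporting events are errors — the sum of supporting event
qualities, capped at 255 — rather than a genotype-likelihood QUAL.  The
"below 0.01" threshold is kept as stated even though on a Phred scale it is
effectively permissive; `variant_quality_units = "probability"` reads the
same number as a maximum error probability (0.01 ⇒ Phred 20) for users who
prefer the stricter interpretation.  The 5% denominator counts reads that
survive the read-level filters, for internal consistency; both choices are
configurable.

One measurable consequence of the full-length mapping rule: supporting
reads whose indel lies within ~8 bp of an end score better clipped and are
therefore unmapped, so the *observed* support fraction at an editing site
planted at molecule fraction 0.5 settles around 0.35–0.40, not 0.5.  The
binomial bookkeeping invariant (support/coverage ≈ fraction) holds at the
pileup level and is tested there.

## The classification cascade

Filters run in a fixed order — paternal allele, splice junction, paralog,
known variant — and the first match assigns the label; candidates matching
nothing are *residual*.  The counts always partition the input, and the
report writer refuses to render a summary that violates this.

**Paternal allele.**  Every indel-supporting read is realigned to the
homologous locus of the other haplotype (located through the liftover
tables).  The candidate is a genuine diploid difference when each one
matches there full-length without gaps, allowing `mm_max_paternal = 3`
mismatches (supporting reads passed the ≤3-mismatch rule against the
calling haplotype, and substitution errors persist against the other one).
Both patterns occur: all reads paternal, or a maternal/paternal mixture.

**Splice junction.**  Three criteria against a single transcript of the
reference-derived annotation: (1) the unedited 65 bp window (32 bp each
side of the anchor) aligns gaplessly at its expected reference locus;
(2) it aligns gaplessly to the transcript only partially (at least
`min_anchor = 15` bp, at most `partial_max = 0.9` of the window), the
transcript overlaps the candidate locus, and the alignment breakpoint falls
within `junction_tol = 15` bp of an annotated junction; (3) the
indel-carrying sequence aligns to the same transcript full-length without
gaps, allowing `mm_max_splice = 3` mismatches.  Criterion (3) accepts
either the edited window or the supporting reads themselves (≥90% of them);
the read-based route matters because real junction artifacts sometimes
align with *two* small gaps, which no single reapplied indel can
reconstruct.  `junction_tol` is generous because the gapless segment can
legitimately overshoot the boundary through a short repeat or chance
matches.  The locus-overlap and junction-proximity conditions exist to stop
the splice filter from absorbing paralog- and misassembly-derived
candidates, whose edited windows also match a transcript perfectly.

**Paralog.**  The edited window is scanned against the whole reference
(both strands) for a gapless match covering at least `full_min = 0.95` of
its length away from the candidate's own locus, allowing
`mm_max_paralog = 6` mismatches — more than the splice filter because the
planted copies diverge by 2%, i.e. ~1.3 expected substitutions per 65 bp
window, and the source criteria impose no mismatch cap on this search.

**Known variant.**  The candidate, lifted to reference coordinates, must
match a database indel of identical kind and sequence exactly, or within
the homopolymer run that makes two left-aligned representations
equivalent.

## Sensitivity analysis

Maternal/paternal single-base differences are enumerated either from the
truth liftover or by anchored global alignment of the contig pair (the two
routes are cross-checked on small contigs).  Sites are ranked by read
coverage under the same read-level filters as calling, sites in
homopolymer runs longer than 5 are excluded, and recovery is the fraction
of selected sites matched by a passing candidate — on maternal coordinates
alone, and combined with a paternal-side calling run (the identical
pipeline with haplotypes swapped).  Both the top-N (default 100) and the
all-covered (≥5 reads) denominators are reported, since the published
"nearly 90%" could refer to either.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally, 1-based in SAM/VCF/GFF3.
'N' never scores as a match.  Candidates whose anchor would fall before
position 0 (event at a contig start) are dropped, as they cannot be
expressed in anchored notation.  Windows truncate at contig ends with the
offset recorded.  Global alignment is guarded to ~3×10^7 cells; larger
contig pairs must use the liftover route.  Stage seeds are a fixed affine
function of the master seed so stages can be re-run in isolation.

## Problem sizes

The shipped analyses and tests use the default study conditions above
(200 kb genome, 200k reads) for end-to-end properties, with 8–20 replicate
genomes for the specificity and retention measurements, and smaller
configurations (40–60 kb, 6k–40k reads) for unit-level behaviour.  These
sizes were chosen so a complete run takes seconds to minutes on one core
while every mechanism still yields multiple candidates per run.

## Known limitations

* The aligner is deliberately not splice-aware — the artifact under study
  exists precisely because the original analysis used non-splice-aware
  mappers — and has no base-quality-aware scoring or paired-end logic.
* MAPQ is a monotone contract, not BFAST's or bowtie2's formula; filter
  thresholds on it (Q20) are meaningful but not numerically transferable.
* The classifier's BLAST-equivalent searches use score/identity thresholds;
  E-values are meaningless at desk-scale database sizes.
* Editing with insert-base composition biases (e.g. uridine-only) is
  supported via configuration but defaults to a random base, since the
  insertion chemistry in human is unknown.
* Overlapping mechanisms (two planted features within one read window) are
  excluded by generator design; on real data such compound sites would
  surface as residual candidates needing manual review.
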