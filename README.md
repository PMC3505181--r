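# indelrdd

Detection and false-positive filtering of single-base **indel RNA-DNA
differences** (putative insertional/deletional RNA editing) in short-read
RNA-seq data mapped against a matching diploid genome.

## The problem

Insertion/deletion RNA editing is established in kinetoplastids,
paramyxoviruses and *Physarum*, but essentially undocumented in human.
Hunting for it genome-wide means calling single-base indels between RNA-seq
reads and the same individual's genome — and the raw call set is dominated
by four artifact classes:

| Mechanism | Why reads look "edited" |
| --- | --- |
| Diploid (paternal) allele | reads come from the haplotype not used as mapping reference |
| Splice junction | a non-splice-aware aligner forces junction reads onto the genome with a small gap |
| Paralog | a transcribed copy missing from the assembly donates reads to its sibling locus |
| Known genomic variant | a real homozygous indel missing from the assembly (misassembly), present in the SNP database |

`indelrdd` implements the whole workflow: a **synthetic diploid genome and
read simulator** that plants each mechanism with truth labels (plus optional
genuine editing at a controllable molecule fraction), a **seed-and-extend
gapped aligner** (affine-gap Smith-Waterman; only full-length alignments
count), a **pileup-based indel caller** with the standard initial filters
(base/mapping quality ≥ Q20, indel ≥ 3 bp from read ends, ≤ 3 mismatches on
supporting reads, ≥ 2 non-duplicate supporting reads, ≥ 5 covering reads,
≥ 5% supporting fraction, single allele, size 1, no N, homopolymer ≤ 5), a
**four-way classification cascade** assigning each surviving candidate
exactly one label (`paternal_allele`, `splice_junction`, `paralog`,
`known_variant`, or `residual` — the putative editing signal), and a
**sensitivity analysis** measuring recovery of haplotype indel differences.

The core claim the pipeline supports: with stringent filtering, *every*
initial candidate is explained by an artifact mechanism (residual = 0)
while genuine planted editing is retained.

## Worked example

```r
library(indelrdd)
cfg <- default_config(seed = 1, out_dir = "results/demo_run")
run <- run_pipeline(cfg)
run$classification$counts
```

With the default study conditions (200 kb diploid genome, 20 spliced genes
of which 5 carry artifact-prone "decoy" introns, 5 paralog pairs, 10
heterozygous and 10 misassembly indels, 200,000 33 bp reads at 1% error, no
planted editing) this prints:

```
      initial_candidates         paternal_alleles         splice_junctions
                      24                        7                        5
       paralog_sequences known_genomic_variations                 residual
                       5                        7                        0
```

24 candidates pass the initial filters; the cascade attributes every one of
them to its planted mechanism (here 100% agreement with truth, checked with
`expected_labels()`), and the residual row — the would-be editing signal —
is 0.  Re-running with `cfg$editing$n_sites <- 20` plants twenty genuine
editing events at a molecule fraction of 0.5; those sites then survive the
entire cascade as `residual` calls.

All stage artifacts land in `out_dir`: genomes (FASTA), gene models
(GFF3), truth and known-variant VCFs, reads (FASTQ) with a truth table,
alignments (SAM), the candidate VCF, a per-candidate filter audit, the
classification table, and the category summary in the standard five-row
layout plus Residual.

The `analysis/` directory holds numbered driver scripts
(`01_demo_run.R` … `04_sensitivity.R`) that reproduce the demo run, the
specificity and label-accuracy replicates, the signal-retention
measurement, and the sensitivity analysis, writing tables under
`results/`.

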