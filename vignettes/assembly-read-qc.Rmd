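---
title: "Assessing assemblies and reads with asmqc: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing assemblies and reads with asmqc: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

## The assessment model

De novo assemblies of non-model organisms rarely have a reference genome to
validate against, so `asmqc` judges an assembly by the only two objects that
always exist: the reads and the scaffolds. The underlying assumption is that
a good assembly should *explain its own input* — most reads should map back
onto the scaffolds uniquely and cleanly — and that reads that were bad
before assembly (low base quality) are the natural suspects when they map
badly afterwards. The two reports are designed to be cross-checked: a
dataset dominated by poor-quality reads in the pre-assembly report explains
a dataset dominated by clipped or unmapped reads in the post-assembly one.

### Pre-assembly: base-quality categorization

Each read is summarized by its minimum base score (MinimalQ) and by
%HighQ(q), the fraction of its bases at or above Phred q. The categories
are:

* **HIGH** — MinimalQ ≥ 20, i.e. %HighQ(20) = 100%. Every base has at most
  a 1% error probability.
* **POOR** — strictly more than 10% of bases score Q14 or less ("less than
  Q15" and "Q14 or less" are the same criterion for integer scores; the
  code tests `score <= 14`). The boundary is strict: exactly 10% low bases
  is MEDIUM.
* **MEDIUM** — everything else.

N bases keep their (typically minimal) quality scores and participate in
all quality statistics; GC content is computed over unambiguous bases only.
Both choices match common QC practice. The %HighQ distribution is reported
on a fixed grid q ∈ {10, 15, 20, 25, 30, 35, 40} rather than all 94
possible scores to keep bundles small; the grid is an argument. Within each
grid value the empirical distribution over reads is stored as quantiles at
5% steps plus the fraction of reads at exactly 100% — a compact,
JSON-stable encoding of the cumulative curve.

### Sampling

Analyses run on a uniform random sample (default one million reads, the
scale at which the statistics stabilize while staying fast). From a file
path the sample is drawn by `ShortRead::FastqSampler`, a single-pass
streaming reservoir sampler, so arbitrarily large FASTQ files are handled
in bounded memory; from an in-memory read set a plain index sample is
drawn, since the streaming property is moot once the data are loaded. Both
paths are deterministic given `(input, n, seed)`. The sample is written to
`sampled.fastq` so the *same* reads feed both the quality statistics and
any external aligner; sampling does not guarantee preservation of input
order. Sampling can be bypassed entirely.

### Post-assembly: seven labels from SAM evidence

The aligner itself is pluggable — the analysis consumes SAM, and a
convenience wrapper can invoke `bwa mem` (local) and `bwa aln`/`samse`
(end-to-end) when available. From each run, every sampled read is reduced
to one observation: mapped or not, multiplicity (primary record plus
secondary/supplementary records plus XA-tag alternative hits; MAPQ is
deliberately not consulted, because reported locations are the explicit
evidence of repeat placement), substitutions, indel bases, clipped bases,
and the alignment score. Substitution counting prefers the MD tag, which
encodes the exact substituted positions; without MD it falls back to
NM − (inserted + deleted bases), since NM conflates indels with
substitutions. Clips sum soft and hard CIGAR operations, and hard-clipped
bases are added back to the read length so all density ratios are over the
full read. Read length and N content always come from the FASTQ record,
not the SAM SEQ field, which may be hard-clipped or reverse-complemented.

Labels are assigned in a fixed order: **N** (the read contains an ambiguous
base — screened before any mapping evidence, so even a perfectly mapped
N-containing read is N), **F** (unmapped), **M** (multiplicity > 1),
**P** (unique, error-free), **S** (≥ 1 substitution), **C** (contains
clips), **O** (otherwise: indels only). A unique read with both
substitutions and clips is S under this order; because the original flow
diagram for this tie is not published, `label_reads(priority = "CS")`
provides the alternative reading. The choice only moves reads between S and
C and, with equal default thresholds, rarely changes PM%.

### PM% and the verdict

P and M are always highly mapped; F is always poorly mapped. S, C, N and O
reads are split by their error-density ratio — mismatch, clip, N and indel
ratio respectively — against a threshold: strictly above means poorly
mapped. PM% is the sum of the poorly-mapped percentages, and with two
aligner runs the final PM% is their mean. The assembly passes when final
PM% < 20 (strict).

Threshold defaults and their provenance: only the clip-ratio threshold
(0.3) is anchored in the method's published description. The mismatch, N
and indel thresholds reuse 0.3 for uniformity, are configurable, and are
flagged in the HTML report. The method's description is silent on whether
O reads contribute to PM% at all; here they do, through an indel-density
ratio under the same mechanism, and `thresholds(other = NA)` switches to
the stricter reading in which only F/S/C/N contribute. Raising any
threshold can only shrink the poorly-mapped side, so PM% is monotone
non-increasing in every threshold — a property the test suite checks.

### Contiguity metrics

Nx is the length of the scaffold at which the cumulative length of
descending-sorted scaffolds first reaches x% of the assembly size (the
"≥ crossing" convention, matching the QUAST tool family), Lx the count of
scaffolds in that prefix; ties among equal-length scaffolds are resolved by
the sorted position at which the threshold is crossed, which leaves the
statistics permutation-invariant. GC% excludes ambiguous bases from its
denominator. NGx/LGx against a known genome size are computed only when
that size is supplied, and are NA when the assembly never reaches x% of it.

## Numerical and display choices

* All percentages are carried at full double precision; only display is
  rounded, to one decimal. Display rounding is decimal-aware (the value is
  snapped to four decimal digits first, so binary float noise cannot flip a
  digit) and exact halves round toward zero — the convention that
  reproduces the method's printed statistics, e.g. the mean of per-aligner
  PM% values 8.8 and 16.3, 12.55, displays as 12.5.
* The Phred offset is fixed at +33 (all modern Illumina data);
  auto-detection is error-prone and deliberately not attempted.
* Degenerate inputs fail loudly: empty read collections, empty assemblies,
  zero-length reads and sampled reads missing from a SAM are errors;
  mapped records lacking both MD and NM degrade to zero substitutions with
  a warning; a label with no alignment scores yields an empty summary, not
  an error.
* Exit codes of the command-line wrapper: 0 pass, 2 failed assessment,
  1 runtime error, so CI pipelines can gate on the verdict.

## What the synthetic fixtures emulate — and what they do not

`sim_quality_reads` constructs quality strings that *satisfy the category
definitions by construction* (HIGH: all scores in 20–40; MEDIUM: one base
in 15–19; POOR: ⌊0.1·L⌋+1 bases in 2–14), and `sim_labeled_sam` writes SAM
records whose FLAG/CIGAR/MD/NM/AS/XA fields force each read's ground-truth
label: planted substitutions with consistent MD strings, soft clips of
controlled length, alternating insertion/deletion O reads (exercising both
the CIGAR I/D and MD deletion syntax), M reads alternating XA-tag hits and
secondary records, and NM always equal to substitutions plus indel bases so
both substitution-derivation paths stay testable. Category and label mixes
are apportioned deterministically (largest remainder), so tests assert
exact equality of recovered fractions rather than approximations; a
stochastic mode exists for property-style tests. Error-density ratios are
planted at a low and a high value around the 0.3 threshold with a
deterministic above-threshold count, which makes the expected PM% exactly
hand-computable. Alignment scores are drawn from label-specific normal
distributions with means declining 0.98L (P) → 0.85L (S) → 0.70L (C),
emulating the observed ordering of score distributions.

These fixtures validate the *bookkeeping*: parsing, classification,
thresholding, aggregation, determinism. They do not model realistic
sequencing error spectra (no quality-by-cycle decay, no platform-specific
substitution biases, no adapter contamination), nor realistic genome
repeat structure — M reads are declared multi-mapped by their SAM evidence
rather than by genuine sequence duplication. Passing tests therefore
demonstrate that the statistics are computed correctly from alignment
evidence, not that any particular real dataset will pass or fail the
assessment. An integration test aligning fixture reads with `bwa`
(both strategies) checks that the pipeline behaves sensibly on real
aligner output.

## Problem sizes

The test suite and acceptance script run on deliberately small inputs:
fixture SAMs of 100–700 reads, 5,000–10,000 simulated reads for
pre-assembly recovery and monotonicity sweeps, 500 random assemblies of up
to 30 scaffolds for the contiguity oracle, and 10,000 seeded draws for the
sampling-uniformity check. These sizes give exact or tight statistical
checks in seconds; all statistics scale linearly in reads and SAM records,
and the default one-million-read sample is the intended production scale.

## Known limitations

* Single-end analysis only: paired files are treated as independent
  single-end inputs, and mate/insert-size evidence is unused.
* Only one reported location scheme is understood (secondary/supplementary
  records and XA tags); aligners that report multiplicity some other way
  will undercount M reads.
* The seven-label scheme attributes each read to its primary alignment's
  error profile; a multi-mapped read with errors at its primary site is
  simply M.
* Base-by-base coverage analysis, orthologue completeness and
  reference-based misassembly detection are out of scope — they answer
  different questions than read-mapping self-consistency.
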