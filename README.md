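# asmqc

Two-way quality assessment of de novo genome assemblies and their input
sequencing reads. Draft assemblies of non-model organisms usually have no
reference genome to validate against, so `asmqc` assesses them from two
directions that need nothing but the reads and the scaffolds themselves:

* **Pre-assembly**: are the reads any good? A uniform sample of reads is
  scored by per-base Phred quality and each read is categorized as
  high-, medium- or poor-quality.
* **Post-assembly**: do the reads map back cleanly onto the assembly built
  from them? Each sampled read is classified from its SAM alignment evidence
  into one of seven labels, and the headline *poorly-mapped percentage*
  (PM%) summarizes how much of the input the assembly fails to explain.

## The statistics

**Read quality.** For a read with base scores *q1 … qL*,

* MinimalQ = min *qi*;
* %HighQ(q) = #\{*i* : *qi* ≥ *q*\} / *L*, so %HighQ(q) = 100% ⇔ MinimalQ ≥ q.

A read is **HIGH** when MinimalQ ≥ 20, **POOR** when strictly more than 10%
of its bases score Q14 or less, and **MEDIUM** otherwise.

**Read labels.** Each sampled read receives exactly one label, decided in
order: **N** (contains an ambiguous base — screened before mapping), **F**
(unmapped), **M** (multi-mapped: primary plus any secondary/supplementary
record or XA-tag hit), **P** (unique, error-free alignment), **S** (unique,
≥ 1 substitution), **C** (unique, contains soft/hard clips), **O** (unique,
indel errors only).

**PM%.** P and M reads are highly mapped; F reads are poorly mapped; S, C,
N and O reads are split by an error-density ratio against a threshold
(default 0.3), e.g.

    clip ratio = total clipped length / read length

and the reads whose ratio exceeds the threshold join the poorly-mapped side.
PM% is the sum of the poorly-mapped percentages. With two aligner runs
(typically local + end-to-end, e.g. `bwa mem` and `bwa aln/samse`) the final
PM% is the mean of the two, and the assembly **passes** when PM% < 20.

**Contiguity.** Nx = length of the scaffold at which descending-sorted
scaffolds first cover x% of the assembly; Lx = number of scaffolds in that
prefix; plus max scaffold, GC% (over unambiguous bases) and Ns per 100 kbp.

## Worked example

```r
library(asmqc)
# simulate 1,400 reads spanning all seven labels, and their "assembly"
fx  <- sim_labeled_sam(n_reads = 1400, seed = 42)
asm <- tempfile(fileext = ".fasta")
Biostrings::writeXStringSet(fx$reference, asm)

obs  <- digest_sam(fx$sam, fx$reads)      # SAM -> per-read observations
prof <- profile_labels(label_reads(obs), obs, aligner = "sim")
prof
#> Label profile (sim, 1400 reads)
#>    P    S    C    O    M    F    N
#> 14.3 14.3 14.3 14.3 14.3 14.3 14.3

pm <- compute_pm(prof, thresholds())
pm
#> PM% breakdown (sim): PM% = 42.9
pass_assessment(average_pm(pm, pm))
#> [1] FALSE

contiguity_stats(asm)
#> Assembly: 1 scaffolds, 20000 bp (max 20000)
#>    N25=20000  N50=20000  N75=20000
#>    L80=1  L90=1  L99=1
#>   GC% 50.21   Ns/100kbp 0.00
```

The uniform seven-label mix puts 1/7 of reads in each class; all F reads
(14.3%) plus the halves of the S/C/N/O classes whose planted error ratios
exceed 0.3 (4 × 7.14% × 0.5) are poorly mapped, giving PM% = 42.9 — far
above the 20% pass cutoff, hence `FALSE`.

Full pipelines write JSON bundles and self-contained HTML reports:

```r
run_pre("reads.fastq", "out",  sample_size = 1e6, seed = 1)
run_post("out/sampled.fastq", "assembly.fasta",
         c(mem = "mem.sam", backtrack = "bt.sam"), "out")
```

or from a shell, `Rscript inst/scripts/asmqc.R all reads.fastq assembly.fa
-o out --align` (exit status 0 = pass, 2 = failed assessment, 1 = error).

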