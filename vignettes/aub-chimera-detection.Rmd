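---
title: "Detecting chromosomal micro-mosaicism from A-U-B chimeric reads"
author: "aubscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal micro-mosaicism from A-U-B chimeric reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aubscan)
```

## The problem

Cultured somatic cells accumulate sporadic, karyotypically invisible
chromosomal rearrangements — chromosomal micro-mosaicism. A fusion between
two non-homologous chromosomes present in a small fraction of cells leaves a
faint but characteristic trace in shotgun sequencing data: single reads
whose 5′ part derives from one chromosome and whose 3′ part derives from
another. Standard pipelines discard such reads because they fail to align
end-to-end to a single chromosome, so the signal is ordinarily invisible.

`aubscan` recovers that signal with a deliberately conservative curation
scheme, and separately detects fusions between *homologous* chromosomes
(interallelic chimeras), which alignment alone cannot see, from trio
genotypes.

## Non-homologous chimeras: the A-U-B scheme

Each read of length at least `min_read_len` is split into contiguous,
non-overlapping bins of exactly `bin_size` bases (the sub-`bin_size`
3′ residue is discarded). Each bin is aligned end-to-end and independently
against the unmasked genome. A read is called chimeric only when its bin
labels form the pattern **A⁺ U B⁺**: one or more bins uniquely aligned to
chromosome A, exactly one unaligned transition bin (U), then one or more
bins uniquely aligned to a different chromosome B. Everything else that is
neither cleanly single-chromosome nor fully unaligned is *eliminated*:
reads with any multi-mapping bin, with extra unaligned bins, with unaligned
terminal bins, with more than two chromosomes, or with a direct A→B
transition and no U bin. Two consequences are intentional:

* a junction falling exactly on a bin boundary produces no U bin and is
  missed — we keep the scheme's stated definition rather than "improving"
  it, because the eliminated class is part of the method's published
  accounting;
* a read whose junction lies inside a high-identity repeat multi-maps and
  is eliminated rather than mis-called, which is what makes calls on
  unmasked genomes trustworthy.

### Junction refinement and the signed gap

Each candidate junction is refined by sliding a window of one bin length
in single-base steps across the span from the start of the last A bin to
the end of the first B bin. With `last_a` the largest window start uniquely
aligned to A and `first_b` the smallest start beyond it uniquely aligned to
B, the signed gap is

$$\mathrm{gap} = \mathrm{first\_b} - \mathrm{last\_a} - \mathrm{window}.$$

* **gap < 0** — *dually aligning* junction: the two windows overlap on a
  tract of `-gap` bases that is identical in the read, the A flank and the
  B flank (a microhomology, typically 20–60 bases, the signature of
  microhomology-mediated end joining);
* **gap = 0** — *base-to-base* juxtaposition;
* **gap > 0** — *gapped* junction: inserted bases aligning to neither
  donor.

If no window aligns to A (or none to B downstream of the last A window)
the event is demoted to eliminated; if B-unique windows occur only
*upstream* of the last A window the event is demoted with reason
`non-monotonic` (interleaved repeats can produce this).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_size` | 200 (long-read), 50 (short-read) | bases | long enough for confident unique alignment, short enough to localise the transition |
| `min_read_len` | 600 / 150 | bases | a read must hold at least three bins (A, U, B) |
| `max_mismatch` | `ceil(0.02 * bin_size)` (4 / 1) | substitutions | uniqueness tolerance of the built-in aligner; external aligners' own flags govern SAM ingestion |
| `refine_max_mismatch` | 0 | substitutions | each tolerated mismatch can shift the measured gap by up to 2 bases; 0 keeps the homology-length estimate unbiased (on noisy reads a non-zero value finds more windows at the cost of that bias) |
| `window_step` | 1 | bases | single-base refinement resolution |

The built-in aligner is a seed-and-extend search: a query is cut into
`max_mismatch + 1` disjoint 15-mers, so by the pigeonhole principle every
locus within tolerance is seeded; candidates are verified by direct
mismatch counting over the full query, and the status is `unique` /
`multi` / `unmapped` by the count of qualifying loci across both strands.
For queries of length at least `(max_mismatch + 1) * 15` this is provably
identical to an exhaustive scan, and the test suite asserts that
equivalence against an independent brute-force oracle. `N` mismatches
everything (including another `N`); queries containing `N` may fail
seeding and are reported unmapped — the simulator never emits `N`.
Real-scale data aligned externally (e.g. bowtie2 end-to-end on per-bin
FASTQ) enter through `ingest_alignments()` with query names
`"readid/binindex"`.

## Interallelic chimeras from trio genotypes

Homologous chromosomes cannot be told apart by alignment, so fusions
between allelic copies are detected from genotypes instead. Sites present
in offspring, mother and father (SNVs only, three-way intersection) where
at least one parent carries an allele the other lacks are *informative*:
such an allele observed in a read is a maternal or paternal label.
Per read, labels form a sequence; alleles shared by both parents are
*ambiguous* and skipped (they carry no parent-of-origin signal — they are
never counted as switches). Reads are then:

* `maternal` / `paternal` — zero transitions;
* `interallelic_chimera` — exactly one M↔P transition;
* `eliminated_multiswitch` — two or more transitions (reads are too short
  for two genuine crossovers; these are treated as artefacts);
* `eliminated_mutated` — any allele found in neither parent (sporadic
  culture mutation or sequencing error).

### The somatic mutation correction

The mutation rate is estimated per read: the fraction of
genotype-comparable reads carrying at least one non-parental allele.
Under the independence model in which a base mutates to one of the three
others with probability 0.75 per allele, a diploid genotype is unexpected
with probability $0.75^2 = 0.5625$ (about 56%), and a hemizygous
(male X) observation still matches the maternal allele with probability
0.25 — the package reports both the observed and the model values. Because
roughly the mutation-rate fraction of apparent single switches are
mutation artefacts rather than recombinations, the raw frequency

$$\mathrm{raw\%} = \frac{\#\,\mathrm{chimera}}{\#\,\mathrm{maternal} +
\#\,\mathrm{paternal} + \#\,\mathrm{chimera}} \times 100$$

is deflated to $\mathrm{corrected\%} = \mathrm{raw\%} \times
(1 - \mathrm{rate})$. The denominator deliberately excludes
ambiguous-only and uninformative reads; with published per-class read
counts this choice reproduces the printed percentages exactly, so it is
forced by the published accounting rather than free. The correction
formula itself is verified against all four published raw/corrected pairs
in the unit tests.

## Summary statistics

`events_per_billion()` (events / bases × 10⁹), `sample_summary()`
(mapped %, mean read length, support statistics),
`nonchimeric_support()` (non-chimeric reads with a unique alignment
within ±1 bin of either junction flank — the window is a package choice,
configurable), `annotate_repeats()` (BED intersection of the two refined
window footprints; the U bin itself has no genomic projection since it is
unaligned, and the two flanking windows cover the junction vicinity on
both donors; the primary class is the largest overlap, ties broken
alphabetically), `composition()` (GC%, CpG% over the $L-1$ dinucleotide
positions — the denominator is a documented package choice — and
G/C skew $(G-C)/(G+C)$, defined 0 when $G+C=0$),
`chromosome_pair_matrix()` (symmetric pair counts, Pearson correlation of
per-chromosome involvement against chromosome length),
`sex_chromosome_accounting()` (observed X-U-A percentage, and an expected
percentage that re-scales the test sample's observed value by the ratio
of X-mapped read fractions — with equal X capture, expected equals
observed; the direction of this normalization is inferred from the
published table arithmetic and verified in tests),
`gap_distribution()` and `gene_body_coverage()` (observed
transcript coverage of a seeded random selection of event intervals
versus the mean over 10 length-preserving uniform re-placements;
normalization across samples is seeded downsampling to the smallest
sample's event count).

## What the simulator emulates — and what it does not

The simulator exists so that every stage is testable without external
data, with machine-readable truth.

* **Genome**: i.i.d. uniform background with planted repeat families
  (one master unit per family, copies placed non-overlapping, each copy
  independently diverged). Divergence 0 creates exact multi-mapping
  stress; per-copy i.i.d. divergence creates an older/younger subfamily
  uniqueness gradient. It does **not** emulate nested or truncated
  repeats, GC heterogeneity, or segmental duplications.
* **Reads**: uniform sampling, either strand, fixed or log-normal
  lengths, i.i.d. substitution errors (default 1%, a free choice — the
  source platforms' error rates are not pinned down). No indels: the
  detection method aligns fixed-length windows end-to-end and real indel
  error is absorbed by the external aligner in real-data mode; an indel
  error model would change the toy aligner, not the method.
* **Implants**: the three junction classes built by direct construction;
  dual implants copy the homology tract into donor B so the tract is
  genuinely present at both loci. All genome edits are applied before any
  read is built. Junction-adjacent bases are adjusted so the declared
  homology or insert is *maximal* — otherwise a coincidental match
  (probability 1/4 per boundary base) legitimately extends the apparent
  homology and the refined gap, while remaining a correct measurement of
  the constructed sequence. Truth gaps are therefore exactly recoverable,
  and an independent oracle in the tests re-derives every gap by direct
  read-versus-donor comparison.
* **Trios**: biallelic SNV sites with a configurable informative
  fraction; offspring reads sampled from one parental haplotype; a
  fraction `s` of reads receives exactly one switch placed between two
  adjacent covered *doubly diagnostic* sites (both transmitted alleles
  parent-unique), and a disjoint fraction `m` receives one non-parental
  allele. Placing switches at doubly diagnostic sites makes the truth
  labels exactly recoverable in noise-free observations, which is what
  lets the tests assert label-level equality rather than only rate-level
  agreement. Real data differ: switches may fall in ambiguous stretches
  (reducing sensitivity), observations carry base-calling error, and
  coverage is non-uniform — so passing tests demonstrate correctness of
  the curation logic, not real-data sensitivity.

All generators are deterministic given their seed; identical
configurations produce byte-identical output files.

## Problem sizes and numerical choices

The test and acceptance workloads use two-chromosome genomes of 50–60 kb,
50 implanted junctions with 1000 background reads for end-to-end recall,
and 20,000 simulated trio reads (switch rate 4%, mutation rate 50%) for
rate recovery — sizes chosen so the whole suite exercises every code path
in a few minutes on one core while keeping binomial tolerances tight
(recovery is asserted within 3 binomial standard deviations at the
estimate's own denominator). Tie-breaks are deterministic everywhere:
repeat-class ties resolve alphabetically, window ties cannot arise (starts
are distinct), and the aligner's locus set is order-independent. Degenerate
inputs (empty read sets, zero events, zero classifiable reads, fewer than
three chromosomes for the length correlation) return empty results or
explicit errors rather than NaNs.

## Limitations

* Intra-chromosomal rearrangements, fusions involving more than two
  chromosomes, and telomeric fusions (telomere tracts exceed the bin
  length) are out of scope.
* Junctions exactly on bin boundaries are missed by construction.
* The toy aligner is for toy genomes (it holds a k-mer index in memory
  and is written in R); real-scale data should be aligned externally and
  ingested as SAM/BAM.
* Duplicate-read filtering is not applied before detection for long
  reads; short-read (MeDIP-style) inputs are expected to be deduplicated
  upstream, as is platform practice.
* The gap-histogram double-Gaussian overlay, sequence-motif enrichment
  and fragile-site overlap analyses are not implemented.
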