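---
title: "Detecting intronization signatures in coding exons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intronization signatures in coding exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronsig)
```

## The question and the statistic

In compact genomes such as the *Paramecium tetraurelia* macronucleus,
introns are extremely short (mostly 21-30 bp) and typically bounded by
5'-GTA ... TAG-3'. Any coding tract that happens to carry these boundary
motifs is a *candidate cryptic intron*: the spliceosome occasionally
excises it, and over evolutionary time such a tract can convert into a
real intron. If that conversion is usually harmful, selection should purge
candidate cryptic introns from coding sequence — but only on the strand
and in the size range where the spliceosome operates.

`intronsig` measures this with DNA strand asymmetry (DSA). For a segment
class with sense-strand count $N_s$ and antisense-strand count $N_a$,

$$S = \frac{N_s - N_a}{N_s + N_a}.$$

The antisense strand is the built-in null: under strand-symmetric
evolution a motif and its reverse complement occur at equal rates on the
two strands, so $S \approx 0$, while purifying selection against
sense-strand segments drives $S < 0$. $S$ is always in $[-1, 1]$, equals
$\pm 1$ exactly when one strand count is zero and the other positive, and
is reported as missing (not zero) when both counts are zero — an empty
size class carries no signal.

The assumptions worth keeping in mind:

* **Symmetric mutational background.** Real coding sequence is not
  strand-symmetric at the codon level, so the absolute DSA of, say, all
  GT|AG segments includes an amino-acid-usage component. The analysis
  therefore always contrasts strata (signal class, length mod 3, size
  window, exon position, expression class) rather than interpreting one
  absolute value.
* **Segments are counted where splicing happens.** Enumeration runs
  within single exons and never across exon-exon or exon-intron
  boundaries: cryptic splicing acts on the pre-mRNA, where annotated
  introns interrupt the CDS, so a cryptic intron that spans an annotated
  splice site is not a coherent object. This was a genuinely open choice
  (one could enumerate over the spliced CDS instead); the per-exon
  convention also keeps antisense enumeration exactly symmetric, because
  it runs per exon on the reverse complement.
* **Length includes the boundary dinucleotides**, matching how annotated
  intron lengths are measured, and **all overlapping and nested GT...AG
  pairs are counted** — the enumeration is exhaustive, which is what the
  quadratic-oracle test checks.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_len`, `max_len` | 15, 40 | nt | window covering >99% of annotated introns in the target genome |
| `prevalent_range` | 21-30 | nt | the size range holding ~95% of annotated introns; where depletion is expected to concentrate |
| `genes_per_draw` | 500 | genes | bootstrap draw size; without replacement within a draw |
| `replicates` | 1000 | draws | bootstrap distribution size |
| `min_reads` | 10 | reads | coverage filter: a locus enters splicing-level classes only with >= 10 analysed reads |
| `n_bins` | 10 | — | equal-width CDS position bins |
| flank `width` | 15 | nt | exonic window scanned next to annotated splice sites |
| `tail_window` | 200 | bp | the "gene tail" region for last-intron distances |

The bootstrap resamples **genes**, not exons or segments, because
segments within a gene share sequence context and are not independent.
Draws are without replacement within a replicate ("draw 500 genes"), which
gives slightly narrower distributions than with-replacement resampling;
the choice is deliberate and localised in `bootstrap_group_dsa()`.

## Flank scans

Exon erosion — the capture of exonic sequence by an existing intron —
predicts selection against GTA immediately upstream of annotated 5'
splice sites and against TAG immediately downstream of 3' splice sites.
`flank_motif_dsa()` scores each offset $d$ separately (offset 1 = the
motif's nearest base touches the splice site). The antisense count at
offset $d$ is taken at the *mirrored* offset on the reverse complement of
the window, so both strands are compared at the same physical distance
from the splice site. Pooling the whole window into one score was the
alternative; per-offset scoring is strictly more informative (the pooled
score is recoverable by summing `Ns` and `Na` over offsets), so only the
per-offset table is emitted.

## Splicing quantification

Per locus (annotated intron or cryptic segment), reads fall into three
categories: **spliced** (unique reads of the exactly matching junction),
**alternative** (unique reads of junctions in the same connected
component, linked by sharing a donor or an acceptor — but not both, since
identical coordinates mean the same junction), and **retained** (reads
whose contiguous alignment spans the whole locus; when both mates of a
pair support the same locus they count once, mirroring how a junction
read counts once per fragment). Levels are category proportions of the
total, so they sum to one by construction — the conservation invariant
the tests assert.

Two input paths produce identical profiles: raw read intervals, or
pre-aggregated per-locus counts. The count path makes the module fully
testable without any alignment machinery and is what the synthetic
junction generator emits. Clustering operates on whatever junction set
the caller supplies; for cryptic-segment analyses the caller passes novel
(non-annotated) junctions only, so alternative evidence for a segment is
not conflated with annotated splicing — the other convention (mixed
clusters) can be had by simply passing the full table.

Whether junction reads should additionally be filtered by alignment
overhang is not modelled; the `overhang` column is parsed and preserved
so such a filter can be applied upstream.

## PTC scanning under translation table 6

In *Paramecium* TAA and TAG encode glutamine; TGA is the only stop. A
retained intron introduces a premature termination codon iff some codon
of the retained transcript that intersects the intron equals TGA. The
scan is frame-aware: the intron's phase is the upstream CDS length mod 3,
and codons spanning the exon-intron boundaries are assembled from up to
2 nt of flanking exonic context. Boundary-spanning codons are included by
default — a stop is a stop wherever the codon's nucleotides come from —
with `include_boundary = FALSE` restricting the scan to fully intronic
codons, since either convention is defensible. For 3n, phase-0 introns
the two conventions coincide with a plain disjoint-triplet scan of the
intron, which the tests use as a cross-check. Reading does not continue
past the intron, so downstream frameshift consequences of non-3n introns
are outside the flag's meaning.

## The synthetic-data generator

`simulate_genome()` emulates what matters for these analyses:

* gene architecture: Poisson intron count (mean 2.9), lognormal exon
  lengths (median 194 bp, mean ~354 bp, clamped at 30 bp so every exon
  can host segments), introns drawn 95% from 21-30 nt and 5% from the
  rest of 15-40 nt;
* composition: iid nucleotides at 72% AT in exons, 80% AT in introns,
  intergenic spacers in between; 69% of introns carry GTA...TAG
  boundaries, the rest are canonical GT...AG with at least one suboptimal
  signal position;
* expression: lognormal, independent of architecture;
* both strands, multiple chromosomes, written out as exactly the
  FASTA/GFF3/TSV the I/O layer reads.

Planted signal comes from `apply_strand_depletion()`: each sense-strand
segment of the selected stratum is independently disrupted with
probability $\delta$ by a *single point mutation* (the A of its GTA or
the T of its TAG, chosen at random, becomes C), so length distributions
and everything else are preserved. Under equal baseline strand rates the
expected score is

$$S(\delta) = \frac{(1-\delta) - 1}{(1-\delta) + 1} = -\frac{\delta}{2-\delta},$$

which `expected_dsa()` returns and the recovery tests check at
$\delta \in \{0.2, 0.5, 0.8\}$ against three bootstrap standard errors
(the SD of the bootstrap distribution). Two honest side effects of the
single-base edit are worth knowing. First, overlapping segments can share
the mutated base, so realised depletion slightly exceeds $\delta$ and the
recovered score sits a little below $-\delta/(2-\delta)$ — well within
the bootstrap noise at the tested scale. Second, a disrupted GTA|TAG
segment does not vanish: it *becomes* a GTn|TAG (or GTA|nAG) segment,
exactly as a real point mutation would, so those classes gain sense
counts. The correct null strata for "no planted signal" are therefore the
non-3n GTA|TAG classes, which the tests use.

What the generator does **not** emulate: codon structure (exons are iid,
so the synthetic baseline DSA is symmetric where real coding sequence is
not), any coupling between expression and architecture (expression
-stratified contrasts are null in synthetic data), UTRs, sequencing error
or alignment artefacts (junction tables and counts are generated
directly, never FASTQ). Passing recovery tests therefore demonstrates
that the estimators are correct and unbiased under known signal — not
that real-data backgrounds are flat.

## Numerical and convention choices

* Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
  inclusive) and the STAR `SJ.out.tab` junction dialect are converted at
  the I/O boundary, in both directions, and the conversions are their own
  inverses.
* Only `CDS` features define exons; UTR introns are out of scope.
* Expression quartiles are rank-based on log2 values (hence invariant to
  monotone transforms); ties break toward the lower quartile; genes with
  zero expression are excluded from quartile analyses (log2 undefined,
  logged via a message) but retained everywhere else. Q1 is "weak", Q4
  "high" throughout.
* CDS bins: `floor(position * n_bins / cds_length) + 1`, features located
  by their 5'-most CDS coordinate (midpoint binning is available as a
  config flag for callers that prefer it).
* Tail distance is measured from the last intron's 3' splice site to the
  CDS end, in CDS coordinates (equivalently, the last exon's length);
  which intron edge to use was unspecified, and the 3'ss makes the
  quantity the length of uninterrupted terminal coding sequence.
* Two-proportion and contingency tests are run without continuity
  correction so the statistic equals the textbook $\chi^2$ contingency
  form; Bonferroni correction is `min(1, p * n_comparisons)` where
  requested. Degenerate inputs (zero totals, zero variance) are flagged,
  never fatal.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds deterministically from one master seed, and its outputs
  are byte-identical across reruns.

## Problem sizes

The recovery analyses run at 2000 genes (bootstrap: 500 genes x 1000
replicates), splicing recovery at 1000 loci of depth 100, flank scans at
10^4 windows, and the end-to-end determinism check at 300 genes; these
sizes give standard errors a few times smaller than the effects being
recovered while keeping a full run in minutes on one core.

## Known limitations

* No codon-aware null model: DSA is interpreted via stratum contrasts,
  not corrected for amino-acid usage.
* No spliced-alignment or multimapper handling: the package consumes
  junction tables and uniquely mapped read intervals produced upstream.
* The PTC flag does not model NMD efficiency or scan beyond the intron.
* Non-GT..AG splice boundaries (e.g. AT-AC) are not searched.
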