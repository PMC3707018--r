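---
title: "Methods: draft-genome anchoring, QC and marker validation"
author: "draftanchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: draft-genome anchoring, QC and marker validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(draftanchor)
```

`draftanchor` implements the bespoke computational stages around a
short-read draft plant-genome assembly: estimating genome size from the
k-mer depth distribution of the reads, preprocessing the reads, summarising
the assembly, superscaffolding it along a sequence-tag (WGP-style) physical
map, validating SSR/COSII markers by in-silico PCR, and quantifying
expression over curated genome regions. The assembler itself, repeat
annotation and transcriptome assembly are deliberately out of scope: those
are standard published tools, while the stages here are the glue a genome
project writes itself.

## Genome-size estimation from the k-mer depth distribution

Let $n(d)$ be the number of distinct canonical k-mers observed exactly $d$
times in the reads (the *depth histogram*). A canonical k-mer is the
lexicographically smaller of a k-mer and its reverse complement, so the
histogram is strand-invariant; `count_kmers()` computes it exactly, packing
each k-mer ($k \le 31$, odd so that no k-mer is its own reverse complement)
into a 62-bit code in C++. Windows containing N are skipped.

The estimator is the classical ratio method:

$$\hat G = \frac{\sum_{d \ge c} d\,n(d)}{d^\ast}, \qquad
d^\ast = \arg\max_{d \ge c} n(d),$$

where $c$ is the *error cutoff*: sequencing errors create a spike of
low-depth k-mers, and $c$ is chosen as the first valley of the dense
histogram — the smallest $d \ge 2$ with $n(d) \le n(d-1)$, $n(d) \le
n(d+1)$ and positive mass below $d$ (without an error tail there is nothing
to cut and $c$ falls back to 1 with a warning). Ties in the peak search
break toward the smaller depth and no smoothing is applied, so the whole
procedure is deterministic. The peak depth $d^\ast$ is the effective k-mer
coverage $\approx C\,(L-k+1)/L \cdot (1-e)^k$ for read length $L$, base
coverage $C$ and error rate $e$; dividing the error-free k-mer mass by it
recovers the genome length for a low-repeat genome. Because the peak is an
integer, the estimate carries a quantisation error of order $1/d^\ast$
(about 4% at $d^\ast \approx 24$), which dominates the error budget at the
simulation scale used in the tests. No mixture-model decomposition of
heterozygosity or repeats is attempted; the method is the plain ratio
estimator.

`genome_coverage()` then reports assembled bases as a percentage of the
estimate, rounded half-up to one decimal, matching the convention of
published assembly tables (all printed-precision rounding in the package is
half-up via `round_half_up()`, never banker's rounding).

## Read preprocessing

Two preset policies mirror the common DNA / RNA rules for CASAVA ≥ 1.8
Illumina data (Phred+33 throughout):

* DNA: trim 3' bases with quality < 30, then discard reads shorter than
  50 bases or with fewer than 90% of bases at Q30 or more;
* RNA: keep reads of at least 50 bases with at least 75% of bases at Q20
  or more.

The DNA fraction rule is stated ambiguously in the literature this mirrors;
we interpret it as *at least 90% of bases at Q30+*, structurally identical
to the unambiguous RNA rule, and evaluate it on the post-trim read (the
rules are listed as trim first, then discard). Empty post-trim reads count
as "short". Trimming is idempotent and every read lands in exactly one of
kept / short / fraction, which the tests assert as invariants.

## Assembly statistics

N50 is the largest length $L$ such that sequences of length $\ge L$ hold at
least half the assembled bases; the implementation compares
$2\,\mathrm{cumsum} \ge \mathrm{total}$ in exact integer arithmetic so odd
totals carry no floating-point ambiguity. Undefined bases are N characters
(lowercase input is normalised on read). The minimum-length filter
(boundary inclusive) reproduces the usual "discard sequences < 200 bp"
final-assembly step.

## Physical-map superscaffolding

The physical map supplies map contigs, each an ordered list of short
sequence tags (ranks 0,1,2,…). The pipeline is deliberately conservative,
mirroring the published discard rules:

1. **Tag placement** (`place_tags()`): exact, full-length matching on both
   strands (Biostrings); mismatch tolerance is available but defaults to 0
   because the tags derive from the same species. Tags hitting the
   assembly more than once are excluded from anchoring.
2. **Anchoring** (`anchor_scaffolds()`): a scaffold whose tags hit several
   map contigs is discarded (`multi_contig`). Orientation requires at
   least two tags and *full* pairwise concordance of (scaffold offset, map
   rank) — ascending gives `+`, descending `-`; any discordance, tied
   offsets or a single tag gives `unknown_orientation` and the scaffold is
   discarded. No majority voting: "oriented unambiguously" is taken
   literally.
3. **Chaining** (`build_superscaffolds()`): each map contig with at least
   two anchored, oriented scaffolds yields one superscaffold, components
   ordered by mean tag rank (ties broken by scaffold id and flagged).

Gap lengths between consecutive components are estimated from a template
genome when tag template coordinates are available: the template distance
between the two components' tag spans minus the component bases that
extend past their outermost tags, clamped to [10 bp, 50 kb]. The clamp
keeps AGP output valid when the template and the assembly disagree; without
a template a fixed 100 bp gap is used. Both bounds and the fixed gap are
package design choices — the published procedure states only that gaps were
estimated from a related genome, without a formula. Gaps are written as N
runs (and N/W rows in AGP v2.1), so superscaffolding adds undefined bases
by construction; the tests assert the added N count equals the emitted gap
total.

Internal coordinates are 0-based half-open everywhere; AGP output converts
to 1-based inclusive on write.

## In-silico PCR and marker concordance

Primer matching is ungapped, full-length and substitution-only: on an
18–24-mer, the 95% identity threshold admits at most one substitution, and
indel behaviour of any particular aligner is not reconstructed. Both
primers must independently reach the identity threshold. An amplicon is a
convergent pairing — one primer site on the plus strand, the other
downstream on the minus strand — on the same sequence, with outer span at
least the two primer lengths (overlapping sites are rejected) and at most
`max_product_bp` (default 2,000 bp, a package choice: SSR/COSII products
are short and no explicit cap is published). The pair is unordered, so
swapping forward and reverse primers leaves the amplicon set unchanged.

A marker maps `unique` in a genome when it yields exactly one amplicon
genome-wide, `multiple` for two or more, `none` otherwise; only `unique`
markers are retained. `aggregate_concordance()` cross-tabulates the joint
two-genome category (`A_only`, `B_only`, `both`, `neither`) against an
external evidence panel (PCR amplification results, genetic-map
membership), and `concordance_summary()` reports "mapped to genome X"
totals with whole-number half-up percentages, the convention of the marker
tables it reproduces.

## Probe placement and region expression

Array probes are retained only as perfect, genome-wide-unique matches. Both
strands are searched; a probe matching forward at one locus and
reverse-complemented at another has two matches and is rejected, while a
palindromic probe hitting the same interval on both strands counts once.
Retained probes are annotated with the region that fully contains them;
partial overlaps are flagged, not annotated. Region expression is the sum
of FPKM values of transcripts overlapping the region by at least one base
on the same sequence; strand is ignored and transcript (not exon) spans are
used, the minimal faithful reading of the published summing rule. Overlap
is delegated to `IRanges::findOverlaps()`; an all-pairs brute-force scan
serves as the test oracle.

## The synthetic-fixture generator

Every stage is tested against planted truth produced by `sim_config()` and
the `simulate_*`/`plant_*`/`fragment_*`/`generate_*` functions. The
defaults are the package's study conditions: 100 bp reads at 40×
coverage with 0.5% substitution error from a 100 kb i.i.d. genome at
GC 0.4; 40 scaffolds and a 4-contig map with 3 tags of 50 bp per scaffold
(superscaffolding runs on a 1 Mb genome); a 50-marker panel with 5 markers
planted twice, 5 with two-substitution primer copies and 5 with a
one-substitution copy. Each operation draws from its own RNG stream derived
from (seed, operation name), so fixtures are bit-reproducible and adding an
operation never perturbs the others.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data — matters as much: genomes are i.i.d. with no
repeat families or heterozygosity (k-mer histograms stay unimodal, tag and
probe placements are unique with high probability), errors are uniform
substitutions without quality-by-cycle structure or indels, and reads are
single-end with no insert-size model. Recovery rates of 100% on these
fixtures certify the bookkeeping and the decision rules, not performance on
repeat-rich gigabase genomes, where multi-mapping tags, collapsed repeats
and bimodal histograms dominate the difficulty.

Problem sizes in the test-suite and in `scripts/acceptance.R` (100 kb
genomes for estimator recovery over 10 seeds, a 1 Mb superscaffolding
fixture, 10,000 reads for QC) were chosen as the smallest scales at which
the statistical checks are stable; the published headline numbers from
~100× gigabase read sets are arithmetic-checked from their printed inputs
instead, since recomputing them requires the raw archives.

## Command-line interface

`da_run()` dispatches the subcommands `readqc`, `gsize`, `stats`,
`superscaffold`, `ispcr`, `concordance`, `probequant` and `simulate`; a
thin launcher ships at `system.file("cli/draftanchor.R", package =
"draftanchor")`. Every run can write a JSON report with the fully resolved
parameters (including the seed), output paths and counters, sufficient to
reproduce the run. Gzip input is auto-detected by magic bytes. All
subcommands are single-threaded and deterministic; there is deliberately no
parallelism flag, so a report plus inputs always reproduces byte-identical
outputs.
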