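---
title: "Discovering S-locus sRNA dominance modifiers: models, parameters, design"
author: "slocusmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering S-locus sRNA dominance modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slocusmod)
```

## The biological question and the pipeline's logic

Brassicaceae sporophytic self-incompatibility is governed by the S-locus
(*SRK* on the stigma side, *SCR* on the pollen side). Dominance among
S-haplotypes in pollen is mediated by S-linked small RNAs: a hairpin
precursor on a dominant haplotype produces sRNAs that silence *SCR* of more
recessive haplotypes. In an allotetraploid carrying homeologous S-haplotypes
(a *C. orientalis*-derived B copy and a *C. grandiflora*-derived A copy, as
in *Capsella bursa-pastoris*), the combination of (i) a pseudogenized B
*SCR*, (ii) an expressed B-side precursor and (iii) a target of its sRNA on
the A haplotype is the molecular signature of instant self-compatibility at
polyploid formation.

The pipeline encodes that argument as a chain of falsifiable steps, each
with its own module and tests: inverted repeats → expression screen →
hairpin structure filter → retained precursors → expressed-sRNA windows →
targets on the homeolog. Diversity statistics (π, θ~W~ at *SRK*), frameshift
calls (*SCR*), and coverage-based presence calls complete the picture.

## Inverted-repeat detection

Candidate precursors are inverted repeats: a left arm followed, after a
loop, by an approximate reverse complement of itself. We align the sequence
locally against its own reverse complement under the einverted-style linear
scoring — match +4, mismatch −4, gap −8 per gapped column, minimum score 50
— with the repeat span (left-arm start through right-arm end) bounded at
350 nt. Arm complementarity here is strict Watson–Crick; G:T is a mismatch,
because at this stage the object is a DNA palindrome, not an RNA duplex.

Two design points deserve record:

* **Span semantics.** "Maximum separation between start of repeat and end of
  inverted repeat = 350" is read as a bound on the total span, the
  einverted `maxrepeat` meaning. The scan runs in overlapping windows of
  twice the span with step equal to the span, which covers every admissible
  repeat at least once.
* **Report granularity.** Overlapping alignments are reduced to local
  maxima. Selection is iterative: take the best candidate (score, then
  smaller span, then leftmost), hard-mask its arm footprint so no later
  alignment can reuse those positions, rescan the affected window, repeat.
  This makes the reported set *provably identical* to a greedy reduction
  over the exhaustive enumeration of all arm-interval pairs, which is what
  `ir_bruteforce()` computes and what the equivalence suite asserts on
  hundreds of random sequences. The per-cell dynamic program alone does not
  have this property (a cell keeps only its best path, so a lower-scoring
  non-overlapping alternative could be lost when the winner is removed);
  the mask-and-rescan loop is what restores it.

## Hairpin screen

The retained-precursor rules are applied to the arm-vs-arm alignment:
terminal loop **< 40 nt** (strict), **> 20** paired stem columns (strict),
**≤ 4** mismatched columns, **≤ 2** asymmetric bulges. A column counts as
paired if the opposed bases form A:T, G:C, or G:U — the wobble is admitted
here because the folded hairpin is an RNA. Thermodynamic folding is out of
scope by design: candidates are near-palindromes found by the previous
stage, and the filter thresholds are all countable features of the
alignment, so the alignment itself is the structure proxy. Consequences of
that choice: paired columns are totalled across bulge-separated segments
(the rules bound mismatches and bulges separately), and a bulge is a
maximal run of consecutive gap columns, regardless of its length.

The screen is ordered: expression first, then structure. Expression is the
copy count of mapped 21–24 nt reads overlapping either arm; the retention
threshold defaults to ≥ 5 copies. No published numeric cutoff exists for
"retained based on sRNA expression data", so this is a declared, tunable
default — at the synthetic scenario's sequencing depth the planted precursor
exceeds it by two orders of magnitude and background reads never reach it,
so conclusions are insensitive to its exact value.

## Small-RNA handling

Reads are adapter-clipped (an exact match of ≥ 8 nt of the adapter prefix),
restricted to 18–27 nt, and collapsed to (sequence, count). Mapping is
exact by default (1 mismatch optional) against the supplied haplotypes on
both strands, with every placement reported. The default is exact matching
because desk-scale references are short and exactness keeps the independent
full-scan oracle cheap; no aligner heuristics are reproduced. Multimappers
are down-weighted 1/n~placements~ in quantification (a unique-only mode
exists). Note that an sRNA from a hairpin arm legitimately maps twice — once
per arm, on opposite strands — so the designed sRNA has n = 2 by
construction. Qualities are parsed and ignored.

## Target affinity

sRNA–target affinity is a local alignment of the sRNA (5'→3') against the
transcript read 3'→5', scored match +1, mismatch −1, gap −2, G:U wobble
−0.5, on both target strands. Scores are half-integers: they are carried as
doubled integers end to end, so a cutoff comparison never touches floating
point. The cutoff is 18 with `>=` as the default comparator (a hit at
exactly 18.0 qualifies); the stricter `>` is available because printed
descriptions of the threshold vary between "cutoff of 18" and "affinity
greater than 18". Gaps are permitted on either strand of the duplex at −2
per gapped column (linear), which is the simplest reading consistent with a
per-column scoring matrix. Overlapping local optima reduce to the best hit
per cluster, per strand (ties: fewer gaps, then leftmost), so a palindromic
site can legitimately report once per strand.

## Diversity at SRK

`diversity()` computes, from an aligned sample of n sequences: S (retained
columns with ≥ 2 distinct bases, multi-allelic columns counted once), π
(mean pairwise difference per retained site) and θ~W~ = S / (a~n~ L) with
a~n~ = Σ 1/i. Columns containing a gap or N in *any* sequence are excluded
(complete deletion) — the conservative choice when the reference tool's
missing-data behaviour is undocumented; pairwise deletion would be the
alternative and would raise L slightly. Values are kept at full precision
and rounded only for display.

## SCR annotation and coverage calls

Frameshift calls use global pairwise alignment with affine gaps (match +1,
mismatch −1, open −5, extend −1), so a contiguous 31-bp deletion is one
indel rather than 31 — this is the reason affine costs are used at this
stage while the repeat finder is linear. An indel disrupts the frame iff
its length is not a multiple of 3, and one disrupting indel suffices for a
pseudogene call. The 8-cysteine SCR scan translates all six frames and
reports windows of 8 consecutive cysteines whose 7 spacings fall inside
configurable windows (default 2–40 residues each — the conservation
criterion fixes the cysteine count, not the spacings, so the defaults are
declared placeholders) with no stop codon inside the window.

Presence calls reduce "broad and even coverage" to numbers: breadth =
fraction of positions with depth ≥ 1, evenness = fraction within
[0.25×, 4×] of the median depth, present ⇔ breadth ≥ 0.9. Depth tables are
accepted as already filtered (e.g. to properly paired reads).

## The synthetic scenario

`synthetic_config()` fixes the study conditions for all tests:

* two 30 kb haplotypes (real S-haplotypes run ~23–31 kb) with the gene
  order U-box, mirS3, SCR, SRK, ARK3;
* a hairpin planted in the B-like mirS3: 60-nt arms, 15-nt loop, 2 arm
  mismatches, 1 single-nt bulge — passing every filter rule by
  construction. Mismatches are placed as self-pairs (a base opposite
  itself), which can never be Watson–Crick nor G:U, and the four flanking
  and innermost-loop pairings are forced to self-pairs so the stem can
  neither creep outward nor into the loop: the recovered alignment is
  exactly the designed one;
* a designed 24-nt sRNA taken from the left arm, and a target site on the
  A-like haplotype built column-by-column from it — default 2 wobbles + 1
  mismatch, affinity 24 − 1.5·2 − 2·1 = 19.0, with designed non-match columns
  kept interior so trimming cannot beat the design;
* a B *SCR* with a 0/1/31-bp deletion against an intact 8-cysteine
  reference CDS; the A-like locus carries only short degenerate
  SCR-similarity fragments (20% substitutions), mirroring the situation
  where the A-side gene is not confidently annotatable;
* decoy inverted repeats (perfect 15-bp arms, 50-nt loops) that score ≥ 50
  but fail both the stem and loop rules;
* sRNA reads: uniform starts over the arms, lengths 21–24 nt (probabilities
  0.15/0.15/0.2/0.5, favouring the 24-nt class that carries the signal),
  per-site copies Poisson(20), the designed sRNA boosted to Poisson(60)+1
  so it is deterministically the most abundant window; 20 single-copy
  background reads elsewhere;
* infinite-sites population samples at θ = 0.001, n = 4, L = 25 kb — the
  magnitude of the published *SRK* diversity values — under which θ~W~ is
  exactly unbiased, giving the parameter-recovery test;
* depth profiles: Poisson(20) when present; absent haplotypes covered only
  over 8% conserved flanks at each end (breadth ≈ 0.16, well below the 0.9
  presence threshold), emulating the control where only one subgenome's
  haplotype is carried.

Each generator operation draws from its own stream derived from
(seed, operation tag), so outputs are byte-reproducible and adding an
operation never perturbs another's draws. What the generator does *not*
emulate — and what passing tests therefore do not establish about real
data: repeat landscapes and gene families (background is i.i.d.),
sequencing errors and quality artefacts, competitive mapping against a
whole genome, linkage/recombination structure in the population samples,
and library-size normalization across sRNA libraries.

## Numerical choices and degenerate inputs

* All internal coordinates are 1-based inclusive, the R/Bioconductor
  convention; GFF3 and depth tables are read and written in their native
  1-based forms, so no conversion layer exists anywhere.
* U is normalized to T at ingest; N never counts as a match, pair, or
  wobble anywhere; sequences with characters outside A/C/G/T/N/U are
  format errors naming the offending line.
* Affinity scores are exact half-integers (doubled-integer arithmetic);
  alignment scores are integers; π/θ~W~ are double precision with no
  intermediate rounding.
* Ties: inverted repeats — score, then smaller span, then leftmost left
  arm; target hits — score, then fewer gaps, then leftmost start; the
  top-expressed sRNA window — copy count, then lexicographic sequence.
* Degenerate inputs have defined behaviour: empty FASTA → empty set; a
  homopolymer → no repeats; no usable alignment columns → an explicit
  undefined-estimate error; empty depth profile → error; a pure-adapter
  read collapses to nothing.

## Problem sizes

The shipped tests and the acceptance script run the oracle-equivalence
suites on 200 random sequences of 30–60 nt (repeat finder, exact
score-and-coordinate agreement) and 200 random sRNA/target pairs of 8–12 /
20–40 nt (target scanner), the estimator-recovery study on 200 replicates
of n = 4 × 25 kb, and the end-to-end screen on the default 30 kb scenario.
These sizes keep the whole verification cycle at a few minutes on one core
while leaving every planted feature's recovery exactly checkable.

## Known limitations

Hairpin evaluation is alignment-based, not a fold: a candidate whose
best RNA structure differs materially from its best palindromic alignment
could be mis-scored near the filter thresholds. Expression screening uses a
declared default cutoff, not a published one. The cysteine spacing windows
are placeholders. Mapping is uncompetitive (restricted to the supplied
loci): reads that would multimap genome-wide appear unique here. The
diversity module deliberately omits synonymous/non-synonymous partitioning,
sliding windows and neutrality tests.
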