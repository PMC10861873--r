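---
title: "Designing Cas12a CRISPRi libraries and scoring pooled screens with crispacer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Cas12a CRISPRi libraries and scoring pooled screens with crispacer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispacer)
```

## The problem

CRISPR interference silences a gene by parking a catalytically dead Cas
protein on its DNA. For bacterial small regulatory RNAs (sRNAs) — short,
often intergenic genes that transposon mutagenesis hits too rarely — a
targeted CRISPRi library is the practical route to pooled loss-of-function
screening. In AT-rich genomes the choice of nuclease matters: the SpCas9
`NGG` PAM is scarce precisely where sRNA genes are most AT-rich, while the
Cas12a `TTV` PAM is plentiful. `crispacer` designs such Cas12a libraries
end-to-end and scores the resulting two-condition fitness screens.

This vignette describes the model and procedure, the tunable parameters and
their defaults, the numerical choices, and what the bundled synthetic data
do and do not establish.

## Coordinates and target regions

Internally everything is 0-based, half-open, on the forward strand; emitted
tables are 1-based inclusive. The transcription start site (TSS) defaults to
the annotated gene's strand-aware 5′ end; GFF3 input may carry a `tss`
attribute to override it, since generic annotations lack a TSS field while
TSS-resolved transcriptome maps provide one. Each gene contributes two
regions: the *promoter*, the `promoter_window` (default 50 nt) immediately
upstream of the TSS, and the *transcribed* region, the gene interval itself;
they are adjacent at the TSS and never overlap. Promoters running off a
linear contig edge are truncated with a warning — the behaviour for such
edge genes was an open choice and truncation keeps them designable rather
than dropping them.

## Spacer enumeration and the strand rules

dCas12a blocks transcription effectively from either strand when bound in
the promoter, but within a gene body only when the gRNA anneals to the
template strand — equivalently, when protospacer and PAM lie on the coding
strand. `enumerate_candidates()` therefore returns every position where a
`TTV` PAM plus a full `spacer_length` window (default 20 nt; Cas12a CRISPRi
practice, exposed in the config since no single canonical value exists) fits
inside the promoter-plus-gene window, keeping both strands in the promoter
and only the coding strand in the gene body. Candidates straddling the
promoter/gene boundary are classified by the protospacer 5′ end — a single
unambiguous rule. Windows touching non-ACGT genome characters are discarded:
such spacers could be neither synthesized nor matched unambiguously.

Ranking is lexicographic, not a weighted score: (1) GC fraction inside
`[gc_min, gc_max]` = [0.35, 0.75]; (2) region priority promoter → 5′ portion
of the gene → 3′ portion, with the 5′ portion defined as the first
`five_prime_fraction` (default 0.5) of the gene length; (3) extended `TTTV`
PAM before plain `TTV`; (4) smaller distance of the protospacer 5′ end from
the TSS; (5) forward-strand coordinate and strand as final tie-breakers.
The prioritization criteria are known only as an ordered preference, without
weights; a lexicographic order reproduces that preference exactly, is
auditable, and makes the output byte-deterministic.

Selection takes ranked candidates that survive the off-target filter (tested
lazily, so a gene with abundant clean sites never scans more than it needs):
up to `guides_per_gene` (3) gRNAs, preferring non-overlapping protospacers
but accepting overlap when nothing else remains, then
`array_spacers_per_gene` (3) further spacers that must be pairwise
non-overlapping and disjoint from the gRNAs. One deliberate subtlety: the
preferred-GC pool is exhausted — including the overlap fallback — before any
out-of-window candidate is considered, so whenever enough preferred-GC
candidates exist the selected gRNAs are all in-window; non-overlap
preference is subordinate to GC preference. Shortfalls are never silent:
they appear in `failure_notes` and in the failure report.

## Off-target filtering

A spacer is discarded if any window on either strand of any replicon lies
within `offtarget_max_mismatch` (default 2, "fewer than three mismatches")
Hamming distance of it *and* is preceded by a `TTV` PAM on the same strand.
Plain mismatch counting over the full spacer — no seed weighting, no indels
— mirrors how the rule is stated for this system. The PAM at the off-target
site must match `TTV` itself, not the extended `TTTV`. The intended locus is
excluded by exact interval-and-strand identity; a window overlapping the
intended site but shifted still counts as a second locus (the conservative
reading of "a second genomic locus"). The search object precomputes padded
strand sequences per replicon (with origin wrap-around for circular
replicons) and scans them with an early-exit mismatch counter in compiled
code; its results are exactly those of a naive sliding-window scan, which
the test suite asserts against an independent brute-force oracle.

## Array folding validation

Cas12a matures its own gRNAs from a repeat–spacer array, cleaving at the
direct repeat's 3′-terminal hairpin; a spacer that base-pairs with a repeat
can sequester that hairpin in the primary transcript and abolish
processing. `crispacer` treats the repeat sequence as configuration input
and derives, once, the *reference hairpin*: the base pairs of the isolated
repeat's minimum-free-energy structure that form the 3′-terminal stem-loop.
A repeat whose isolated MFE structure is unstructured is rejected outright.
`check_array_folding()` folds the full transcript and requires, for every
repeat copy, that all reference pairs (translated to transcript
coordinates) occur in at least one "most probable" structure — defined here
as the MFE structure plus suboptimals within `energy_window` (default
2 kcal/mol) capped at `max_structures` (default 20), both exposed because
no published cutoff exists for "most probable". Whether one single structure
must satisfy *all* repeats, or each repeat may be satisfied by a different
near-optimal structure, is genuinely ambiguous; both are implemented
(`strict_fold`), with the per-repeat mode as default since a transcript
ensemble populates multiple structures. Enlarging the window or the cap can
only add structures, so a pass can never turn into a fail — a property the
suite checks. Folding goes through ViennaRNA's `RNAsubopt` behind a narrow
adapter (sequence in, dot-bracket plus energy out); an absent engine is a
hard error, never a silent pass. `design_array()` tries spacer triples and
orderings in ranked order up to `array_attempt_cap` (50) before giving up
and leaving the gene with gRNAs only.

The bundled `synthetic_repeat()` — an AT-rich 5′ segment plus a designed
6-bp GC stem closed by a GAAA tetraloop — is a synthetic stand-in used by
examples and tests; real libraries should supply their nuclease's own
repeat via `repeat_unit()`.

## Cloning output

gRNA spacers are emitted between configurable Gibson homology arms. Arrays
are partitioned at repeat–spacer unit boundaries into three duplexes of two
oligos each (six oligos per array), offset by 4 nt so annealing leaves 4-nt
sticky ends. Junction overhangs default to the first 4 nt of the downstream
unit; the vector-facing outer overhangs are configured constants, since they
belong to the destination plasmid, which this package does not model.
Orthogonality requires overhangs pairwise distinct, non-palindromic *and*
pairwise non-complementary — a sticky end anneals to its reverse complement,
so two mutually complementary junctions would cross-ligate; on a clash the
junction shifts by up to ±3 nt before erroring. `reconstruct_from_oligos()`
simulates annealing and ligation exhaustively and returns the
double-stranded portion of the unique product. A duplex has no intrinsic
top strand, so every valid set assembles in two strand readings of the same
molecule; the vector-facing left overhang anchors which reading is
reported. Round-trip exactness over every emitted array is asserted in the
suite.

## Screen scoring

Members (a gRNA or a whole array) are quantified by extracting the spacer
between the constant vector flanks (up to `max_flank_mismatch` = 1 mismatch
per flank, either read orientation) and matching it exactly to the
manifest; an array member is counted when any constituent spacer is seen.
Fitness is `log2((stress + pc)/(control + pc))` per replicate on
counts-per-million, with pseudocount 0.5 keeping zero counts finite; the
per-gene score averages over all members targeting the gene, unweighted.
Significance uses a two-sided one-sample t test on the pooled
member-by-replicate log2FC values against zero, Benjamini–Hochberg
corrected across genes; hits require `|mean log2FC| > 0.5` *and*
`FDR < 0.05`, with positive values meaning enrichment under stress. The
original screen analysis of this kind used edgeR; reproducing that
package's internals is out of scope here, so the default statistic is this
transparent CPM + pseudocount + location-test + BH chain, and `test_fun` is
a pluggable hook for anything stricter. The suite cross-checks the per-gene
scores against an independent edgeR analysis on simulated counts (rank
correlation > 0.9) without ever substituting it for the implementation.

## What the synthetic data emulate — and what they do not

`make_genome()` draws i.i.d. bases at a target GC of 0.35 (the AT-rich
*Bacteroides* sRNA context), plants non-overlapping sRNA-sized genes
(80–250 nt) on both strands with free 50-nt promoters, and can rewrite
chosen genes as *PAM deserts* (no TT or AA dinucleotide, hence no TTV on
either strand) to exercise documented design failure. `plant_decoys()`
copies chosen spacers back at stated Hamming distances with or without a
PAM. `simulate_screen()` draws log-normal member abundances and
negative-binomial counts with variance μ + φμ² (φ = 0 recovers Poisson),
multiplying stress means by 2^effect for planted genes; defaults mirror the
screen conditions used throughout: 135 genes × 4 members, 3 replicates,
10⁶ reads per sample, φ = 0.1, planted |log2FC| = 1.5. All generators are
deterministic under a single integer seed.

Real genomes are not i.i.d.: they carry repeats, skewed oligonucleotide
composition, mobile elements and paralogy, all of which make off-target
near-matches far more likely than in these fixtures. Real screens add PCR
bias, bottlenecks and member dropout that the count model omits. Passing
tests therefore establish that the *rules are implemented exactly as
specified* and that the scoring recovers effects under the stated noise
model — not that a given wet-lab library will achieve the same design
completeness or screen power.

## Problem sizes and numerical choices

The test and acceptance runs use: 100 random 1-kb sequences for the census
oracle; a 50-kb genome with 30 planted decoys for the off-target oracle; a
100-kb genome with 20 genes (2 PAM deserts) for rule conformance; a 6.3-Mb,
135-gene genome for the genome-scale design run; and 20 simulation seeds
each for screen power and null calibration. These sizes make the full suite
run in a few minutes on a single CPU while keeping every check at the scale
the procedure is meant for. Ties in ranking are broken by coordinates, all
randomness is seed-threaded, and repeated runs are byte-identical.

## Known limitations

No thermodynamic on-target efficiency model (candidates are rule-ranked,
not activity-predicted); no CFD-style partial off-target scoring; no
pseudoknots or gRNA–target RNA duplexes in folding; no primer-level QC of
the emitted oligos; promoter motifs (−33/−7 boxes) are not located, so the
promoter window is positional only; and the screen statistic assumes
approximately normal pooled log2FC values per gene — genes with a single
surviving member are reported but untestable.
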