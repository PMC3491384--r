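---
title: "Methods: small-RNA processing inference in a minimal archaeal genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA processing inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the design
decisions behind them. The system under study is the RNA-processing
machinery of a minimal, compact archaeal genome: crRNA maturation from two
CRISPR arrays, tRNA maturation by trans-splicing of separately encoded
halves in the absence of RNase P, and rRNA-modification guidance by C/D
box and H/ACA box sRNAs.

## Coordinates and conventions

All internal intervals are 0-based half-open on the forward strand;
minus-strand features keep forward intervals with a strand flag, and
conversion to 1-based inclusive happens only at the GFF3 boundary. The
3′-end coordinate of a mapped read is its last aligned base, not the
half-open bound: termini are biological bases. Offsets between a TSS and
a repeat count bases between the two positions on the transcript strand,
so "offset 33" means `first_repeat_start − tss = 33` in forward
coordinates.

## Read processing and the micro-mapper

Quality trimming uses the running-sum method: with per-base error
probabilities $p_i$ and limit $L = 0.05$, the partial sums of $(L - p_i)$
are clipped at zero and the kept segment ends at the running-sum maximum.
This is a reproducible open formulation of the "quality score limit"
style of trimming used by common commercial pipelines, whose exact
algorithm is unpublished. Adapter suffixes are removed at ≥ 90% identity
over ≥ 8 nt; terminal poly-A runs of ≥ 6 nt are stripped; reads shorter
than 15 nt are discarded and counted.

The mapper is exact-seed (k = 12, seeds tiled at k/2 so one substitution
plus one indel still leave a clean seed on reads of ≥ ~2k nt) and extend
by banded semi-global alignment with costs mismatch 2, insertion 3,
deletion 3. Reads are aligned end to end — there is no soft clipping — so
the length-fraction threshold is trivially satisfied and identity
(matches / alignment columns ≥ 0.8) is the live acceptance filter. This
also means junction-spanning reads from circular sRNAs stay unmapped,
which is intentional: circularity evidence is collected separately from
the raw reads. Cost ties across placements default to seeded random
placement (`random_best_seeded`): CRISPR repeats are exact multi-copies,
and discarding multireads would erase the repeat-internal coverage that
tag inference needs; the run seed keeps results reproducible.

Termini calling returns all local maxima of the strand/side end-count
array with support ≥ 5 reads; the global maximum is the modal terminus
(ties resolved towards the transcript-upstream side), and non-modal
maxima with local fraction ≥ 0.10 inside a ±10 nt window are trimming
hotspots. The window and fraction are configurable; the defaults are
deliberate round values, since the underlying phenomenon (discrete
pause sites of 3′ exonucleolytic trimming) has no published numeric rule.

## CRISPR arrays and crRNA maturation

Detection chains k-mer self-matches (k = 13) whose gaps are compatible
with a repeat + spacer period, processing the most frequent seeds first
so that a seed lying fully inside the repeat claims the whole array
before boundary-straddling seeds can fragment it. Repeats are extended
column-wise while the majority base carries ≥ 75% of copies, then
boundary columns below 90% identity are shrunk back — without the shrink
step, a chance agreement of the bases flanking a small array extends the
repeat by one. Bounds (repeats 20–50 nt, spacers 17–50 nt, ≥ 3 repeats)
follow common CRISPR definitions; a spacer up to 1.5× the upper bound is
tolerated with a `long_spacer` flag rather than breaking the chain,
because real arrays do contain the occasional oversized spacer.

Orientation prefers reads (the strand carrying the array-overlapping
coverage); the genome-only fallback picks the strand that puts the more
AT-rich 150-nt flank upstream, where the AT-rich leader should lie. When
both are available and disagree, reads win with a warning.

Maturation statistics per spacer: the 5′ tag length is the modal offset
of read 5′ ends upstream of the spacer start, constrained to fall within
the repeat, with the tag sequence read from the repeat consensus suffix
(so the tag is a consensus suffix by construction); 3′ offsets are
measured from the last spacer base; abundances are normalised within the
array. The TSS is the modal 5′ end in the leader, ties towards the
upstream-most position; box A is the best Hamming match to TTTAAA in the
−35..−20 window with ≤ 1 mismatch, ties towards distance 26 (the
tRNA-promoter spacing of this organism's promoters) and then upstream.

## Trans-spliced tRNA halves

The clamp is the flanking sequence on the intron-side end of each half
(40 nt window), trimmed at the first downstream T-stretch of ≥ 5 T — the
polypyrimidine terminator. Clamp pairs are scored by the best ungapped
antiparallel duplex; G·U wobble counts 0.5 (configurable), and pairs with
a longest contiguous duplex under 8 nt are rejected. Assignment is exact
maximum-weight bipartite matching by bitmask dynamic programming
(instances here are ≤ 12 × 12); a pair that can be exchanged without
changing the optimal total is flagged ambiguous rather than silently
reported. One-to-one matching is a deliberate, testable contract — loci
whose halves are genuinely shared must be flagged, not silently reused.
tRNA and half annotations come from the GFF3 input; gene finding with
covariance models is out of scope.

## C/D box and H/ACA box sRNAs

Box budgets: box C is RUGAUGA with the core GAU exact and ≤ 1 mismatch
elsewhere — chosen so that a natural box C variant carrying a single
substitution (as in the intron-encoded sRNA this system contains) still
passes; box D is exact CUGA; the internal C′/D′ relax to ≤ 2 / ≤ 1. The
chain constraints (C→D separation 40–90 nt, guides 10–21 nt, D′→C′
linker 0–8 nt, permuted D→C gap 2–15 nt) encode the compact archaeal
arrangement and, together, hold the false-positive rate on random
sequence below one call per 100 kb — the guide windows are what buys the
specificity, since the box motifs alone are far too common. Overlap
resolution keeps the candidate with fewest total mismatches, preferring
the canonical reading on ties, so a permuted call stands only where no
equally good canonical ordering exists.

Circularity evidence is junction-spanning reads only: a read matching the
doubled locus sequence across the 3′→5′ junction with ≥ 12 nt exactly on
each side. Five junction reads make a circle; a permuted circle becomes
`circular_permuted`, the arrangement whose circular reading restores
C-before-D. Target prediction implements the D+5 rule: the methylated
base is the one paired to the guide nucleotide five positions upstream of
box D/D′, within a contiguous antisense duplex of ≥ 10 pairs (G·U
allowed), ranked by duplex length then fewest wobbles.

H/ACA structure comes from a maximum-base-pairing (Nussinov) fold with
minimum loop 3 and G·U admitted — a deliberate desk-scale substitute for
free-energy folding, and the package's main structural simplification:
maximum pairing can tie between structures, so the anatomy reader is
written to tolerate one-base register shifts (k-turns are recognised from
short bulges whose ±2 nt neighbourhood carries the tandem G/A signature
on both strands; the pocket is the longest unpaired run per side).
Candidates need two hairpins of ≥ 25 nt and ≥ 8 pairs around an ACA
hinge; the H-domain status distinguishes a canonical ANANNA hinge from
the ACA-only hinge this system's single H/ACA sRNA shows. Pseudouridine
targets require the pocket 3′ strand to end 14–16 nt upstream of its ACA
and bipartite pairing of 4–8 nt per flank around an unpaired U-N.

## The synthetic scenario

The generator's defaults are the study conditions: 41 spacers on two
arrays sharing a 28-nt repeat that ends ATTGAAAG, leaders identical for
exactly 130 nt, TSS on an A at offset 33, box A at −27, an 8-nt 5′ tag,
geometric 3′ trimming (p = 0.25) with a secondary fixed mode that
produces a discrete hotspot, per-spacer abundance decay 0.8, six tRNA
pairs with 12-nt GC-rich clamps and planted +2 (GC) / +1 (A) / −1 (A)
precursor 3′ offsets, a tRNA with a C1 start and templated G−1 reads, an
intron-encoded C/D sRNA inside a 66-nt tRNA intron with a 6-GC-pair
hairpin, seven C/D sRNAs covering every genomic context (one permuted,
two circular), and one 159-nt H/ACA sRNA. Read depth defaults to 100
reads per feature with 0.1% substitution error, constant Q30 qualities,
and 3′-anchored RT drop-off on tRNAs (0.005 per nt) that reproduces the
under-representation of structured, modified RNAs.

Planted motif neighbourhoods are scrubbed so the planted signal is the
unique in-window optimum (no second near-TTTAAA in the box A window; the
permuted locus's gap and tail are fixed sequences that admit no spurious
internal boxes). The generator therefore emulates signal geometry and
abundance structure, not sequencer realism: no quality decay, no indel
errors, no paired ends, uniform random background rather than genomic
composition. Passing tests show the inference machinery is correct under
the stated processing model; they do not show robustness to real-library
artefacts.

## Problem sizes and numerical details

The test suite runs the full default scenario once (50-kb genome, ~6,000
reads), twenty reduced scenarios (error-free, ~17-kb genomes) for the
abundance-decay recovery, and twenty 50-kb random genomes for the
false-positive measurement — sizes chosen so the whole suite completes in
minutes on one core. Relative abundances are checked to sum to 1 within
1e-9. Degenerate inputs are contracts, not crashes: zero-read spacers are
reported with count 0 and a flag, a missing leader yields a flagged
undefined TSS, an absent box A is a negative result, empty result sets
produce headers-only reports, and stages without their required inputs
are skipped with explicit `NULL` summary fields.

## Known limitations

Maximum-pairing folds are not thermodynamic: hairpin calls on real
sequences should be treated as candidates. The mapper's lack of soft
clipping under-maps reads that run across transcript boundaries. The
sRNA report numbers loci by coordinate order, which need not match any
published numbering. Spacer-to-protospacer matching, Cas gene analysis
and wet-lab circularity assays are outside the package's scope.
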