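---
title: "Methods: characterizing an IES landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an IES landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieskit)
```

This vignette explains the models and procedures behind `ieskit`, the
assumptions they make, the defaults and why they were chosen, and
what the synthetic-data generator does and does not emulate.

## The biological setting

Ciliates maintain a germline micronucleus (MIC) and a somatic
macronucleus (MAC). During sexual development the new MAC is derived
from the MIC by eliminating thousands of internal eliminated
sequences (IESs): MIC-limited segments flanked on both sides by
MAC-destined sequence (MDS). In *Blepharisma stoltei*, the system
this package is modelled on, IESs are typically bounded by short
terminal direct repeats (pointers) that usually contain the
dinucleotide `TA`, short IESs show a strikingly periodic length
distribution (~10 bp spacing, one DNA helical turn), and many longer
IESs are recently proliferated MITEs — miniature inverted-repeat
transposable elements whose target-site duplications (TSDs) coincide
with the IES pointers. Development-specific 24 nt small RNAs with a
5′-U preference (scnRNA-like) accumulate over IESs late in
development.

## Coordinates and the floating-window problem

All internal coordinates are 0-based half-open; GFF3 (1-based
inclusive) and the repeat TSV are converted at the file boundary.
An IES on the MAC is a *point* (`mac_point`: inserted before that
position), because it is absent from the MAC product; on the hybrid
MAC + IES assembly the same record is a *span*. Both live on one
record.

When a pointer bounds an IES, excision at any offset within the
repeat yields the same MAC sequence, so the true excision site is
unknowable from sequence alone ("floating" IES). `normalize_left()`
therefore rotates every window to its left-most equivalent position
before any terminal-repeat analysis; the operation provably preserves
the MAC product and is idempotent (both property-tested). All
detectors assume left-normalized input.

## Pointer and TIR detection

`find_tdr()` reports the longest exact common prefix of the IES and
its right MDS flank (bounded by the flank length). The minimum length
for a pointer call is 2 bp: 1 bp "repeats" arise by chance at rate
`Σ p_b² ≈ 0.28` under this genome's composition and carry no signal;
the threshold is configurable. A pointer containing `TA` anywhere
marks the IES TA-bound even when longer than 2 bp.

`find_tir()` compares element prefix bases against complements of
suffix bases until the first mismatch, the element midpoint, or the
25 bp cap. The element is taken to start immediately after the single
in-IES pointer copy of the left-normalized record (`strip = "left"`);
stripping neither or both ends is available because the convention
genuinely admits more than one reading — the chosen one keeps exactly
one pointer copy inside the element, which is the copy the element
physically contains. The cap exists because uncapped extension on
palindromic elements reports half the element length; it is disabled
(`cap = NULL`) when curating repeat-family boundaries, where full TIR
length is the quantity of interest.

## The null model for repeat lengths

Observed pointer/TIR length counts are compared against a geometric
i.i.d. model: with per-position match probability
`m = Σ p_b²` (direct) or `m = Σ p_b p_comp(b)` (inverted), the
expected number of IESs with repeat length exactly `L` out of `n` is
`n · m^L · (1 − m)`, which sums to `n` over all `L`. Base frequencies
are estimated from the concatenation of all IES sequences and both
flanks (a user-supplied vector overrides, and the estimate is
reported). This closed form is the package's explicit stand-in for a
null over repeat lengths — it ignores positional composition
heterogeneity and is labelled as such in output headers; the test
suite validates it against Monte-Carlo simulation of 10⁵ junction
pairs within 3 binomial SDs per length bin. A useful identity:
`m_direct − m_inverted = (p_A − p_T)² + (p_C − p_G)²`, so for
strand-symmetric compositions the two coincide.

## Length peaks, periodicity, size classes

`call_length_peaks()` operates on the 1 bp-binned histogram of
TA-bound IES lengths. A peak is a bin strictly greater than both
neighbours with count ≥ 100 (the cutoff keeps sampling noise on a
few-per-bin background from producing spurious classes); a plateau of
equal counts resolves to its left-most bin, a deterministic
tie-break. Size-class ranges are the width at half peak height: the
outermost contiguous bins with count ≥ height/2. Periodicity is the
median of consecutive peak-center differences within the periodic
range (default 65–115 bp); the median is robust to one missing or
shifted peak where a mean is not. Each IES receives exactly one
label: the covering peak (nearest center, ties to the smaller),
otherwise "periodic-offpeak" or "nonperiodic-offpeak" by range.

## Junction matrices

For TA-bound IESs only (other junctions have no common reference
point to align on), each record contributes two 24-position strings
anchored on the left-most `TA` of each pointer copy: 10 MDS bases
ending just before the TA and 14 IES bases starting just after it,
with the right junction reverse-complemented into the
5′-(MDS)-TA-(IES)-3′ orientation. The TA itself is excluded.
Junctions with insufficient sequence are skipped and counted. The
output is a base-count matrix (logo rendering is downstream and out
of scope). Left-most-TA anchoring is deterministic; note it is
mirror-symmetric only for pointers with a single TA occurrence
(`TA`, `TAT`/`ATA`, `TAA`/`TTA`) — for `TATA` the two pointer copies
anchor different physical TAs under strand reversal, a documented
property of the convention rather than a defect.

## Intragenic depletion

If insertion points were uniform, the intragenic count would be
Binomial(n, genic fraction). The reported p-value is the exact
one-sided lower tail, computed in log space (`pbinom(log.p = TRUE)`,
cross-checked in the tests against an independent log-sum-exp sum of
`dbinom` terms) so that depletion signals far beyond double underflow
(p ≪ 1e-300) remain quantifiable via `log10_p`. The choice of an
exact binomial is this package's decision; "intragenic" means the
insertion point falls strictly inside a gene interval (a point at a
boundary interrupts nothing).

## Mobile-IES (MITIES) calling

A family signature is a TIR consensus plus a TSD motif set closed
under reverse complement (packaged presets: Bogo/BogoMITE with the
30 bp C-rich TIR and `TAA`/`TTA` TSD; BstTc1 with the 38 bp TIR,
`TATA` TSD and the 10 bp microsatellite unit `GGGAAGGACT`). An IES is
MOBILE_IES when its pointer *equals* a TSD motif exactly and, after
stripping that pointer, the element begins with the family TIR and
ends with its reverse complement, each arm within a mismatch fraction
of 0.10. TSD matching is exact because pointer/TSD correspondence is
the defining observation; TIR matching is tolerant because element
copies diverge. Poly-C run-length variability (plausibly assembly
error) can be absorbed by optionally collapsing homopolymer runs ≥ 4
before comparison (`collapse = TRUE`, default off). An IES that is
not mobile but contains a supplied repeat copy of the family strictly
inside its hybrid span is NESTED; the interior margin defaults to
5 bp — enough to exclude copies that merely abut the junctions, small
enough not to miss genuinely nested copies.

`smallest_repeat_unit()` is the exact string period (smallest `p`
with `s[i] == s[i+p]` for all valid `i`), computed with the KMP
border array in O(n) and oracle-tested against brute force;
fractional copy numbers are allowed. `triad_motif()` formats the
DDE/D catalytic-triad shorthand (residues plus the gap between the
second and third, e.g. `DD35D`).

## sRNA quantification

Reads are counted once each with fixed priority: excluded
(tRNA/rRNA overlap ≥ 1 bp) first, then IES, then CDS, then NON.
Priority counting (rather than double-counting reads overlapping
both an IES and a CDS) is this package's documented choice; with
point-insertion IESs inside genes such overlaps are common, and
priority keeps column sums equal to library sizes. RPKM uses the
total genomic length of each feature *type* in place of transcript
length: `1e9 · count / (total_mapped · feature_length)`. The 5′ base
is read from the read sequence as sequenced, so genomic strand needs
no complementing. One placement per read is assumed (primary
mappings).

## The synthetic-data generator

`simulate_all()` is first-class, tested code that defines the study
conditions:

- **Genome**: i.i.d. bases at 33.5% GC over 4 × 500 kb contigs; gene
  intervals tiled to cover ~77%, mean gene 2 kb; a few 80 bp tRNA
  intervals in intergenic gaps.
- **IESs** (n = 8000): pointer classes at the observed rates
  (TA-bound 0.759, other exact repeat 0.165, none 0.076; TA motifs
  weighted TA 0.7, TAT 0.1, ATA 0.1, TATA 0.1); lengths from a
  mixture of integer-Gaussian peaks (σ = 1) at 65, 72, 83, 93, 104,
  110 bp (periodic; interpolated between the anchor peaks at 65, 72
  and 110 — a "partly interpolated" preset, not a reproduction of any
  published peak table) and 153, 174, 228, 389 bp (nonperiodic), plus
  a uniform 50–600 bp off-peak tail (20%); insertion points
  intragenic with probability 0.70 against a 77% genic fraction,
  reproducing the observed mild depletion.
- **Families**: 30 BogoMITE and 22 BstTc1 mobile elements built as
  TSD + TIR + core + revcomp(TIR) at sites where the genome carries
  the TSD (so the planted pointer *is* the TSD); nested full-length
  and degenerate partial copies planted strictly inside long host
  IESs; divergence applied as uniform point mutations of the TIR
  arms (default 0.5%).
- **Truth exactness**: candidate sites are validated before being
  claimed so that the planted pointer terminates exactly where
  recorded, no record needs left-shifting, and planted TIRs do not
  extend into the core (the core's first base is forced to mismatch
  the complement of its last). Excising all planted spans reproduces
  the somatic genome byte-for-byte — asserted in the tests.
- **sRNA time course**: seven time points (2–38 h), 20,000 reads
  each; lengths 18–30 nt with 22 nt at 32% and 24 nt at 30%; the
  24 nt IES-origin weight ramps from 0.15 to 0.60 after the 14 h
  switch while the CDS weight falls, emulating scnRNA dynamics; the
  first base is forced to T with probability 0.9 for 24 nt
  IES-origin reads (0.25 otherwise).
- **Determinism**: all draws are pure functions of the seed, with
  separate sub-streams for genome, IES and sRNA stages so adding
  reads never perturbs the genome.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: sequencing error and coverage
variation (retention scores are assigned, not simulated from reads),
compositional heterogeneity (real genomes are not i.i.d.),
scrambled or overlapping IESs, multi-mapping reads, chromosome
fragmentation/telomeres, and genuine evolutionary divergence
structure beyond uniform point mutation.

## Problem sizes and numerical choices

The default synthetic system (2 Mbp, 8,000 IESs) is large enough
that every planted length peak clears the 100-count cutoff with
comfortable margin (~600 draws per peak, ~230 in the center bin)
while the whole simulate-and-characterize cycle completes in well
under a minute on one core; the property suites use 10⁴ random
instances per oracle and 10⁵ junction pairs for the Monte-Carlo
null check. Degenerate inputs are defined, not special-cased:
empty histograms yield zero peaks, an empty element yields TIR
length 0, empty IES lists make insertion the identity, and a
composition with match probability 1 is an error rather than an
infinite ratio.

## Known limitations

- Pointer matching is exact; no probabilistic/fuzzy variant.
- The geometric null ignores dinucleotide structure; enrichment
  ratios at short lengths should be read comparatively, not as
  calibrated p-values.
- Divergence of repeat copies is an input column (or a generator
  parameter), never recomputed by alignment.
- `TATA` pointers anchor junction windows asymmetrically under
  strand reversal (see above).
- BAM/SAM and FASTQ are out of scope; placements arrive as BED6 +
  FASTA.
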