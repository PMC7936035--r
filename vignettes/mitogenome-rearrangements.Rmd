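---
title: "Models and methods: mitochondrial gene-order rearrangement analysis"
author: "mitoRearr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mitochondrial gene-order rearrangement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoRearr)
```

This vignette documents the models behind `mitoRearr`, the decisions
taken where the design was genuinely open, the calibrations of the
statistical components, and what the simulation-based validations do and
do not establish about real data.

## The gene-order model

A mitochondrial gene order is a circular sequence of signed elements:
the 37 genes (13 protein-coding genes, 2 rRNAs, 22 tRNAs named by
one-letter code with the L1/L2 and S1/S2 isoacceptor split), the Control
Region (`CoRe`, the H-strand replication origin) and the L-strand origin
(`OL`). The sign records the encoding strand (`+` = H, `-` = L). Because
a circular DNA molecule has no intrinsic starting point or reading side,
every arrangement has `2n` equivalent readings; `canonicalizeOrder()`
maps all of them to one normal form: rotate so *cox1* comes first, and
if *cox1* lies on the L-strand, mirror-complement the whole order first.
Two orders are equal iff their canonical element lists coincide.
Duplicate elements receive deterministic copy tags in traversal order
from the canonical start (letters for genes, numbers for Control
Regions): tags follow genomic position, not homology, because position
is what an annotation can actually observe. `OL` is treated as an
unsigned positional element — it participates in order comparison but
never in orientation checks, as no inversion of the L-strand origin has
been reported for these genomes.

Partial genomes are accepted throughout: `canonicalizeOrder()` and
`extractGeneOrder()` take a `fallbackStart` for records lacking *cox1*
and flag the result, and downstream tables simply omit absent genes
rather than inventing zeros.

## The rearrangement event model

Six executable operators cover the classical mechanism taxonomy:

| kind | effect | cost |
|---|---|---|
| transposition (`t`) | contiguous block moved, same strand | 1 |
| inversion (`I`) | block reversed and strand-flipped in place | 1 |
| inverse transposition (`it`) | moved and flipped | 1 |
| tandem duplication (`TD`) / triplication (`TriD`) | block duplicated adjacently, nothing lost | 1 |
| TDRL / TD-PRL (`tdrl`) | block duplicated, then random loss trims each copy | 1 |
| partial random loss (`PRL`) | a set of redundant copies deleted | 1 |
| loss | contiguous block deleted outright (even sole copies) | 1 |

Every kind costs one **event**; weights are configurable in
`eventModel()` but the default counts events the way the field counts
rearrangements: a completed duplication-plus-loss episode is one event,
and so is a partial random loss that drops several redundant copies at
once (the losses are one mutational episode of the same duplication
cycle, and treating them otherwise would make the single-step loss of a
duplicated tRNA pair cost two).

Two structural restrictions on the duplication operator deserve
explanation, because they are the package's own modeling decisions:

1. **Each copy retains a contiguous block.** The random-loss phase may
   trim a copy's flanks but not excise interior pieces piecemeal; an
   interleaved retention pattern is representable as a duplication plus
   follow-up events at the same total cost or one more.
2. **Each copy retains at least two elements.** A duplication in which
   one copy is reduced to a single gene is operationally
   indistinguishable from a single-gene move and is modeled by
   transposition instead.

Without these restrictions a single duplication event can emulate a
long-range duplicative insertion of one element (duplicate a six-gene
block, discard essentially all of one copy). That operator is so
powerful that it collapses distances between arrangements which differ
by a whole duplication *history* — in particular, it makes the
re-acquisition of a duplicated Control Region from a single-CoRe
arrangement a one-step event, at which point parsimony prefers single
origins for arrangements that the remnant evidence shows arose in
parallel. The restricted operator keeps duplication events identifiable
from the evidence they leave behind (retained duplicates and contiguous
spacer remnants), which is exactly how such events are recognized in
annotated genomes.

## Minimal event paths

`inferEvents()` searches breadth-first over operator applications, all
states reduced to canonical form, and returns every minimal path (up to
`maxPaths`, deterministically ordered). Three practical devices keep the
search exact where it matters and tractable everywhere else:

- **Region restriction.** By default the search window is the region
  where the two orders actually differ (their longest common flanks are
  anchored), padded by the maximal duplication length; an explicit
  window such as `c("nad5", "F")` restricts the search to the
  notothenioid hot spot, and `region = NULL` searches everything
  downstream of the canonical anchor.
- **One-event completion.** For the final step of any search the
  candidate events are *derived* from the mismatch between a state and
  the target (subsequence embedding for pure losses, mismatch-anchored
  segments for duplications, end-block relocations for content-neutral
  events) rather than enumerated blindly. This step is exact.
- **Target-guided expansion.** Intermediate levels of multi-event
  searches only expand events that reduce the copy-number gap toward the
  target, repair a target adjacency, or fix a strand mismatch; plain
  duplications are allowed to overshoot (a later loss cleans up). This
  pruning is a heuristic: it can in principle miss an exotic minimal
  path through an intermediate that looks less target-like, so
  `mode = "exhaustive"` remains available and is what the
  oracle-equivalence tests exercise (against an independent brute-force
  enumeration, on orders of up to 7 elements). Guided and exhaustive
  searches agree on every tested case.

Distances above the search depth are composed transitively through the
candidate state pool during ancestral reconstruction (below), which
resolves, e.g., three-event transitions through an observed intermediate
without deep search.

## Ancestral reconstruction

`reconstructAncestral()` runs Sankoff dynamic programming on a rooted
phylogeny over a **finite candidate state pool**: the distinct observed
tip orders plus optional `extraStates` (for the notothenioid fixture,
the unsampled pre-inversion Trematominae intermediate, which the pathway
analysis posits). Pairwise directed costs come from `eventDistance()` at
`poolDepth` (default 2) and are closed transitively over the pool
(Floyd–Warshall, with concatenated representative paths). A pool rather
than open-ended state search is a deliberate trade: rearrangements are
rare and derived arrangements are observed, so unobserved intermediates
beyond the supplied ones almost never lower the total cost, while the
pool keeps the DP exact over its state space (verified against
exhaustive assignment enumeration on trees of up to 6 tips).

All co-optimal assignments are enumerated (capped); the **primary**
assignment used for tabulation picks, at every tie, the
lexicographically smallest state name — a deterministic, reportable
convention. `detectHomoplasy()` reports, by default across the
co-optimal set, every arrangement that is derived on two or more edges
not on a single root-to-tip path; since any co-optimal assignment is an
equally parsimonious history, a parallel origin in any of them is a
legitimate parsimony finding.

On the shipped 28-taxon fixture the reconstruction needs 13 events,
roots the family in the typical vertebrate arrangement (forced by the
non-Antarctic outgroups), and flags Noto2GO and Noto3GO as twice-derived
— and the result is invariant to the alternative basal placement of
*Pleuragramma antarctica* (`compareTopologies()`).

### Fixture provenance

The eight nototheniid arrangements, the pre-inversion intermediate and
the typical vertebrate order are encoded from the published linearized
layouts and pathway descriptions. Two caveats are flagged in the fixture
metadata: RacoGO's exact element list is published only in figure
panels, so the shipped order (`nad5,T,-P,CoRe,-nad6,-E,cob,-P,CoRe,F` in
the hot-spot slice — a duplication of the *trnP*–CoRe pair, consistent
with the reported double Control Region and the tendency of retained
duplicates to be tRNAs) is marked `figure_derived`; GymnGO follows the
textual pathway description (retained *trnE* and *trnP* duplicates).
The reference topology is a transcription: species named in the running
text are placed exactly; the remaining tips within Trematominae,
Artedidraconinae, Bathydraconinae and Channichthyinae are plausible
congeners, which does not affect any structural result (only
subfamily-level shape and gene-order assignments enter the analysis).
Species published after the study window ship as optional fixture tips
(`notoTipOrders(later = TRUE)`) and are excluded from the reference
analyses.

## Intergenic spacers and remnant scanning

`extractSpacers()` returns every inter-feature gap of at least 10 nt
(circular wrap included). `scanSpacer()` aligns a spacer locally
(Smith–Waterman; match +2, mismatch −3, gap open −5, gap extend −2 —
conventional BLASTN-like scoring, bit-exact for reproducibility) against
every gene of the same genome on both strands, Control Region included,
since CoRe remnants are key rearrangement evidence. tRNAs are excluded
from the default library (remnants shorter than ~40 nt cannot be called
reliably); `minGeneLength = 0` scans against everything.

**Decision rule and calibration.** A hit supports a
rearrangement-derived spacer (GR-ISP) iff the alignment spans ≥ 15 nt at
≥ 70% identity *and* reaches raw score ≥ 30, **or** contains an exact
run of ≥ 18 nt. The score term carries the statistical weight: length
and identity alone are not discriminating, because optimal local
alignment finds short stretches of 70–80% identity between *any* two
random sequences — a rule without the score term accepts nearly every
random spacer. The defaults were calibrated on simulated
random-composition null spacers scanned against a full simulated gene
library: false positives run at ≈ 0–1%, while every remnant of ≥ 20 nt
with ≤ 10% divergence is detected (such a remnant always attains score
≥ 30, or — when both end positions are mutated — an 18 nt exact run).
Strongly biased spacer composition inflates the null tail toward ~1–2%;
`spacerThresholds()` exposes everything for stricter settings. Because
no numeric criteria for the spacer classes are available from real-data
reports, these calibrated thresholds are a stand-in, and real GR-ISP
counts should not be compared against them uncritically.

`peptideCheck()` translates a protein-coding remnant in the frame
implied by its position in the source gene (vertebrate mitochondrial
code) and reports the longest identical amino-acid run against the
protein — the same evidence used to identify apocytochrome-b C-terminus
remnants in trnE–trnT spacers. `classifySpacers()` labels each spacer
STD-ISP or GR-ISP and cross-references GR-ISPs against event paths: a
spacer corroborates a pathway when its remnant's gene is among the
elements that the path duplicates and loses.

## Strand compositional bias

Skews are (A−T)/(A+T) and (G−C)/(G+C); on the deposited strand of an
unrearranged vertebrate mitogenome the synonymous third positions are
A- and C-rich (positive AT-skew, negative GC-skew), the footprint of
deamination-biased replication. `classifyCodonDegeneracy()` classifies
codons under translation table 2 (TGA = Trp, ATA = Met, AGA/AGG = stop
— getting these wrong misassigns whole codon families), verified in the
tests against an independently transcribed code table.
`extractDegenerateSets()` pools third-position bases of the 4-fold
(NNN4) and 2-fold (NNR2+NNY2) degenerate codons across protein-coding
genes; genes translocated to the opposite strand (e.g. *nad1* after the
Trematominae inversion) are excluded automatically by comparing each
gene's strand with its typical-arrangement strand, because their bias is
mirrored.

The strand-symmetry test is the binomial normal approximation
`z = (nA − nT)/sqrt(nA + nT)` with a two-sided normal p-value (likewise
G vs C). The historical reference equations for this test are not
reprinted in the literature the package follows; the binomial
approximation is the natural reading and its type-I error calibrates at
the nominal 5% (±1%) over 10,000 simulated nulls. Pools under 10 sites
are flagged low-power. Group comparisons of |skew| use the two-sample
pooled-variance Student's t-test (not Welch), and no multiple-testing
correction is applied across genes or partitions by default, mirroring
per-gene reporting practice (`p.adjust` can always be applied to the
returned tables).

`decideReversal()` applies the two-criterion rule per degenerate-site
class: a **full** reversal requires, for both NNN4 and NNR2+NNY2, skew
signs opposite to the unrearranged expectation *and* rejection of strand
symmetry for both A-vs-T and G-vs-C; a **partial** reversal is any
proper, non-empty subset of the sign oppositions (the pattern of a
recent Control Region inversion); otherwise **none**. An unrearranged
genome therefore returns "none" even though its (expected-sign) biases
are highly significant.

## Pairwise Ka/Ks

`pairwiseKaKs()` implements Nei–Gojobori (1986) counting under the
vertebrate mitochondrial code with Jukes–Cantor correction. Conventions,
stated explicitly because variants abound: synonymous site fractions
count mutations to stop codons as nonsynonymous; multiple-hit codons
average over all substitution orderings, excluding paths through stop
codons when any stop-free path exists; codons containing gaps,
ambiguity characters or stops in either sequence are dropped pairwise;
proportions ≥ 0.75 are flagged saturated with undefined distance; pairs
with Ks = 0 report an absent ratio rather than infinity (which would
distort distribution summaries). The implementation is checked to 1e-9
against an independent path-enumeration oracle. `kaksDistribution()`
summarizes all pairwise ratios per gene in box-plot form (median, mean,
quartiles, 1.5×IQR whiskers, outlier count), ordered by OXPHOS complex
(I: *nad* genes; III: *cob*; IV: *cox* genes; V: *atp* genes).

## The simulator

`simulateAncestor()` builds a typical-arrangement genome with realistic
element lengths (~16.5 kb at scale 1; protein-coding genes are valid
ORFs under code table 2). Sequence evolution is site-independent and
HKY-like (transition/transversion ratio κ = 4) with two strand-asymmetry
multipliers for the deamination reactions of the heavy strand (A→G ×2,
C→T ×6), which on the deposited strand appear as T→C and G→A and drive
the canonical positive AT / negative GC skews. Neutral positions start
at `A .32, C .36, G .12, T .20` — near the model's mutational
equilibrium, so unrearranged lineages keep their skew signs at any
branch length. Protein-coding genes evolve with per-gene ω
(accept/reject of nonsynonymous proposals; defaults span strong
purifying selection for *cox1* to relaxed for *atp8*) — crude relative
to codon models, but sufficient for rank recovery, which is what the
validation asks of it. Scripted rearrangement events apply at chosen
branches; every duplication initially carries complete extra copies, and
losses convert dropped copies into spacer remnants that subsequently
decay by extra substitutions and geometric deletion chunks. An inversion
containing the Control Region flips the genome's replication polarity
and with it the mutational asymmetry. All randomness flows from one
seed through named substreams (per branch, per component), so individual
components reproduce in isolation.

The three reversal scenarios are scripted from the substitution model's
relaxation dynamics (computed from the rate matrix, not fitted to any
test): after a polarity flip, the weakly biased AT-skew crosses zero
near branch length 0.2 while the strongly biased GC-skew crosses near
0.4. "none" = no inversion (b = 0.3); "partial" = inversion + b = 0.3
(AT flipped, GC not — the recent-inversion pattern); "full" = inversion
+ b = 1.5 (both re-equilibrated).

**What the simulations do not show.** The simulator omits tRNA secondary
structure, recombination, nuclear copies (numts), among-site rate
variation and indels outside remnants; its genomes are cleaner than real
ones. Validation against it demonstrates that the algorithms recover
what they are designed to recover under the stated model — not that
real annotations are error-free, nor that the calibrated spacer
thresholds transfer to genomes with extreme composition.

## Problem sizes and numerical choices

The test suite and the acceptance script run at reduced scales chosen as
the package's own validation design: oracle equivalence on orders of
≤ 7 elements and trees of ≤ 6 tips; planted-event recovery over 100
events (single event per branch; pairs with up to two stacked events are
exercised separately, where ~4% of trials are genuinely ambiguous —
two events whose composition equals a cheaper or different-kind event,
e.g. duplication-then-loss equalling one TD-PRL); spacer calibration on
500 planted remnants and 400–500 nulls against a half-scale library;
symmetry-test calibration on 10,000 binomial nulls; Ka/Ks rank recovery
over 60–100 replicates of six 0.6-scale genomes at pairwise divergence
0.3. Searches cap at 200,000 states and raise an explicit truncation
error beyond that; path enumeration caps at a configurable `maxPaths`.

## Known limitations

- The guided multi-event search is a pruned heuristic; exact behavior
  is guaranteed for single events, for the final completion step, and
  wherever the exhaustive mode is feasible.
- Unit event costs are a convention; where mechanisms differ wildly in
  rate, weighted models (supported, reported per path) or likelihood
  methods would be preferable.
- The reconstruction explores only the supplied candidate state pool;
  pathologically intermediate-rich histories would need `extraStates`.
- Real-data stages out of scope by design: genome assembly and
  annotation, sequence alignment construction, phylogeny inference and
  dating, and branch-site selection tests. Trees and annotations are
  inputs, never inferred.
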