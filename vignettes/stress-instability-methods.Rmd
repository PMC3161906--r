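---
title: "Simulating stress-induced amplification and genome-wide instability: models and methods"
author: "ampshower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating stress-induced amplification and genome-wide instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampshower)
```

## The system being modelled

In the Lac assay, starving bacteria carrying a leaky marker allele on a
conjugative F′ episome escape starvation by amplifying the marker into a
high-copy tandem array (on the order of 70 copies of a ~20 kb amplicon).
Array-CGH surveys of such amplified isolates show two striking patterns:
the amplification events themselves are frequently *complex* — the
amplicon's repeating unit carries internal inverted duplications,
partially inverted blocks, or internal deletions, consistent with repeated
template switching at replication forks (MMBIR) followed by expansion
through unequal crossing-over — and a measurable fraction of amplified
isolates additionally carries *unrelated* structural events (deletions,
inversions) elsewhere in the genome, while stressed isolates without
amplification carry none. The second observation is the basis for the
inference that amplification arises in a differentiated subpopulation of
stressed cells that is transiently permissive for chromosomal structural
change.

`ampshower` implements that entire analysis on synthetic genomes: the
reference system, the rearrangement classes, the scan simulation and
calling rule, the junction-level assays, and the cohort statistics. No
real strain data are used anywhere; everything is generated, which is what
makes every step exactly checkable.

## The synthetic reference

`buildReference()` generates two circular replicons with i.i.d. uniform
base composition outside planted features:

* a chromosome (default 200 kb) and an F′-like episome (default 100 kb).
  The real system is a 4.6 Mb chromosome with a ~100 kb F′; the default
  chromosome is scaled down so that a full 540-isolate cohort analysis
  runs in seconds, and every size is a `referenceConfig()` parameter;
* a **shared block** (default 40 kb) copied verbatim from the chromosome
  onto the episome, emulating the chromosomal segment carried on the F′,
  with a 3 kb **marker locus** (the *lac* analogue) inside it.  The
  sequence identity of the two copies is a class invariant, enforced by
  the `ReferenceModel` validity method and preserved by every
  sequence-editing operation;
* **REP cassettes**: clusters of 2–4 planted ~38 nt pseudopalindromes
  (stem 12–16 nt, loop 4–8 nt, up to 2 stem mismatches), one cluster
  placed immediately downstream of the marker's chromosomal source to
  emulate the junction-hotspot REP cluster near *lac*.  What matters for
  the analyses is their structure-forming potential, not their exact
  sequence, so they are random palindromes rather than real REP elements;
* a **mask** of excluded intervals (the repeat/prophage exclusion of the
  real analysis).  Masks are aligned to the probe grid so that the number
  of excluded probes equals masked length divided by spacing;
* a tiling **probe array** (default 100 nt spacing on both replicons;
  episome density is a separate knob because the real array's relative
  coverage of the F′ is not documented).  Probes inside masks are dropped.

Coordinates are 1-based and closed throughout the package (the native
Bioconductor convention); BED files are converted to 0-based half-open on
export and back on import by `rtracklayer`.

## Rearrangements as oriented segment plans

A `SegmentPlan` is an ordered list of oriented reference intervals; `-`
segments realize as reverse complements, multiplicity is repetition, and
two derived quantities follow mechanically: `realizeSequence()` (the
rearranged molecule) and `copyNumberProfile()` (per-base coverage in
reference coordinates — the exact expectation behind every simulated
scan). The identity plan realizes the reference, and for every plan the
profile sums to the total segment length (conservation), which is enforced
as a property test across all builders.

Each structure class is built by the template-switch construction that
explains it:

* **Tandem amplification**: `copies` head-to-tail repeats of the amplicon;
  one novel junction type (amplicon end → amplicon start).
* **Embedded inverted duplication (EID)**: unit
  `[flank, inner(+), inner(−), flank′]`, i.e. two inverted switches that
  duplicate the inner region in opposite orientation, then expansion of
  the unit; the inner region sits at twice the amplicon copy number.  A
  `triplication = TRUE` option uses the `[inner(+), inner(−), inner(+)]`
  unit — the pre-crossover inverted triplication — because the scan data
  cannot distinguish duplicated from triplicated inner regions in every
  isolate, so both layouts are supported and neither asserted.
* **Partially inverted (split) amplification**: the plan follows the
  two-inverted-switch mechanism literally:
  `[1..le](+) + (copies−1) × {right(−), left(+)} + [le+1..L](+)`.  This
  layout gives both gained blocks exactly `copies` coverage, leaves the
  gap between them at 1, and produces exactly two novel junction types
  (the last unit's left copy is reference-adjacent to the resuming
  backbone).  A naive tandem `{left(+), right(−)}` unit would instead give
  the right block one extra copy and a third junction type.
* **Embedded deletion**: unit pairs of one full plus one deleted amplicon
  copy; the deleted interval sits at half the amplicon copy number; both
  junction types are in direct orientation.  A zero-length deletion
  degenerates to the plain amplification.
* **Inversion with endpoint micro-indels**: the inverted segment's
  endpoints are displaced by signed offsets (|offset| ≤ 100 nt, matching
  the few-tens-of-bp displacements seen at near-reciprocal inversion
  junctions); a positive offset leaves a micro-duplication, a negative one
  a micro-deletion, and the realized length is the reference length plus
  the two offsets.
* **Unlinked deletion**: one direct novel junction, used as the
  "secondary event" class.

`composePlans()` splices disjoint events on one replicon into a single
plan and refuses overlapping event regions (no overlapping within-isolate
events are modelled, matching the observed cohorts, where no isolate
carried two interacting secondary events).

## Designed microhomology

Junction microhomology is defined by breakpoint-placement ambiguity: the
maximal k such that the junction can be written at k+1 equivalent
positions because both parental strands share the same k-mer across the
join; the leftmost placement is reported. This is the standard structural
variant convention and matches how junction sequences are printed (the
shared tract once).

Builders *construct* the requested microhomology rather than hoping to
find it: the k-base tract ending at the donor side of the junction is
copied into the acceptor's upstream template (or, where junction geometry
requires, mirrored onto the donor's downstream template), and one capping
base immediately outside the tract on each side is mutated so the measured
ambiguity equals k exactly. Edits are applied to the reference before
realization — designing the genome, not the rearranged molecule — and
edits falling inside the shared block are mirrored to the other replicon
so the identity invariant holds. Two geometric subtleties are handled
explicitly: at a coordinate-symmetric inverted junction (donor end equal
to acceptor start) left and right ambiguity are forced equal, so inverted
junctions offset the acceptor start by one base, after which any k ≥ 0 is
designable (a base never equals its own complement, so the off-side
ambiguity is structurally zero); and where two junctions' planted regions
interact (the two EID junctions both touch the inner region's right end),
planting is iterated to a fixed point and verified, erroring out rather
than silently delivering a wrong tract if events are placed pathologically
close.

Inversion junctions are designed with k = 0; the caps then guarantee that
prefix/suffix alignment of the realized molecule against the reference
terminates exactly at the designed breakpoints, which is what makes
`junctionMicroindels()` recover the endpoint offsets exactly rather than
up to chance matches.

## Scan simulation, calling, classification

`simulateRatios()` draws `log2(cn_sample/cn_ref) + ε`, `ε ~ N(0, σ²)`
i.i.d. per probe; σ = 0 gives exact ratios. Zero sample copies over a
positive reference use a floor pseudo-count of 0.01 (flagged); probes with
zero reference copy are dropped with a warning. The default σ of 0.2 log2
units is a realistic per-probe noise level for two-colour oligo arrays
after normalization; it leaves the 2-fold calling threshold five standard
deviations from neutrality.

`callSegments()` implements the published rule and nothing more: maximal
runs of at least `minProbes = 2` adjacent probes with |log2| ≥ 1
(inclusive on both the threshold and the run length), where *adjacent*
means separated by exactly one probe spacing — so runs break across masked
gaps — and the first and last probes of a circular replicon are adjacent
(a call may wrap the origin, flagged `wraps`). Call boundaries are the
outermost qualifying probes extended by half a spacing; since the true
boundary lies between the last inside probe and the first outside one,
noise-free boundary error is at most one spacing. `est_copy` is
`2^mean(log2)` relative to reference copy 1; translation to cellular copy
number (the elevated F′ count of amplified cells) is deliberately out of
scope. No smoothing or segmentation (CBS, HMM) is applied: the published
analysis used a run-length threshold, and the package implements exactly
that.

`classifyEvents()` applies the structure catalogue in linear copy units:
a gain covering the marker is an amplification (AMP); an AMP whose
interior holds a run at ≥ 1.4× the flanking amplicon copy is an EID, at
≤ 0.6× an embedded deletion; two gains with agreeing copy (within 25%)
separated by a normal-copy gap are a split amplicon (candidate partially
inverted amplification, flagged for PCR confirmation); a loss neither
overlapping nor within one spacing of an AMP is a secondary deletion;
anything else is labelled unclassified with a reason. Two numerical
details matter in the noisy regime: calls separated by a *probe-free* gap
are first merged (a masked gap splits one physical event into two calls,
which would otherwise mimic a split amplicon), and interior runs are
assembled with a looser per-probe gate (1.2× / 0.75×) while the 1.4× /
0.6× decision fold is applied to the run's median copy with a minimum run
of five probes — single noisy probes then neither fragment a true inner
segment nor fabricate one. The flanking copy is the more conservative of
the two edge medians (up to 10 probes per edge) so one contaminated edge
cannot bias the comparison.

Copy-neutral inversions are invisible to all of this, as they are to real
aCGH; they are detected by `inversionScreen()`, which places
same-orientation primers every 2 kb within 20 kb of the marker and runs
exact-match in-silico PCR (`unidirectionalPcr()`): same-orientation pairs
yield no product on the reference, and exactly the inversions that flip a
primer site make a pair convergent. The pipeline keeps PCR-only
detections separate from aCGH classes, and a PCR hit counts as a
*secondary* inversion only when the aCGH class does not already explain it
as amplification-linked (an EID's inverted inner copy legitimately fires
the screen). Primer binding is exact-match by design: the assay's logic
is orientation, and a thermodynamic model would add nothing the synthetic
data could test.

## Stem-loop prediction

`findStemLoops()` enumerates maximal inverted repeats (stem ≥ 6 nt by
default, loop 3–50 nt, at most 1 mismatch, innermost and outermost stem
pairs required to base-pair) rather than folding thermodynamically: the
claims the module supports are positional — junctions sit on stems rather
than loops of predicted structures — not energetic, and enumeration is
exactly testable (strand symmetry, monotonicity in the stem threshold,
guaranteed recovery of the planted REP cassettes). The original analysis
used a commercial folding tool whose parameters are not documented; this
replacement is declared, not claimed equivalent, and the published
stem/loop/both/unstructured counts are therefore not asserted anywhere.
`classifyJunctionStructure()` classes the whole microhomology footprint
(not a point) against all structures within a 100 nt window: footprints
touching only stems are "stem", only loops "loop", both "both", none
"unstructured".

## Statistics

`petoOddsRatio()` implements the one-step estimator
`exp((O − E)/V)` with hypergeometric expectation `E = n1·m1/N` and
variance `V = n1·n2·m1·m2/(N²(N−1))`, with the z-interval
`exp((O−E)/V ± z/√V)`. It exists precisely because the control arm of
both published comparisons has zero events, where the sample odds ratio is
undefined. On the published tables it reproduces OR 6.7 (lower bound 3.1)
for 28/300 vs 0/240 and OR 6.2 (CI 1.2–31.0) for 6/300 vs 0/240 at one
printed decimal. The upper bound of the first interval computes to ≈14.3
against a printed 14.1; the discrepancy (a rounding path or a variant
variance formula) cannot be resolved from the published numbers alone, so
that single bound is not asserted.

`fisherExact()` computes exact hypergeometric tails; the two-sided p-value
uses the point-probability rule (all tables at most as probable as the
observed one), the dominant convention and the one used by R's reference
implementation, against which — and against a direct
binomial-coefficient enumeration — it is tested to 10⁻¹². On the
secondary-event table it gives p = 0.036, matching the printed value; on
the 28-event table it gives ≈4×10⁻⁸ where 0.0001 is printed, which looks
like a reporting floor, so printed p-values are computed but not asserted.
`proportionPct()` rounds half-up at the printed precision (28/300 → 9.3%,
16/300 → 5.3%, 4/300 → 1.33%, 22/90 → 24%).

`cohortCompare()` counts *isolates* with at least one qualifying event —
the isolate, not the event, is the counting unit — under two filters kept
deliberately distinct: `"any_extra"` (any structural event beyond the
plain amplification; the 28-event analysis) and `"secondary"` (events not
explained by the amplification; the 6-event analysis, where a junction
shared with the amplification makes an event related rather than
secondary).

## Cohort simulation and its defaults

`cohortConfig()` defaults are the study conditions: 300 amplified vs 240
stressed control isolates; every amplified isolate carries an
amplification covering the marker with lognormal copy number (mean 70,
SD 23) and amplicon length normal with mean 22.7 kb; per-isolate extra
event probabilities 16/300 (EID), 2/300 (split), 1/300 (embedded
deletion), 4/300 (unlinked deletion, length 0.2–7.5 kb, microhomology
1–4 nt), 2/300 (inversion); at most one extra event per isolate (no
isolate with two was observed; a joint distribution is not identifiable
from the data); controls carry no events. Amplification junction
endpoints are snapped into a REP cassette cluster with probability 0.24,
mirroring the observed 22/90 junction-at-REP fraction, which makes
REP-enrichment analyses recoverable from simulated cohorts. The master
seed fans out to per-isolate seeds through a fixed counter scheme, so any
isolate is reproducible in isolation and the whole cohort is
deterministic.

The copy-number path (ratios → calls → classes) depends only on segment
coverage, so cohort simulation skips sequence-level junction planting
unless `sequences = TRUE`; junction and PCR analyses realize sequences
only for the isolates that need them.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: dye bias, GC and fragment-length effects and
their normalization; probe-specific response; real REP/IS sequence
homology (and hence any homology-driven, as opposed to structure-driven,
junction preference); replication-fork biochemistry and event timing
during starvation; selection dynamics shaping copy-number and amplicon
distributions beyond the reported summary statistics; and translocations
or junctions refractory to PCR, which the original study could not resolve
either.

## Numerical and calibration choices

* Threshold semantics are inclusive ("2-fold or more" means |log2| ≥ 1),
  and boundary behaviour is tested explicitly at exactly 1.0.
* Junction ties are resolved by left-alignment (leftmost equivalent
  placement reported).
* Problem sizes: unit tests run on a 30 kb + 20 kb reference; the
  caller-contract cohort (300 + 240 isolates, noise-free) on the default
  200 kb + 100 kb reference; the parameter-recovery calibration (200
  cohorts of 540 isolates at σ = 0.2, true secondary-event probability
  0.02) on a 100 kb + 50 kb reference with 1,500 probes.  These sizes keep
  the full suite desk-scale while leaving every probe-level quantity at
  the realistic 100 bp resolution.
* In the calibration, the control arm's event probability is exactly zero,
  so the true odds ratio is infinite and "coverage" needs a referent: the
  replicate confidence intervals are assessed against the large-sample
  value of the Peto functional under the design (the expected table
  6/294 vs 0/240, OR ≈ 6.15).  This is the quantity the one-step
  estimator targets under a structural zero, and the only finite
  generating value consistent with the design.
* `simulateCohort()` writes the truth table before any calling, and the
  classification path provably never reads it (tested by deleting the
  truth and comparing outputs).

## Known limitations

* Exact-match PCR and enumerated (non-thermodynamic) hairpins are
  simplifications chosen for testability; both are declared replacements
  for wet-lab or commercial-software steps, not emulations of them.
* The split-amplicon classifier flags candidates for PCR confirmation but
  the package does not model the confirmation failure modes
  (translocations, unamplifiable junctions) seen in a minority of real
  isolates.
* Circular replicons are handled for probe adjacency, interval wrap and
  junction enumeration, but event intervals themselves must stay clear of
  the origin (enforced with a clear error); in-silico PCR treats realized
  molecules as linear.
* The Peto upper bound discrepancy on the 28-event table (14.3 vs 14.1)
  is documented above and left unresolved, as it must be.
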