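---
title: "Models and methods in htrec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in htrec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htrec)
```

`htrec` studies heterologous recombination (Ht-REC) — recombination
between sequences that share little or no homology — from two directions:
the structural variants it leaves in mammalian genomes, and a genetic
scoring system that measures its frequency across a balancer inversion in
*C. elegans*.  This vignette explains the models behind both halves, the
parameters that matter, and the design choices made where the science
left the design open.

## Derivative chromosomes and their observables

A rearranged haplotype is represented as a `DerivativeChromosome`: an
ordered list of oriented reference segments (0-based, half-open
coordinates) read along the derivative molecule.  The intact chromosome
is one forward segment; every event operation rewrites the segment list.
Two observables are derived from it, mimicking what a short-read WGS
pipeline reports:

* **Junctions** (`deriveJunctions`): one breakpoint junction per adjacent
  segment pair whose reference coordinates are not contiguous.  A
  breakend records the retained terminal base and a side: `R` (retained
  sequence at coordinates at or below the position) or `L` (retained at
  or above).  The encoding maps one-to-one onto BEDPE strands
  (`R` to `+`, `L` to `-`).  Junctions are canonically ordered and
  deduplicated — a junction present in both arms of a fused palindromic
  chromosome is one molecular join and real callers report it once.
* **Copy number** (`deriveCopyNumber`): per-base coverage of the
  reference by derivative segments, plus the `baselineCN - 1` intact
  homologs, averaged over bins (default 1 kb in the clone simulator),
  rounded to integers and merged into segments.  Events are placed on one
  haplotype of a diploid (`baselineCN = 2`) genome; the ploidy is
  configurable because the immortalized fibroblast lines this emulates
  have no firmly established ploidy.

Event operations cover the classes seen in Rtel1-deficient genomes:
deletion, tandem duplication, inversion, templated duplication with
distant intra-chromosomal insertion, breakage-fusion-bridge (BFB) cycles
and chromothripsis.  Intervals must fall inside a currently-present,
forward-oriented region, which keeps the arithmetic unambiguous when
events accumulate.

### Templated duplication with distant insertion

The signature novel class is parameterized by
`TemplatedInsertionParams`: a template of 2 kb to 100 kb is copied —
leaving the original in place, hence +1 copy number over the template —
and inserted 10 kb to 5 Mb away (measured template midpoint to insertion
point), replacing 6 bp to 1 kb at the insertion site, in inverted
orientation with probability 0.8.  The bounds are the observed ranges;
the "several megabases" upper end is fixed at 5 Mb and the inverted
proportion at 0.8, both configurable, because only qualitative statements
("typically inverted", "up to several megabases") are available.  The
mechanism this emulates is replicative: a stalled fork switches by
Ht-REC to a distant template, copies tens of kilobases, and switches
back near the original stall — which is why the junction geometry links
the insertion-site flanks to the two template boundaries.

### Breakage-fusion-bridge

Each cycle draws a break uniformly within a window (default the distal
10% of the current derivative) from the unstable end, discards the
distal piece, and fuses the retained molecule to its own reverse
complement.  Each completed cycle leaves one fold-back junction (an
inverted junction whose breakends nearly coincide) and doubles the copy
number of retained sequence; sequence distal to the first break is lost.
The break-position law is a modelling choice — no distribution is
observable from end-state genomes — and the 10% default concentrates
amplification steps near the unstable end, the pattern seen in real BFB
profiles.

### Chromothripsis

A region is cut at `nFragments - 1` uniform positions; fragments survive
independently with `retainProb`, and survivors are re-ligated in random
order and orientation.  Copy number inside the region therefore
oscillates between two states, and junction orientations are close to
uniform over the four categories — the two hallmarks the detector tests.

## The clone simulator

`simulateClone` draws an event count and class mix from a genotype
profile, places events uniformly with rejection of overlap against
previously placed events (at most 1000 retries), applies them
sequentially and derives the observables.  The two built-in profiles
encode the contrast between genotypes:

| parameter | `wild_type` | `rtel1_null` |
|---|---|---|
| events per clone | 8–12 | 15–35 |
| classes | del 0.50, dup 0.35, inv 0.15 | del 0.40, dup 0.18, inv 0.07, templated insertion 0.20, BFB 0.10, chromothripsis 0.05 |
| deletion sizes | 0.5–10 kb (log-uniform) | 1–500 kb (log-uniform) |
| genome | 100 Mb, diploid | 100 Mb, diploid |

Event counts and the qualitative size contrast (wild-type events below
10 kb; mutant deletions frequently beyond 100 kb) are the documented
study conditions; the class proportions and log-uniform size law are this
package's choices, fixed once to resemble the reported class spectrum.
At most one BFB and one chromothripsis event are drawn per clone (a
second BFB tail on one linear chromosome is not representable), the BFB
is applied last, and the distal 20% of the chromosome is reserved as its
footprint so the arm doubling cannot silently destroy other placed
events.

What the generator does *not* emulate matters for interpretation:
there is no read-level noise, no breakend uncertainty, no microhomology
or untemplated insertion at joins (`insertLen` defaults to 0), one
rearranged haplotype per clone, a single chromosome, and no
inter-chromosomal translocations.  Passing round-trip tests therefore
demonstrates internal consistency of simulator and classifier at the
call level, not performance on raw sequencing data.

## The classifier

`classifySample` assigns every junction to exactly one event or simple
class (the report partitions the junction set).  The order is greedy,
complex before simple, with two refinements that proved necessary:

1. **Reciprocal inversion pairing first.**  A clean inversion produces a
   head-to-head and a tail-to-tail junction at matching positions.  Such
   pairs are set aside as `inversion` before anything else; otherwise any
   inversion smaller than the fold-back gap (10 kb) masquerades as a
   fold-back and is swallowed by BFB calling.
2. **Templated insertions before BFB.**  An inserted copy lying close to
   its template yields one inverted junction with a small breakend gap —
   again fold-back-like.  The insertion geometry (two junctions whose
   site-side breakends flank a 6 bp–1 kb deletion, template copy number
   at least one above its flanks) is essentially never satisfied by two
   genuine fold-backs, so insertions are resolved first.  Competing
   candidate pairings are resolved by smallest site deletion, then
   leftmost template.

Chromothripsis calling clusters breakends by gap (default 1 Mb), keeps
the largest component of junctions with mutually overlapping spans —
shattering interleaves junction spans, whereas an independent event that
merely lies nearby does not — and requires at least 8 breakends, at most
2 copy-number states inside the region, and junction orientations
compatible with uniformity (chi-squared goodness of fit at alpha 0.05).
Copy-number segments shorter than 5 kb are ignored when counting states:
with binned profiles, every fragment boundary that is not bin-aligned
produces a one-bin segment at an intermediate value.  BFB calling
requires at least one fold-back junction together with amplification
immediately proximal to the outermost fold-back and loss distal to it
extending to the chromosome end; the cycle estimate is the number of
fold-back junctions.  All thresholds live in `classifierConfig()`; no
published rule set exists for these calls, so the defaults were chosen
once to make classification of the simulator's own output reliable, and
nested events the greedy order cannot resolve are simply consumed by the
earlier call.

Round-trip fidelity is measured by `eventRecovery`: across 100 seeded
clones (alternating profiles), simple events are recovered exactly and
overall class recovery exceeds 90% — the dominant residual losses being
chromothripsis events whose orientation test fails by chance (about 5%
by construction at alpha 0.05) and insertions whose junctions land
inside a shattered region.

## Cohort statistics

`summarizeSample` counts breakpoints **one per junction**, not per
breakend — the two conventions differ by a factor of two and the
terminology in the field is loose, so the convention is fixed and
documented here.  Deletion sizes are spans of simple deletion-type
junctions.  `compareGroups` applies the two-sided Wilcoxon rank-sum
test (exact for combined sizes up to 20 without ties, normal
approximation with tie correction otherwise), matching the analysis used
for per-subclone breakpoint counts and deletion sizes.  The real
subclone values cannot be reproduced without the original 30x WGS data,
so the cohort level is validated by properties: exact agreement of the
Wilcoxon p with full enumeration for group sizes up to 5, and separation
of simulated 4-vs-4 wild-type/mutant cohorts at p < 0.05 in at least 80%
of 100 replicates.

## The balancer scoring system

The worm half models a self-fertilizing hermaphrodite carrying one
normal chromosome II and one balancer (`mIn1`-type inversion) homolog.
The default cross (`defaultCross()`) places the semi-dominant `dpy-25`
marker on the normal chromosome and the recessive `rol-1` plus
semi-dominant GFP insertion `mIs14` on the balancer, on either side of
the balanced interval.  A single crossover within the interval occurs
with probability `r` per meiosis and produces the two reciprocal
recombinant haplotypes; gametes are then `normal` and `balancer` with
probability `(1-r)/2` each and the recombinants with `r/2` each.  Progeny
arise by random union of two gametes, are weighted by per-genotype
viability and renormalized.  Double crossovers are ignored: they restore
the flanking-marker configuration and are invisible to this assay.

Phenotypes are modelled dosage-aware for semi-dominant markers
(heterozygous and homozygous carriers distinguishable), and a phenotype
class counts as recombinant only when *no* non-recombinant genotype maps
to it.  Under these rules every recombinant genotype is visible except
the reciprocal double heterozygote, which is phenotypically identical to
the parental heterozygote — one structural reason the assay
underestimates `2r`, alongside the reduced viability of aneuploid
recombinants, which the viability weights express.  With `r = 0` and
full viability the model returns the familiar 50% heterozygote / 25%
each homozygote split.

`estimateFrequency` reports `100 * k / n` rounded to two decimals with
an exact Clopper–Pearson 95% CI; `compareFrequencies` uses Fisher's
exact test when either group total is at most 1000 and the chi-squared
test without continuity correction otherwise (the cutoff mirrors the
source analyses; the continuity choice is ours).  `foldChange` reports
the ratio of the two *rounded* percentages under both integer
conventions — `round()` and `trunc()` — and flags when they disagree,
because both conventions demonstrably occur in published fold values
derived from these frequencies (27.33 printed as 27; 110.67 printed
as 110).

For two-marker map distances from a cis double-heterozygote self cross,
the visible recombinant classes are the two single-marker phenotypes,
with summed expectation `R = p - p^2/2`.  `mapDistance` offers the
`direct` estimator (`100 * R`, optionally detectability-corrected) and
the `self_cross_corrected` estimator `p = 1 - sqrt(1 - 2R)`, which
inverts the self-cross expectation exactly; which estimator the original
interval measurements used is not stated, so both are provided and
neither is asserted as canonical.  CIs propagate the exact binomial CI
on the recombinant count through the chosen estimator.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open throughout; BEDPE export follows the
  0-based standard.
* Copy-number binning rounds bin means half-to-even (R's `round`);
  per-base profiles (`binSize = 1`) are exact and match a brute-force
  per-base depth count on 100 kb genomes in the tests.
* Degenerate inputs reject early with diagnostics: empty genomes,
  intervals outside forward-retained sequence, unplaceable events after
  1000 retries, zero progeny totals, recombinant fractions above 0.5
  under the corrected estimator.
* Test and validation problem sizes were chosen to keep the full suite
  in the tens of seconds on one CPU: 100 clones for recovery, 100
  replicates of 4-vs-4 cohorts, broods of 10^5 (10^6 for the consistency
  check), 100-seed parameter-recovery runs.  All stochastic checks use
  fixed seeds.

## Known limitations

Single-chromosome bookkeeping (no translocations beyond fold-back
fusion); no germline/somatic subtraction; no read-level or
breakend-noise modelling; the classifier's thresholds are tuned to the
simulator's noise-free calls and would need re-tuning for real caller
output; the scoring system assumes hermaphrodite selfing (no male
cross-progeny) and a single crossover per interval.
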