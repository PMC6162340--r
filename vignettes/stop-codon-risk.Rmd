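---
title: "Premature stop-codon risk from somatic hypermutation: model, simulator and pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Premature stop-codon risk from somatic hypermutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmstop)
```

## The problem

Germinal-center (GC) B cells improve their antibodies by somatic
hypermutation (SHM): AID-initiated point mutations (and occasional indels)
accumulate in the immunoglobulin V genes at roughly $10^{-3}$ mutations per
nucleotide per division while cells proliferate in the GC dark zone (DZ).
Mutation is indifferent to consequence, so a predictable fraction of cells
ruins its own receptor by acquiring a premature stop codon (TAA/TAG/TGA
upstream of the natural end of the coding sequence) or a frameshifting
deletion. How large should that fraction be, and how do you measure it in
index-sorted subpopulations that were deliberately enriched during FACS
sorting? `shmstop` implements the full chain: an analytic per-division risk
model, a Monte-Carlo SHM simulator that cross-checks it, an alignment-based
stop-calling pipeline for Sanger and NGS amplicon reads, and the
gate-weighted frequency normalization for enrichment-sorted populations —
exercised end to end on synthetic data with recorded ground truth.

## The analytic model

### Codon-level risk

For each non-stop codon we enumerate all nine single-nucleotide
substitutions and count how many yield a stop. An "at-risk" codon (count 1)
has a $1/9$ chance that a uniformly placed random mutation in it creates a
stop — $1/3$ for hitting the critical position times $1/3$ for the critical
base; "doubly at-risk" codons have $2/9$. `codon_stop_risk()` performs the
enumeration and nothing is hard-coded: the count is whatever enumeration
yields (for the standard code, non-stop codons max out at 2).

### Region enrichment

SHM is not uniform: mutations concentrate in the CDRs and at AID hotspot
motifs. The model uses a crude but effective weighting — CDR positions are
5× more likely to be hit, motif positions 2×, and a motif inside a CDR
composes multiplicatively to 10× (configurable; the composition rule
matters little because enrichment itself barely moves the answer — with all
weights equal, $q$ changes from about 6.4% to 5.8% on the original gene).
The motif set defaults to RGYW and WRCY on the coding strand, the classic
AID hotspots; the motif definition is configurable because reasonable
people disagree on the exact set. Region fractions are normalized over
*all* weighted region sizes so they sum to one.

The template-level per-mutation stop probability is computed position-wise:

$$q = \frac{\sum_i w_i\,c_i/3}{\sum_i w_i}$$

where $w_i$ is the enrichment weight of nucleotide position $i$ and $c_i$
the number of its three substitutions that create a stop. This generalizes
the codon-level $1/9$–$2/9$ bookkeeping (the two agree exactly when a codon
lies within one region) and handles codons straddling region boundaries.

### From per-mutation to per-division and per-cohort

* `per_division_mutation_probability()`: $p_m = L\mu$, the linear
  treatment — 393 nt at $10^{-3}$ gives 0.393. (A Poisson treatment would
  give $1 - e^{-0.393} = 0.325$ for "at least one"; the model is linear
  throughout and the simulator's default oracle mode matches it.)
* `point_stop_probability()`: $p_{point} = q\,p_m$.
* `estimate_deletion_rate()`: deletions are rare and hard to measure
  directly, so the rate is inferred from published correlations of point
  mutation load and deletion frequency: a cell with $X$ mutations is
  assumed to have completed $X/p_m$ divisions (rounded to the nearest
  integer), so its per-division retention solves
  $\text{retention}^{divisions} = 1 - \text{deletion fraction}$. The three
  anchor points (20 mutations/40% deleted, 15/15%, 5/5%) average to a
  retention of 0.994, i.e. $p_{del} = 0.006$.
* `frameshift_stop_probability()`: indels of length not divisible by 3 —
  taken as $2/3$ of indels — shift the frame and are counted as
  stop-causing: $p_{fs} = p_{del}\cdot 2/3 = 0.004$.
* `combined_stop_probability()`: $p_{stop} = p_{point} + p_{fs}$.
* `snapshot_division_distribution()`: a cohort doubling every division and
  observed at an instant contains $2^k$-weighted proportions of cells with
  $k$ completed divisions: for at most two divisions, $1/7, 2/7, 4/7$
  (14%/29%/57%).
* `expected_stop_frequency()`:
  $E = \sum_k P(k)\,\bigl(1 - (1-p_{stop})^k\bigr)$.

### Rounding modes

The headline numbers of this chain are only reproducible when each
intermediate is rounded to its displayed precision (three decimals on
probabilities) before feeding the next step; `stop_expectation_chain()`
therefore offers `rounding = "printed"` (0.393 → 0.025 → 0.994 → 0.006 →
0.004 → 0.029 → 4.1%) and `rounding = "full"` (no intermediate rounding;
ends at 4.12%). Printed mode is the reference for reproducing the chain;
full precision is the default recommendation for new analyses. Two related
numerical notes: the chain multiplies $q = 0.064$ by $p_m = 0.393$ (a
transcription slip elsewhere quoting 39.9% is ignored — $6.4 \times 39.3$
still rounds to 2.5%), and the three-division snapshot percentages
7/14/27/54 correspond to rounding every component of $1/15, 2/15, 4/15,
8/15$ upward (they sum to 102); the package returns exact probabilities and
leaves display rounding to the caller.

```{r chain}
stop_expectation_chain(rounding = "printed")[c("p_m", "p_point", "retain_prob",
                                               "p_del", "p_fs", "p_stop",
                                               "expected_percent")]
```

## The SHM simulator

`simulate_cohort()` is the stochastic counterpart used to validate the
analytic chain and to drive the synthetic-data generator's mechanistic
mode. Per division a cell acquires point mutations (position sampled
proportionally to region weights, substituted base uniform over the three
alternatives) and, with probability $p_{del}$, one deletion with length
uniform over {1, 2, 3} nt (so exactly $1/3$ of deletions are in-frame,
matching the modelled frameshift fraction; the length distribution is
configurable, and deletions are placed so they never run past the 3' end).
Two per-division mutation-count modes exist because "a 39.3% chance of a
mutation per division" conflates a probability with an expected count:
`"bernoulli"` (at most one mutation, probability $L\mu$) matches the linear
analytic model exactly and is the default for oracle comparisons;
`"poisson"` (count $\sim$ Poisson($L\mu$)) is the more mechanistic choice.
Back-mutation is allowed (no infinite-sites assumption). Every simulated
cell carries a replayable event log, and its truth flags (premature stop by
substitution, frameshift) are computed from the tracked template anchors —
not from any alignment — so the stop-calling pipeline can be tested against
an independent reference.

## The stop-calling pipeline

Reads are aligned globally to the template with affine gap scoring (match
+5, mismatch −4, gap open 10, gap extend 0.5 — classic EMBOSS-needle
defaults), auto-reoriented if the reverse complement aligns better, and
excluded with a warning below a 50% identity floor. `call_stops()` then:

1. takes the net indel length from the alignment's gap columns; if it is
   not a multiple of 3 the read receives one `frameshift` call at the
   template codon of the first frame-breaking gap run;
2. translates the read codon-by-codon in the template-anchored forward
   frame and emits a `substitution_stop` call for every stop codon fully
   upstream of the first frame break and starting strictly before the
   template's final codon.

The *net* rule in step 1 is deliberate: with needle-style scoring, clusters
of adjacent substitutions can align as balanced deletion/insertion pairs,
and a naive "any frame-breaking gap" rule would miscall such reads as
frameshifted. Deciding by the net indel length makes the call a function of
the read sequence rather than of gap-placement ambiguity, and is what makes
the simulator round-trip exact.

For bulk NGS samples, reads are collapsed to unique sequences and filtered
by the per-sample abundance rule: with $n$ cells sorted, a sequence passes
only if it makes up **strictly more than** $(100/n)\%$ of reads. The strict
inequality follows the rule as stated; the boundary case (exactly one
cell's expected share) fails. The per-sample stop frequency is
read-weighted: stop-carrying passing reads over all passing reads, ×100.
Sanger mode calls one sequence per sorted cell with no abundance filter.

One property of the threshold worth knowing: a sequence private to a single
cell sits *at* the threshold in expectation regardless of sequencing depth
(its expected share is exactly $1/n$), so the passing set is dominated by
sequences shared by two or more cells. In real GCs clonal structure makes
shared sequences common; the synthetic generator mutates every cell
independently, so its NGS samples are a stress test of the filter rather
than a faithful clonal population, and the Sanger branch is the
quantitative route for per-cell truths.

## Enrichment-corrected population frequencies

Rare gates (BCR-low, specific cell-cycle stages) are deliberately
oversampled during index sorting, so naive pooling of sequenced cells is
biased. `rollup_frequency()` undoes this by weighting each leaf's stop
frequency with its **pre-enrichment** cytometry fraction, recursively:
$f(\text{node}) = \sum_{child} f(child)\cdot \text{fraction}(child)$. The
rollup is associative (level-by-level equals a flattened weighted sum) and,
when sequencing is proportional to the gate fractions, collapses to the
pooled estimate. Wilson 95% intervals are computed per leaf
(`prop.test`, no continuity correction) and propagated by the same weights
— an extension beyond the original mean±SEM-across-mice reporting, useful
for single synthetic experiments. Leaves with zero sequenced cells error by
default; `zero_policy = "renormalize"` drops them and rescales their
siblings, a choice the original procedure leaves open.

## The synthetic generator

`generate_scenario()` produces a complete, seed-deterministic synthetic
experiment: a random in-frame V-gene template (131 codons, codons drawn
uniformly from the 61 non-stop codons, three CDR blocks covering ~15% of
codons), a gated cell population, an index table with gate-conditional
Gaussian channels (sufficient for join/rollup testing; no cytometer physics
intended), per-gate Sanger FASTA, per-gate NGS FASTQ with negative-binomial
reads per cell (mean 50, dispersion 5), per-base errors ($10^{-3}$ by
default) and contaminant sequences injected at 0.3 cells' worth of reads —
below the strict threshold by construction.

Two generation modes exist because acceptance testing needs exact known
truths while model validation needs emergent ones: `"prescribed"` draws
each cell's stop status Bernoulli(leaf truth) and builds a matching
sequence (one stop-creating substitution 80% of the time, a 1–2 nt
frameshifting deletion 20% — the mechanism mix is a one-time calibration,
not an estimate), on top of stop-free background mutations;
`"mechanistic"` runs the SHM simulator per gate and lets truth emerge.

The preset scenarios use the magnitudes measured in index-sorted GCs as
generator truths (not as reproduction claims): `"wildtype"` has DZ 4.6% and
LZ 1.3% zone truths, realized as BCR-high/BCR-low leaf splits (fractions
0.84/0.16 with leaf truths 2.2%/17.2% in the DZ — chosen so the weighted
zone truth is exactly 4.6% — and 1.0%/2.875% in the LZ) with the rare
BCR-low leaves enriched 10×; `"bcl2"` mimics an apoptosis-inhibited setting
(DZ 11.6%, LZ 0.8%). What the generator does **not** emulate: clonal
lineage structure (cells mutate independently), PCR amplification bias,
read-pair assembly (reads are emitted pre-assembled), insertions, and
base-substitution spectra (no transition/transversion or strand bias). A
passing recovery test therefore shows the pipeline arithmetic and the
enrichment correction are right, not that every property of real amplicon
data is captured.

## Problem sizes and runtime choices

The validation suite uses cohorts of 20,000 cells for simulator/analytic
agreement (Monte-Carlo SE ≈ 0.14 percentage points, compared at 3 SE),
2,000 elevated-rate cells for the calling round trip, and ten seeds of the
wildtype scenario at 8,000 cells with 500 sequenced per zone for end-to-end
recovery; these sizes put the binomial uncertainty well below the effect
sizes being checked while keeping a full run to a couple of minutes on one
CPU.

## Known limitations

* The original gene's exact CDR boundaries and motif annotation are not
  public, so its specific $q = 6.4\%$ cannot be regenerated from sequence;
  the chain accepts $q$ as an input (default 0.064) and computes $q$ from
  any supplied template.
* The analytic model is linear and unconditioned: no selection between
  divisions, no insertion-specific rates, no mutation spectra.
* Codon indices reported for calls in reads with deletions are template
  anchors reconstructed through alignment and can shift by one codon in
  homopolymer runs; boolean calls are unaffected.
* The NGS threshold's singleton-suppression behaviour (above) is inherent
  to the published rule, not an implementation artifact.
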