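---
title: "Methods: simulating and assembling an HICF BAC physical map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and assembling an HICF BAC physical map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hicfmap)
```

## The problem

A BAC physical map orders the clones of a large-insert genomic library into
contigs by comparing restriction fingerprints: two clones whose inserts
overlap share restriction fragments, and the number of shared, size-matched
bands measures their overlap. High-information-content fingerprinting
(HICF) digests each clone with five enzymes — four six-cutters whose sticky
ends receive one of four fluorescent colors by single-base extension
labeling, plus the frequent blunt cutter HaeIII — and sizes the labeled
fragments on a capillary sequencer. The resulting color-resolved band sets
feed an FPC-style assembly: clones are clustered when the probability that
their shared bands are coincidental (the Sulston score) falls below a
cutoff, contig consensus-band (CB) maps are built, poorly fitting clones
are flagged questionable (Q), and an iterated schedule of increasingly
permissive merge rounds grows the map. In parallel, a three-dimensional
pooling of the library lets a PCR screen with marker-specific primers
assign genetic-map loci to clones in few reactions, anchoring contigs to
chromosomes.

`hicfmap` implements this pipeline end to end on simulated data with full
ground truth: every stage is a testable function, and the simulator's clone
coordinates make sensitivity, chimerism and ordering directly measurable.

## The synthetic data generator

The generator's defaults describe the study conditions all shipped
benchmarks run under:

* **Genome**: 27 Mb of uniform-random sequence in 12 chromosomes, each one
  linkage group, with `cm_per_mb = 2.7` (a ~1,200 cM map at full scale,
  uniform recombination — the map is used for positional labels, not for
  interference modeling). Two tandem-repeat families (5 kb unit x 30
  near-identical copies each, emulating rDNA arrays that produce "stacked"
  contigs) and two dispersed families (3 kb, 25 copies, 2% divergence) are
  implanted and annotated as ground truth.
* **Library**: 10 plates x 384 wells = 3,840 clones, insert size normal
  with mean 50 kb and sd 5 kb, uniform start positions, 20% empty wells.
  This reproduces the reference library's depth of ~5.7 genome equivalents
  (3,072 x 50 kb / 27 Mb = 5.7). The genome length is the one degree of
  freedom chosen to preserve that depth, which drives every downstream
  distribution (contig sizes, positives per marker), while keeping the
  published plate count, insert scale and empty fraction.
* **Fingerprinting**: exact in-silico digestion with the five-enzyme set,
  one band per labeled fragment end (a doubly labeled fragment yields two
  peaks, one per colored strand end), the 50-500 nt retention window,
  Gaussian sizing noise of sd 0.15 nt, and integerization at x30. Random
  50 kb inserts carry ~70 valid bands under these settings. A 20%
  fingerprint failure rate emulates poor-quality wet-lab profiles by
  subsampling a failed clone's bands so the minimum-band filter rejects it;
  without it a clean simulation would retain essentially every non-empty
  clone, which no real fingerprinting run achieves.
* **Markers**: 215 markers in the published class mix (117 RFLP / 96 SNP /
  2 SSR), spread evenly over linkage groups with jitter, each a 100-1,000
  bp PCR target; `round(0.2 * n)` of them amplify 2-3 duplicated loci
  planted at independent random positions. PCR positivity is interval
  containment, so duplicated loci amplify together while their surrounding
  fingerprints differ — sequence-level near-identity between copies would
  add nothing observable and is not simulated.

What the generator does **not** emulate: restriction-site cloning bias
(clone starts are uniform; a per-site weighting hook would go in
`sample_bac_library`), GC or compositional structure, partial digestion,
chromatogram-level artifacts, and — importantly — genomic regions absent
from the library. The last point is why a simulated screen anchors ~99% of
markers while real screens lose ~17% to representation holes, and why the
simulated positives-per-marker distribution sits slightly higher than a
real library's: validation against ground truth says nothing about library
representativeness.

## Band matching and the Sulston score

Bands match when they have the same color and integerized sizes within
tolerance 12 (= 0.4 nt x 30). Matching is one-to-one and greedy over
size-sorted lists, which attains the maximum bipartite matching for
interval tolerances; the test suite verifies this against an exhaustive
`igraph` maximum-matching oracle on all instance shapes up to 8 bands.

The coincidence probability of `M` shared bands between clones with
`n_low <= n_high` bands follows the classical approximation

    p1    = 1 - (1 - 2 tol / gellen)^n_high
    score = sum_{k=M}^{n_low} C(n_low, k) p1^k (1 - p1)^(n_low - k)

evaluated in log space (`sulston_score()`). Two conventions deserve
explanation:

* **Gel length per color.** `gellen = 13,500` is the band space of one
  color (450 nt window x 30). Because each color occupies its own band
  space — fingerprint processing conventionally applies per-color integer
  offsets of 15,000 so colors can never collide — the pairwise scorer uses
  an effective gel length of `gellen * n_colors = 54,000` with the total
  band counts. Using the per-color space with total counts would inflate
  `p1` about fourfold and make every cutoff effectively four orders looser.
* **What the formula models.** The binomial treats each band of the
  smaller clone as independently matched with probability `p1`; a band of
  the larger clone may serve several, and dependencies between bands are
  ignored. The Monte-Carlo oracle `simulate_band_coincidence()` therefore
  simulates exactly that event — a low-clone band counts as matched when
  any high-clone band lies within tolerance, with bands placed uniformly
  on the continuous interval `(0, gellen]` — and the acceptance suite
  checks agreement within 3 binomial standard errors at 10^6 replicates
  for every configuration up to 6 bands. A one-to-one matching oracle
  would disagree at second order (its `P(M = 2)` is about half the
  formula's term), and a discrete-uniform one at first order in the
  tolerance; neither deviation is an implementation error, both are part
  of the model the formula defines.

## Assembly protocol

`iterative_assembly()` runs the standard iterated build: single-linkage
clustering at the stringent initial cutoff 1e-45, breaking of contigs with
more than 5% Q-clones (DQer, re-clustering offenders at cutoffs tightened
by 1e-3 per step down to a 1e-99 floor), then for each cutoff of
1e-40 ... 1e-15 an End-to-End merge (contigs merge when at least `Match =
2` pairs of clones placed within `FromEnd = 50` consensus units of the
contig ends score at or below the cutoff), a Singles-to-End round
(singletons join the best-scoring contig end; ties break by lower score,
then lexicographic id; at most `best_contig = 100` candidate links are
evaluated per singleton), and a 10% DQer when needed. The `build_log`
records contig, singleton and Q counts after every step; contig counts are
non-increasing across merges and singleton counts across Singles-to-End
rounds by construction. Single-linkage clustering stands in for FPC's
incremental build: the protocol's observable contract — clusters at a
cutoff, Q fractions, the merge trajectory — is what the parameters specify,
not FPC's internal ordering heuristics.

### Consensus-band maps and clone ordering

The CB map is a lightweight consensus: member clones are ordered, then
placed one at a time; each clone's bands are tolerance-matched against the
accumulated consensus, unmatched bands extend the unit list, and the
matched fraction against the pre-existing consensus is recorded. A clone
matching less than `q_fit = 0.5` of its bands is Q-flagged (the
conventional FPC notion, which the protocol uses but never defines).
Chimeric clones bridging unrelated groups match about half or less and are
flagged, which is what the DQer exploits.

Ordering uses graph geodesics on the shared-band similarity `S = M /
min(n_i, n_j)`. The shared-band fraction of an overlapping pair falls
roughly linearly with genomic offset but saturates near zero beyond one
insert length, so a linear edge length `1 - S` would let shortest paths
jump barely-overlapping pairs and collapse the order; the odds-style
length `(1 - S) / S` diverges as `S` approaches the informative floor
(0.15), making a chain of strong overlaps always cheaper than one long
jump. Edges below the floor carry an additive penalty equal to the clone
count so they act only as a connectivity fallback. Two Dijkstra sweeps
locate the tiling's diameter endpoints (the farthest clone from an
arbitrary start is a true end); clones are ordered by the difference of
their distances from the two ends, which cancels most per-edge estimation
noise, and a few adjacent-transposition sweeps against the local context
polish small inversions. Orientation is canonicalized by clone id, making
runs reproducible.

Two kinds of clone pairs carry no ordering information in band space:
pairs whose true starts differ by less than the positional resolution, and
nested ("buried") pairs where one span contains the other. At ~70 bands
the shared-band fraction estimates a pairwise offset with a standard error
of a few kb, compounded along geodesic paths; we take 10% of the mean
insert (5 kb at desk scale) as the ~2-sigma discrimination limit. The
order-accuracy benchmark counts a contig as correctly ordered when every
clone pair beyond that resolution, excluding nested pairs, is concordant
with the genome after optimal reversal.

### Physical length

Contig length is consensus-unit count times a kb-per-band calibration,
defaulting to mean insert size over mean valid band count (50/70 ≈ 0.71 kb
per unit at desk scale; 139/102.1 ≈ 1.36 at the reference scale). The
protocol's own reports never state a conversion, so the calibration is a
parameter everywhere it is used.

## Pooled PCR screening

`build_pools()` replicates each 384-well plate into a 96-well plate with
the four clones of every 2x2 quadrant sharing a well, then forms plate
pools (384 clones), superpools of five plates, and per-plate row pools (12
wells x 4 = 48 clones) and column pools (8 x 4 = 32). Screening runs four
rounds: all superpools; the plate pools of positive superpools; the 12
column and 8 row pools of each positive plate; then every clone of each
candidate well (positive row x positive column) individually, which
resolves the 4-clone well ambiguity deterministically. With zero error
rates the decoded set provably equals the containment truth, and the
acceptance suite verifies this for 1,000 random markers against an
interval-tree oracle. Per-reaction false-positive/negative rates are
supported for robustness studies; no published value exists, so both
default to 0. A marker with no positive superpool is flagged a library
dropout.

## Anchoring, coincidence and conflicts

Markers link to every contig or singleton holding at least one of their
fingerprinted positives; positives without valid fingerprints are counted
separately (anchored/dropout/no-fingerprint accounting always sums to the
panel size). The PCR-vs-FPC coincidence of a marker is the fraction of its
fingerprinted positives in the modal map unit, computed for markers linked
to at most one contig — extra singleton links do not disqualify a marker,
otherwise the statistic would be identically 1 — with modal ties resolved
toward the larger unit, then lexicographic id. Contigs linked to two or
more markers are checked for conflicts by searching for an assignment of
one genetic position per marker (duplicated markers may carry two) that
puts all on one linkage group within an implied physical separation
(`cM / cm_per_mb`) no larger than the contig's estimated length; contigs
with no such assignment are reported with the reason.

## Evaluation metrics

Against simulator truth, `assembly_accuracy()` reports:

* **sensitivity** — the fraction of valid-clone pairs overlapping by at
  least half the shorter span that share a contig;
* **false-join rate** — among score edges at the final cutoff joining
  co-contiged clones, the fraction connecting clones with zero true
  overlap and no shared annotated repeat family. The rate is measured on
  joining edges because in any correctly assembled long contig most clone
  *pairs* are non-overlapping by transitivity; the edges are what the
  clustering actually asserted;
* **order accuracy** — the fraction of contigs of at least 4 clones
  correctly ordered up to reversal at the resolution above.

Under the default conditions (seeds 1, 7, 42) the pipeline reaches ~98-99%
sensitivity, 0% false joins and ~96-98% order accuracy over ~140 contigs,
with mean PCR/FPC coincidence above 0.97. The repeat-stack contigs produced
by the tandem arrays are the expected residual failure mode of the ordering
benchmark.

## Numerical choices and reproducibility

Binomial tails are summed in log space with the max-term factored out;
scores are handled as log10 throughout the assembly. The all-pairs scorer
computes shared-band counts for every pair but evaluates the binomial only
for pairs with at least 6 matches, keeping pairs with log10 score at or
below -8 (well below the loosest cutoff used anywhere). All ties —
contig ids, merge order, singleton assignment, modal units, orientation —
break deterministically by score then lexicographic id. Every stochastic
stage derives its own sub-seed from the single run seed, so a
configuration reproduces byte-identical outputs. Reported percentages and
averages round half away from zero at the conventional printed precision
(`round_half_up()`), since R's banker's rounding does not reproduce
printed summary tables.

Problem sizes used by the shipped checks: the desk-scale pipeline above
(3,840 clones, ~2,250 valid fingerprints, 215 markers) for the end-to-end
benchmarks; 10^6 Monte-Carlo replicates per band-count configuration for
the score oracle; 1,000 random markers for screen decoding; all instance
shapes to 8 bands for the matcher oracle.

## Known limitations

* Coordinates are 1-based closed (the Bioconductor convention used by the
  interval machinery); BED exports convert to 0-based half-open.
* The CB map is a consensus *list*, not a coordinate frame refined by
  simulated annealing; unit indices order along the contig but unit
  spacing is not calibrated within a contig.
* `min_bands` defaults to 50; 40 is the other convention in circulation
  for the same filter and is available via `band_calling_params()`. The
  discrepancy is inherited from the protocol description, not resolved.
* Uniform clone starts understate the stacking produced by
  restriction-biased libraries; the tandem-repeat families reproduce the
  phenomenon qualitatively but not its genome-wide rate.
* The simulator cannot exhibit library representation holes, so dropout
  rates, positives-per-marker distributions and the estimated effective
  coverage of a real screen are expected to differ in the directions
  discussed above.

## A minimal run

```{r example}
cfg <- sim_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "map_run")
res$summary
assembly_accuracy(res$map, res$library, res$genome)
```
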