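---
title: "Social networks from mixed-species flock observations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social networks from mixed-species flock observations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocknet)
```

## The problem

Winter mixed-species flocks of parids (Carolina chickadees, tufted titmice)
are sampled in the field as *gambit-of-the-group* scans: an observer locates
a flock, identifies every colour-banded bird in it, and moves on. Under the
gambit assumption every pair of birds recorded in the same flock is treated
as associated. A season of such scans yields a binary group-by-individual
(GBI) matrix — one row per flock observation, one column per bird — and the
scientific questions are about the *social structure* this matrix implies:

* How strongly do particular birds associate (edge weights)?
* Does the population divide into communities of birds that flock together
  more than expected (modularity)?
* Do conspecifics associate preferentially (species assortativity)?
* Are these patterns stronger than chance given how often each bird was
  seen and how large flocks were (permutation null models), and robust to
  sampling error (bootstrap)?

flocknet implements this whole chain as a tested, reproducible pipeline,
with a synthetic flock generator that supplies ground truth for every stage.

## From observations to a network

Birds sighted fewer than three times are dropped before any network is
built (`filter_individuals()`, `min_sightings = 3`): rarely seen birds are
likely transients and their association strengths are badly estimated. The
filter runs once, not iteratively — a flock reduced to a single member is
kept, because that sighting still informs the denominator of its member's
association index.

Edge weights are the Simple Ratio Index (SRI), the Jaccard index of two
birds' sighting records:

$$\mathrm{SRI}_{ab} = \frac{x}{x + y_a + y_b}$$

where $x$ counts flocks containing both birds and $y_a$, $y_b$ flocks
containing exactly one. Flocks containing neither bird are ignored (the pure
Jaccard denominator convention). SRI is 0 for birds never sighted together
and 1 for birds always sighted together. Pairs with an empty denominator
cannot occur after filtering; defensively they are reported as undefined and
weighted 0.

Network-level descriptors follow the standard unweighted conventions:
*density* is realized over possible associations ($2E / N(N-1)$, isolates
counted in the denominator); *components* are maximal mutually reachable
sets; *average path length* counts edges along shortest paths and averages
over reachable pairs only, so fragmented networks still report a finite
value — matching how the field's toolchain reports a finite mean distance
for disconnected networks.

## Community structure

Communities are found by the Girvan–Newman procedure: repeatedly remove the
edge with the highest edge betweenness (recomputed after every removal,
Brandes accumulation), record the partition into connected components at
every step, and return the partition maximising Newman's modularity

$$Q = \sum_i (e_{ii} - a_i^2)$$

computed from the weighted mixing matrix (fraction of total edge weight
within and between communities).

**Weighting convention.** The source analyses pass association weights to an
edge-betweenness community routine; such routines treat weights as path
*costs*, while modularity treats them as *strengths*. The package's default
reconciles the two the standard way: betweenness uses distances $d = 1/SRI$
(strong associations are short paths) while $Q$ uses raw SRI strengths.
`weighted = FALSE` binarizes both. Ties in betweenness are broken toward
the lexicographically first edge, making the algorithm fully deterministic.
Girvan–Newman maximises $Q$ only over the partitions in its own removal
sequence; on tiny graphs an exhaustive search sometimes finds a slightly
better partition (the test suite logs this as a diagnostic), which is an
inherent property of the algorithm, not a defect of the implementation.

Categorical assortativity uses the same mixing matrix:
$r = (\sum_i e_{ii} - \sum_i a_i b_i) / (1 - \sum_i a_i b_i)$, weighted by
SRI by default. It is $1$ for perfect assortment and negative for
disassortative mixing; it is undefined (an error) for a single label class.

## Inference

**Serial datastream permutation.** The null model for "is there more
community structure than chance?" must control for flock sizes and
individual sighting frequencies. The group-membership swap does exactly
that: find two flocks and two birds such that each bird is in exactly one
of the flocks, and exchange them — a checkerboard swap preserving all row
and column sums. Following the *serial method*, the package starts from the
empirical matrix, applies swaps sequentially (1000 by default), recomputes
the test statistic after every swap, and reports
$p = \#\{Q_{null} \ge Q_{emp}\}/n$. The raw $count/n$ form is the primary
p-value (matching the source's reporting convention); the
$(count+1)/(n+1)$ correction is always reported alongside. The chain has no
burn-in by construction — the serial method's null distribution *is* the
trajectory from the empirical matrix — but a `burn_in` argument exists for
users who prefer a better-mixed null. Because successive chain states are
correlated, the test's finite-sample calibration is approximate; the
validation suite measures the realized type-I error on exchangeable
synthetic populations and finds it within the binomial band around the
nominal level at the chain lengths used here.

**Node-label permutation.** Species assortativity is tested by shuffling
species labels over nodes (independent uniform permutations, label multiset
preserved) with the network fixed.

**Flock bootstrap and r_community.** Sampling error is quantified by
resampling flocks (GBI rows) with replacement, 1000 replicates by default.
The individual set is deliberately frozen to the empirical network — birds
are not re-filtered inside replicates even if their resampled sighting
count drops below threshold — so that replicate partitions stay comparable
node-for-node. Community robustness is summarised by `r_community`: run
community detection on every replicate, record for each pair of birds the
proportion of replicates assigning them to the same community (pairs absent
from a replicate are skipped for that replicate), and take the categorical
assortativity of this co-membership matrix with respect to the *empirical*
community labels. Replicates are compared by co-membership, never by label
identity, because community labels are arbitrary across replicates. A
partition reproduced by every replicate gives exactly 1; uninformative
replicates give values near 0.

## The synthetic generator

`simulate_flocks()` emulates one site-season of field sampling:

* a population of 30 birds by default (60/40 chickadee/titmouse), in 5
  planted communities of near-equal size;
* 250 flock observations with 2–6 core birds each (rounded normal, mean
  4.2, SD 1.8, truncated at 2 — emulating the published core-bird flock
  sizes);
* per-bird per-flock detection probability 0.85 (roughly the published
  banded fractions);
* conspecific joining bias 1.5.

The mechanism reflects how winter parid flocks actually form: a flock is a
cohesive subset of one community's birds. Between-community association is
carried by *floaters* — a configurable fraction of birds (30% by default)
whose home range overlaps one other community and who occasionally join its
flocks, with per-candidate recruitment weight `p_within` for home birds
versus `(1 - p_within)/(k - 1)` for visiting floaters. This is the design
decision that makes the emitted networks look like field association
networks: sparse between communities (density in the published 0.1–0.3
range), strong within-community edges, and a community structure that
edge-betweenness detection can actually recover. A naive alternative —
letting every recruit choose any bird in the population with
community-biased weights — floods the network with weak between-community
edges; with a season of observation effort virtually every pair is
co-sighted at least once, the Jaccard network approaches completeness, and
edge-betweenness community detection (which relies on few bridges funnelling
many shortest paths) degrades to noise. Field networks are not like that,
because between-community encounters are limited to specific neighbouring
birds, which is what the floater construction models.

At `p_within <= 1/k` the candidate pool widens to the whole population and
all community weights flatten: individuals become exchangeable, the regime
used to measure type-I error. Species and community assignments are
independent by default (communities are mixed-species); the
`species_coupling` knob (0–1) moves community composition toward
species-purity and is how strong species assortativity is induced.
`emulate_site()` packages three presets whose population sizes and species
splits equal the published per-site networks and whose cohesion, floater
rate, observation effort and coupling were set so that emitted networks
land near the published per-site profiles (sparse, fragmented and strongly
modular at the high-quality site; denser, connected and weakly modular at
the low-quality site).

What the generator does **not** model: spatial home ranges and distances,
satellite species, within-season community turnover, scan-level repeated
observation of the same flock, and observer misidentification. Passing
tests therefore demonstrate correctness of the machinery under a
fission-fusion-like sampling model, not fidelity to any particular field
dataset.

## Numerical choices

* Shortest-path tie detection uses an absolute tolerance of 1e-9 on summed
  distances; SRI weights are small rationals and genuine ties are exact to
  machine precision, far below this.
* Betweenness is cached per source node and recomputed after each removal
  only for sources in the component containing the removed edge (removals
  cannot affect shortest paths elsewhere), which keeps full Girvan–Newman
  runs inside 1000-iteration permutation chains tractable.
* Swap candidates are drawn by uniform rejection sampling; after 10 000
  rejections the valid swaps are enumerated exhaustively and one is drawn
  uniformly, so degenerate matrices (no valid swap) are detected exactly
  and flagged rather than looping forever.
* All resampling is driven by a single integer seed; per-stage child seeds
  are derived deterministically, so reports are byte-identical under a
  fixed seed.
* $Q$ is asserted to lie in $[-0.5, 1]$; an edgeless network has $Q = 0$
  with every node its own singleton community.

## Problem sizes used in validation

The packaged validation and acceptance checks run, per condition: 200
exchangeable datasets of 15 birds x 60 flocks with 1000-swap chains for
type-I error; 20 planted-structure datasets at the full study scale (30
birds, 250 flocks, `p_within = 0.85`) with 200-swap chains for power; 20
seeds for planted 3-community recovery; and bootstrap/null comparisons at
200–1000 replicates. These sizes give binomial standard errors of a few
percent on the reported rates while keeping a full run in the minutes
range on one core.

## A worked example

```{r example, eval = FALSE}
library(flocknet)

sim <- simulate_flocks(emulate_site("high", seed = 7))
gbi <- sim$observations |> build_gbi() |> filter_individuals(min_sightings = 3)
net <- build_flock_network(gbi, sim_attributes(sim))

glance(net)                      # density, components, path length
part <- girvan_newman(net)       # communities + modularity
serial_permutation_test(gbi, seed = 1)   # Q against the swap null
r_community(part, bootstrap_flocks(gbi, 1000, seed = 2))
species_assortativity(net)
```

## Known limitations

* Girvan–Newman is quadratic-ish in edges and meant for the study's scale
  (tens of nodes); hundreds of nodes will be slow inside permutation loops.
* The serial permutation p-value inherits the autocorrelation of its chain;
  with short chains it is conservative in the tails. Chain length, not the
  number of recorded values, controls mixing.
* Only disjoint, season-static communities are modelled; overlapping or
  shifting membership is out of scope.
* The association-matrix input path supports network-level statistics only;
  permutation and bootstrap inference require flock-level data, and the
  pipeline reports those stages as unavailable rather than approximating
  them.
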