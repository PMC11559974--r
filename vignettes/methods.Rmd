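---
title: "Methods: from larval dispersal to subpopulation structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from larval dispersal to subpopulation structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`larvanet` turns a Lagrangian simulation of planktonic larval dispersal
into a directed weighted transport network and delineates subpopulations
as flow communities of that network. This vignette is the package's own
account of the model, its parameters, the numerical choices, and the
places where the design was genuinely open.

## The dispersal model

Larvae are passive-horizontal, behaviorally-vertical point particles in
a gridded (or analytic) velocity field. Per 30-minute step, each active
particle is:

1. **Advected** with classical fourth-order Runge–Kutta, horizontal
   only. Velocities are interpolated in space and time at each stage and
   converted from m s⁻¹ to degrees using 110 574 m per degree latitude
   and 111 320·cos(φ) m per degree longitude, evaluated at the stage's
   own latitude.
2. **Diffused** with the first-order Milstein scheme: per axis with
   ΔW ~ N(0, dt), the displacement is √(2K)·ΔW + ½·(∂K/∂axis)·(ΔW² + dt).
   The deterministic half of the Milstein term is exactly the well-mixed
   drift correction, so spatially varying K does not spuriously
   accumulate particles where K is low. ∂K is exact when the fields are
   analytic and a centered difference over half a grid cell otherwise.
3. **Moved vertically** (preferred-depth mode): sinking at the
   particle's constant `wSink` plus swimming toward its preferred depth
   `zPref` at up to `wSwimMax`. If the swim leg would overshoot within
   the step, swimming covers only the remaining distance — the particle
   stops swimming at its preferred depth. Sinking continues regardless:
   the behavioral description stops only the swimming, so a particle
   parked at `zPref` still drifts down at `wSink` and swims back up next
   step, which keeps it hovering just below `zPref`. Depths are clamped
   to 0.1 m below the surface and 0.1 m above the local bathymetry; the
   0.1 m clearances are a numerical choice ("just below the surface /
   just above the bottom" fixes no number). Vertical advection and
   diffusion are deliberately absent: behavior is assumed to dominate
   them.

A particle whose new position falls in a land cell — the zero-velocity
region, since land cells carry identically zero velocity by field
construction — is **beached** and excluded from everything downstream.
The test is implemented as a land-mask lookup of the containing cell
rather than a literal speed == 0 comparison: the two coincide on
well-formed fields, but the mask form stays correct in degenerate
still-water configurations where every speed is zero and nothing should
beach. Particles crossing the lateral field extent are **exited** and
treated like beached ones.

### Behavioral traits

Traits are drawn once at seeding and stay constant for life, from
clipped normal distributions: draws outside `clipNsd` standard
deviations are redistributed uniformly within the band, which keeps the
distribution symmetric and mean-preserving. Defaults are bivalve-larva
estimates:

| parameter | default | clip | meaning |
|---|---|---|---|
| `wSink` | 0.6 ± 0.3 mm s⁻¹ | 1 SD | gravitational sinking speed |
| `wSwimMax` | 2.4 ± 2.0 mm s⁻¹ | 1 SD | maximum vertical swimming speed |
| `zPref` | local MLD ± 5 m | 2 SD | preferred depth |

The depth-preference construction was an open choice (the upstream
description centers it "around the local MLD" without a distribution):
we use a normal centered on the mixed-layer depth at the spawn location
with a 5 m SD, clipped at 2 SD, and initialize the particle at `zPref`.
Both the SD and the initialization are configurable.

### Seeding, PLD, settlement

Particles are seeded quasi-uniformly over water: each water grid cell
receives Poisson(density × cell area) particles at uniform positions,
so the expected count is density × water area. The default density is
1.3 particles km⁻²; the examples and tests use much sparser cohorts
(see *Problem sizes*). Spawning is simultaneous on day 258
(September 15, the modal autumn spawn); transport runs for a fixed
45-day maximum pelagic larval duration (PLD) with daily output.

Settlement is post-processing on the stored trajectories:

* **FD / PD**: every particle still active at day 45 settles in the
  cell of its final position.
* **SH**: only particles spawned over suitable habitat are candidates;
  each settles at its *first* daily output within the competency window
  at which it is over suitable habitat, otherwise it is nonviable. The
  "7-day window before the maximum PLD" is discretized as checks at the
  daily outputs 39, 40, …, 45 (seven checks).

PD and SH are resolved from one shared simulation, so stochastic
transport cannot produce spurious differences between the two cases. A
consequence of the exclusion rules, worth stating explicitly: a
particle that sits over habitat on day 40 but beaches on day 42 does
*not* settle — beached particles are omitted from post-processing
entirely, so only end-of-run active particles can settle in any case.
The alternative reading (settlement freezes the particle before it can
beach) was considered and rejected as inconsistent with the
beached-are-deleted rule.

### Randomness

One integer seed drives a cohort. Seeding and transport use a single
seeded generator with a fixed vectorized draw order (positions, then
traits, then per-step Wiener increments), bracketed so library calls do
not perturb the caller's RNG state. Runs are bit-reproducible for a
fixed seed and configuration; with zero diffusivity they are fully
deterministic. Changing the particle count reshuffles the stream — a
deliberate simplification over per-particle counter streams, accepted
for vectorized performance.

## The hexagonal geodesic grid

Trajectories are reduced to spawn-bin → settlement-bin transitions on a
global icosahedral–hexagonal grid built in the package: a triangular
(Eisenstein-integer) lattice is laid over each icosahedron face in the
face-edge basis, scaled by c_r = (2 + 2τ)(2 + τ)^r with τ = e^{iπ/3},
so |c_r|² = 12·7^r. Cells are the Voronoi cells of the lattice;
resolution r therefore carries exactly 2 + 120·7^r cells globally in an
aperture-7 hierarchy, with exactly twelve pentagons at the icosahedron
vertices (face corners are always lattice points). At resolution 5 the
mean cell area is 4πR²/2 016 842 ≈ 253 km². Points are assigned by
gnomonic projection onto the nearest face plus hexagonal rounding;
cell centers that land on a foreign face are canonically re-indexed in
that face's frame, so every physical cell has a single id. Adjacency is
resolved numerically by probing a ring of points one center-spacing
from the cell center (36 directions), which yields six neighbors for
hexagons and five for pentagons and is symmetrized where used. Known
distortion: cells straddling icosahedron edges can be split between the
two face lattices; the package's regional domains sit in face interiors
where this never triggers.

## Flow map, pruning, transport network

The flow map keeps one (spawn cell, settle cell) pair per settled
particle and deliberately forgets intermediate bins. Pairs whose settle
cell no surviving particle spawned in are deleted, *iterated to a fixed
point*: deleting pairs can empty a spawn cell, which invalidates
further pairs, so a single pass cannot guarantee that every node keeps
out-links. The fixed-point reading is the package's resolution of an
ambiguity (the deletion rule is stated once, but only iteration
actually delivers "no nodes without out-links"); pruning is idempotent
and its output satisfies settle-set ⊆ spawn-set. Counts are stored as
integers and normalized on demand into transition probabilities, so
each node's out-weights sum to 1 within 10⁻¹² and the network
approximates a Markov chain. Nodes appear only if at least one retained
particle spawned there.

## Map-equation community detection

Communities minimize the two-level map equation. Node visit rates p are
the stationary distribution of a walk that follows links with
probability 1 − τ and teleports with probability τ = 0.15 to nodes in
proportion to their total in-link weight ("smart" teleportation),
solved by power iteration to 10⁻¹²; a vanishing uniform floor
(10⁻¹² of the largest in-weight) keeps visit rates strictly positive on
nodes that are never settled into. Teleportation is *unrecorded*: link
flows are the teleportation-free f_ij = p_i·w_ij, so teleport moves are
never encoded and Σf = Σp = 1. Pruning makes teleportation unnecessary
for well-definedness; it is kept (configurable, τ = 0 allowed) for
ergodicity on reducible networks.

The codelength of a partition M is

L(M) = q·H(Q) + Σ_m p̃_m·H(P_m),

with entropies in bits, 0·log 0 := 0, module-enter flows q_m, module
codebook rates p̃_m = Σ_{i∈m} p_i + exit_m, and self-loops never
contributing to enter/exit. **Markov time** t scales every enter and
exit flow linearly inside both terms, leaving node rates and
intra-module flows untouched: at t = 1 this is the standard two-level
map equation (cross-checked in the tests against an independently
written implementation to 10⁻⁹ bits), and larger t makes boundary
crossings costlier, so minimization returns coarser communities. The
default t = 2 matches the scale at which the method is normally run on
regional transport networks; the fixture tests verify the qualitative
ordering (community count non-increasing over t = 1, 2, 3). The exact
internal scaling of reference implementations is not documented; this
linear scaling is the package's own, stated rather than assumed
equivalent.

The optimizer is a seeded greedy search: random node order; repeated
single-node moves to the neighboring module with the best strict
codelength decrease (> 10⁻¹² bits, candidates scanned in ascending
module id for determinism); aggregation of modules into super-nodes and
recursion; node-level fine-tuning; all restarted `outerLoops` times
keeping the best, and never returning anything worse than the
single-module partition. An ensemble over seeds 0…n−1 (default 100,
with 20 outer loops, mirroring standard practice) returns the
minimum-codelength partition (ties to the lowest seed) plus the full
ensemble for boundary-persistence analysis. For networks of ≤ 10 nodes,
`bruteForcePartition()` enumerates all set partitions and is used as
the optimizer's oracle in the tests (19/20 random 8-node instances must
match to 10⁻¹² bits; greedy single-node moves can in principle require
a two-node swap to escape, so exact equality in all 20 is not
guaranteed).

## Community quality

With spawn/settle counts aggregated by community: coherence
ρ_c = retained spawners / spawners, fortress F_c = internal settlers /
settlers. Both are exact integer-count ratios; a community receiving no
settlers reports fortress as missing (with a warning) rather than 0,
distinguishing "no inflow" from "external inflow only". The
community-level connectivity matrix divides the same integer counts by
the same row totals, so its diagonal equals ρ bit-exactly.

The **mixing parameter** is specified upstream only by its properties
(range [0, 1]; unity iff every bin spreads equally to every bin of its
community). We operationalize it as the mean over member bins of the
base-2 entropy of the bin's within-community transition distribution
(renormalized over members, self-loops included), divided by log₂ n_c.
Singletons return 1 by convention and bins with no internal flow
contribute 0; both conventions are included in global averages.

**Classification** tests source/sink first: sink if ρ − F ≥ δ, source
if F − ρ ≥ δ (δ = 0.05; the ≥ matters — a printed difference of exactly
0.05 is a source/sink call); otherwise impermeable if min(ρ, F) ≥ h,
permeable if max(ρ, F) < h (h = 0.95, with ≥ on the impermeable side so
a ratio printed as 0.95 qualifies), and "unclassified" for the residual
straddle (one ratio ≥ h, the other < h, difference < δ) rather than
forcing a label. Threshold comparisons carry a 10⁻⁹ guard so that
two-decimal inputs are not misclassified by floating-point round-off
(0.98 − 0.93 < 0.05 in doubles). Global metrics are bin-count-weighted
means over communities.

**Boundary persistence**: a bin is a boundary bin in one partition if
any grid neighbor belongs to a different community; its persistence is
the fraction of ensemble partitions in which it is a boundary bin.
Neighbors outside the network are ignored.

## The synthetic fixture

The generator supplies fields with the structure the pipeline assumes,
not ocean dynamics. `makeDoubleGyre()` builds a 600 km × 600 km basin
(10 km cells, two-cell land ring) holding two counter-rotating gyres
derived from a streamfunction (hence non-divergent), peak speed
0.15 m s⁻¹, an exponential vertical shear profile e^{−z/50 m} so
near-surface and mixed-layer transport differ appreciably, a ±25%
seasonal modulation anchored at mid-months and interpolated
piecewise-linearly (cyclically across December–January), and constant
horizontal diffusivity 20 m² s⁻¹. `makeMldAndBathy()` adds a
bathymetric bowl (80–300 m) and an MLD field (mean 40 m, ±15 m seasonal
cycle, gentle west–east gradient), refusing configurations where the
MLD would exceed the bathymetry. `makeHabitatPatches()` grows disjoint
contiguous habitat patches by seeded random accretion from
farthest-point-sampled seed cells. Analytic and gridded backends share
one interpolation contract (bilinear horizontal, linear vertical,
piecewise-linear cyclic time; velocity forced to zero over land cells
in both), so kernel tests can use exact fields while the pipeline
exercises the gridded path.

What the fixture does *not* emulate — and hence what passing tests do
not show about real data: mesoscale eddies and realistic shear
structure, tides, interannual variability, temperature-dependent PLD,
mortality, spawn-time variation, and coastline complexity beyond a
rectangular land ring. The fixture validates the machinery
(conservation identities, settlement semantics, detection behavior),
not any oceanographic conclusion.

## Problem sizes

The reference configuration (1.3 particles km⁻², grid resolution 5,
100 detection seeds × 20 outer loops) reflects production use. The
package's examples, tests and acceptance script run the same code at
reduced sizes chosen to finish in minutes: cohorts of 1.5–3 thousand
particles, grid resolution 4 (≈1770 km² cells, ~180 network nodes on
the fixture), detection ensembles of 10 seeds × 5 outer loops, and
Monte-Carlo kernel checks at n = 10⁵. Statistical assertions are posed
within 3 standard errors at those sizes.

## Known limitations

* The greedy optimizer is a heuristic; optimality is verified only
  against small-network enumeration and planted structure.
* The grid's icosahedron-edge cells can be split between face lattices;
  irrelevant for regional domains, but a global-domain user should
  treat cell areas near those edges as approximate.
* Gridded-field I/O uses a plain-text container with CF-like coordinate
  variables; it is meant for fixtures and interchange at test scale,
  not for multi-gigabyte model output.
* The mixing parameter is one defensible operationalization of a
  verbally specified quantity; comparisons across studies should check
  definitions.
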