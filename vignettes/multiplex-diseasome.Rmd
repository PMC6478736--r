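---
title: "Methods: multiplex disease networks, map-equation communities and cohesion testing"
author: "mxdiseasome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplex disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models, their
assumptions, the tunable parameters, and the numerical and design choices
made where the problem left the design open. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## 1. From bipartite associations to a multiplex

Each layer starts from a bipartite table of (disease, item) associations,
where the item family is genes for the genotype layer and symptoms for the
phenotype layer. Identifiers are whitespace-trimmed and case-folded at
load; merged knowledge bases disagree on casing, and silent near-duplicate
diseases would otherwise fragment the projection. `projectLayer()` links
two diseases iff they share at least one item and records the shared-item
count per edge. Following the analysis design, **all downstream analyses
treat layers as unweighted**; the shared count is reporting metadata only.

`assembleMultiplex()` hosts every layer on one disease universe: the union
of nodes with degree ≥ 1 in at least one layer. Diseases isolated in a
single layer stay as isolated nodes of that layer (this is what lets one
layer's information "rescue" the other), whereas diseases isolated in all
layers carry no information and are removed, with the count reported.
When source vocabularies differ, `applyCrosswalk()` maps source disease
identifiers to unified identifiers (many-to-one allowed; item sets of
merged sources are united), optionally dropping unmapped diseases.

## 2. The multilayer walker and its flow

Community detection runs on *state nodes* (disease, layer). From state
(u, α) the walker:

* with probability 1 − r follows a uniformly chosen edge of u **within**
  layer α;
* with probability r (the **relax rate**) chooses uniformly among *all*
  edges of u across all layers and lands in the chosen edge's layer.

A state whose disease has no edge in its own layer always relaxes —
otherwise its transition row would be undefined. With a single layer the
two cases coincide and r is irrelevant, so single-layer detection is the
one-layer special case of the same code path.

The default `relaxRate = 0.45` balances within-layer exploration against
cross-layer mixing; values near 0.5 are the standard operating point for
relax-rate multiplex walkers, and a `relaxRate` argument exposes the dial.

**Teleportation.** The stationary distribution is computed by power
iteration on τ·uniform + (1 − τ)·P with τ = 0.15 over state nodes.
Teleportation exists purely to make the solve well-posed on disconnected
or bipartite-ish structures; it is **unrecorded**: the flows entering the
map equation are π·P (the walk's own steps), renormalized, and a state's
recorded visit rate is its incoming recorded flow. With one connected
layer and τ = 0 the visit rates are exactly degree-proportional, which the
tests assert, and the dense-eigenvector oracle bounds the power-iteration
error below 1e−8 on small instances.

Numerical settings: L1 convergence tolerance 1e−12, iteration cap 10,000,
non-convergence is an error reporting the residual, never a silent
fallback.

## 3. The two-level map equation and the optimizer

For a partition M of state nodes, with module exit flows qᵢ, module
visit-rate sums, and state visit rates p, the description length is

L(M) = q↷ H(Q) + Σᵢ p↻ⁱ H(Pⁱ),

computed in bits from the recorded flows. Only the flat two-level code is
implemented: the analysis this package supports reports flat communities,
and a hierarchical code would change the object being optimized.

The optimizer is deliberately simple and fully specified:

* every state starts in its own module;
* sweeps of best single-node moves (to a neighbor's module or to a fresh
  empty module) run until no move lowers L;
* greedy module-pair merges follow, and the two phases alternate until
  neither improves;
* the whole search restarts from `nTrials` (default 10) random node
  orders, keeping the lowest-L partition;
* ties between candidate moves break toward the lowest module id, making
  runs deterministic given (input, seed, nTrials, relaxRate);
* final community ids are relabelled by decreasing aggregate flow, so
  community 1 is always the highest-flow community.

Improvement thresholds use an epsilon of 1e−12 to avoid chasing rounding
noise. The test suite checks the optimizer against exhaustive partition
enumeration (all connected labelled graphs on 3–5 nodes, seeded random
graphs on 6–8 nodes, and small two-layer multiplexes), and checks that the
detected L never exceeds the all-in-one-module or all-singletons
partitions. Greedy search carries no optimality guarantee at scale; on
hundreds of state nodes the restarts are the only hedge, which is the main
reason community counts on real data should be read as approximate.

**Bridge diseases** are diseases whose states in different layers carry
different community ids — the multiplex-specific output that a flattened
or single-layer analysis cannot produce.

## 4. Null models

Degree-preserving randomization is double-edge-swap rewiring (igraph's
`keeping_degseq`, 10·|E| swap attempts per replicate by default) rejecting
self-loops and parallel edges; the degree multiset is asserted unchanged
on every call. It underlies three analyses:

* **edge-overlap significance**: observed overlapping links vs the null
  distribution over per-layer independent rewirings (both layers rewired
  per replicate — the symmetric reading of per-layer randomization);
  Shapiro–Wilk on the null sample is reported descriptively and never
  gates the z-score;
* **edge-wise gene similarity**: mean gene-overlap Jaccard over a
  network's edges vs degree-matched ensembles, per layer and for the
  overlap network; pairs lacking gene sets are skipped and counted rather
  than scored 0;
* **partition correspondence**: the mean Jaccard of disease overlap over
  all cross-partition community pairs ("all pairs" taken literally, not
  best-match pairs), z-scored against partitions re-detected on rewired
  layers. With few replicates this null can be constant (rewired dense
  layers often collapse to one module); the z is then reported undefined
  rather than forced.

`swapFactor = 0` gives the identity "randomization", kept as a degenerate
control: the null concentrates on the observed value and z is undefined.

## 5. The four similarity metrics and their conventions

* **Relative risk** RR = (C_AB/N)/(P_A·P_B/N²). RR is scale-invariant in
  the counts. Pairs where either disease lacks a prevalence entry are
  *missing*, never 0 — unscorable and dissimilar are different facts.
  Pairs of covered diseases absent from the co-occurrence table have
  C = 0 and RR = 0. Log-RR uses base 10, matching order-of-magnitude
  reporting; rank-based tests downstream are unaffected by the log.
* **Gene-overlap Jaccard**; both-empty input is undefined and returns NA.
* **Ancestor-based gene-set similarity.** With T(g) the ancestor-closed
  annotation profile of gene g and w_S(t) the fraction of S's genes whose
  profile contains t: sim(g, S) = Σ_{t∈T(g)} w_S(t)/|T(g)|, symmetrized
  over both directions. The published description of this measure is a
  sketch ("rank each term by the genes annotated by its ancestors"), so
  this concrete reading is isolated behind one function and can be
  swapped. It equals 1 for sets with identical annotation profiles. Note
  one subtlety the tests document: *adding* a gene of B to A is **not**
  guaranteed to raise S(A, B) — both directional means are convex
  combinations, so the provable bound is
  S(A∪{b}, B) ≥ min(S(A, B), S({b}, B)).
  Evidence-code filtering (EXP, IPI, IDA, IMP, IGI, IEP, ISS, ISA, ISM,
  ISO) happens at load; objects carrying other codes are rejected loudly
  so that unfiltered input cannot slip through.
* **Semantic similarity** is a lookup in a precomputed symmetric matrix in
  [0, 1]; 0.3 and 0.6 are the interpretive cutoffs (uninformative /
  informative / significantly functionally similar). Coverage is partial
  by nature; missing pairs are flagged and excluded from statistics.

## 6. Cohesion testing

Communities of at least `minSize = 10` diseases are assessed; a
community's disease set is the union over layers, and a bridge disease
contributes pairs to both of its communities. The test is a one-sided
Wilcoxon–Mann–Whitney: community pairwise values against the
**background of all disease pairs over the retained communities** (within-
and cross-community pooled, minus the pairs of the community under test).
The pooled definition matters: a background made only of *other
communities' within-pairs* cannot detect anything when all communities are
cohesive — every community would be compared against equals — so the
all-pairs reading is the one consistent with the method's purpose; the
community under test is excluded to avoid self-contamination.

Conventions: exact enumeration when the smaller sample has ≤ 10 tie-free
values (determinism at small n), normal approximation with continuity
correction otherwise; significance at raw P < 0.01 (−log₁₀ P > 2);
no multiple-testing correction enters the headline counts, matching the
fixed-threshold radar-plot convention, but a Benjamini–Hochberg column is
emitted for transparency. Fully tied or unscorable inputs report P = 1
with a flag. The suite calibrates the test's type-I error at 0.01 under
shuffled labels (1000 repeats, binomial 95% bounds).

Per-process z-scores (`processSimilarityZ`) compare a disease gene set's
similarity to a process term's annotated gene set against 1000 equally
sized uniform draws from the gene universe; a zero-variance null reports
an undefined z with a flag.

## 7. What the synthetic generator emulates — and what it does not

`generateDiseasome()` plants K groups of diseases sharing group-specific
gene and symptom pools, which is precisely the statistical structure the
pipeline exploits: group-mates share items (dense within-group projection
edges), cross-group edges arise only from noise, comorbidity and semantic
similarity are elevated within groups, and annotations are group-biased on
a small is-a tree.

Defaults (the study conditions of the test suite and acceptance script):
4 groups × 25 diseases; pools of 40 genes and 40 symptoms per group; 4
gene and 5 symptom draws per disease; background rate ε = 0.002 per
out-of-pool item; symptom contamination ρ = 0.05 per draw; within/between
relative-risk targets 5/1 in a population of 1e5 with prevalences
200–2000; ontology depth 3, branching 3, 2 terms per gene; semantic block
means 0.6/0.2 with sd 0.1. On ε: the background count is
Binomial(#outside items, ε), so ε must be read per outside item; 0.002
yields ≈ 0.2 spurious items per disease — a few percent of a disease's
records, the contamination level one expects of curated association
databases — while keeping the defaults in the strong-signal regime that
the recovery analyses presuppose. Comorbidity counts invert the RR
formula (C = round(RR·P_A·P_B/N), clipped to C ≤ min(P_A, P_B)), making
RR a directly controllable effect size whose empirical value converges to
the target as N grows. The ontology is a tree by default for analytic
tractability; general DAGs are supported by the same structures.
`alignedLayers = FALSE` rotates the symptom-group assignment by half a
group so each symptom community straddles two gene groups — the regime
that produces bridge diseases and discordant single-layer partitions.

What it does **not** emulate: heavy-tailed degree distributions and hub
diseases of real diseasomes, correlated pool sizes, partial metric
coverage (real semantic matrices cover ~87% of diseases; the synthetic one
covers all), identifier noise, or patient-level comorbidity sampling.
Passing tests therefore certify the machinery — projection, flow,
optimization, null models, statistics — under controlled assumptions, not
performance on any real diseasome.

## 8. Problem sizes and determinism

Tests and the acceptance script run at deliberately desk-scale sizes
chosen as the package's own benchmark conditions: 100-disease multiplexes
(200 state nodes) for pipeline runs, 3–8-node graphs for exhaustive
oracles, 2000 rewiring replicates for the overlap null, 200 for the
gene-similarity ensembles, 10 optimizer restarts, 20 seeds per noise level
for the recovery sweep, 1000 repeats for the type-I calibration. Every
stochastic step takes an explicit integer seed; identical (input, seed,
settings) reproduce bit-identical outputs, which the suite asserts.

## 9. Known limitations

* Two-level map equation only; no hierarchical or overlapping-community
  variants (bridges come from the state-node structure, not from an
  overlapping objective).
* Greedy optimization is exact only where exhaustive checks run; on real
  diseasome-scale inputs, community counts and bridge counts are
  approximate and restart-dependent by nature.
* Unweighted layers throughout; shared counts are carried but unused.
* The ancestor-based similarity is one concrete reading of a sketched
  measure and is intentionally swappable.
* Aggregate comorbidity only; no record-level processing.
* The identifier crosswalk is a lookup, not a semantic integrator: curing
  vocabulary overlap (synonym resolution, ontology mapping) is upstream
  work this package consumes as a table.
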