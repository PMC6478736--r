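# mxdiseasome

Multiplex disease networks from shared genes and symptoms: layer
construction, relax-rate map-equation community detection, and
null-model-based similarity analysis, in R (S4 / Bioconductor style).

## The problem

Disease classifications built from clinical observation alone ignore
molecular aetiology, and gene-centric views ignore clinical presentation.
A way to reconcile the two is to represent diseases twice over the same
disease universe:

* a **genotype layer** — diseases linked if they share at least one
  associated gene;
* a **phenotype layer** — diseases linked if they share at least one
  symptom;

and to treat the pair as a **multiplex network**. Both layers come from
bipartite association tables (disease–gene, disease–symptom) projected
onto the disease component; a disease with no link in one layer stays as
an isolated node of that layer, and diseases isolated in *every* layer are
removed. The package is aimed at systems-biology and network-medicine
researchers who want to build such multiplexes from their own association
tables, find flow-based disease communities that fuse both kinds of
evidence, and quantify how cohesive those communities are.

## The core methods

**Cross-layer overlap.** Disease pairs connected in both layers
("overlapping links") are counted and compared with a null ensemble in
which each layer is rewired by degree-preserving double-edge swaps; the
package reports the null mean ± sd, the z-score and a descriptive
Shapiro–Wilk normality P of the null sample.

**Multiplex communities.** A random walker explores state nodes
(disease, layer). From state (u, α) it follows, with probability 1 − r, a
uniformly chosen edge of u inside layer α; with probability r (the **relax
rate**, default 0.45) it relaxes the layer constraint and picks among all
of u's edges across layers. Communities are the partition of state nodes
minimizing the two-level **map equation**

L(M) = q↷ H(Q) + Σᵢ p↻ⁱ H(Pⁱ)  [bits],

the expected per-step description length of the walk under a two-level
codebook. The optimizer is a greedy single-node-move search with
module-merge passes, restarted over random node orders, and is checked in
the test suite against exhaustive partition enumeration on small graphs.
A disease whose genotype-layer and phenotype-layer states land in
different communities is a **bridge disease**.

**Four similarity metrics.** For pairs of diseases inside a community:
relative-risk comorbidity RR = (C_AB/N)/(P_A·P_B/N²), gene-overlap
Jaccard J = |g_A ∩ g_B|/|g_A ∪ g_B|, an ontology ancestor-based gene-set
similarity (terms weighted by the fraction of the other set's genes
annotated by each term's descendants-closure), and a precomputed
phenotype semantic-similarity matrix (0.3/0.6 interpretive cutoffs).
Each community of ≥ 10 diseases is tested (one-sided rank test) against
the background of all disease pairs across the retained communities.

**Planted-structure generator.** `generateDiseasome()` emits a fully
synthetic tripartite dataset — group-structured gene/symptom pools with
background noise and contamination, comorbidity counts with configurable
within/between-group relative risk, a small is-a term tree with
group-biased annotations, and a block-elevated semantic matrix — so every
stage is testable without downloads. `recoveryScore()` scores detected
communities against the planted labels by normalized mutual information.

## Worked example

```r
library(mxdiseasome)

ds  <- generateDiseasome(syntheticConfig(seed = 1))   # 4 groups x 25 diseases
mx  <- syntheticMultiplex(ds)
mx
#> MultiplexNetwork: 100 diseases, 2 layers
#>   genotype: 487 edges
#>   phenotype: 717 edges

overlapSignificance(mx, nReps = 500, seed = 1)
#> OverlapResult: observed 196 overlapping edges
#>   null (500 degree-preserving reps): 72.55 +/- 7.23, z = 17.08
#>   null normality (Shapiro-Wilk) P = 0.145 [descriptive]

part <- detectCommunities(mx, relaxRate = 0.45, seed = 1, nTrials = 10)
part
#> MultiplexPartition: 4 communities over 200 state nodes (relax rate 0.45)
#>   community sizes (diseases): 25 - 25; codelength 6.6962 bits

recoveryScore(ds@labels, part)
#> [1] 1

assessCohesion(part, geneSets = geneSets(ds@genes),
               comorbidity = ds@comorbidity, dag = ds@dag,
               semantic = ds@semantic, minSize = 10)
#> CohesionReport: 4 communities (size >= 10), alpha = 0.01
#>   rr: 4/4 significant
#>   geneOverlap: 4/4 significant
#>   goBP: 4/4 significant
#>   semantic: 4/4 significant
#>   on all 4 metrics: 4/4; on >= 2 metrics: 4/4
```

The overlap z-score of 17 says the two layers share far more edges than
degree-matched chance; the four communities recovered at relax rate 0.45
coincide exactly with the planted groups (NMI = 1), and every community is
significantly cohesive on all four similarity measures against the pooled
pair background.

Real association tables enter through `readBipartite()` (2-column TSV),
`readCrosswalk()`/`applyCrosswalk()` (identifier unification),
`readComorbidity()`, `readAnnotations()` (evidence-code filtered) and
`readSemanticMatrix()`; multiplexes round-trip through
`writeMultiplex()`/`readMultiplex()` (3- or 4-column multilayer edge
lists).

## Vignette

`vignettes/multiplex-diseasome.Rmd` documents the flow model, the map
equation and optimizer, the statistical conventions of the cohesion test,
what the synthetic generator does and does not emulate, and the package's
numerical choices and limitations.
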