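Package: mxdiseasome
Title: Multiplex Disease Networks from Shared Genes and Symptoms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds genotype- and phenotype-based disease-disease network
    layers from bipartite disease-gene and disease-symptom associations,
    assembles them into a multiplex network over one disease universe, and
    detects flow-based disease communities by minimizing the two-level map
    equation for a multilayer random walker with a relax rate. Cross-layer
    edge overlap and edge-wise gene similarity are assessed against
    degree-preserving null models. Intra-community cohesion is scored with
    four disease-pair similarity measures (relative-risk comorbidity,
    gene-overlap Jaccard, ontology ancestor-based gene-set similarity, and a
    precomputed phenotype semantic-similarity matrix) against the pooled
    community background. A planted-structure generator produces synthetic
    tripartite data with aligned or misaligned layers so that every pipeline
    stage can be exercised without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Matrix, igraph
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Clustering, SystemsBiology
RoxygenNote: 7.3.3
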