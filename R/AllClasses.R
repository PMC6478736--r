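# S4 classes for the disease multiplex pipeline.

#' BipartiteAssociations: disease-item association records
#'
#' Holds deduplicated disease-gene or disease-symptom association pairs, the
#' raw input of one network layer. Identifiers are whitespace-trimmed and
#' case-folded at construction so that records from merged knowledge bases
#' compare consistently.
#'
#' @slot kind either \code{"gene"} or \code{"symptom"}.
#' @slot records two-column \code{data.frame} (\code{disease}, \code{item}),
#'   no duplicated pairs, no empty identifiers.
#' @export
setClass("BipartiteAssociations",
  slots = c(kind = "character", records = "data.frame"))

setValidity("BipartiteAssociations", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% c("gene", "symptom"))
    msg <- c(msg, "kind must be one of 'gene', 'symptom'")
  rec <- object@records
  if (!identical(colnames(rec), c("disease", "item")))
    msg <- c(msg, "records must have columns 'disease', 'item'")
  else {
    if (anyDuplicated(paste(rec$disease, rec$item, sep = "\r")))
      msg <- c(msg, "duplicate (disease, item) pairs")
    if (any(!nzchar(rec$disease)) || any(!nzchar(rec$item)))
      msg <- c(msg, "empty identifiers after whitespace normalization")
  }
  if (length(msg)) msg else TRUE
})

#' DiseaseLayer: one disease-disease network layer
#'
#' An undirected, simple disease-disease graph obtained by bipartite
#' projection: two diseases are linked iff they share at least one item
#' (gene or symptom). The number of shared items is retained per edge for
#' reporting; all analyses treat the layer as unweighted.
#'
#' @slot name layer name, e.g. \code{"genotype"}.
#' @slot nodes character vector of disease identifiers hosted by the layer
#'   (isolated nodes allowed).
#' @slot edges \code{data.frame} with columns \code{from}, \code{to},
#'   \code{shared}; \code{from < to} lexicographically, no self-loops, no
#'   duplicates, \code{shared >= 1}.
#' @export
setClass("DiseaseLayer",
  slots = c(name = "character", nodes = "character", edges = "data.frame"))

setValidity("DiseaseLayer", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "shared") %in% colnames(e)))
    return("edges must have columns 'from', 'to', 'shared'")
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be stored with from < to")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msg <- c(msg, "duplicate edges")
    if (any(e$shared < 1)) msg <- c(msg, "shared counts must be >= 1")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be layer nodes")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated nodes")
  if (length(msg)) msg else TRUE
})

#' MultiplexNetwork: layers over one disease universe
#'
#' Two (or more) disease layers indexed by a shared disease universe. A
#' disease isolated in one layer is kept as an isolated node of that layer;
#' diseases isolated in every layer are removed at assembly.
#'
#' @slot diseases the shared disease universe (sorted, unique).
#' @slot layers named list of [DiseaseLayer-class] objects, each hosting
#'   exactly the universe.
#' @export
setClass("MultiplexNetwork",
  slots = c(diseases = "character", layers = "list"))

setValidity("MultiplexNetwork", function(object) {
  msg <- character()
  if (!length(object@layers)) msg <- c(msg, "at least one layer required")
  if (!length(object@diseases)) msg <- c(msg, "empty disease universe")
  for (ly in object@layers) {
    if (!is(ly, "DiseaseLayer")) { msg <- c(msg, "layers must be DiseaseLayer"); break }
    if (!identical(ly@nodes, object@diseases)) {
      msg <- c(msg, "all layers must index the same disease universe"); break
    }
  }
  deg <- rep(0L, length(object@diseases))
  names(deg) <- object@diseases
  for (ly in object@layers) {
    t1 <- table(c(ly@edges$from, ly@edges$to))
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
  }
  if (length(deg) && any(deg == 0))
    msg <- c(msg, "diseases isolated in all layers must be removed")
  if (length(msg)) msg else TRUE
})

#' OverlapResult: cross-layer edge-overlap significance
#'
#' @slot observed observed number of edges present in every layer.
#' @slot nullMean,nullSd mean and standard deviation of the overlap under
#'   per-layer degree-preserving randomization.
#' @slot z z-score \code{(observed - nullMean)/nullSd}; \code{NA} when the
#'   null is degenerate (\code{nullSd == 0}).
#' @slot nReps number of null replicates.
#' @slot normalityP Shapiro-Wilk P value of the null sample (descriptive
#'   only, never gates the z-score).
#' @slot nullSample the null overlap counts.
#' @export
setClass("OverlapResult",
  slots = c(observed = "integer", nullMean = "numeric", nullSd = "numeric",
            z = "numeric", nReps = "integer", normalityP = "numeric",
            nullSample = "numeric"))

#' FlowDistribution: stationary visit rates of the multilayer walker
#'
#' State nodes are (disease, layer) pairs. From state (u, alpha) the walker
#' follows, with probability \code{1 - relaxRate}, a uniformly chosen edge of
#' u within layer alpha; with probability \code{relaxRate} it relaxes and
#' chooses uniformly among all edges of u across all layers, landing in the
#' chosen edge's layer. States whose disease has no edge in their layer
#' always relax. The stationary distribution is computed by power iteration
#' with uniform teleportation; teleportation steps are unrecorded, i.e. they
#' stabilize the solve but contribute no flow to the map equation.
#'
#' @slot states \code{data.frame} (\code{disease}, \code{layer}) indexing the
#'   state nodes.
#' @slot visitRates recorded stationary visit rates (sum to 1).
#' @slot transition sparse row-stochastic transition matrix (teleport
#'   excluded).
#' @slot flow sparse recorded flow matrix \code{diag(pi) \%*\% transition},
#'   normalized to total 1.
#' @slot relaxRate,teleportRate walker parameters.
#' @slot iterations,residual power-iteration diagnostics.
#' @export
setClass("FlowDistribution",
  slots = c(states = "data.frame", visitRates = "numeric",
            transition = "Matrix", flow = "Matrix",
            relaxRate = "numeric", teleportRate = "numeric",
            iterations = "integer", residual = "numeric"))

setValidity("FlowDistribution", function(object) {
  msg <- character()
  if (abs(sum(object@visitRates) - 1) > 1e-9)
    msg <- c(msg, "visit rates must sum to 1")
  rs <- Matrix::rowSums(object@transition)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "transition rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' MapEquationTerms: two-level map-equation codelength
#'
#' @slot index index-codebook term (bits) for switching between modules.
#' @slot module sum of within-module codebook terms (bits).
#' @slot total total description length \code{index + module} (bits).
#' @export
setClass("MapEquationTerms",
  slots = c(index = "numeric", module = "numeric", total = "numeric"))

setValidity("MapEquationTerms", function(object) {
  msg <- character()
  if (abs(object@total - (object@index + object@module)) > 1e-9)
    msg <- c(msg, "total must equal index + module terms")
  if (object@total < -1e-9) msg <- c(msg, "codelength must be non-negative")
  if (length(msg)) msg else TRUE
})

#' MultiplexPartition: community assignment of state nodes
#'
#' @slot states \code{data.frame} (\code{disease}, \code{layer}).
#' @slot assignment integer community id per state node, contiguous from 1,
#'   relabelled by decreasing aggregate flow.
#' @slot visitRates recorded visit rate per state node.
#' @slot relaxRate relax rate used for detection.
#' @slot codelength [MapEquationTerms-class] of the returned partition.
#' @slot seed,nTrials optimizer settings (best of \code{nTrials} restarts).
#' @export
setClass("MultiplexPartition",
  slots = c(states = "data.frame", assignment = "integer",
            visitRates = "numeric", relaxRate = "numeric",
            codelength = "MapEquationTerms", seed = "integer",
            nTrials = "integer"))

setValidity("MultiplexPartition", function(object) {
  msg <- character()
  a <- object@assignment
  if (length(a) != nrow(object@states))
    msg <- c(msg, "one assignment per state node required")
  if (length(a) && !identical(sort(unique(a)), seq_len(max(a))))
    msg <- c(msg, "community ids must be contiguous integers from 1")
  if (length(msg)) msg else TRUE
})

#' ComorbidityTable: aggregate co-occurrence counts
#'
#' Pairwise co-occurrence counts C_AB, per-disease prevalence P_A and the
#' population size N, the inputs of the relative-risk comorbidity score.
#'
#' @slot counts \code{data.frame} (\code{a}, \code{b}, \code{count}) with
#'   \code{a < b}; pairs absent from the table count as zero co-occurrence
#'   when both diseases have a prevalence, and as missing otherwise.
#' @slot prevalence named numeric vector of per-disease prevalence.
#' @slot population total population size N.
#' @export
setClass("ComorbidityTable",
  slots = c(counts = "data.frame", prevalence = "numeric",
            population = "numeric"))

setValidity("ComorbidityTable", function(object) {
  msg <- character()
  p <- object@prevalence
  if (is.null(names(p)) || any(!nzchar(names(p))))
    msg <- c(msg, "prevalence must be a named vector")
  if (any(p <= 0)) msg <- c(msg, "prevalence must be positive")
  if (length(object@population) != 1L || object@population <= 0)
    msg <- c(msg, "population must be a positive scalar")
  if (any(p > object@population)) msg <- c(msg, "prevalence cannot exceed N")
  cnt <- object@counts
  if (!all(c("a", "b", "count") %in% colnames(cnt)))
    msg <- c(msg, "counts must have columns 'a', 'b', 'count'")
  else if (nrow(cnt)) {
    if (any(cnt$a >= cnt$b)) msg <- c(msg, "count pairs must satisfy a < b")
    if (any(cnt$count < 0)) msg <- c(msg, "co-occurrence counts must be >= 0")
    known <- cnt$a %in% names(p) & cnt$b %in% names(p)
    if (!all(known)) msg <- c(msg, "count pair diseases must have prevalence")
    else if (any(cnt$count > pmin(p[cnt$a], p[cnt$b])))
      msg <- c(msg, "C_AB cannot exceed min(P_A, P_B)")
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationDAG: is-a term hierarchy with gene annotations
#'
#' A directed acyclic is-a hierarchy of annotation terms (e.g. biological
#' process terms) plus gene-term annotations restricted to a fixed set of
#' allowed evidence codes. Construction rejects disallowed evidence codes
#' loudly; use [readAnnotations()] to filter a raw table.
#'
#' @slot parents named list: term -> character vector of parent terms
#'   (empty for roots).
#' @slot annotations \code{data.frame} (\code{gene}, \code{term},
#'   \code{evidence}).
#' @slot namespace annotation namespace label, e.g. \code{"BP"}.
#' @slot cache environment memoizing ancestor closures.
#' @export
setClass("AnnotationDAG",
  slots = c(parents = "list", annotations = "data.frame",
            namespace = "character", cache = "environment"))

setValidity("AnnotationDAG", function(object) {
  msg <- character()
  trm <- names(object@parents)
  if (is.null(trm) || anyDuplicated(trm))
    return("parents must be a uniquely named list")
  pp <- unlist(object@parents, use.names = FALSE)
  if (length(pp) && !all(pp %in% trm))
    msg <- c(msg, "every parent must itself be a term")
  ann <- object@annotations
  if (!all(c("gene", "term", "evidence") %in% colnames(ann)))
    msg <- c(msg, "annotations need columns 'gene', 'term', 'evidence'")
  else {
    if (nrow(ann) && !all(ann$term %in% trm))
      msg <- c(msg, "every annotated term must exist in the hierarchy")
    bad <- setdiff(unique(ann$evidence), allowedEvidenceCodes())
    if (length(bad))
      msg <- c(msg, paste0("disallowed evidence codes: ",
                           paste(bad, collapse = ", "),
                           " (filter with readAnnotations)"))
  }
  if (length(pp)) {
    el <- cbind(rep(trm, lengths(object@parents)), pp)
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    if (!igraph::is_dag(g)) msg <- c(msg, "parent relation must be acyclic")
  }
  if (length(msg)) msg else TRUE
})

#' SemanticMatrix: precomputed disease-disease semantic similarity
#'
#' Symmetric matrix of phenotype semantic-similarity scores in [0, 1] with
#' unit diagonal, covering a subset of the disease universe (coverage is
#' typically partial). Scores below 0.3 are uninformative, scores in
#' [0.3, 0.6] informative, and scores above 0.6 indicate significant
#' functional similarity.
#'
#' @slot values symmetric numeric matrix with disease dimnames.
#' @export
setClass("SemanticMatrix", slots = c(values = "matrix"))

setValidity("SemanticMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must have matching disease dimnames")
  if (!isSymmetric(unname(v), tol = 1e-9)) msg <- c(msg, "matrix must be symmetric")
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "similarities must lie in [0, 1]")
  if (nrow(v) && any(abs(diag(v) - 1) > 1e-9, na.rm = TRUE))
    msg <- c(msg, "diagonal must be 1 where present")
  if (length(msg)) msg else TRUE
})

#' CohesionReport: intra-community similarity significance
#'
#' Per community x metric: the number of pairs, scorable pairs, median
#' similarity, one-sided P value against the pooled background of pairs from
#' the other retained communities, and -log10 P. The summary counts
#' communities significant per metric, on all metrics and on at least two.
#'
#' @slot table per community x metric results.
#' @slot summary list of summary counts.
#' @slot minSize community size threshold used.
#' @slot alpha significance threshold on P.
#' @export
setClass("CohesionReport",
  slots = c(table = "data.frame", summary = "list", minSize = "integer",
            alpha = "numeric"))

#' SyntheticConfig: parameters of the planted-structure generator
#'
#' @slot nGroups number of planted disease groups K.
#' @slot diseasesPerGroup diseases per group.
#' @slot genePoolSize,symptomPoolSize size of each group-specific item pool.
#' @slot genesPerDisease,symptomsPerDisease items drawn from the own-group
#'   pool per disease.
#' @slot backgroundRate epsilon: per-item probability of an extra
#'   out-of-pool background item.
#' @slot contaminationRate rho: probability that a symptom draw comes from
#'   another group's pool.
#' @slot rrWithin,rrBetween target relative risk for within-/between-group
#'   disease pairs.
#' @slot population comorbidity population size N.
#' @slot prevalenceRange range of per-disease prevalence (uniform draw).
#' @slot ontologyDepth,ontologyBranching shape of the is-a term tree.
#' @slot termsPerGene annotation terms drawn per gene from the group's leaf
#'   term pool.
#' @slot semanticWithin,semanticBetween,semanticSd block means and noise of
#'   the semantic matrix.
#' @slot alignedLayers if \code{FALSE}, symptom pools are assigned to a
#'   cyclically shifted group, giving discordant layer communities.
#' @slot seed RNG seed of the generator.
#' @export
setClass("SyntheticConfig",
  slots = c(nGroups = "integer", diseasesPerGroup = "integer",
            genePoolSize = "integer", symptomPoolSize = "integer",
            genesPerDisease = "integer", symptomsPerDisease = "integer",
            backgroundRate = "numeric", contaminationRate = "numeric",
            rrWithin = "numeric", rrBetween = "numeric",
            population = "numeric", prevalenceRange = "numeric",
            ontologyDepth = "integer", ontologyBranching = "integer",
            termsPerGene = "integer", semanticWithin = "numeric",
            semanticBetween = "numeric", semanticSd = "numeric",
            alignedLayers = "logical", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  pos <- c(nGroups = object@nGroups, diseasesPerGroup = object@diseasesPerGroup,
           genePoolSize = object@genePoolSize,
           symptomPoolSize = object@symptomPoolSize,
           genesPerDisease = object@genesPerDisease,
           symptomsPerDisease = object@symptomsPerDisease,
           population = object@population,
           ontologyDepth = object@ontologyDepth,
           ontologyBranching = object@ontologyBranching,
           termsPerGene = object@termsPerGene)
  if (any(pos <= 0)) msg <- c(msg, "all sizes must be positive")
  for (r in c(object@backgroundRate, object@contaminationRate))
    if (r < 0 || r >= 1) msg <- c(msg, "rates must lie in [0, 1)")
  if (object@genesPerDisease > object@genePoolSize)
    msg <- c(msg, "gene pool smaller than per-disease draws")
  if (object@symptomsPerDisease > object@symptomPoolSize)
    msg <- c(msg, "symptom pool smaller than per-disease draws")
  if (length(object@prevalenceRange) != 2L ||
      any(object@prevalenceRange <= 0) ||
      diff(object@prevalenceRange) < 0 ||
      object@prevalenceRange[2] > object@population)
    msg <- c(msg, "prevalenceRange must be increasing, positive and <= N")
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: planted-structure inputs for the whole pipeline
#'
#' @slot genes,symptoms [BipartiteAssociations-class] tables.
#' @slot labels named integer vector of planted group labels per disease.
#' @slot comorbidity [ComorbidityTable-class] with the configured
#'   within-/between-group relative risks.
#' @slot dag [AnnotationDAG-class] with group-biased gene annotations.
#' @slot semantic [SemanticMatrix-class] with block-elevated similarities.
#' @slot config the generating [SyntheticConfig-class].
#' @export
setClass("SyntheticDataset",
  slots = c(genes = "BipartiteAssociations",
            symptoms = "BipartiteAssociations",
            labels = "integer", comorbidity = "ComorbidityTable",
            dag = "AnnotationDAG", semantic = "SemanticMatrix",
            config = "SyntheticConfig"))
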