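# Planted-structure generator: tripartite disease-gene-symptom data with
# group structure, comorbidity, an annotation tree and a block semantic
# matrix, plus the recovery score.

#' Configuration of the planted-structure generator
#'
#' Defaults describe four groups of 25 diseases. Each disease draws 4 genes
#' from its group's pool of 40 and 5 symptoms from its group's pool of 40
#' (with 5% of symptom draws contaminated from other pools). Background
#' noise adds each out-of-pool item independently with probability 0.002,
#' i.e. about 0.2 spurious items per disease, a few percent of its records
#' as in curated association databases. Within-group disease pairs have a target
#' comorbidity relative risk of 5 against 1 between groups, in a population
#' of 1e5 with prevalences of 200-2000. Gene annotations sit on a depth-3,
#' branching-3 is-a tree whose leaves are partitioned among groups; the
#' semantic matrix has within-/between-group means 0.6/0.2 with sd 0.1.
#'
#' @param nGroups,diseasesPerGroup,genePoolSize,symptomPoolSize,genesPerDisease,symptomsPerDisease
#'   group-structure sizes.
#' @param backgroundRate,contaminationRate noise rates (epsilon, rho).
#' @param rrWithin,rrBetween,population,prevalenceRange comorbidity
#'   parameters.
#' @param ontologyDepth,ontologyBranching,termsPerGene annotation-tree
#'   parameters.
#' @param semanticWithin,semanticBetween,semanticSd semantic-block
#'   parameters.
#' @param alignedLayers if \code{FALSE}, symptom pools are shifted by one
#'   group, producing discordant single-layer communities.
#' @param seed generator seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nGroups = 4, diseasesPerGroup = 25,
                            genePoolSize = 40, symptomPoolSize = 40,
                            genesPerDisease = 4, symptomsPerDisease = 5,
                            backgroundRate = 0.002, contaminationRate = 0.05,
                            rrWithin = 5, rrBetween = 1,
                            population = 1e5,
                            prevalenceRange = c(200, 2000),
                            ontologyDepth = 3, ontologyBranching = 3,
                            termsPerGene = 2,
                            semanticWithin = 0.6, semanticBetween = 0.2,
                            semanticSd = 0.1, alignedLayers = TRUE,
                            seed = 42) {
  new("SyntheticConfig",
      nGroups = as.integer(nGroups),
      diseasesPerGroup = as.integer(diseasesPerGroup),
      genePoolSize = as.integer(genePoolSize),
      symptomPoolSize = as.integer(symptomPoolSize),
      genesPerDisease = as.integer(genesPerDisease),
      symptomsPerDisease = as.integer(symptomsPerDisease),
      backgroundRate = backgroundRate,
      contaminationRate = contaminationRate,
      rrWithin = rrWithin, rrBetween = rrBetween,
      population = population, prevalenceRange = prevalenceRange,
      ontologyDepth = as.integer(ontologyDepth),
      ontologyBranching = as.integer(ontologyBranching),
      termsPerGene = as.integer(termsPerGene),
      semanticWithin = semanticWithin, semanticBetween = semanticBetween,
      semanticSd = semanticSd, alignedLayers = alignedLayers,
      seed = as.integer(seed))
}

# draw item associations for one item family (genes or symptoms)
.drawItems <- function(diseases, group, pools, mDraw, eps, rho) {
  allItems <- unlist(pools, use.names = FALSE)
  rec <- lapply(seq_along(diseases), function(i) {
    k <- group[i]
    own <- sample(pools[[k]], mDraw)
    if (rho > 0) {
      contam <- runif(mDraw) < rho
      if (any(contam)) {
        other <- unlist(pools[-k], use.names = FALSE)
        own[contam] <- sample(other, sum(contam))
      }
    }
    bg <- character()
    if (eps > 0) {
      outside <- setdiff(allItems, pools[[k]])
      bg <- outside[runif(length(outside)) < eps]
    }
    items <- unique(c(own, bg))
    cbind(rep(diseases[i], length(items)), items)
  })
  do.call(rbind, rec)
}

#' Generate a planted-structure synthetic dataset
#'
#' Emulates the statistical assumptions the diseasome analysis exploits:
#' K planted disease groups with group-specific gene and symptom pools and
#' background noise, elevated within-group comorbidity (counts obtained by
#' inverting the relative-risk formula, clipped to feasibility), a small
#' is-a term tree with group-specific leaf-term annotation pools, and a
#' block-elevated semantic matrix. Fully reproducible from the config seed.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [SyntheticDataset-class].
#' @examples
#' ds <- generateDiseasome(syntheticConfig(nGroups = 2,
#'   diseasesPerGroup = 8, seed = 7))
#' ds
#' @export
generateDiseasome <- function(config = syntheticConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  set.seed(config@seed)
  K <- config@nGroups
  n <- config@diseasesPerGroup
  diseases <- sprintf("d%03d", seq_len(K * n))
  labels <- setNames(rep(seq_len(K), each = n), diseases)

  genePools <- lapply(seq_len(K), function(k)
    sprintf("g%03d", (k - 1L) * config@genePoolSize +
              seq_len(config@genePoolSize)))
  sympPools <- lapply(seq_len(K), function(k)
    sprintf("s%03d", (k - 1L) * config@symptomPoolSize +
              seq_len(config@symptomPoolSize)))
  # symptom-layer grouping: identical to the gene grouping when layers are
  # aligned; rotated by half a group otherwise, so each symptom group
  # straddles two gene groups and the layers disagree
  sympGroup <- labels
  if (!config@alignedLayers) {
    shift <- n %/% 2L
    idx <- ((seq_along(diseases) - 1L + shift) %% (K * n)) + 1L
    sympGroup <- setNames(unname(labels[idx]), diseases)
  }

  gRec <- .drawItems(diseases, labels, genePools, config@genesPerDisease,
                     config@backgroundRate, 0)
  sRec <- .drawItems(diseases, sympGroup, sympPools,
                     config@symptomsPerDisease,
                     config@backgroundRate, config@contaminationRate)
  genes <- bipartiteAssociations(gRec[, 1], gRec[, 2], "gene")
  symptoms <- bipartiteAssociations(sRec[, 1], sRec[, 2], "symptom")

  # comorbidity: invert RR_AB = (C/N)/(P_A P_B / N^2)
  prev <- setNames(round(runif(K * n, config@prevalenceRange[1],
                               config@prevalenceRange[2])), diseases)
  pr <- .allPairs(diseases)
  same <- labels[pr[, 1]] == labels[pr[, 2]]
  target <- ifelse(same, config@rrWithin, config@rrBetween)
  cAB <- round(target * prev[pr[, 1]] * prev[pr[, 2]] / config@population)
  cAB <- pmin(cAB, prev[pr[, 1]], prev[pr[, 2]])
  comorbidity <- comorbidityTable(
    data.frame(a = pr[, 1], b = pr[, 2], count = as.numeric(cAB)),
    prev, config@population)

  # is-a tree of the configured depth/branching; leaves split among groups
  b <- config@ontologyBranching; d <- config@ontologyDepth
  nodes <- "t1"; parents <- list(t1 = character())
  level <- "t1"; counter <- 1L
  for (lv in seq_len(d)) {
    nxt <- character()
    for (p in level) {
      kids <- sprintf("t%d", counter + seq_len(b)); counter <- counter + b
      for (kid in kids) parents[[kid]] <- p
      nxt <- c(nxt, kids)
    }
    level <- nxt
  }
  leaves <- level
  leafGroup <- rep_len(seq_len(K), length(leaves))
  allGenes <- unlist(genePools, use.names = FALSE)
  geneGroup <- rep(seq_len(K), each = config@genePoolSize)
  ann <- do.call(rbind, lapply(seq_along(allGenes), function(i) {
    pool <- leaves[leafGroup == geneGroup[i]]
    terms <- sample(pool, min(config@termsPerGene, length(pool)))
    cbind(allGenes[i], terms, sample(allowedEvidenceCodes(), length(terms),
                                     replace = TRUE))
  }))
  dag <- annotationDAG(parents,
                       data.frame(gene = ann[, 1], term = ann[, 2],
                                  evidence = ann[, 3]),
                       namespace = "BP")

  # block-elevated semantic matrix with truncated noise, unit diagonal
  mu <- ifelse(same, config@semanticWithin, config@semanticBetween)
  v <- pmin(pmax(rnorm(nrow(pr), mu, config@semanticSd), 0), 1)
  sm <- diag(1, K * n)
  dimnames(sm) <- list(diseases, diseases)
  sm[cbind(pr[, 1], pr[, 2])] <- v
  sm[cbind(pr[, 2], pr[, 1])] <- v
  semantic <- semanticMatrix(sm)

  new("SyntheticDataset", genes = genes, symptoms = symptoms,
      labels = labels, comorbidity = comorbidity, dag = dag,
      semantic = semantic, config = config)
}

#' Assemble the multiplex network of a synthetic dataset
#'
#' Projects the gene and symptom association tables onto disease layers and
#' assembles the two-layer multiplex.
#'
#' @param ds a [SyntheticDataset-class].
#' @return a [MultiplexNetwork-class].
#' @export
syntheticMultiplex <- function(ds) {
  stopifnot(is(ds, "SyntheticDataset"))
  suppressMessages(assembleMultiplex(list(
    projectLayer(ds@genes, "genotype"),
    projectLayer(ds@symptoms, "phenotype"))))
}

#' Write all tables of a synthetic dataset
#'
#' Emits the exact plain-text formats the loaders read: gene and symptom
#' bipartite TSVs, a labels TSV, comorbidity pair/prevalence TSVs, the
#' annotation and term-parent TSVs and the semantic matrix TSV.
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticDataset <- function(ds, dir) {
  stopifnot(is(ds, "SyntheticDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  writeLines(paste(ds@genes@records$disease, ds@genes@records$item,
                   sep = "\t"), file.path(dir, "genes.tsv"))
  writeLines(paste(ds@symptoms@records$disease, ds@symptoms@records$item,
                   sep = "\t"), file.path(dir, "symptoms.tsv"))
  w(data.frame(disease = names(ds@labels), group = unname(ds@labels)),
    "labels.tsv")
  w(ds@comorbidity@counts, "comorbidity_pairs.tsv")
  w(data.frame(disease = names(ds@comorbidity@prevalence),
               prevalence = unname(ds@comorbidity@prevalence)),
    "prevalence.tsv")
  ann <- ds@dag@annotations
  w(data.frame(gene = ann$gene, term = ann$term, evidence = ann$evidence,
               namespace = ds@dag@namespace), "annotations.tsv")
  pl <- ds@dag@parents
  pl <- pl[lengths(pl) > 0]
  w(data.frame(child = rep(names(pl), lengths(pl)),
               parent = unlist(pl, use.names = FALSE)), "term_parents.tsv")
  sm <- data.frame(disease = rownames(ds@semantic@values),
                   ds@semantic@values, check.names = FALSE)
  write.table(sm, file.path(dir, "semantic.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Recovery score: NMI between planted labels and detected communities
#'
#' Normalized mutual information (arithmetic-mean normalization,
#' \eqn{2 I(X;Y) / (H(X) + H(Y))}) between the planted group labels and the
#' disease-level detected communities. A disease assigned to two
#' communities (a bridge) is scored by the community of its higher-flow
#' state node. Degenerate single-cluster inputs return 0 by convention,
#' flagged via an attribute.
#'
#' @param labels named integer vector (disease -> planted group).
#' @param partition a [MultiplexPartition-class] over the same diseases.
#' @return NMI in [0, 1]; attribute \code{"degenerate"} is \code{TRUE} when
#'   either side has a single cluster.
#' @export
recoveryScore <- function(labels, partition) {
  stopifnot(is(partition, "MultiplexPartition"))
  tab <- assignment(partition)
  # higher-flow assignment per disease
  tab <- tab[order(tab$disease, -tab$visitRate), ]
  tab <- tab[!duplicated(tab$disease), ]
  common <- intersect(names(labels), tab$disease)
  if (!length(common)) stop("no shared diseases between labels and partition")
  x <- labels[common]
  y <- setNames(tab$community, tab$disease)[common]
  ct <- table(x, y)
  pxy <- ct / sum(ct)
  px <- rowSums(pxy); py <- colSums(pxy)
  hx <- -sum(.plogp(px)); hy <- -sum(.plogp(py))
  if (hx == 0 || hy == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mi <- sum(pxy[pxy > 0] * log2(pxy[pxy > 0] /
                                  (outer(px, py)[pxy > 0])))
  out <- 2 * mi / (hx + hy)
  attr(out, "degenerate") <- FALSE
  max(0, min(1, out)) -> val
  attributes(val) <- attributes(out)
  val
}

setMethod("show", "SyntheticDataset", function(object) {
  cfg <- object@config
  cat(sprintf("SyntheticDataset: %d diseases in %d planted groups (seed %d)\n",
              cfg@nGroups * cfg@diseasesPerGroup, cfg@nGroups, cfg@seed))
  cat(sprintf("  %d gene and %d symptom associations; aligned layers: %s\n",
              nrow(object@genes@records), nrow(object@symptoms@records),
              cfg@alignedLayers))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: K = %d x %d diseases; eps = %g, rho = %g; RR %g/%g; seed %d\n",
              object@nGroups, object@diseasesPerGroup,
              object@backgroundRate, object@contaminationRate,
              object@rrWithin, object@rrBetween, object@seed))
})
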