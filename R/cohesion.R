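# Intra-community similarity assessment against the pooled community
# background, and per-process gene-set similarity z-scores.

#' Disease pairs of retained communities
#'
#' A community's disease set is the union of its member diseases over
#' layers; a bridge disease contributes pairs to both of its communities.
#' Communities below the size threshold are excluded.
#'
#' @param partition a [MultiplexPartition-class].
#' @param minSize minimum community size in diseases (default 10).
#' @return named list: community id -> 2-column matrix of unordered disease
#'   pairs.
#' @export
communityPairs <- function(partition, minSize = 10) {
  stopifnot(is(partition, "MultiplexPartition"))
  sets <- communities(partition)
  sets <- sets[lengths(sets) >= minSize]
  lapply(sets, .allPairs)
}

#' One-sided significance of community values against a background
#'
#' Rank-based (Wilcoxon/Mann-Whitney) one-sided test of the community's
#' pairwise similarity values being higher than the background values.
#' Exact enumeration is used when the smaller sample has at most 10 values
#' and the data are tie-free; otherwise the normal approximation with
#' continuity correction. Unscorable or fully tied inputs report P = 1 with
#' a flag.
#'
#' @param values community pairwise similarity values (NAs dropped).
#' @param background pooled background values (NAs dropped).
#' @return list with \code{p}, \code{negLogP} and \code{flag} (one of
#'   \code{"ok"}, \code{"unscorable"}, \code{"degenerate"}).
#' @export
communitySignificance <- function(values, background) {
  values <- values[is.finite(values)]
  background <- background[is.finite(background)]
  if (!length(values) || !length(background))
    return(list(p = 1, negLogP = 0, flag = "unscorable"))
  if (length(unique(c(values, background))) == 1L)
    return(list(p = 1, negLogP = 0, flag = "degenerate"))
  exact <- min(length(values), length(background)) <= 10 &&
    !any(duplicated(c(values, background)))
  p <- suppressWarnings(
    wilcox.test(values, background, alternative = "greater",
                exact = exact, correct = TRUE)$p.value)
  list(p = p, negLogP = -log10(p), flag = "ok")
}

# per-pair metric evaluators; each returns a numeric vector over the rows
# of a 2-column pair matrix, NA = unscorable
.metricEvaluators <- function(geneSets = NULL, comorbidity = NULL,
                              dag = NULL, semantic = NULL) {
  ev <- list()
  if (!is.null(comorbidity))
    ev$rr <- function(p) comorbidityRR(comorbidity, p[, 1], p[, 2])
  if (!is.null(geneSets)) {
    J <- .jaccardMatrix(geneSets)
    ev$geneOverlap <- function(p) {
      out <- rep(NA_real_, nrow(p))
      ok <- p[, 1] %in% rownames(J) & p[, 2] %in% rownames(J)
      out[ok] <- J[cbind(p[ok, 1], p[ok, 2])]
      out
    }
  }
  if (!is.null(geneSets) && !is.null(dag)) {
    S <- .diseaseBPMatrix(geneSets, dag)
    ev$goBP <- function(p) {
      out <- rep(NA_real_, nrow(p))
      ok <- p[, 1] %in% rownames(S) & p[, 2] %in% rownames(S)
      out[ok] <- S[cbind(p[ok, 1], p[ok, 2])]
      out
    }
  }
  if (!is.null(semantic))
    ev$semantic <- function(p) semanticSimilarity(semantic, p[, 1], p[, 2])$value
  ev
}

# disease x disease ancestor-based gene-set similarity matrix, computed in
# one sparse pass (diseases without annotated genes are absent)
.diseaseBPMatrix <- function(geneSets, dag) {
  geneSets <- geneSets[lengths(geneSets) > 0]
  prof <- .geneProfiles(dag)
  sets <- lapply(geneSets, function(g) intersect(unique(g), names(prof)))
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) return(matrix(numeric(), 0, 0))
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  prof <- prof[genes]
  terms <- sort(unique(unlist(prof, use.names = FALSE)))
  M <- sparseMatrix(i = rep(seq_along(prof), lengths(prof)),
                    j = match(unlist(prof, use.names = FALSE), terms),
                    x = 1, dims = c(length(genes), length(terms)))
  Inc <- sparseMatrix(i = match(unlist(sets, use.names = FALSE), genes),
                      j = rep(seq_along(sets), lengths(sets)),
                      x = rep(1 / lengths(sets), lengths(sets)),
                      dims = c(length(genes), length(sets)))
  W <- crossprod(M, Inc)                   # term weights w_S(t) per disease
  V <- (M / Matrix::rowSums(M)) %*% W      # sim(gene, disease)
  X <- as.matrix(crossprod(Inc, V))        # mean over the disease's genes
  S <- (X + t(X)) / 2
  dimnames(S) <- list(names(sets), names(sets))
  S
}

#' Assess intra-community cohesion on four similarity metrics
#'
#' For every community of at least \code{minSize} diseases and every
#' available metric (relative-risk comorbidity, gene-overlap Jaccard,
#' ancestor-based gene-set similarity, semantic similarity), compares the
#' community's pairwise values against the background of all disease pairs
#' over the retained communities (within- and cross-community pairs pooled,
#' excluding the pairs of the community under test) with a one-sided rank
#' test. A community is
#' significant at \code{alpha} (default P < 0.01, i.e. -log10 P > 2).
#' Metrics whose inputs are missing are skipped with a warning.
#' Benjamini-Hochberg adjusted P values are reported per metric for
#' transparency but the headline counts use raw P.
#'
#' @param partition a [MultiplexPartition-class].
#' @param geneSets named list disease -> gene set (for the gene-overlap and
#'   gene-set similarity metrics).
#' @param comorbidity a [ComorbidityTable-class] or \code{NULL}.
#' @param dag an [AnnotationDAG-class] or \code{NULL}.
#' @param semantic a [SemanticMatrix-class] or \code{NULL}.
#' @param minSize minimum community size (default 10).
#' @param alpha significance threshold on raw P (default 0.01).
#' @return a [CohesionReport-class].
#' @export
assessCohesion <- function(partition, geneSets = NULL, comorbidity = NULL,
                           dag = NULL, semantic = NULL, minSize = 10,
                           alpha = 0.01) {
  pairs <- communityPairs(partition, minSize = minSize)
  if (!length(pairs)) stop("no community of size >= ", minSize)
  ev <- .metricEvaluators(geneSets, comorbidity, dag, semantic)
  if (!length(ev)) {
    warning("no metric inputs supplied; nothing to assess")
    return(new("CohesionReport", table = data.frame(), summary = list(),
               minSize = as.integer(minSize), alpha = alpha))
  }
  comIds <- names(pairs)
  # background universe: all disease pairs over the retained communities
  universe <- sort(unique(unlist(lapply(pairs, c), use.names = FALSE)))
  allU <- .allPairs(universe)
  allKeys <- .pairKey(allU[, 1], allU[, 2])
  rows <- list()
  for (metric in names(ev)) {
    valsAll <- ev[[metric]](allU)
    for (ci in seq_along(comIds)) {
      keys <- .pairKey(pairs[[ci]][, 1], pairs[[ci]][, 2])
      v <- valsAll[match(keys, allKeys)]
      bg <- valsAll[!(allKeys %in% keys)]
      sig <- communitySignificance(v, bg)
      rows[[length(rows) + 1L]] <- data.frame(
        community = comIds[ci], metric = metric,
        nPairs = length(v), nScorable = sum(is.finite(v)),
        median = if (any(is.finite(v))) median(v[is.finite(v)]) else NA_real_,
        p = sig$p, negLogP = sig$negLogP, flag = sig$flag,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$pBH <- NA_real_
  for (metric in unique(tab$metric)) {
    sel <- tab$metric == metric
    tab$pBH[sel] <- p.adjust(tab$p[sel], method = "BH")
  }
  tab$significant <- tab$p < alpha
  perMetric <- vapply(names(ev), function(mt)
    sum(tab$significant[tab$metric == mt]), integer(1))
  byCom <- split(tab$significant, tab$community)
  allMetrics <- sum(vapply(byCom, all, logical(1)))
  atLeastTwo <- sum(vapply(byCom, function(s) sum(s) >= 2L, logical(1)))
  summ <- list(nCommunities = length(comIds), perMetric = perMetric,
               onAllMetrics = allMetrics, onAtLeastTwo = atLeastTwo,
               nMetrics = length(ev))
  new("CohesionReport", table = tab, summary = summ,
      minSize = as.integer(minSize), alpha = alpha)
}

#' Per-community cohesion table
#' @param report a [CohesionReport-class].
#' @return \code{data.frame}.
#' @export
cohesionTable <- function(report) {
  stopifnot(is(report, "CohesionReport"))
  report@table
}

#' Cohesion summary counts
#' @param report a [CohesionReport-class].
#' @return list of counts (communities significant per metric, on all
#'   metrics, on at least two).
#' @export
cohesionSummary <- function(report) {
  stopifnot(is(report, "CohesionReport"))
  report@summary
}

#' Significance of a disease gene set's similarity to a biological process
#'
#' Computes the ancestor-based gene-set similarity between a disease's
#' genes and the genes annotated to a process term (the term or any of its
#' descendants), and z-scores it against \code{nRandom} equally sized
#' uniform gene draws from the interactome universe.
#'
#' @param diseaseGenes character vector of the disease's genes.
#' @param term the process term.
#' @param dag an [AnnotationDAG-class].
#' @param universe character vector of candidate genes to draw from (must
#'   be at least as large as \code{diseaseGenes}).
#' @param nRandom number of random draws (default 1000).
#' @param seed integer seed.
#' @return list with \code{similarity}, \code{nullMean}, \code{nullSd},
#'   \code{z} (\code{NA} with flag \code{"degenerate"} when the null sd is
#'   0) and \code{flag}.
#' @export
processSimilarityZ <- function(diseaseGenes, term, dag, universe,
                               nRandom = 1000, seed = 1) {
  stopifnot(is(dag, "AnnotationDAG"))
  if (!term %in% names(dag@parents)) stop("unknown term: ", term)
  diseaseGenes <- unique(diseaseGenes)
  universe <- unique(universe)
  if (length(universe) < length(diseaseGenes))
    stop("gene universe smaller than the disease gene set")
  prof <- .geneProfiles(dag)
  processGenes <- names(prof)[vapply(prof, function(ts) term %in% ts,
                                     logical(1))]
  if (!length(processGenes)) stop("no genes annotated to term ", term)
  sObs <- genesetBPSimilarity(diseaseGenes, processGenes, dag)
  set.seed(seed)
  null <- vapply(seq_len(nRandom), function(r) {
    g <- sample(universe, length(diseaseGenes))
    genesetBPSimilarity(g, processGenes, dag)
  }, numeric(1))
  null <- null[is.finite(null)]
  mu <- mean(null); sdv <- sd(null)
  list(similarity = sObs, nullMean = mu, nullSd = sdv,
       z = if (isTRUE(sdv > 0)) (sObs - mu) / sdv else NA_real_,
       flag = if (isTRUE(sdv > 0)) "ok" else "degenerate")
}

setMethod("show", "CohesionReport", function(object) {
  s <- object@summary
  cat(sprintf("CohesionReport: %d communities (size >= %d), alpha = %g\n",
              s$nCommunities, object@minSize, object@alpha))
  for (mt in names(s$perMetric))
    cat(sprintf("  %s: %d/%d significant\n", mt, s$perMetric[[mt]],
                s$nCommunities))
  cat(sprintf("  on all %d metrics: %d/%d; on >= 2 metrics: %d/%d\n",
              s$nMetrics, s$onAllMetrics, s$nCommunities,
              s$onAtLeastTwo, s$nCommunities))
})
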