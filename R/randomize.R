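# Degree-preserving null models: edge-overlap and edge-wise gene-similarity
# significance.

#' Degree-preserving randomization of a layer
#'
#' Rewires the layer by double-edge swaps that conserve every node's degree
#' and reject self-loops and multi-edges (configuration-model sampling with
#' \code{swapFactor * |E|} swap attempts). Shared-item counts are meaningless
#' after rewiring and are set to 1. With \code{swapFactor = 0} the layer is
#' returned unchanged (identity randomization, useful as a degenerate-null
#' control).
#'
#' @param layer a [DiseaseLayer-class] with at least 2 edges.
#' @param seed optional integer seed (set when reproducibility of a single
#'   call is needed; ensemble functions seed once themselves).
#' @param swapFactor swap attempts per edge (default 10).
#' @return a rewired [DiseaseLayer-class] with the exact degree sequence of
#'   the input.
#' @export
randomizeLayer <- function(layer, seed = NULL, swapFactor = 10) {
  stopifnot(is(layer, "DiseaseLayer"))
  if (nrow(layer@edges) < 2L)
    stop("degree-preserving randomization needs at least 2 edges")
  if (!is.null(seed)) set.seed(seed)
  if (swapFactor == 0) return(layer)
  g <- .layerGraph(layer)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = ceiling(swapFactor * igraph::ecount(g))))
  el <- igraph::as_edgelist(g2)
  out <- diseaseLayer(layer@name, layer@nodes,
                      data.frame(from = el[, 1], to = el[, 2], shared = 1L))
  # degree conservation asserted on every call
  stopifnot(identical(.layerDegree(out), .layerDegree(layer)))
  out
}

#' Significance of cross-layer edge overlap
#'
#' Compares the observed number of overlapping links (edges present in every
#' layer) with a null distribution obtained by independently rewiring each
#' layer with degree-preserving randomization, \code{nReps} times. Reports
#' the null mean, standard deviation, z-score and a descriptive
#' Shapiro-Wilk normality P value of the null sample (never used to gate the
#' z-score).
#'
#' @param mx a [MultiplexNetwork-class] (two layers in the diseasome; any
#'   number accepted).
#' @param nReps number of null replicates (default 5000).
#' @param seed integer seed for the replicate ensemble.
#' @param swapFactor swap attempts per edge and replicate.
#' @return an [OverlapResult-class].
#' @export
overlapSignificance <- function(mx, nReps = 5000, seed = 1, swapFactor = 10) {
  stopifnot(is(mx, "MultiplexNetwork"))
  observed <- nrow(edgeOverlap(mx))
  set.seed(seed)
  graphs <- lapply(mx@layers, .layerGraph)
  null <- vapply(seq_len(nReps), function(r) {
    keys <- lapply(graphs, function(g) {
      if (swapFactor > 0 && igraph::ecount(g) >= 2L)
        g <- igraph::rewire(g, igraph::keeping_degseq(
          loops = FALSE, niter = ceiling(swapFactor * igraph::ecount(g))))
      el <- igraph::as_edgelist(g)
      .pairKey(el[, 1], el[, 2])
    })
    length(Reduce(intersect, keys))
  }, numeric(1))
  m <- mean(null); s <- sd(null)
  normP <- if (s > 0 && nReps >= 3)
    tryCatch(shapiro.test(if (nReps > 5000) sample(null, 5000) else null)$p.value,
             error = function(e) NA_real_) else NA_real_
  new("OverlapResult", observed = as.integer(observed), nullMean = m,
      nullSd = s, z = if (s > 0) (observed - m) / s else NA_real_,
      nReps = as.integer(nReps), normalityP = normP, nullSample = null)
}

# pairwise gene-overlap Jaccard matrix over the diseases covered by geneSets
.jaccardMatrix <- function(geneSets) {
  geneSets <- geneSets[lengths(geneSets) > 0]
  ds <- names(geneSets)
  genes <- sort(unique(unlist(geneSets, use.names = FALSE)))
  M <- sparseMatrix(i = rep(seq_along(geneSets), lengths(geneSets)),
                    j = match(unlist(geneSets, use.names = FALSE), genes),
                    x = 1, dims = c(length(ds), length(genes)))
  inter <- as.matrix(tcrossprod(M))
  sz <- lengths(geneSets)
  un <- outer(sz, sz, `+`) - inter
  J <- inter / un
  dimnames(J) <- list(ds, ds)
  J
}

# mean Jaccard over an edge list (matrix of from/to), given the J matrix;
# returns mean and counts of scorable/skipped edges
.meanEdgeJaccard <- function(from, to, J) {
  ok <- from %in% rownames(J) & to %in% rownames(J)
  vals <- J[cbind(from[ok], to[ok])]
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       nScorable = sum(ok), nSkipped = sum(!ok))
}

#' Edge-wise gene-similarity profile of the multiplex
#'
#' For each requested network (each layer and/or the overlap network of
#' edges present in every layer), computes the average gene-overlap Jaccard
#' index over edges whose endpoint diseases both have a gene set, and
#' z-scores it against ensembles of networks with the same degree
#' distribution in each layer (degree-preserving rewiring). Pairs with a
#' missing gene set are skipped and counted.
#'
#' @param mx a [MultiplexNetwork-class].
#' @param geneSets named list: disease -> gene set.
#' @param networks which networks to profile: layer names and/or
#'   \code{"overlap"}.
#' @param nReps number of null replicates.
#' @param seed integer seed.
#' @param swapFactor swap attempts per edge and replicate.
#' @return \code{data.frame} with one row per network: mean Jaccard, null
#'   mean/sd, z-score, edge counts and an \code{empty} flag for networks
#'   with no scorable edge.
#' @export
edgeJaccardProfile <- function(mx, geneSets,
                               networks = c(layerNames(mx), "overlap"),
                               nReps = 1000, seed = 1, swapFactor = 10) {
  stopifnot(is(mx, "MultiplexNetwork"))
  networks <- match.arg(networks, c(names(mx@layers), "overlap"),
                        several.ok = TRUE)
  geneSets <- geneSets[lengths(geneSets) > 0]
  names(geneSets) <- .normId(names(geneSets))
  J <- .jaccardMatrix(geneSets)

  edgeTab <- function(layers) {
    keys <- lapply(layers, function(el) .pairKey(el[, 1], el[, 2]))
    common <- Reduce(intersect, keys)
    if (!length(common)) return(NULL)
    do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  }
  obsEdges <- lapply(networks, function(nw) {
    if (nw == "overlap") {
      ov <- edgeOverlap(mx)
      if (nrow(ov)) cbind(ov$from, ov$to) else NULL
    } else {
      e <- mx@layers[[nw]]@edges
      if (nrow(e)) cbind(e$from, e$to) else NULL
    }
  })
  names(obsEdges) <- networks
  obs <- lapply(obsEdges, function(e) {
    if (is.null(e)) list(mean = NA_real_, nScorable = 0L, nSkipped = 0L)
    else .meanEdgeJaccard(e[, 1], e[, 2], J)
  })

  set.seed(seed)
  graphs <- lapply(mx@layers, .layerGraph)
  nullMeans <- matrix(NA_real_, nReps, length(networks),
                      dimnames = list(NULL, networks))
  for (r in seq_len(nReps)) {
    els <- lapply(graphs, function(g) {
      if (swapFactor > 0 && igraph::ecount(g) >= 2L)
        g <- igraph::rewire(g, igraph::keeping_degseq(
          loops = FALSE, niter = ceiling(swapFactor * igraph::ecount(g))))
      igraph::as_edgelist(g)
    })
    for (nw in networks) {
      e <- if (nw == "overlap") edgeTab(els) else els[[nw]]
      if (!is.null(e) && nrow(e))
        nullMeans[r, nw] <- .meanEdgeJaccard(e[, 1], e[, 2], J)$mean
    }
  }
  res <- lapply(networks, function(nw) {
    nm <- nullMeans[, nw]
    nm <- nm[is.finite(nm)]
    mu <- if (length(nm)) mean(nm) else NA_real_
    sdv <- if (length(nm) > 1) sd(nm) else NA_real_
    ok <- is.finite(obs[[nw]]$mean)
    data.frame(network = nw,
               meanJaccard = obs[[nw]]$mean,
               nullMean = mu, nullSd = sdv,
               z = if (ok && isTRUE(sdv > 0)) (obs[[nw]]$mean - mu) / sdv
                   else NA_real_,
               nScorable = obs[[nw]]$nScorable,
               nSkipped = obs[[nw]]$nSkipped,
               empty = !ok,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: observed %d overlapping edges\n", object@observed))
  cat(sprintf("  null (%d degree-preserving reps): %.2f +/- %.2f, z = %s\n",
              object@nReps, object@nullMean, object@nullSd,
              if (is.na(object@z)) "undefined (degenerate null)"
              else sprintf("%.2f", object@z)))
  if (!is.na(object@normalityP))
    cat(sprintf("  null normality (Shapiro-Wilk) P = %.3g [descriptive]\n",
                object@normalityP))
})
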