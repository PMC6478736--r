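# Map-equation community detection on the multiplex, bridge diseases and
# cross-partition comparison.

# Greedy two-level map-equation minimization over recorded flows.
# ft: flow triplets (i, j, x, diagonal-free); pn: visit rates; order: node
# visiting order. Single-node moves to neighboring (or fresh) modules are
# applied while they lower L; converged sweeps alternate with greedy
# module-pair merges until neither phase improves. Ties break toward the
# lowest module id.
.optimizeMapEq <- function(ft, pn, order, eps = 1e-12) {
  nS <- length(pn)
  outAdj <- vector("list", nS); inAdj <- vector("list", nS)
  og <- split(seq_along(ft$i), ft$i)
  ig <- split(seq_along(ft$j), ft$j)
  for (k in names(og)) outAdj[[as.integer(k)]] <- og[[k]]
  for (k in names(ig)) inAdj[[as.integer(k)]] <- ig[[k]]
  outTot <- numeric(nS); inTot <- numeric(nS)
  if (length(ft$x)) {
    ot <- tapply(ft$x, ft$i, sum); outTot[as.integer(names(ot))] <- ot
    it <- tapply(ft$x, ft$j, sum); inTot[as.integer(names(it))] <- it
  }

  m <- seq_len(nS)
  qMod <- outTot            # singleton exit flow = total out-flow
  pMod <- pn
  size <- rep(1L, nS)
  qtot <- sum(qMod)

  moveSweeps <- function() {
    improvedAny <- FALSE
    repeat {
      improved <- FALSE
      for (u in order) {
        A <- m[u]
        oi <- outAdj[[u]]; ini <- inAdj[[u]]
        modOut <- m[ft$j[oi]]; modIn <- m[ft$i[ini]]
        cand <- sort(unique(c(modOut, modIn)))
        cand <- cand[cand != A]
        fresh <- 0L
        if (size[A] > 1L) {           # moving out into a fresh module
          fresh <- which(size == 0L)[1L]
          if (!is.na(fresh)) cand <- c(cand, fresh) else fresh <- 0L
        }
        if (!length(cand)) next
        wout <- numeric(length(cand)); win <- numeric(length(cand))
        if (length(oi)) {
          s <- tapply(ft$x[oi], match(modOut, cand), sum)
          idx <- as.integer(names(s)); ok <- !is.na(idx)
          wout[idx[ok]] <- s[ok]
        }
        if (length(ini)) {
          s <- tapply(ft$x[ini], match(modIn, cand), sum)
          idx <- as.integer(names(s)); ok <- !is.na(idx)
          win[idx[ok]] <- s[ok]
        }
        woutA <- sum(ft$x[oi][modOut == A])
        winA <- sum(ft$x[ini][modIn == A])
        qA <- qMod[A]; pA <- pMod[A]
        qA2 <- qA - (outTot[u] - woutA) + winA
        pA2 <- pA - pn[u]
        qB <- qMod[cand]; pB <- pMod[cand]
        qB2 <- qB + (outTot[u] - wout) - win
        pB2 <- pB + pn[u]
        qtot2 <- qtot + (qA2 - qA) + (qB2 - qB)
        dL <- (.plogp(qtot2) - .plogp(qtot)) -
          2 * (.plogp(qA2) - .plogp(qA) + .plogp(qB2) - .plogp(qB)) +
          (.plogp(qA2 + pA2) - .plogp(qA + pA) +
           .plogp(qB2 + pB2) - .plogp(qB + pB))
        best <- which.min(dL)
        if (dL[best] < -eps) {
          B <- cand[best]
          qMod[A] <<- qA2; pMod[A] <<- pA2; size[A] <<- size[A] - 1L
          qMod[B] <<- qB2[best]; pMod[B] <<- pB2[best]
          size[B] <<- size[B] + 1L
          qtot <<- qtot2[best]
          m[u] <<- B
          improved <- TRUE; improvedAny <- TRUE
        }
      }
      if (!improved) break
    }
    improvedAny
  }

  mergePass <- function() {
    improvedAny <- FALSE
    repeat {
      live <- which(size > 0L)
      if (length(live) < 2L) break
      # aggregated inter-module flows
      mi <- m[ft$i]; mj <- m[ft$j]
      cross <- mi != mj
      if (!any(cross)) break
      key <- paste(pmin(mi[cross], mj[cross]), pmax(mi[cross], mj[cross]),
                   sep = "\r")
      wsum <- tapply(ft$x[cross], key, sum)
      parts <- do.call(rbind, strsplit(names(wsum), "\r", fixed = TRUE))
      a <- as.integer(parts[, 1]); b <- as.integer(parts[, 2])
      w <- as.numeric(wsum)               # W[a,b] + W[b,a]
      qab <- qMod[a] + qMod[b] - w
      pab <- pMod[a] + pMod[b]
      qtot2 <- qtot - w
      dL <- (.plogp(qtot2) - .plogp(qtot)) -
        2 * (.plogp(qab) - .plogp(qMod[a]) - .plogp(qMod[b])) +
        (.plogp(qab + pab) - .plogp(qMod[a] + pMod[a]) -
         .plogp(qMod[b] + pMod[b]))
      ord <- order(dL, a, b)
      best <- ord[1L]
      if (dL[best] < -eps) {
        A <- a[best]; B <- b[best]
        m[m == B] <<- A
        qMod[A] <<- qab[best]; pMod[A] <<- pab[best]
        size[A] <<- size[A] + size[B]
        qMod[B] <<- 0; pMod[B] <<- 0; size[B] <<- 0L
        qtot <<- qtot2[best]
        improvedAny <- TRUE
      } else break
    }
    improvedAny
  }

  repeat {
    a <- moveSweeps()
    b <- mergePass()
    if (!a && !b) break
    if (!b) { if (!moveSweeps()) break }
  }
  as.integer(factor(m))
}

#' Detect multiplex communities by map-equation minimization
#'
#' Greedy minimization of the two-level map equation over the recorded flows
#' of the relax-rate walker, restarted from \code{nTrials} random node
#' orders; the lowest-codelength partition is returned with community ids
#' relabelled by decreasing aggregate flow. Single-layer detection is the
#' special case of a one-layer multiplex (the relax rate is then
#' irrelevant). Deterministic given \code{seed}.
#'
#' @param mx a [MultiplexNetwork-class].
#' @param relaxRate relax rate of the walker (default 0.45).
#' @param seed integer seed.
#' @param nTrials number of random-order restarts (default 10).
#' @param teleportRate,tol,maxIter passed to [stationaryFlow()].
#' @return a [MultiplexPartition-class].
#' @export
detectCommunities <- function(mx, relaxRate = 0.45, seed = 1, nTrials = 10,
                              teleportRate = 0.15, tol = 1e-12,
                              maxIter = 10000) {
  stopifnot(is(mx, "MultiplexNetwork"), nTrials >= 1)
  flow <- stationaryFlow(mx, relaxRate = relaxRate,
                         teleportRate = teleportRate, tol = tol,
                         maxIter = maxIter)
  ft <- .flowTriplets(flow@flow)
  pn <- flow@visitRates
  nS <- length(pn)
  set.seed(seed)
  best <- NULL; bestL <- Inf
  for (t in seq_len(nTrials)) {
    ord <- sample.int(nS)
    m <- .optimizeMapEq(ft, pn, ord)
    st <- .moduleStats(ft, pn, m)
    L <- .codelengthTerms(st$q, st$pm, pn)
    if (L@total < bestL - 1e-12) { best <- m; bestL <- L@total }
  }
  # relabel by decreasing aggregate flow, ties by lowest old id
  pm <- as.vector(tapply(pn, factor(best, levels = seq_len(max(best))), sum))
  relabel <- order(-pm, seq_along(pm))
  newId <- integer(length(pm)); newId[relabel] <- seq_along(pm)
  best <- newId[best]
  st <- .moduleStats(ft, pn, best)
  terms <- .codelengthTerms(st$q, st$pm, pn)
  new("MultiplexPartition", states = flow@states, assignment = best,
      visitRates = pn, relaxRate = relaxRate, codelength = terms,
      seed = as.integer(seed), nTrials = as.integer(nTrials))
}

#' @describeIn assignment assignment table of a partition.
#' @export
setMethod("assignment", "MultiplexPartition", function(x) {
  data.frame(x@states, community = x@assignment,
             visitRate = unname(x@visitRates), stringsAsFactors = FALSE)
})

#' @describeIn communities disease sets of a partition's communities.
#' @export
setMethod("communities", "MultiplexPartition", function(x) {
  tab <- assignment(x)
  lapply(split(tab$disease, tab$community), unique)
})

#' @describeIn diseases universe of a partition.
#' @export
setMethod("diseases", "MultiplexPartition", function(x) {
  sort(unique(x@states$disease))
})

#' Bridge diseases of a multiplex partition
#'
#' Diseases whose state nodes in different layers are assigned to different
#' communities; they tie a genotype-layer community to a distinct
#' phenotype-layer community.
#'
#' @param p a [MultiplexPartition-class] over at least 2 layers.
#' @return character vector of bridge diseases.
#' @export
bridgeDiseases <- function(p) {
  stopifnot(is(p, "MultiplexPartition"))
  if (length(unique(p@states$layer)) < 2L)
    stop("bridge diseases require a partition over >= 2 layers")
  tab <- assignment(p)
  nCom <- tapply(tab$community, tab$disease, function(v) length(unique(v)))
  sort(names(nCom)[nCom > 1L])
}

# mean Jaccard over all cross-partition community pairs
.meanCommunityJaccard <- function(setsA, setsB) {
  if (!length(setsA) || !length(setsB))
    stop("a partition with zero communities cannot be compared")
  universe <- sort(unique(c(unlist(setsA), unlist(setsB))))
  mk <- function(sets) sparseMatrix(
    i = match(unlist(sets, use.names = FALSE), universe),
    j = rep(seq_along(sets), lengths(sets)), x = 1,
    dims = c(length(universe), length(sets)))
  MA <- mk(setsA); MB <- mk(setsB)
  inter <- as.matrix(crossprod(MA, MB))
  un <- outer(lengths(setsA), lengths(setsB), `+`) - inter
  mean(inter / un)
}

#' Compare two partitions by mean community-overlap Jaccard
#'
#' Computes the mean Jaccard index of the disease overlap over all pairs of
#' communities (one from each partition). When a two-layer multiplex and
#' \code{nReps > 0} are supplied, the value is z-scored against partitions
#' re-detected on independently degree-preserving-randomized copies of each
#' layer (single-layer detection per randomized layer).
#'
#' @param pA,pB [MultiplexPartition-class] objects (typically the
#'   single-layer partitions of the two layers).
#' @param mx optional [MultiplexNetwork-class] with 2 layers for the null
#'   ensemble.
#' @param nReps number of null replicates (0 = no null).
#' @param seed integer seed.
#' @param nTrials optimizer restarts per null detection.
#' @param swapFactor swap attempts per edge for the rewiring.
#' @return list with \code{meanJaccard}, and when a null was run,
#'   \code{nullMean}, \code{nullSd}, \code{z}.
#' @export
comparePartitions <- function(pA, pB, mx = NULL, nReps = 0, seed = 1,
                              nTrials = 5, swapFactor = 10) {
  stopifnot(is(pA, "MultiplexPartition"), is(pB, "MultiplexPartition"))
  obs <- .meanCommunityJaccard(communities(pA), communities(pB))
  out <- list(meanJaccard = obs)
  if (!is.null(mx) && nReps > 0) {
    stopifnot(is(mx, "MultiplexNetwork"), length(mx@layers) == 2L)
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max %/% 2L, nReps * 3L)
    null <- vapply(seq_len(nReps), function(r) {
      parts <- lapply(seq_along(mx@layers), function(k) {
        ly <- randomizeLayer(mx@layers[[k]], swapFactor = swapFactor)
        m1 <- suppressMessages(assembleMultiplex(list(ly)))
        detectCommunities(m1, relaxRate = pA@relaxRate,
                          seed = seeds[(r - 1L) * 2L + k],
                          nTrials = nTrials)
      })
      .meanCommunityJaccard(communities(parts[[1]]), communities(parts[[2]]))
    }, numeric(1))
    out$nullMean <- mean(null)
    out$nullSd <- sd(null)
    out$z <- if (out$nullSd > 0) (obs - out$nullMean) / out$nullSd else NA_real_
    out$nullSample <- null
  }
  out
}

setMethod("show", "MultiplexPartition", function(object) {
  k <- max(object@assignment)
  sizes <- lengths(communities(object))
  cat(sprintf("MultiplexPartition: %d communities over %d state nodes (relax rate %.2f)\n",
              k, length(object@assignment), object@relaxRate))
  cat(sprintf("  community sizes (diseases): %d - %d; codelength %.4f bits\n",
              min(sizes), max(sizes), object@codelength@total))
})
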