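# Multilayer random-walker flow and the two-level map equation.

# state index helper: state of disease i (1..n) in layer a (1..L) is
# (a-1)*n + i
.stateFrame <- function(mx) {
  n <- length(mx@diseases)
  data.frame(disease = rep(mx@diseases, times = length(mx@layers)),
             layer = rep(names(mx@layers), each = n),
             stringsAsFactors = FALSE)
}

#' Stationary flow of the relax-rate multilayer walker
#'
#' Builds the row-stochastic transition matrix of the multiplex random
#' walker and computes its stationary visit rates by power iteration with
#' uniform (unrecorded) teleportation. From state (u, alpha) the walker
#' steps, with probability \code{1 - relaxRate}, along a uniformly chosen
#' edge of u within layer alpha; with probability \code{relaxRate} it
#' relaxes the layer constraint and chooses uniformly among all edges of u
#' across all layers, landing in the chosen edge's layer. A state whose
#' disease has no edge in its layer always relaxes. Recorded flows (used by
#' the map equation) exclude teleportation; the recorded visit rate of a
#' state is its incoming recorded flow.
#'
#' @param mx a [MultiplexNetwork-class].
#' @param relaxRate relax rate r in [0, 1] (default 0.45).
#' @param teleportRate uniform teleportation probability used to stabilize
#'   the solve on disconnected structures (default 0.15); with a single
#'   connected layer and \code{teleportRate = 0}, visit rates are
#'   proportional to degree.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return a [FlowDistribution-class].
#' @export
stationaryFlow <- function(mx, relaxRate = 0.45, teleportRate = 0.15,
                           tol = 1e-12, maxIter = 10000) {
  stopifnot(is(mx, "MultiplexNetwork"),
            relaxRate >= 0, relaxRate <= 1,
            teleportRate >= 0, teleportRate < 1)
  n <- length(mx@diseases)
  L <- length(mx@layers)
  nS <- n * L
  # per-layer degrees (n x L) and directed edge lists in disease indices
  deg <- matrix(0L, n, L)
  dirEdges <- vector("list", L)   # per layer: 2-col matrix u -> v (both dirs)
  for (a in seq_len(L)) {
    e <- mx@layers[[a]]@edges
    if (nrow(e)) {
      ui <- match(e$from, mx@diseases); vi <- match(e$to, mx@diseases)
      dirEdges[[a]] <- cbind(c(ui, vi), c(vi, ui))
      t1 <- tabulate(c(ui, vi), nbins = n)
      deg[, a] <- t1
    } else dirEdges[[a]] <- matrix(integer(), ncol = 2)
  }
  ktot <- rowSums(deg)
  if (any(ktot == 0)) stop("multiplex contains diseases isolated in all layers")

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  allDir <- do.call(rbind, lapply(seq_len(L), function(b)
    cbind(dirEdges[[b]], b)))   # u, v, layer of edge
  for (a in seq_len(L)) {
    # effective relax probability of (u, a): r, or 1 when deg(u, a) = 0
    rEff <- ifelse(deg[, a] > 0, relaxRate, 1)
    # within-layer steps
    de <- dirEdges[[a]]
    if (nrow(de)) {
      u <- de[, 1]; v <- de[, 2]
      ii <- c(ii, (a - 1L) * n + u)
      jj <- c(jj, (a - 1L) * n + v)
      xx <- c(xx, (1 - rEff[u]) / deg[u, a])
    }
    # relax steps: all edges of u across all layers, landing in that layer
    if (nrow(allDir)) {
      u <- allDir[, 1]; v <- allDir[, 2]; b <- allDir[, 3]
      ii <- c(ii, (a - 1L) * n + u)
      jj <- c(jj, (b - 1L) * n + v)
      xx <- c(xx, rEff[u] / ktot[u])
    }
  }
  P <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(nS, nS))
  rs <- Matrix::rowSums(P)
  if (any(abs(rs - 1) > 1e-9))
    stop("internal error: transition rows do not sum to 1")

  pi0 <- rep(1 / nS, nS)
  tau <- teleportRate
  iter <- 0L; resid <- Inf
  Pt <- Matrix::t(P)
  while (iter < maxIter) {
    iter <- iter + 1L
    piNew <- tau / nS + (1 - tau) * as.vector(Pt %*% pi0)
    piNew <- piNew / sum(piNew)
    resid <- sum(abs(piNew - pi0))
    pi0 <- piNew
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
                 maxIter, resid))
  Fm <- Diagonal(x = pi0) %*% P
  Fm <- Fm / sum(Fm)
  visit <- as.vector(Matrix::colSums(Fm))
  states <- .stateFrame(mx)
  names(visit) <- .stateIds(states)
  new("FlowDistribution", states = states, visitRates = visit,
      transition = P, flow = Fm, relaxRate = relaxRate,
      teleportRate = teleportRate, iterations = iter, residual = resid)
}

# core codelength computation from flow triplets and module statistics;
# q = per-module exit flow, pm = per-module visit-rate sum, pn = per-state
# visit rates
.codelengthTerms <- function(q, pm, pn) {
  qtot <- sum(q)
  index <- .plogp(qtot) - sum(.plogp(q))
  module <- sum(.plogp(q + pm)) - sum(.plogp(q)) - sum(.plogp(pn))
  new("MapEquationTerms", index = index, module = module,
      total = index + module)
}

# exit flow and flow sum per module for a given assignment
.moduleStats <- function(flowT, pn, m) {
  nMod <- max(m)
  cross <- m[flowT$i] != m[flowT$j]
  q <- vapply(seq_len(nMod), function(k) 0, numeric(1))
  if (any(cross)) {
    agg <- tapply(flowT$x[cross], m[flowT$i[cross]], sum)
    q[as.integer(names(agg))] <- agg
  }
  pm <- as.vector(tapply(pn, factor(m, levels = seq_len(nMod)), sum))
  list(q = q, pm = pm)
}

# sparse flow matrix -> triplet list without the diagonal
.flowTriplets <- function(Fm) {
  Ft <- as(Fm, "TsparseMatrix")
  keep <- Ft@i != Ft@j & Ft@x > 0
  list(i = Ft@i[keep] + 1L, j = Ft@j[keep] + 1L, x = Ft@x[keep])
}

#' @describeIn codelength codelength of a state-node partition under a flow
#'   distribution. \code{assignment} is an integer community id per state
#'   node (in the order of \code{object@states}).
#' @param assignment integer vector of community ids.
#' @export
setMethod("codelength", "FlowDistribution", function(object, assignment) {
  stopifnot(length(assignment) == nrow(object@states))
  m <- as.integer(factor(assignment))
  ft <- .flowTriplets(object@flow)
  st <- .moduleStats(ft, object@visitRates, m)
  .codelengthTerms(st$q, st$pm, object@visitRates)
})

#' @describeIn codelength stored codelength of a detected partition.
#' @export
setMethod("codelength", "MultiplexPartition", function(object) object@codelength)

#' @describeIn visitRates recorded visit rates of a flow distribution.
#' @export
setMethod("visitRates", "FlowDistribution", function(x) x@visitRates)

#' @describeIn visitRates visit rates stored with a partition.
#' @export
setMethod("visitRates", "MultiplexPartition", function(x) x@visitRates)

setMethod("show", "MapEquationTerms", function(object) {
  cat(sprintf("MapEquationTerms: L = %.6f bits (index %.6f + modules %.6f)\n",
              object@total, object@index, object@module))
})

setMethod("show", "FlowDistribution", function(object) {
  cat(sprintf("FlowDistribution: %d state nodes, relax rate %.2f, teleport %.2f\n",
              nrow(object@states), object@relaxRate, object@teleportRate))
  cat(sprintf("  converged in %d iterations (residual %.3g)\n",
              object@iterations, object@residual))
})
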