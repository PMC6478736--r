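# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (dense matrices, explicit loops,
# enumeration) and share no code with the package internals they check.

# ---- fixture builders ----

cliqueEdges <- function(v) t(combn(v, 2))

makeLayer <- function(name, edgeMat, nodes = unique(c(edgeMat))) {
  diseaseLayer(name, nodes,
               data.frame(from = edgeMat[, 1], to = edgeMat[, 2]))
}

# one-layer multiplex from an edge matrix
makeMx1 <- function(edgeMat) {
  suppressMessages(assembleMultiplex(list(makeLayer("g", edgeMat))))
}

makeMx <- function(...) {
  suppressMessages(assembleMultiplex(list(...)))
}

# random connected labelled graph on n nodes (node names n01...)
randomConnectedGraph <- function(n, p = 0.4) {
  repeat {
    full <- t(combn(sprintf("n%02d", seq_len(n)), 2))
    keep <- runif(nrow(full)) < p
    if (sum(keep) < 1) next
    g <- igraph::graph_from_edgelist(full[keep, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) == n && igraph::count_components(g) == 1)
      return(full[keep, , drop = FALSE])
  }
}

# all connected labelled graphs on n nodes, as a list of edge matrices
allConnectedGraphs <- function(n) {
  full <- t(combn(sprintf("n%02d", seq_len(n)), 2))
  nE <- nrow(full)
  out <- list()
  for (mask in seq_len(2^nE) - 1L) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(nE) - 1L)))
    if (sum(keep) < n - 1) next
    em <- full[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
    if (igraph::vcount(g) == n && igraph::count_components(g) == 1)
      out[[length(out) + 1L]] <- em
  }
  out
}

# all set partitions of 1..n (restricted-growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxUsed) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (b in seq_len(maxUsed + 1L))
      rec(c(prefix, b), max(maxUsed, b))
  }
  rec(integer(), 0L)
  out
}

# ---- dense flow oracle ----

# stationary flow of the relax-rate walker by dense eigen-decomposition;
# mirrors the stated transition rule with explicit loops
oracleFlow <- function(mx, r, tau = 0.15) {
  ds <- diseases(mx)
  n <- length(ds); L <- nLayers(mx)
  nS <- n * L
  adj <- lapply(mx@layers, function(ly) {
    A <- matrix(0, n, n, dimnames = list(ds, ds))
    e <- ly@edges
    for (row in seq_len(nrow(e))) {
      A[e$from[row], e$to[row]] <- 1
      A[e$to[row], e$from[row]] <- 1
    }
    A
  })
  deg <- vapply(adj, rowSums, numeric(n))
  deg <- matrix(deg, nrow = n)
  ktot <- rowSums(deg)
  P <- matrix(0, nS, nS)
  for (a in seq_len(L)) for (u in seq_len(n)) {
    s <- (a - 1L) * n + u
    re <- if (deg[u, a] > 0) r else 1
    if (deg[u, a] > 0)
      for (v in which(adj[[a]][u, ] > 0))
        P[s, (a - 1L) * n + v] <- P[s, (a - 1L) * n + v] + (1 - re) / deg[u, a]
    for (b in seq_len(L))
      for (v in which(adj[[b]][u, ] > 0))
        P[s, (b - 1L) * n + v] <- P[s, (b - 1L) * n + v] + re / ktot[u]
  }
  M <- tau / nS + (1 - tau) * P
  ev <- eigen(t(M))
  i <- which.min(abs(ev$values - 1))
  pi0 <- Re(ev$vectors[, i])
  pi0 <- pi0 / sum(pi0)
  Fm <- diag(pi0) %*% P
  Fm <- Fm / sum(Fm)
  list(pi = pi0, flow = Fm, visit = colSums(Fm))
}

# ---- naive map-equation oracle ----

# codelength of assignment m from a dense flow matrix and visit rates,
# written directly from the two-level map equation
oracleCodelength <- function(Fm, p, m) {
  H <- function(w) {
    w <- w[w > 0]
    if (!length(w)) return(0)
    w <- w / sum(w)
    -sum(w * log2(w))
  }
  mods <- sort(unique(m))
  q <- vapply(mods, function(k)
    sum(Fm[m == k, m != k, drop = FALSE]), numeric(1))
  qtot <- sum(q)
  idx <- if (qtot > 0) qtot * H(q) else 0
  modTerm <- 0
  for (i in seq_along(mods)) {
    w <- c(q[i], p[m == mods[i]])
    modTerm <- modTerm + sum(w) * H(w)
  }
  idx + modTerm
}

# exhaustive minimum codelength over all partitions of the states
oracleMinCodelength <- function(Fm, p) {
  parts <- allPartitions(length(p))
  best <- Inf
  for (m in parts) best <- min(best, oracleCodelength(Fm, p, m))
  best
}

# ---- misc oracles ----

# NMI from the contingency table, direct formula
oracleNMI <- function(x, y) {
  ct <- table(x, y)
  pxy <- ct / sum(ct)
  px <- rowSums(pxy); py <- colSums(pxy)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  e <- outer(px, py)
  sel <- pxy > 0
  mi <- sum(pxy[sel] * log2(pxy[sel] / e[sel]))
  2 * mi / (ent(px) + ent(py))
}

# transitive-closure ancestors by boolean matrix powers
oracleAncestors <- function(parentList, term) {
  terms <- names(parentList)
  A <- matrix(FALSE, length(terms), length(terms),
              dimnames = list(terms, terms))
  for (t in terms) A[t, parentList[[t]]] <- TRUE
  R <- A | diag(TRUE, length(terms))
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  terms[R[term, ]]
}

# brute-force evaluator of the ancestor-weighted gene-set similarity
oracleBPSimilarity <- function(setA, setB, parentList, geneTerms) {
  closure <- function(g) {
    ts <- geneTerms[[g]]
    unique(unlist(lapply(ts, oracleAncestors, parentList = parentList)))
  }
  A <- setA[vapply(setA, function(g) length(geneTerms[[g]]) > 0, logical(1))]
  B <- setB[vapply(setB, function(g) length(geneTerms[[g]]) > 0, logical(1))]
  if (!length(A) || !length(B)) return(NA_real_)
  simDir <- function(G, S) {
    profS <- lapply(S, closure)
    mean(vapply(G, function(g) {
      tg <- closure(g)
      w <- vapply(tg, function(t)
        mean(vapply(profS, function(ts) t %in% ts, logical(1))), numeric(1))
      sum(w) / length(tg)
    }, numeric(1)))
  }
  (simDir(A, B) + simDir(B, A)) / 2
}

# shared-item count between two diseases by direct set intersection
oracleSharedCount <- function(assoc, d1, d2) {
  r <- assoc@records
  length(intersect(r$item[r$disease == d1], r$item[r$disease == d2]))
}
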