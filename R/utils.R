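# Internal helpers.

# canonical key for an unordered disease pair
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# normalize identifiers: trim whitespace, case-fold
.normId <- function(x) {
  tolower(trimws(x))
}

# x * log2(x) with 0 log 0 = 0
.plogp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# state-node labels "<disease>|<layer>"
.stateIds <- function(states) {
  paste(states$disease, states$layer, sep = "|")
}

# degree of every node of a layer (named, over the layer's node set)
.layerDegree <- function(layer) {
  deg <- setNames(rep(0L, length(layer@nodes)), layer@nodes)
  if (nrow(layer@edges)) {
    t1 <- table(c(layer@edges$from, layer@edges$to))
    deg[names(t1)] <- as.integer(t1)
  }
  deg
}

# igraph object of a layer (unweighted, keeps isolated nodes)
.layerGraph <- function(layer) {
  igraph::graph_from_data_frame(layer@edges[, c("from", "to")],
                                directed = FALSE, vertices = layer@nodes)
}

# all unordered pairs of a character vector, as a 2-column matrix
.allPairs <- function(x) {
  if (length(x) < 2L) return(matrix(character(), ncol = 2))
  t(combn(sort(x), 2L))
}
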