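# Bipartite projection, multiplex assembly and the multilayer edge-list
# format.

#' Construct a disease layer from an edge table
#'
#' @param name layer name.
#' @param nodes character vector of hosted diseases.
#' @param edges \code{data.frame} with columns \code{from}, \code{to} and
#'   optionally \code{shared} (defaults to 1). Edges are canonicalized to
#'   \code{from < to} and deduplicated.
#' @return a [DiseaseLayer-class].
#' @export
diseaseLayer <- function(name, nodes, edges) {
  nodes <- sort(unique(.normId(nodes)))
  if (is.null(edges) || !nrow(edges)) {
    e <- data.frame(from = character(), to = character(), shared = integer())
  } else {
    from <- .normId(as.character(edges$from))
    to <- .normId(as.character(edges$to))
    shared <- if ("shared" %in% colnames(edges)) as.integer(edges$shared)
              else rep(1L, length(from))
    e <- data.frame(from = pmin(from, to), to = pmax(from, to),
                    shared = shared, stringsAsFactors = FALSE)
    e <- e[!duplicated(paste(e$from, e$to, sep = "\r")), , drop = FALSE]
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
  }
  new("DiseaseLayer", name = name, nodes = nodes, edges = e)
}

#' Project bipartite associations onto the disease component
#'
#' Links two diseases iff they share at least one item; the edge's
#' \code{shared} count is the size of the shared-item set. Diseases that
#' share no item with anyone remain isolated nodes of the layer.
#'
#' @param assoc a non-empty [BipartiteAssociations-class].
#' @param name layer name (defaults to \code{"genotype"} for gene
#'   associations and \code{"phenotype"} for symptom associations).
#' @return a [DiseaseLayer-class].
#' @examples
#' a <- bipartiteAssociations(c("D1", "D1", "D2", "D3"),
#'                            c("g1", "g2", "g2", "g3"), "gene")
#' projectLayer(a)
#' @export
projectLayer <- function(assoc, name = NULL) {
  stopifnot(is(assoc, "BipartiteAssociations"))
  rec <- assoc@records
  if (!nrow(rec)) stop("cannot project an empty association set")
  if (is.null(name))
    name <- if (assoc@kind == "gene") "genotype" else "phenotype"
  ds <- sort(unique(rec$disease))
  it <- sort(unique(rec$item))
  M <- sparseMatrix(i = match(rec$disease, ds), j = match(rec$item, it),
                    x = 1, dims = c(length(ds), length(it)))
  S <- tcrossprod(M)            # shared-item counts
  S <- as(triu(S, k = 1), "TsparseMatrix")
  edges <- data.frame(from = ds[S@i + 1L], to = ds[S@j + 1L],
                      shared = as.integer(S@x), stringsAsFactors = FALSE)
  out <- diseaseLayer(name, ds, edges)
  message(sprintf("projectLayer[%s]: %d diseases, %d edges, %d isolated",
                  name, length(ds), nrow(out@edges),
                  sum(.layerDegree(out) == 0)))
  out
}

#' Assemble disease layers into a multiplex network
#'
#' The disease universe is the union of nodes with degree >= 1 in at least
#' one layer; diseases isolated in every layer are removed (their count is
#' reported). Each layer is re-hosted on the universe so that a disease with
#' no edges in one layer appears as an isolated node of that layer.
#'
#' @param layers list of [DiseaseLayer-class] objects (at least one; two for
#'   the genotype/phenotype diseasome).
#' @return a [MultiplexNetwork-class].
#' @export
assembleMultiplex <- function(layers) {
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, is, logical(1), "DiseaseLayer")))
  allNodes <- sort(unique(unlist(lapply(layers, slot, "nodes"))))
  deg <- setNames(rep(0L, length(allNodes)), allNodes)
  for (ly in layers) {
    d <- .layerDegree(ly)
    deg[names(d)] <- deg[names(d)] + d
  }
  universe <- allNodes[deg > 0]
  if (!length(universe)) stop("empty disease universe: no layer has edges")
  nRemoved <- length(allNodes) - length(universe)
  message(sprintf("assembleMultiplex: %d diseases in universe, %d isolated-in-all-layers removed",
                  length(universe), nRemoved))
  hosted <- lapply(layers, function(ly)
    diseaseLayer(ly@name, universe, ly@edges))
  names(hosted) <- vapply(hosted, slot, character(1), "name")
  if (anyDuplicated(names(hosted))) stop("layer names must be unique")
  new("MultiplexNetwork", diseases = universe, layers = hosted)
}

#' Edges present in every layer
#'
#' The "overlapping links" of the multiplex: disease pairs connected in all
#' layers (for the diseasome, pairs sharing at least one gene and at least
#' one symptom). Invariant under layer order.
#'
#' @param mx a [MultiplexNetwork-class].
#' @return \code{data.frame} with columns \code{from}, \code{to}.
#' @export
edgeOverlap <- function(mx) {
  stopifnot(is(mx, "MultiplexNetwork"))
  keys <- lapply(mx@layers, function(ly) .pairKey(ly@edges$from, ly@edges$to))
  common <- Reduce(intersect, keys)
  if (!length(common))
    return(data.frame(from = character(), to = character()))
  parts <- do.call(rbind, strsplit(sort(common), "\r", fixed = TRUE))
  data.frame(from = parts[, 1], to = parts[, 2], stringsAsFactors = FALSE)
}

#' Write a multiplex network as a multilayer edge list
#'
#' Plain-text format: a comment header \code{# layers: <name> <name> ...}
#' followed by lines \code{layer_index TAB disease_i TAB disease_j TAB
#' shared_count} with 1-based layer indices and \code{i < j}
#' lexicographically.
#'
#' @param mx a [MultiplexNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMultiplex <- function(mx, path) {
  stopifnot(is(mx, "MultiplexNetwork"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# layers:", paste(names(mx@layers), collapse = " ")), con)
  for (k in seq_along(mx@layers)) {
    e <- mx@layers[[k]]@edges
    if (nrow(e))
      writeLines(paste(k, e$from, e$to, e$shared, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a multilayer edge list
#'
#' Accepts both 3-column (\code{layer from to}) and 4-column (\code{layer
#' from to shared}) lines; a \code{# layers:} comment names the layers,
#' otherwise they are named \code{layer1}, \code{layer2}, ...
#'
#' @param path path to the edge-list file.
#' @return a [MultiplexNetwork-class].
#' @export
readMultiplex <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  layerNames <- NULL
  hdr <- grep("^#\\s*layers:", lines, value = TRUE)
  if (length(hdr))
    layerNames <- strsplit(trimws(sub("^#\\s*layers:", "", hdr[1])),
                           "\\s+")[[1]]
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!length(fields) || any(nf < 3L | nf > 4L))
    stop("multilayer edge-list lines must have 3 or 4 tab-separated columns")
  idx <- as.integer(vapply(fields, `[`, character(1), 1L))
  from <- vapply(fields, `[`, character(1), 2L)
  to <- vapply(fields, `[`, character(1), 3L)
  shared <- rep(1L, length(fields))
  shared[nf == 4L] <- as.integer(vapply(fields[nf == 4L], `[`,
                                        character(1), 4L))
  nL <- max(idx)
  if (is.null(layerNames)) layerNames <- paste0("layer", seq_len(nL))
  if (length(layerNames) < nL)
    stop("edge list references more layers than the header names")
  layers <- lapply(seq_len(nL), function(k) {
    sel <- idx == k
    diseaseLayer(layerNames[k], unique(c(from[sel], to[sel])),
                 data.frame(from = from[sel], to = to[sel],
                            shared = shared[sel]))
  })
  assembleMultiplex(layers)
}

# ---- accessors and show methods ----

#' @describeIn diseases universe of a multiplex network.
#' @export
setMethod("diseases", "MultiplexNetwork", function(x) x@diseases)

#' @describeIn layerNames layer names of a multiplex network.
#' @export
setMethod("layerNames", "MultiplexNetwork", function(x) names(x@layers))

#' @describeIn nLayers number of layers of a multiplex network.
#' @export
setMethod("nLayers", "MultiplexNetwork", function(x) length(x@layers))

#' @describeIn edges edge table of a disease layer.
#' @export
setMethod("edges", "DiseaseLayer", function(x) x@edges)

setMethod("show", "BipartiteAssociations", function(object) {
  cat(sprintf("BipartiteAssociations (%s): %d associations, %d diseases, %d items\n",
              object@kind, nrow(object@records),
              length(unique(object@records$disease)),
              length(unique(object@records$item))))
})

setMethod("show", "DiseaseLayer", function(object) {
  cat(sprintf("DiseaseLayer '%s': %d nodes, %d edges (%d isolated)\n",
              object@name, length(object@nodes), nrow(object@edges),
              sum(.layerDegree(object) == 0)))
})

setMethod("show", "MultiplexNetwork", function(object) {
  cat(sprintf("MultiplexNetwork: %d diseases, %d layers\n",
              length(object@diseases), length(object@layers)))
  for (ly in object@layers)
    cat(sprintf("  %s: %d edges\n", ly@name, nrow(ly@edges)))
})
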