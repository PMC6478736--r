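# Disease-pair similarity measures: relative-risk comorbidity, gene-overlap
# Jaccard, ontology ancestor-based gene-set similarity and semantic-matrix
# lookup.

#' Allowed annotation evidence codes
#'
#' Experimental and computational-analysis evidence codes admitted for
#' gene-term annotations: EXP, IPI, IDA, IMP, IGI, IEP, ISS, ISA, ISM, ISO.
#'
#' @return character vector of codes.
#' @export
allowedEvidenceCodes <- function() {
  c("EXP", "IPI", "IDA", "IMP", "IGI", "IEP", "ISS", "ISA", "ISM", "ISO")
}

#' Relative-risk comorbidity score
#'
#' \deqn{RR_{AB} = \frac{C_{AB}/N}{P_A P_B / N^2}}
#' the observed co-occurrence of two diseases relative to the expectation if
#' they were independent. RR > 1 indicates comorbidity. Vectorized; invariant
#' under uniform scaling of all counts.
#'
#' @param cAB observed co-occurrence count(s).
#' @param pA,pB prevalence of each disease (must be positive).
#' @param n population size (positive).
#' @return numeric relative risk(s).
#' @examples
#' relativeRisk(10, 100, 50, 1000)  # 2.0
#' @export
relativeRisk <- function(cAB, pA, pB, n) {
  if (any(n <= 0)) stop("population size must be positive")
  if (any(pA <= 0) || any(pB <= 0)) stop("prevalence must be positive")
  (cAB / n) / (pA * pB / n^2)
}

#' Log10 relative risk for reporting
#'
#' RR spans orders of magnitude depending on prevalence, so the base-10
#' logarithm is used when values are reported or visualized.
#'
#' @inheritParams relativeRisk
#' @return numeric log10 relative risk(s) (\code{-Inf} for RR = 0).
#' @export
logRelativeRisk <- function(cAB, pA, pB, n) {
  log10(relativeRisk(cAB, pA, pB, n))
}

#' Construct a comorbidity table
#'
#' @param counts \code{data.frame} (\code{a}, \code{b}, \code{count}) of
#'   pairwise co-occurrence counts (pairs canonicalized to \code{a < b}).
#' @param prevalence named numeric vector of per-disease prevalence.
#' @param population population size N.
#' @return a [ComorbidityTable-class].
#' @export
comorbidityTable <- function(counts, prevalence, population) {
  prevalence <- setNames(as.numeric(prevalence), .normId(names(prevalence)))
  if (nrow(counts)) {
    a <- .normId(as.character(counts$a)); b <- .normId(as.character(counts$b))
    counts <- data.frame(a = pmin(a, b), b = pmax(a, b),
                         count = as.numeric(counts$count),
                         stringsAsFactors = FALSE)
    counts <- counts[!duplicated(paste(counts$a, counts$b, sep = "\r")), ,
                     drop = FALSE]
    rownames(counts) <- NULL
  }
  new("ComorbidityTable", counts = counts, prevalence = prevalence,
      population = population)
}

#' Read comorbidity aggregates from TSV tables
#'
#' @param pairPath TSV with columns \code{a}, \code{b}, \code{count}
#'   (header required).
#' @param prevalencePath TSV with columns \code{disease},
#'   \code{prevalence}.
#' @param population population size N.
#' @return a [ComorbidityTable-class].
#' @export
readComorbidity <- function(pairPath, prevalencePath, population) {
  pairs <- read.delim(pairPath, stringsAsFactors = FALSE)
  prev <- read.delim(prevalencePath, stringsAsFactors = FALSE)
  comorbidityTable(pairs, setNames(prev$prevalence, prev$disease), population)
}

#' Relative risk of disease pairs from a comorbidity table
#'
#' Pairs in which either disease lacks a prevalence entry are unscorable and
#' return \code{NA} (missing is distinct from dissimilar); pairs of covered
#' diseases absent from the count table have observed co-occurrence 0 and
#' RR 0.
#'
#' @param ct a [ComorbidityTable-class].
#' @param a,b character vectors of disease identifiers (recycled).
#' @return numeric vector of relative risks with \code{NA} for unscorable
#'   pairs.
#' @export
comorbidityRR <- function(ct, a, b) {
  stopifnot(is(ct, "ComorbidityTable"))
  a <- .normId(a); b <- .normId(b)
  key <- .pairKey(a, b)
  tabKey <- .pairKey(ct@counts$a, ct@counts$b)
  cAB <- ct@counts$count[match(key, tabKey)]
  cAB[is.na(cAB)] <- 0
  known <- a %in% names(ct@prevalence) & b %in% names(ct@prevalence)
  out <- rep(NA_real_, length(key))
  if (any(known))
    out[known] <- relativeRisk(cAB[known], ct@prevalence[a[known]],
                               ct@prevalence[b[known]], ct@population)
  unname(out)
}

#' Gene-overlap Jaccard index of two gene sets
#'
#' \deqn{J_{AB} = |g_A \cap g_B| / |g_A \cup g_B|}
#' Returns \code{NA} when both sets are empty (undefined, distinct from 0).
#'
#' @param gA,gB character vectors of gene identifiers.
#' @return numeric in [0, 1], or \code{NA} for the empty-empty case.
#' @examples
#' geneJaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
geneJaccard <- function(gA, gB) {
  gA <- unique(gA); gB <- unique(gB)
  un <- length(union(gA, gB))
  if (un == 0L) return(NA_real_)
  length(intersect(gA, gB)) / un
}

# ---- annotation hierarchy ----

#' Construct an annotation DAG
#'
#' @param parents either a named list (term -> parent terms) or a
#'   two-column \code{data.frame} (\code{child}, \code{parent}); terms
#'   appearing only as parents are added as roots.
#' @param annotations \code{data.frame} with columns \code{gene},
#'   \code{term}, \code{evidence}. Evidence codes outside
#'   [allowedEvidenceCodes()] are rejected; use [readAnnotations()] to
#'   filter raw tables.
#' @param namespace namespace label (default \code{"BP"}).
#' @return an [AnnotationDAG-class].
#' @export
annotationDAG <- function(parents, annotations, namespace = "BP") {
  if (is.data.frame(parents)) {
    ch <- as.character(parents[[1]]); pa <- as.character(parents[[2]])
    terms <- unique(c(ch, pa))
    plist <- split(pa, factor(ch, levels = terms))
    plist <- lapply(plist, as.character)
  } else {
    plist <- lapply(parents, as.character)
    terms <- unique(c(names(plist), unlist(plist, use.names = FALSE)))
    missing <- setdiff(terms, names(plist))
    plist[missing] <- list(character())
    plist <- plist[terms]
  }
  ann <- data.frame(gene = as.character(annotations$gene),
                    term = as.character(annotations$term),
                    evidence = as.character(annotations$evidence),
                    stringsAsFactors = FALSE)
  ann <- ann[!duplicated(ann), , drop = FALSE]
  rownames(ann) <- NULL
  new("AnnotationDAG", parents = plist, annotations = ann,
      namespace = namespace, cache = new.env(parent = emptyenv()))
}

#' Read gene annotations and a term hierarchy from TSV tables
#'
#' The annotation table (GAF-style columns \code{gene}, \code{term},
#' \code{evidence}, \code{namespace}) is filtered to the requested namespace
#' and to the allowed evidence codes; dropped-row counts are reported. The
#' parent table has columns \code{child}, \code{parent}.
#'
#' @param annotationPath,parentPath TSV paths (headers required).
#' @param namespace namespace to keep (default \code{"BP"}).
#' @param evidence evidence codes to keep.
#' @return an [AnnotationDAG-class].
#' @export
readAnnotations <- function(annotationPath, parentPath, namespace = "BP",
                            evidence = allowedEvidenceCodes()) {
  ann <- read.delim(annotationPath, stringsAsFactors = FALSE)
  par <- read.delim(parentPath, stringsAsFactors = FALSE)
  n0 <- nrow(ann)
  if ("namespace" %in% colnames(ann)) ann <- ann[ann$namespace %in% namespace, ]
  nNs <- n0 - nrow(ann)
  ann2 <- ann[ann$evidence %in% evidence, , drop = FALSE]
  message(sprintf("readAnnotations: %d rows; %d outside namespace %s; %d with disallowed evidence codes dropped",
                  n0, nNs, namespace, nrow(ann) - nrow(ann2)))
  annotationDAG(par[, c("child", "parent")], ann2, namespace = namespace)
}

#' Ancestor closure of a term
#'
#' All ancestors of a term through the is-a relation, including the term
#' itself; memoized on the DAG object.
#'
#' @param dag an [AnnotationDAG-class].
#' @param term a term identifier present in the hierarchy.
#' @return character vector of terms.
#' @export
termAncestors <- function(dag, term) {
  stopifnot(is(dag, "AnnotationDAG"))
  if (!term %in% names(dag@parents)) stop("unknown term: ", term)
  memo <- dag@cache
  walk <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    anc <- t
    for (p in dag@parents[[t]]) anc <- union(anc, walk(p))
    memo[[t]] <- anc
    anc
  }
  walk(term)
}

# ancestor-closed annotation profile per gene: named list gene -> term set
.geneProfiles <- function(dag, genes = NULL) {
  ann <- dag@annotations
  if (!is.null(genes)) ann <- ann[ann$gene %in% genes, , drop = FALSE]
  byGene <- split(ann$term, ann$gene)
  lapply(byGene, function(ts)
    unique(unlist(lapply(unique(ts), termAncestors, dag = dag),
                  use.names = FALSE)))
}

#' Ancestor-based gene-set similarity
#'
#' Ranks every term with respect to a gene set by the fraction of the set's
#' genes annotated by the ancestors of that term, and scores a gene against
#' a set as the average of those weights over the gene's ancestor-closed
#' annotation profile:
#' \deqn{sim(g, S) = \sum_{t \in T(g)} w_S(t) / |T(g)|,\quad
#'       w_S(t) = |\{h \in S : t \in T(h)\}| / |S|}
#' where \eqn{T(g)} is the ancestor closure of gene g's annotations. The
#' set-set similarity is the symmetrized mean
#' \eqn{S = [mean_{g \in A} sim(g, B) + mean_{g \in B} sim(g, A)] / 2}.
#' Genes without annotations are ignored; if a set has no annotated gene the
#' pair is unscorable and \code{NA} is returned.
#'
#' @param setA,setB character vectors of gene identifiers.
#' @param dag an [AnnotationDAG-class] (annotations already restricted to
#'   the namespace and evidence codes of interest).
#' @return numeric in [0, 1], or \code{NA} if either set has no annotated
#'   gene.
#' @export
genesetBPSimilarity <- function(setA, setB, dag) {
  prof <- .geneProfiles(dag, unique(c(setA, setB)))
  A <- intersect(unique(setA), names(prof))
  B <- intersect(unique(setB), names(prof))
  if (!length(A) || !length(B)) return(NA_real_)
  simDir <- function(G, S) {
    termsS <- unlist(prof[S], use.names = FALSE)
    wS <- table(termsS) / length(S)
    mean(vapply(G, function(g) {
      tg <- prof[[g]]
      sum(wS[match(tg, names(wS))], na.rm = TRUE) / length(tg)
    }, numeric(1)))
  }
  (simDir(A, B) + simDir(B, A)) / 2
}

# ---- semantic similarity matrix ----

#' Construct a semantic similarity matrix
#'
#' @param values symmetric numeric matrix in [0, 1] with disease dimnames
#'   and unit diagonal.
#' @return a [SemanticMatrix-class].
#' @export
semanticMatrix <- function(values) {
  rownames(values) <- .normId(rownames(values))
  colnames(values) <- .normId(colnames(values))
  new("SemanticMatrix", values = values)
}

#' Read a semantic similarity matrix from a square TSV
#'
#' Expects a header row of disease identifiers and a first column of
#' disease identifiers.
#'
#' @param path TSV path.
#' @return a [SemanticMatrix-class].
#' @export
readSemanticMatrix <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  semanticMatrix(as.matrix(tab))
}

#' Interpretive band of a semantic-similarity score
#'
#' Scores below 0.3 are uninformative, scores in [0.3, 0.6] informative,
#' scores above 0.6 significantly functionally similar.
#'
#' @param x numeric scores.
#' @return character vector of band labels (\code{NA} propagates).
#' @export
semanticBand <- function(x) {
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & x < 0.3] <- "uninformative"
  out[!is.na(x) & x >= 0.3 & x <= 0.6] <- "informative"
  out[!is.na(x) & x > 0.6] <- "significantly functionally similar"
  out
}

#' Look up semantic similarity of disease pairs
#'
#' Pairs outside the matrix coverage are missing (\code{NA} value and band)
#' and must be excluded from statistics, never treated as zero.
#'
#' @param m a [SemanticMatrix-class].
#' @param a,b character vectors of disease identifiers (recycled).
#' @return \code{data.frame} with columns \code{a}, \code{b}, \code{value},
#'   \code{band}.
#' @export
semanticSimilarity <- function(m, a, b) {
  stopifnot(is(m, "SemanticMatrix"))
  a <- .normId(a); b <- .normId(b)
  k <- pmax(length(a), length(b))
  a <- rep_len(a, k); b <- rep_len(b, k)
  v <- rep(NA_real_, k)
  ok <- a %in% rownames(m@values) & b %in% rownames(m@values)
  v[ok] <- m@values[cbind(a[ok], b[ok])]
  data.frame(a = a, b = b, value = v, band = semanticBand(v),
             stringsAsFactors = FALSE)
}

setMethod("show", "ComorbidityTable", function(object) {
  cat(sprintf("ComorbidityTable: %d pair counts, %d diseases with prevalence, N = %g\n",
              nrow(object@counts), length(object@prevalence),
              object@population))
})

setMethod("show", "AnnotationDAG", function(object) {
  cat(sprintf("AnnotationDAG (%s): %d terms, %d annotations over %d genes\n",
              object@namespace, length(object@parents),
              nrow(object@annotations),
              length(unique(object@annotations$gene))))
})

setMethod("show", "SemanticMatrix", function(object) {
  cat(sprintf("SemanticMatrix: %d diseases covered\n", nrow(object@values)))
})
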