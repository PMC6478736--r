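# Loading and mapping bipartite disease-item associations.

#' Construct a BipartiteAssociations object
#'
#' Identifiers are whitespace-trimmed and case-folded; duplicate pairs are
#' merged.
#'
#' @param disease,item character vectors of equal length.
#' @param kind \code{"gene"} or \code{"symptom"}.
#' @return a [BipartiteAssociations-class].
#' @examples
#' bipartiteAssociations(c("D1", "D1", "D2"), c("g1", "g2", "g1"), "gene")
#' @export
bipartiteAssociations <- function(disease, item, kind = c("gene", "symptom")) {
  kind <- match.arg(kind)
  stopifnot(length(disease) == length(item))
  disease <- .normId(as.character(disease))
  item <- .normId(as.character(item))
  if (any(!nzchar(disease)) || any(!nzchar(item)))
    stop("empty disease or item identifier after whitespace normalization")
  keep <- !duplicated(paste(disease, item, sep = "\r"))
  rec <- data.frame(disease = disease[keep], item = item[keep],
                    stringsAsFactors = FALSE)
  rec <- rec[order(rec$disease, rec$item), , drop = FALSE]
  rownames(rec) <- NULL
  new("BipartiteAssociations", kind = kind, records = rec)
}

#' Read a bipartite association table
#'
#' Reads a two-column TSV (\code{disease_id TAB item_id}); lines starting
#' with \code{#} are treated as header/comment lines. Rows with a column
#' count other than two raise a parse error naming the offending line.
#' Duplicate pairs are merged and the duplicate count reported.
#'
#' @param path path to the TSV file.
#' @param kind \code{"gene"} or \code{"symptom"}.
#' @return a [BipartiteAssociations-class].
#' @export
readBipartite <- function(path, kind = c("gene", "symptom")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  if (!any(keep)) stop("empty association file: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(keep)[which(nf != 2L)[1L]]
    stop("malformed row (expected 2 tab-separated columns) at line ", bad,
         " of ", path)
  }
  disease <- vapply(fields, `[`, character(1), 1L)
  item <- vapply(fields, `[`, character(1), 2L)
  out <- bipartiteAssociations(disease, item, kind)
  nDup <- length(disease) - nrow(out@records)
  message(sprintf("readBipartite: %d rows, %d duplicate pairs merged, %d %s associations over %d diseases",
                  length(disease), nDup, nrow(out@records), kind,
                  length(unique(out@records$disease))))
  out
}

#' Read an identifier crosswalk table
#'
#' Two-column TSV mapping source disease identifiers to unified disease
#' identifiers (many-to-one allowed); \code{#} lines are skipped. A source
#' identifier mapping to more than one unified identifier is an error: the
#' mapping must be a function.
#'
#' @param path path to the TSV file.
#' @return named character vector (source -> unified).
#' @export
readCrosswalk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) && any(lengths(fields) != 2L))
    stop("crosswalk rows must have exactly 2 tab-separated columns")
  src <- .normId(vapply(fields, `[`, character(1), 1L))
  dst <- .normId(vapply(fields, `[`, character(1), 2L))
  dup <- duplicated(src)
  if (any(dup)) {
    conflict <- tapply(dst, src, function(v) length(unique(v)) > 1L)
    if (any(conflict))
      stop("crosswalk is not a function: source ids map to several unified ids: ",
           paste(utils::head(names(conflict)[conflict], 5), collapse = ", "))
    src <- src[!dup]; dst <- dst[!dup]
  }
  setNames(dst, src)
}

#' Map association disease identifiers through a crosswalk
#'
#' Replaces source disease identifiers by unified identifiers (merging the
#' item sets of sources that map to the same unified disease) and
#' deduplicates. Unmapped diseases are dropped when \code{dropUnmapped} is
#' set and passed through verbatim otherwise.
#'
#' @param assoc a [BipartiteAssociations-class].
#' @param xw named character vector (source -> unified), as returned by
#'   [readCrosswalk()].
#' @param dropUnmapped drop records whose disease has no crosswalk entry.
#' @return a [BipartiteAssociations-class] on unified identifiers.
#' @export
applyCrosswalk <- function(assoc, xw, dropUnmapped = FALSE) {
  stopifnot(is(assoc, "BipartiteAssociations"))
  rec <- assoc@records
  names(xw) <- .normId(names(xw))
  xw[] <- .normId(xw)
  hit <- rec$disease %in% names(xw)
  mapped <- rec$disease
  mapped[hit] <- unname(xw[rec$disease[hit]])
  if (dropUnmapped) {
    nDrop <- length(unique(rec$disease[!hit]))
    rec <- rec[hit, , drop = FALSE]
    mapped <- mapped[hit]
    message(sprintf("applyCrosswalk: dropped %d unmapped diseases, %d records remain",
                    nDrop, nrow(rec)))
  }
  if (!nrow(rec))
    return(new("BipartiteAssociations", kind = assoc@kind,
               records = data.frame(disease = character(),
                                    item = character())))
  bipartiteAssociations(mapped, rec$item, assoc@kind)
}

#' Per-disease item sets of an association table
#'
#' @param assoc a [BipartiteAssociations-class].
#' @return named list: disease -> character vector of items (e.g. gene
#'   sets).
#' @export
geneSets <- function(assoc) {
  stopifnot(is(assoc, "BipartiteAssociations"))
  split(assoc@records$item, assoc@records$disease)
}
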