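# Global pairwise alignment, identities, edit distances, the all-vs-all
# similarity graph and best-hit search.

#' Alignment scoring parameters
#'
#' Defaults mimic the usual amplicon-clustering aligner settings:
#' match +2, mismatch -4, gap open -20, gap extend -2 (a gap of length k
#' costs `gapOpen + k * gapExtend`).
#'
#' @param match,mismatch per-column match reward / mismatch penalty.
#' @param gapOpen,gapExtend affine gap parameters (non-positive).
#' @return a named list of class `align_scoring`.
#' @export
alignScoring <- function(match = 2, mismatch = -4, gapOpen = -20,
                         gapExtend = -2) {
  stopifnot(match > mismatch, gapOpen <= 0, gapExtend <= 0)
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend), class = "align_scoring")
}

.as_seq <- function(x) {
  if (methods::is(x, "AmpliconSet")) as.character(ampliconSequences(x))
  else if (methods::is(x, "XStringSet") || methods::is(x, "XString"))
    as.character(x)
  else as.character(x)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch / Gotoh global alignment with affine gap costs and a
#' fixed traceback tie-break (diagonal over up over left), so the
#' reported alignment is deterministic. Terminal gaps are scored like
#' internal ones.
#'
#' @param a,b non-empty DNA strings (or length-1 `XString`s).
#' @param scoring an [alignScoring()] object.
#' @return list of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`, `columns`,
#'   `matches`.
#' @examples
#' aln <- globalAlign("AAAAA", "AAAA")
#' aln$columns; aln$matches
#' @export
globalAlign <- function(a, b, scoring = alignScoring()) {
  a <- .as_seq(a); b <- .as_seq(b)
  stopifnot(length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("global alignment requires non-empty sequences")
  res <- cpp_nw_align(a, b, scoring$match, scoring$mismatch,
                      scoring$gapOpen, scoring$gapExtend)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment:", x$columns, "columns,", x$matches,
      sprintf("matches (identity %.4f), score %g\n",
              x$matches / x$columns, x$score))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' All-columns identity of an alignment
#'
#' Matching columns divided by total alignment columns, with terminal
#' gap columns counted (the `iddef 1` convention of common amplicon
#' aligners). This is the only identity definition the package uses.
#'
#' @param alignment a `pairwise_alignment` from [globalAlign()].
#' @return identity fraction in `[0, 1]`.
#' @export
alignmentIdentity <- function(alignment) {
  if (is.null(alignment$columns) || alignment$columns == 0)
    stop("alignment has zero columns")
  alignment$matches / alignment$columns
}

#' Pairwise identity of two sequences
#'
#' Convenience wrapper: align globally, return the all-columns identity.
#' The pair is canonically oriented (lexicographically smaller sequence
#' first) before aligning, so `pairIdentity(a, b) == pairIdentity(b, a)`
#' exactly, even when co-optimal alignments differ in match count.
#'
#' @inheritParams globalAlign
#' @return identity fraction in `[0, 1]`.
#' @export
pairIdentity <- function(a, b, scoring = alignScoring()) {
  a <- .as_seq(a); b <- .as_seq(b)
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  alignmentIdentity(globalAlign(a, b, scoring))
}

#' Levenshtein edit distance, optionally banded
#'
#' Number of substitutions plus insertions/deletions separating two
#' sequences. With `maxDist` set, a banded computation is used and
#' `NA` is returned whenever the true distance exceeds `maxDist`.
#'
#' @param a,b character vectors of equal length (pairs are compared
#'   elementwise), or single strings.
#' @param maxDist optional non-negative band limit.
#' @return integer vector of distances; `NA` marks "exceeds maxDist".
#' @examples
#' editDistance("ACGT", "AGT")
#' editDistance("ACGT", "TTTT", maxDist = 2)  # NA: distance is 3
#' @export
editDistance <- function(a, b, maxDist = NULL) {
  a <- .as_seq(a); b <- .as_seq(b)
  if (length(a) != length(b)) stop("a and b must pair up elementwise")
  if (any(nchar(a) == 0) || any(nchar(b) == 0))
    stop("edit distance requires non-empty sequences")
  md <- if (is.null(maxDist)) -1L else as.integer(maxDist)
  if (md < -1L) stop("maxDist must be >= 0")
  d <- cpp_edit_distance(a, b, md)
  d[d < 0L] <- NA_integer_
  d
}

#' Build a sequence similarity network
#'
#' Computes the all-vs-all global-identity graph of an amplicon set: an
#' undirected edge joins every unordered pair with all-columns identity
#' `>= t`. Every amplicon is a node even when isolated. The computation
#' is quadratic in the number of amplicons; an exact banded-edit-distance
#' pre-filter discards pairs that provably cannot reach `t`, but sets
#' beyond `nodeBudget` nodes are refused unless `force = TRUE`.
#'
#' @param amplicons an [AmpliconSet-class] with unique ids.
#' @param t identity threshold in (0, 1]; default 0.97.
#' @param scoring an [alignScoring()] object.
#' @param nodeBudget refuse larger inputs unless forced (default 5000).
#' @param force run regardless of `nodeBudget`.
#' @return a [SimilarityGraph-class].
#' @examples
#' amps <- AmpliconSet(c("ACGTACGTAC", "ACGTACGTAT", "TTTTTTTTTT"),
#'                     ids = c("a", "b", "c"))
#' buildSimilarityGraph(amps, t = 0.9)
#' @export
buildSimilarityGraph <- function(amplicons, t = 0.97,
                                 scoring = alignScoring(),
                                 nodeBudget = 5000, force = FALSE) {
  stopifnot(methods::is(amplicons, "AmpliconSet"), t > 0, t <= 1)
  ids <- ampliconIds(amplicons)
  n <- length(ids)
  if (n > nodeBudget && !force)
    stop("similarity graph over ", n, " amplicons exceeds the node budget (",
         nodeBudget, "); the all-vs-all stage is quadratic -- ",
         "pass force = TRUE to run anyway")
  seqs <- as.character(ampliconSequences(amplicons))
  ed <- cpp_similarity_edges(seqs, t, scoring$match, scoring$mismatch,
                             scoring$gapOpen, scoring$gapExtend)
  id_a <- ids[ed$i]; id_b <- ids[ed$j]
  swap <- id_a > id_b
  tmp <- id_a[swap]; id_a[swap] <- id_b[swap]; id_b[swap] <- tmp
  o <- order(id_a, id_b)
  edges <- data.frame(id_a = id_a[o], id_b = id_b[o],
                      identity = ed$identity[o], stringsAsFactors = FALSE)
  methods::new("SimilarityGraph", nodes = ids, edges = edges, threshold = t)
}

#' Convert a SimilarityGraph to an igraph object
#'
#' @param graph a [SimilarityGraph-class].
#' @return an undirected [igraph::igraph] with an `identity` edge
#'   attribute.
#' @export
asIgraph <- function(graph) {
  stopifnot(methods::is(graph, "SimilarityGraph"))
  g <- igraph::graph_from_data_frame(graph@edges, directed = FALSE,
                                     vertices = data.frame(name = graph@nodes))
  g
}

#' Best reference hit of a query amplicon
#'
#' Scans a reference set by exhaustive global alignment and returns the
#' reference of maximal all-columns identity, provided that identity
#' reaches `floor`; ties go to the lexicographically smallest reference
#' id.
#'
#' @param query a single amplicon (subset of an [AmpliconSet-class] of
#'   length 1) or a DNA string.
#' @param references an [AmpliconSet-class] of reference amplicons.
#' @param floor minimum reportable identity (default 0.70).
#' @param scoring an [alignScoring()] object.
#' @return list with `ref_id` and `identity`, or `NULL` when every
#'   reference is below `floor`.
#' @export
bestHit <- function(query, references, floor = 0.70,
                    scoring = alignScoring()) {
  hits <- bestHits(query, references, floor = floor, scoring = scoring)
  if (is.na(hits$ref_id[1])) return(NULL)
  list(ref_id = hits$ref_id[1], identity = hits$identity[1])
}

#' Best reference hits for many queries
#'
#' @param queries an [AmpliconSet-class] (or character vector) of query
#'   sequences.
#' @inheritParams bestHit
#' @return data.frame with one row per query: `query_id`, `ref_id`,
#'   `identity` (`NA` row when no reference reaches `floor`).
#' @export
bestHits <- function(queries, references, floor = 0.70,
                     scoring = alignScoring()) {
  stopifnot(floor >= 0, floor <= 1)
  if (methods::is(references, "AmpliconSet") && length(references) == 0)
    stop("reference set is empty")
  qseq <- .as_seq(queries)
  qid <- if (methods::is(queries, "AmpliconSet")) ampliconIds(queries)
         else if (!is.null(names(queries))) names(queries)
         else paste0("query", seq_along(qseq))
  rseq <- .as_seq(references)
  rid <- if (methods::is(references, "AmpliconSet")) ampliconIds(references)
         else if (!is.null(names(references))) names(references)
         else paste0("ref", seq_along(rseq))
  if (length(rseq) == 0) stop("reference set is empty")
  idm <- cpp_identity_matrix(qseq, rseq, scoring$match, scoring$mismatch,
                             scoring$gapOpen, scoring$gapExtend)
  # argmax with lexicographic tie-break on reference id
  ord <- order(rid)
  best <- apply(idm[, ord, drop = FALSE], 1L, function(row) {
    k <- which.max(row)  # first maximum in id order
    c(k, row[k])
  })
  ref_id <- rid[ord][best[1L, ]]
  identity <- best[2L, ]
  below <- identity < floor - 1e-9
  data.frame(query_id = qid,
             ref_id = ifelse(below, NA_character_, ref_id),
             identity = ifelse(below, NA_real_, identity),
             stringsAsFactors = FALSE)
}

#' Write an edge list as TSV
#'
#' One undirected edge per line, `id_a` before `id_b` lexicographically,
#' identity printed with 6 decimal places.
#'
#' @param graph a [SimilarityGraph-class] (or a data.frame with columns
#'   `id_a`, `id_b`, `identity`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  e <- if (methods::is(graph, "SimilarityGraph")) graph@edges else graph
  out <- data.frame(id_a = e$id_a, id_b = e$id_b,
                    identity = sprintf("%.6f", e$identity))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
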