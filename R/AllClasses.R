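#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importClassesFrom Biostrings DNAStringSet
#' @useDynLib noveltynet, .registration = TRUE
NULL

#' AmpliconSet: dereplicated amplicons with abundances and origin labels
#'
#' An `AmpliconSet` holds dereplicated marker-gene amplicons: unique DNA
#' sequences, each with a read abundance, an origin label
#' (`"environmental"` or `"reference"`) and, for references, an optional
#' taxonomy string. Sequences are stored as a named
#' [Biostrings::DNAStringSet]; names are the amplicon ids and must be
#' unique.
#'
#' Validity requires: non-empty sequences over the alphabet
#' \{A, C, G, T, N\}; integer abundances >= 1; one origin per amplicon.
#'
#' @slot sequences a [Biostrings::DNAStringSet] named by amplicon id.
#' @slot abundance integer vector of read counts, one per amplicon.
#' @slot origin character vector, each `"environmental"` or `"reference"`.
#' @slot taxonomy character vector (NA where absent).
#'
#' @seealso [AmpliconSet()], [readAmplicons()], [dereplicate()]
#' @aliases AmpliconSet-class
#' @exportClass AmpliconSet
setClass("AmpliconSet",
  representation(
    sequences = "DNAStringSet",
    abundance = "integer",
    origin = "character",
    taxonomy = "character"
  )
)

.valid_amplicon_set <- function(object) {
  msg <- character(0)
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || anyNA(ids) || any(ids == "")))
    msg <- c(msg, "all amplicons must have non-empty ids")
  if (!is.null(ids) && anyDuplicated(ids))
    msg <- c(msg, sprintf(
      "duplicate amplicon ids: %s",
      paste(unique(ids[duplicated(ids)])[seq_len(min(3, sum(duplicated(ids))))],
            collapse = ", ")))
  if (length(object@abundance) != n || length(object@origin) != n ||
      length(object@taxonomy) != n)
    msg <- c(msg, "abundance, origin and taxonomy must match the number of sequences")
  if (anyNA(object@abundance) || any(object@abundance < 1L))
    msg <- c(msg, "abundances must be integers >= 1")
  if (!all(object@origin %in% c("environmental", "reference")))
    msg <- c(msg, "origin must be 'environmental' or 'reference'")
  if (n > 0) {
    w <- Biostrings::width(object@sequences)
    if (any(w == 0)) msg <- c(msg, "sequences must be non-empty")
    freq <- Biostrings::letterFrequency(object@sequences,
                                        letters = c("A", "C", "G", "T", "N"))
    if (any(rowSums(freq) != w))
      msg <- c(msg, "sequences may only contain A, C, G, T or N")
  }
  if (length(msg)) msg else TRUE
}
setValidity("AmpliconSet", .valid_amplicon_set)

#' Construct an AmpliconSet
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of DNA
#'   sequences (uppercased on input).
#' @param ids character vector of unique amplicon ids.
#' @param abundance integer read counts (default all 1).
#' @param origin `"environmental"` or `"reference"`; recycled to length.
#' @param taxonomy optional character vector of taxonomy strings
#'   (references only); default all `NA`.
#' @return an [AmpliconSet-class] object.
#' @examples
#' amps <- AmpliconSet(c("ACGT", "ACGA"), ids = c("a1", "a2"),
#'                     abundance = c(5L, 1L), origin = "environmental")
#' amps
#' @export
AmpliconSet <- function(sequences, ids = names(sequences),
                        abundance = rep(1L, length(sequences)),
                        origin = "environmental",
                        taxonomy = NULL) {
  if (is.character(sequences)) {
    bad <- grepl("[^ACGTNacgtn]", sequences)
    if (any(bad))
      stop("sequences may only contain A, C, G, T or N (first offender: ",
           ids[bad][1], ")")
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  } else {
    sequences <- methods::as(sequences, "DNAStringSet")
  }
  if (is.null(ids)) stop("amplicon ids are required")
  names(sequences) <- as.character(ids)
  n <- length(sequences)
  origin <- rep_len(as.character(origin), n)
  if (is.null(taxonomy)) taxonomy <- rep(NA_character_, n)
  methods::new("AmpliconSet",
               sequences = sequences,
               abundance = as.integer(round(abundance)),
               origin = origin,
               taxonomy = rep_len(as.character(taxonomy), n))
}

#' SimilarityGraph: an amplicon sequence similarity network
#'
#' Undirected graph whose nodes are amplicon ids and whose edges connect
#' pairs with all-columns global identity at least the threshold `t`.
#' Every amplicon of the input appears as a node even when isolated.
#'
#' @slot nodes character vector of amplicon ids.
#' @slot edges data.frame with columns `id_a`, `id_b`, `identity`;
#'   `id_a < id_b` lexicographically, one row per unordered edge.
#' @slot threshold the identity threshold `t` used to build the graph.
#'
#' @seealso [buildSimilarityGraph()], [clusterNetwork()]
#' @aliases SimilarityGraph-class
#' @exportClass SimilarityGraph
setClass("SimilarityGraph",
  representation(nodes = "character", edges = "data.frame",
                 threshold = "numeric")
)

setValidity("SimilarityGraph", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  e <- object@edges
  if (!all(c("id_a", "id_b", "identity") %in% names(e)))
    msg <- c(msg, "edges must have columns id_a, id_b, identity")
  else if (nrow(e)) {
    if (!all(e$id_a %in% object@nodes) || !all(e$id_b %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(e$id_a == e$id_b)) msg <- c(msg, "self-edges are not allowed")
    if (any(e$identity < object@threshold - 1e-9))
      msg <- c(msg, "edge identities must be >= threshold")
  }
  if (length(msg)) msg else TRUE
})

#' OTUSet: the result of one clustering approach
#'
#' Holds the OTUs produced by one approach (`"greedy"`, `"network"` or
#' `"swarm"`), as a long membership table plus, for approaches with an
#' internal topology, the within-OTU edge list. The parameters slot
#' records exactly the settings used, so a result is self-describing.
#'
#' @slot approach one of `"greedy"`, `"network"`, `"swarm"`.
#' @slot parameters named list of the clustering parameters used.
#' @slot membership data.frame with columns `otu_id`, `member_id`,
#'   `is_seed` (greedy centroid / swarm seed; all `FALSE` for network).
#' @slot edges data.frame with columns `otu_id`, `id_a`, `id_b`
#'   (internal OTU edges; empty for greedy).
#' @slot removed character vector of amplicon ids dropped by
#'   [filterSmallOtus()].
#'
#' @seealso [clusterGreedy()], [clusterNetwork()], [clusterSwarm()]
#' @aliases OTUSet-class
#' @exportClass OTUSet
setClass("OTUSet",
  representation(approach = "character", parameters = "list",
                 membership = "data.frame", edges = "data.frame",
                 removed = "character")
)

setValidity("OTUSet", function(object) {
  msg <- character(0)
  if (!object@approach %in% c("greedy", "network", "swarm"))
    msg <- c(msg, "approach must be greedy, network or swarm")
  m <- object@membership
  if (!all(c("otu_id", "member_id", "is_seed") %in% names(m)))
    msg <- c(msg, "membership must have columns otu_id, member_id, is_seed")
  else if (nrow(m) && anyDuplicated(m$member_id))
    msg <- c(msg, "an amplicon may belong to only one OTU")
  e <- object@edges
  if (!all(c("otu_id", "id_a", "id_b") %in% names(e)))
    msg <- c(msg, "edges must have columns otu_id, id_a, id_b")
  else if (nrow(e)) {
    mem <- split(m$member_id, m$otu_id)
    ok <- mapply(function(o, a, b) a %in% mem[[o]] && b %in% mem[[o]],
                 e$otu_id, e$id_a, e$id_b)
    if (!all(ok)) msg <- c(msg, "internal edges may only connect OTU members")
  }
  if (length(msg)) msg else TRUE
})
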