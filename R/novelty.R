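# OTU composition classes, shortest paths to references, novelty classes.

#' Classify OTUs by amplicon composition
#'
#' An OTU is `mixed` when it contains both environmental and reference
#' amplicons, `ref_only` when it contains only references, and
#' `env_only` when it contains only environmental amplicons --
#' `env_only` OTUs are the candidates for novel diversity.
#'
#' @param result an [OTUSet-class].
#' @param amplicons the [AmpliconSet-class] that was clustered (supplies
#'   origin labels).
#' @return named character vector, OTU id -> class.
#' @export
classifyOtus <- function(result, amplicons) {
  stopifnot(methods::is(result, "OTUSet"),
            methods::is(amplicons, "AmpliconSet"))
  m <- result@membership
  org <- origins(amplicons)
  if (!all(m$member_id %in% names(org)))
    stop("OTU member(s) missing from the amplicon set: ",
         paste(utils::head(setdiff(m$member_id, names(org)), 3),
               collapse = ", "))
  morg <- org[m$member_id]
  cls <- vapply(split(morg, m$otu_id), function(o) {
    has_env <- any(o == "environmental")
    has_ref <- any(o == "reference")
    if (has_env && has_ref) "mixed" else if (has_ref) "ref_only" else "env_only"
  }, "")
  cls[otuIds(result)]
}

.otu_graph <- function(members, edges) {
  igraph::graph_from_data_frame(edges[, c("id_a", "id_b"), drop = FALSE],
                                directed = FALSE,
                                vertices = data.frame(name = members))
}

#' Shortest-path distances from environmental amplicons to references
#'
#' For every OTU with an internal edge topology (network and swarm
#' approaches), runs a multi-source breadth-first search from all
#' reference members over the internal edges and reports, for each
#' environmental member, the minimal number of edges to its closest
#' reference node. Environmental members of OTUs without any reference
#' get distance `Inf`. Greedy OTUs carry no topology and are rejected.
#'
#' @param result an [OTUSet-class] with internal edges (`network` or
#'   `swarm`).
#' @param amplicons the clustered [AmpliconSet-class] (origin labels).
#' @return named numeric vector, environmental member id -> hop count
#'   (`Inf` when no path to any reference exists).
#' @export
referencePathDistances <- function(result, amplicons) {
  stopifnot(methods::is(result, "OTUSet"))
  if (result@approach == "greedy")
    stop("greedy OTUs have no internal topology; ",
         "path distances are only defined for network and swarm OTUs")
  m <- result@membership
  org <- origins(amplicons)[m$member_id]
  if (anyNA(org)) stop("OTU member(s) missing from the amplicon set")
  sz <- table(m$otu_id)
  edged <- unique(result@edges$otu_id)
  bad <- names(sz)[sz > 1 & !(names(sz) %in% edged)]
  if (length(bad))
    stop("multi-member OTU(s) without internal edges: ",
         paste(utils::head(bad, 3), collapse = ", "))
  out <- numeric(0)
  esplit <- split(result@edges, result@edges$otu_id)
  for (oid in unique(m$otu_id)) {
    sel <- m$otu_id == oid
    members <- m$member_id[sel]
    env <- members[org[sel] == "environmental"]
    if (!length(env)) next
    ref <- members[org[sel] == "reference"]
    if (!length(ref)) {
      out[env] <- Inf
      next
    }
    g <- .otu_graph(members, esplit[[oid]])
    dmat <- igraph::distances(g, v = env, to = ref)
    out[env] <- apply(dmat, 1L, min)
  }
  out
}

#' Novelty class from OTU class and path distance
#'
#' Environmental amplicons directly linked to a reference (distance 1)
#' are `covered` by the reference set; those at finite distance of 2 or
#' more are `novel_variant`s hiding inside mixed OTUs; those with no
#' path to any reference (members of `env_only` OTUs) are `novel`.
#'
#' @param otuClass vector of OTU classes (`mixed`, `ref_only`,
#'   `env_only`).
#' @param pathDistance vector of path distances (positive, possibly
#'   `Inf`), recycled against `otuClass`.
#' @return character vector of `covered`, `novel_variant`, `novel`.
#' @export
classifyNovelty <- function(otuClass, pathDistance) {
  n <- max(length(otuClass), length(pathDistance))
  otuClass <- rep_len(otuClass, n)
  pathDistance <- rep_len(pathDistance, n)
  if (any(otuClass == "env_only" & is.finite(pathDistance)))
    stop("inconsistent input: env_only OTUs cannot have finite path distances")
  if (any(is.finite(pathDistance) & pathDistance < 1))
    stop("path distances must be >= 1")
  ifelse(!is.finite(pathDistance), "novel",
         ifelse(pathDistance == 1, "covered", "novel_variant"))
}

#' Per-amplicon novelty report
#'
#' Assembles, for one clustering result, one record per environmental
#' amplicon retained after filtering: its OTU, the OTU composition
#' class, the shortest-path distance to the nearest reference (network
#' and swarm only; `NA` for greedy), the best-hit identity against the
#' reference set, and the resulting novelty class. For the greedy
#' approach, which has no internal topology, novelty derives from the
#' OTU class alone (`env_only` -> `novel`, otherwise `covered`).
#'
#' Best hits are computed for amplicons in `env_only` OTUs; set
#' `allHits = TRUE` to compute them for every environmental amplicon
#' (needed e.g. to check the coverage/best-hit equivalence of the
#' network approach).
#'
#' @param result an [OTUSet-class].
#' @param amplicons the clustered [AmpliconSet-class].
#' @param references [AmpliconSet-class] of reference amplicons.
#' @param floor best-hit identity floor (default 0.70); identities below
#'   it are reported `NA`.
#' @param allHits compute best hits for all environmental amplicons.
#' @param scoring an [alignScoring()] object.
#' @return data.frame with columns `approach`, `amplicon_id`, `otu_id`,
#'   `otu_class`, `path_distance`, `best_hit_identity`, `novelty_class`.
#' @export
noveltyReport <- function(result, amplicons, references, floor = 0.70,
                          allHits = FALSE, scoring = alignScoring()) {
  stopifnot(methods::is(result, "OTUSet"),
            methods::is(amplicons, "AmpliconSet"),
            methods::is(references, "AmpliconSet"))
  if (length(references) == 0) stop("reference set is empty")
  m <- result@membership
  org <- origins(amplicons)
  ocls <- classifyOtus(result, amplicons)
  env_sel <- org[m$member_id] == "environmental"
  env <- m[env_sel, , drop = FALSE]
  if (nrow(env) == 0) {
    return(data.frame(approach = character(0), amplicon_id = character(0),
                      otu_id = character(0), otu_class = character(0),
                      path_distance = numeric(0),
                      best_hit_identity = numeric(0),
                      novelty_class = character(0), stringsAsFactors = FALSE))
  }
  otu_class <- unname(ocls[env$otu_id])
  if (result@approach == "greedy") {
    pd <- rep(NA_real_, nrow(env))
    novelty <- ifelse(otu_class == "env_only", "novel", "covered")
  } else {
    dist <- referencePathDistances(result, amplicons)
    pd <- unname(dist[env$member_id])
    novelty <- classifyNovelty(otu_class, pd)
  }
  bh <- rep(NA_real_, nrow(env))
  want <- if (allHits) rep(TRUE, nrow(env)) else otu_class == "env_only"
  if (any(want)) {
    hits <- bestHits(amplicons[env$member_id[want]], references,
                     floor = floor, scoring = scoring)
    bh[want] <- hits$identity
  }
  data.frame(approach = result@approach,
             amplicon_id = env$member_id,
             otu_id = env$otu_id,
             otu_class = otu_class,
             path_distance = pd,
             best_hit_identity = bh,
             novelty_class = novelty,
             stringsAsFactors = FALSE)
}

#' Write a novelty report as TSV
#'
#' Serializes a [noveltyReport()] data.frame with `inf` for infinite
#' path distances and `NA` sentinels elsewhere.
#'
#' @param report a [noveltyReport()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNoveltyReport <- function(report, path) {
  out <- report
  out$path_distance <- ifelse(is.na(out$path_distance), "NA",
                              ifelse(is.infinite(out$path_distance), "inf",
                                     format(out$path_distance)))
  out$best_hit_identity <- ifelse(is.na(out$best_hit_identity), "NA",
                                  sprintf("%.6f", out$best_hit_identity))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
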