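# The three de novo OTU construction approaches and the small-OTU filter.

.otu_ids <- function(approach, n) {
  if (n == 0) return(character(0))
  sprintf("%s_%0*d", approach, max(4L, nchar(as.character(n))), seq_len(n))
}

.abundance_order <- function(amplicons) {
  order(-amplicons@abundance, ampliconIds(amplicons))
}

.empty_membership <- function() {
  data.frame(otu_id = character(0), member_id = character(0),
             is_seed = logical(0), stringsAsFactors = FALSE)
}

.empty_otu_edges <- function() {
  data.frame(otu_id = character(0), id_a = character(0), id_b = character(0),
             stringsAsFactors = FALSE)
}

.new_otuset <- function(approach, parameters, membership, edges,
                        removed = character(0)) {
  methods::new("OTUSet", approach = approach, parameters = parameters,
               membership = membership, edges = edges, removed = removed)
}

#' Greedy centroid clustering at a global identity threshold
#'
#' Classic abundance-sorted greedy clustering: amplicons are processed
#' in decreasing-abundance order (ties by id); each amplicon joins the
#' existing centroid of maximal all-columns identity when that identity
#' is at least `t` (ties go to the earliest-created centroid), otherwise
#' it founds a new OTU as centroid. Every member is therefore within the
#' threshold radius of its centroid, and centroids are pairwise below
#' `t` -- the radius cap that makes this approach over-split relative to
#' connected components.
#'
#' @param amplicons an [AmpliconSet-class].
#' @param t identity threshold in (0, 1]; default 0.97.
#' @param scoring an [alignScoring()] object.
#' @return an [OTUSet-class] with `approach = "greedy"`. Greedy OTUs
#'   carry no internal edge topology.
#' @export
clusterGreedy <- function(amplicons, t = 0.97, scoring = alignScoring()) {
  stopifnot(methods::is(amplicons, "AmpliconSet"), t > 0, t <= 1)
  params <- list(t = t, min_otu_size = 1L)
  if (length(amplicons) == 0)
    return(.new_otuset("greedy", params, .empty_membership(),
                       .empty_otu_edges()))
  ord <- .abundance_order(amplicons)
  amps <- amplicons[ord]
  res <- cpp_greedy_cluster(as.character(ampliconSequences(amps)), t,
                            scoring$match, scoring$mismatch,
                            scoring$gapOpen, scoring$gapExtend)
  ids <- .otu_ids("greedy", max(res$otu))
  membership <- data.frame(otu_id = ids[res$otu],
                           member_id = ampliconIds(amps),
                           is_seed = res$is_centroid,
                           stringsAsFactors = FALSE)
  .new_otuset("greedy", params, membership, .empty_otu_edges())
}

#' Connected components of a similarity network as OTUs
#'
#' Each connected component of the sequence similarity network becomes
#' one OTU; its internal edges are all graph edges inside the component.
#' Isolated nodes become singleton OTUs (normally removed later by
#' [filterSmallOtus()]). Unlike greedy clustering, component radii are
#' unbounded, and the result is invariant to input order.
#'
#' @param graph a [SimilarityGraph-class] from [buildSimilarityGraph()].
#' @return an [OTUSet-class] with `approach = "network"`. OTU ids are
#'   assigned in order of each component's first node.
#' @export
clusterNetwork <- function(graph) {
  stopifnot(methods::is(graph, "SimilarityGraph"))
  params <- list(t = graph@threshold, min_otu_size = 1L)
  if (length(graph@nodes) == 0)
    return(.new_otuset("network", params, .empty_membership(),
                       .empty_otu_edges()))
  g <- asIgraph(graph)
  comp <- igraph::components(g)$membership[graph@nodes]
  comp <- match(comp, unique(comp))  # renumber in first-node order
  ids <- .otu_ids("network", max(comp))
  membership <- data.frame(otu_id = ids[comp],
                           member_id = graph@nodes,
                           is_seed = FALSE,
                           stringsAsFactors = FALSE)
  e <- graph@edges
  edges <- if (nrow(e)) {
    data.frame(otu_id = ids[comp[match(e$id_a, graph@nodes)]],
               id_a = e$id_a, id_b = e$id_b, stringsAsFactors = FALSE)
  } else .empty_otu_edges()
  .new_otuset("network", params, membership, edges)
}

#' Swarm-style iterative local-threshold clustering
#'
#' Single-linkage clustering at a small local edit-distance threshold
#' `d`, grown iteratively from abundance-ranked seeds. The most abundant
#' pooled amplicon seeds a new OTU and captures every pooled amplicon
#' within `d` differences; each generation of newly captured amplicons
#' (subseeds) captures further pooled amplicons in turn, until no more
#' can be added. With `breaking` on, chain growth is abundance-aware: a
#' subseed may only capture amplicons of equal or lower abundance (the
#' seed's own first-generation captures are unrestricted), which stops
#' single-linkage chains from bridging adjacent abundance peaks. With
#' `fastidious` on, each light OTU (total read abundance below
#' `boundary`) is grafted after clustering onto the heavy OTU (total
#' abundance at least `boundary`) that minimizes the cross-OTU member
#' edit distance, provided that minimum is at most `2 * d` (ties go to
#' the heaviest OTU, then by OTU id); the minimal-distance pair is added
#' as an internal edge.
#'
#' Internal OTU edges are the full "edit distance <= d" graph restricted
#' to the OTU members, plus graft edges, so the recorded topology is
#' independent of capture order.
#'
#' @param amplicons an [AmpliconSet-class].
#' @param d maximum number of differences (substitutions or indels) for
#'   a link; default 1.
#' @param breaking abundance-aware chain breaking; default `TRUE`.
#' @param fastidious graft light OTUs onto heavy ones; default `TRUE`.
#' @param boundary total-abundance boundary between light and heavy
#'   OTUs; default 3.
#' @return an [OTUSet-class] with `approach = "swarm"`.
#' @export
clusterSwarm <- function(amplicons, d = 1L, breaking = TRUE,
                         fastidious = TRUE, boundary = 3L) {
  stopifnot(methods::is(amplicons, "AmpliconSet"), d >= 1, boundary >= 1)
  d <- as.integer(d); boundary <- as.integer(boundary)
  params <- list(d = d, breaking = breaking, fastidious = fastidious,
                 boundary = boundary, min_otu_size = 1L)
  n <- length(amplicons)
  if (n == 0)
    return(.new_otuset("swarm", params, .empty_membership(),
                       .empty_otu_edges()))
  amps <- amplicons[.abundance_order(amplicons)]
  ids <- ampliconIds(amps)
  ab <- amps@abundance
  pairs <- cpp_pairs_within_d(as.character(ampliconSequences(amps)), d)
  adj <- vector("list", n)
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  in_pool <- rep(TRUE, n)
  otu_of <- integer(n)
  is_seed <- logical(n)
  n_otu <- 0L
  for (s in seq_len(n)) {      # amplicons are in abundance-then-id order
    if (!in_pool[s]) next
    n_otu <- n_otu + 1L
    otu_of[s] <- n_otu
    is_seed[s] <- TRUE
    in_pool[s] <- FALSE
    gen <- s
    first_gen <- TRUE
    while (length(gen)) {
      nextgen <- integer(0)
      for (a in gen) {          # generation kept in abundance order
        caps <- adj[[a]]
        caps <- caps[in_pool[caps]]
        if (breaking && !first_gen)
          caps <- caps[ab[caps] <= ab[a]]
        if (length(caps)) {
          in_pool[caps] <- FALSE
          otu_of[caps] <- n_otu
          nextgen <- c(nextgen, caps)
        }
      }
      gen <- sort(nextgen)      # index order == abundance-then-id order
      first_gen <- FALSE
    }
  }

  graft_edges <- .empty_otu_edges()
  if (fastidious && n_otu > 1L) {
    mass <- vapply(seq_len(n_otu), function(o) sum(ab[otu_of == o]), 1L)
    light <- which(mass < boundary)
    heavy <- which(mass >= boundary)
    if (length(light) && length(heavy)) {
      seqs <- as.character(ampliconSequences(amps))
      otu_of0 <- otu_of  # grafts are all assessed against the initial clustering
      for (lo in light) {
        lmem <- which(otu_of0 == lo)
        best <- NULL
        for (ho in heavy) {
          hmem <- which(otu_of0 == ho)
          grid <- expand.grid(l = lmem, h = hmem)
          dist <- cpp_edit_distance(seqs[grid$l], seqs[grid$h], 2L * d)
          ok <- dist >= 0L
          if (!any(ok)) next
          dmin <- min(dist[ok])
          # minimal pair, ties by lexicographic (light id, heavy id)
          cand <- grid[ok & dist == dmin, , drop = FALSE]
          cand <- cand[order(ids[cand$l], ids[cand$h]), , drop = FALSE]
          rec <- list(otu = ho, dmin = dmin, mass = mass[ho],
                      l = cand$l[1], h = cand$h[1])
          if (is.null(best) || rec$dmin < best$dmin ||
              (rec$dmin == best$dmin && (rec$mass > best$mass ||
               (rec$mass == best$mass && rec$otu < best$otu))))
            best <- rec
        }
        if (!is.null(best)) {
          otu_of[lmem] <- best$otu
          is_seed[lmem] <- FALSE
          graft_edges <- rbind(graft_edges, data.frame(
            otu_id = NA_character_,
            id_a = min(ids[best$l], ids[best$h]),
            id_b = max(ids[best$l], ids[best$h]),
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  keep <- sort(unique(otu_of))
  otu_of <- match(otu_of, keep)  # renumber after grafting
  oids <- .otu_ids("swarm", length(keep))
  membership <- data.frame(otu_id = oids[otu_of], member_id = ids,
                           is_seed = is_seed, stringsAsFactors = FALSE)
  # full distance-<=d graph restricted to members (order-independent)
  edges <- .empty_otu_edges()
  if (nrow(pairs)) {
    same <- otu_of[pairs$i] == otu_of[pairs$j]
    if (any(same)) {
      pi <- pairs$i[same]; pj <- pairs$j[same]
      a <- pmin(ids[pi], ids[pj]); b <- pmax(ids[pi], ids[pj])
      edges <- data.frame(otu_id = oids[otu_of[pi]], id_a = a, id_b = b,
                          stringsAsFactors = FALSE)
    }
  }
  if (nrow(graft_edges)) {
    graft_edges$otu_id <-
      membership$otu_id[match(graft_edges$id_a, membership$member_id)]
    edges <- rbind(edges, graft_edges)
    edges <- edges[!duplicated(edges[c("id_a", "id_b")]), ]
  }
  edges <- edges[order(edges$otu_id, edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL
  .new_otuset("swarm", params, membership, edges)
}

#' Remove small OTUs
#'
#' Drops OTUs with fewer than `minAmplicons` members -- by default
#' singletons and doubletons, the usual guard against spurious
#' sequencing noise. The dropped amplicon ids are recorded in the
#' result's `removed` slot.
#'
#' @param result an [OTUSet-class].
#' @param minAmplicons minimum member count an OTU must have to be
#'   retained; default 3.
#' @return the filtered [OTUSet-class]; `clusterParameters()` records
#'   `min_otu_size`.
#' @export
filterSmallOtus <- function(result, minAmplicons = 3L) {
  stopifnot(methods::is(result, "OTUSet"), minAmplicons >= 1)
  m <- result@membership
  sz <- table(m$otu_id)
  keep_otus <- names(sz)[sz >= minAmplicons]
  keep <- m$otu_id %in% keep_otus
  params <- result@parameters
  params$min_otu_size <- as.integer(minAmplicons)
  e <- result@edges
  .new_otuset(result@approach, params,
              m[keep, , drop = FALSE],
              e[e$otu_id %in% keep_otus, , drop = FALSE],
              removed = c(result@removed, m$member_id[!keep]))
}
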