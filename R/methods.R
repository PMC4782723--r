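# Accessor, subset and show methods.

#' @rdname accessors
#' @export
setMethod("ampliconIds", "AmpliconSet", function(x) names(x@sequences))

#' @rdname accessors
#' @export
setMethod("abundances", "AmpliconSet",
          function(x) stats::setNames(x@abundance, ampliconIds(x)))

#' @rdname accessors
#' @export
setMethod("origins", "AmpliconSet",
          function(x) stats::setNames(x@origin, ampliconIds(x)))

#' @rdname accessors
#' @export
setMethod("taxonomies", "AmpliconSet",
          function(x) stats::setNames(x@taxonomy, ampliconIds(x)))

#' @rdname accessors
#' @export
setMethod("ampliconSequences", "AmpliconSet", function(x) x@sequences)

#' @describeIn AmpliconSet number of amplicons.
#' @param x,object an `AmpliconSet`.
#' @export
setMethod("length", "AmpliconSet", function(x) length(x@sequences))

#' @describeIn AmpliconSet subset by index, logical mask or amplicon id.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "AmpliconSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    i <- match(i, ampliconIds(x))
    if (anyNA(i)) stop("unknown amplicon id(s)")
  }
  methods::new("AmpliconSet", sequences = x@sequences[i],
               abundance = x@abundance[i], origin = x@origin[i],
               taxonomy = x@taxonomy[i])
})

#' Combine two AmpliconSets
#'
#' @param x,y `AmpliconSet` objects with disjoint ids.
#' @param ... ignored.
#' @return the concatenated [AmpliconSet-class].
#' @export
setMethod("c", "AmpliconSet", function(x, ...) {
  args <- list(...)
  for (y in args) {
    x <- methods::new("AmpliconSet",
                      sequences = c(x@sequences, y@sequences),
                      abundance = c(x@abundance, y@abundance),
                      origin = c(x@origin, y@origin),
                      taxonomy = c(x@taxonomy, y@taxonomy))
  }
  x
})

setMethod("show", "AmpliconSet", function(object) {
  n <- length(object)
  cat("AmpliconSet with", n, "amplicons\n")
  if (n) {
    tab <- table(object@origin)
    cat("  origins: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
    cat("  total reads:", sum(object@abundance),
        "| sequence length:", paste(range(Biostrings::width(object@sequences)),
                                    collapse = "-"), "\n")
  }
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("edgeList", "SimilarityGraph", function(x) x@edges)

#' @describeIn SimilarityGraph number of nodes.
#' @param x,object a `SimilarityGraph`.
#' @export
setMethod("length", "SimilarityGraph", function(x) length(x@nodes))

setMethod("show", "SimilarityGraph", function(object) {
  cat("SimilarityGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges at identity >=", object@threshold, "\n")
  invisible(object)
})

#' @rdname accessors
#' @export
setMethod("otuIds", "OTUSet", function(x) unique(x@membership$otu_id))

#' @rdname accessors
#' @export
setMethod("otuMembership", "OTUSet", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("otuSizes", "OTUSet", function(x) {
  m <- x@membership
  sz <- table(factor(m$otu_id, levels = unique(m$otu_id)))
  stats::setNames(as.integer(sz), names(sz))
})

#' @rdname accessors
#' @export
setMethod("clusterParameters", "OTUSet", function(x) x@parameters)

#' @rdname accessors
#' @export
setMethod("edgeList", "OTUSet", function(x) x@edges)

#' @describeIn OTUSet number of OTUs.
#' @param x,object an `OTUSet`.
#' @export
setMethod("length", "OTUSet", function(x) length(otuIds(x)))

setMethod("show", "OTUSet", function(object) {
  sz <- otuSizes(object)
  cat("OTUSet (", object@approach, "): ", length(sz), " OTUs, ",
      nrow(object@membership), " amplicons", sep = "")
  if (length(object@removed))
    cat(" (", length(object@removed), " removed by size filter)", sep = "")
  cat("\n")
  if (length(sz))
    cat("  OTU sizes: min", min(sz), "median", stats::median(sz),
        "max", max(sz), "\n")
  p <- object@parameters
  if (length(p))
    cat("  parameters:",
        paste(sprintf("%s=%s", names(p), vapply(p, format, "")),
              collapse = ", "), "\n")
  invisible(object)
})
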