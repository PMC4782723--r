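#' Accessors for noveltynet classes
#'
#' @param x an [AmpliconSet-class], [SimilarityGraph-class] or
#'   [OTUSet-class] object.
#' @name accessors
NULL

#' @describeIn accessors amplicon ids.
#' @export
setGeneric("ampliconIds", function(x) standardGeneric("ampliconIds"))

#' @describeIn accessors read abundances (named integer vector).
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @describeIn accessors origin labels (named character vector).
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' @describeIn accessors taxonomy strings (named character vector).
#' @export
setGeneric("taxonomies", function(x) standardGeneric("taxonomies"))

#' @describeIn accessors the sequences as a [Biostrings::DNAStringSet].
#' @export
setGeneric("ampliconSequences", function(x) standardGeneric("ampliconSequences"))

#' @describeIn accessors edge list of a graph or OTU set (data.frame).
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @describeIn accessors OTU ids of an [OTUSet-class].
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @describeIn accessors long membership table of an [OTUSet-class].
#' @export
setGeneric("otuMembership", function(x) standardGeneric("otuMembership"))

#' @describeIn accessors named integer vector of OTU sizes.
#' @export
setGeneric("otuSizes", function(x) standardGeneric("otuSizes"))

#' @describeIn accessors clustering parameters of an [OTUSet-class] (list).
#' @export
setGeneric("clusterParameters", function(x) standardGeneric("clusterParameters"))
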