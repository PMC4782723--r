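# FASTA input/output with abundance-annotated headers, dereplication.

.dialects <- c("size", "underscore", "none")

.parse_header <- function(headers, dialect) {
  switch(dialect,
    size = {
      m <- regexpr(";size=([0-9]+);?\\s*$", headers)
      ab <- rep(NA_integer_, length(headers))
      hit <- m > 0
      ab[hit] <- as.integer(sub("^;size=([0-9]+);?\\s*$", "\\1",
                                regmatches(headers, m)))
      ids <- ifelse(hit, substr(headers, 1, m - 1), headers)
      list(id = ids, abundance = ab)
    },
    underscore = {
      m <- regexpr("_([0-9]+)\\s*$", headers)
      ab <- rep(NA_integer_, length(headers))
      hit <- m > 0
      ab[hit] <- as.integer(sub("^_([0-9]+)\\s*$", "\\1",
                                regmatches(headers, m)))
      ids <- ifelse(hit, substr(headers, 1, m - 1), headers)
      list(id = ids, abundance = ab)
    },
    none = list(id = headers, abundance = rep(1L, length(headers)))
  )
}

#' Read amplicons from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file of dereplicated amplicons.
#' Read abundances are parsed from the header according to a dialect:
#' `"size"` expects a `;size=N` suffix (the usearch/vsearch convention),
#' `"underscore"` a trailing `_N` (the swarm convention), and `"none"`
#' assigns abundance 1 to every record. The part of the header after the
#' first whitespace is kept as the taxonomy string.
#'
#' @param path path to a FASTA file.
#' @param origin origin label applied to all records, `"environmental"`
#'   or `"reference"`.
#' @param dialect abundance dialect, one of `"size"`, `"underscore"`,
#'   `"none"`. Default `"size"`.
#' @return an [AmpliconSet-class]. Sequences are uppercased.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">amp1;size=5", "ACGT", ">amp2;size=2", "ACGA"), f)
#' readAmplicons(f, origin = "environmental")
#' @export
readAmplicons <- function(path, origin = c("environmental", "reference"),
                          dialect = c("size", "underscore", "none")) {
  origin <- match.arg(origin)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e)
                     stop("malformed FASTA in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0) {
    return(AmpliconSet(character(0), ids = character(0),
                       abundance = integer(0), origin = origin))
  }
  full <- names(seqs)
  first <- sub("\\s.*$", "", full)
  rest <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), NA_character_)
  parsed <- .parse_header(first, dialect)
  if (dialect != "none" && anyNA(parsed$abundance))
    stop("record '", first[which(is.na(parsed$abundance))[1]],
         "' carries no parsable '", if (dialect == "size") ";size=N" else "_N",
         "' abundance annotation")
  if (anyDuplicated(parsed$id))
    stop("duplicate amplicon id(s): ",
         paste(utils::head(unique(parsed$id[duplicated(parsed$id)]), 3),
               collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- Biostrings::letterFrequency(seqs, "ACGTN") != Biostrings::width(seqs)
  if (any(bad))
    stop("sequence of record '", parsed$id[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  AmpliconSet(seqs, ids = parsed$id, abundance = parsed$abundance,
              origin = origin, taxonomy = rest)
}

#' Write amplicons to a FASTA file
#'
#' Serializes an [AmpliconSet-class] to single-line-sequence FASTA with
#' abundance-annotated headers. A read/write round trip preserves ids,
#' sequences and abundances exactly, and re-serialization is
#' byte-identical.
#'
#' @param amplicons an [AmpliconSet-class].
#' @param path output file path.
#' @param dialect abundance dialect; see [readAmplicons()].
#' @return `path`, invisibly.
#' @export
writeAmplicons <- function(amplicons, path,
                           dialect = c("size", "underscore", "none")) {
  dialect <- match.arg(dialect)
  stopifnot(methods::is(amplicons, "AmpliconSet"))
  ids <- ampliconIds(amplicons)
  ab <- amplicons@abundance
  headers <- switch(dialect,
    size = sprintf(">%s;size=%d", ids, ab),
    underscore = sprintf(">%s_%d", ids, ab),
    none = sprintf(">%s", ids)
  )
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  if (length(ids))
    writeLines(paste(headers, as.character(amplicons@sequences), sep = "\n"),
               con)
  invisible(path)
}

#' Collapse strictly identical sequences
#'
#' Dereplicates an amplicon set: amplicons with strictly identical
#' sequences are merged into one, with abundance equal to the sum of the
#' members' abundances. The merged amplicon keeps the id of the most
#' abundant member (ties broken by the lexicographically smallest id).
#' Output is sorted by decreasing abundance, ties by id. Environmental
#' and reference sets are dereplicated separately; mixed input is an
#' error.
#'
#' @param amplicons an [AmpliconSet-class] with a single origin label.
#' @return the dereplicated [AmpliconSet-class]. Total read count is
#'   conserved and the operation is idempotent.
#' @examples
#' amps <- AmpliconSet(c("ACGT", "ACGT", "TTTT"), ids = c("a", "b", "c"),
#'                     abundance = c(2L, 3L, 1L))
#' abundances(dereplicate(amps))
#' @export
dereplicate <- function(amplicons) {
  stopifnot(methods::is(amplicons, "AmpliconSet"))
  if (length(unique(amplicons@origin)) > 1)
    stop("mixed origins: dereplicate environmental and reference sets separately")
  if (length(amplicons) == 0) return(amplicons)
  seqs <- as.character(amplicons@sequences)
  ids <- ampliconIds(amplicons)
  ab <- amplicons@abundance
  grp <- match(seqs, seqs)  # representative index per distinct sequence
  keys <- unique(grp)
  groups <- split(seq_along(grp), factor(grp, levels = keys))
  picks <- vapply(groups, function(idx) idx[order(-ab[idx], ids[idx])[1]], 1L)
  rep_id <- ids[picks]
  rep_ab <- vapply(groups, function(idx) sum(ab[idx]), 1L)
  rep_tax <- amplicons@taxonomy[picks]
  out <- AmpliconSet(seqs[keys], ids = rep_id, abundance = rep_ab,
                     origin = amplicons@origin[1], taxonomy = rep_tax)
  out[order(-out@abundance, ampliconIds(out))]
}

#' Tabulate an amplicon set
#'
#' @param amplicons an [AmpliconSet-class].
#' @param path optional path; when given, the table is written as TSV.
#' @return data.frame with columns `id`, `abundance`, `origin`, `length`.
#' @export
ampliconTable <- function(amplicons, path = NULL) {
  df <- data.frame(id = ampliconIds(amplicons),
                   abundance = amplicons@abundance,
                   origin = amplicons@origin,
                   length = Biostrings::width(amplicons@sequences),
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
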