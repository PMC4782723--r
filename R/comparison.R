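# Cross-approach comparison: summary table, three-way overlap of novel
# amplicon sets, misclassification audit, divergence profiles.

#' Novel amplicon sets per approach
#'
#' Extracts, from each approach's novelty report, the set of
#' environmental amplicon ids whose OTU class is `env_only` -- the
#' amplicons each approach reports as novel diversity.
#'
#' @param reports named list of [noveltyReport()] data.frames, one per
#'   approach.
#' @return named list of character vectors of amplicon ids.
#' @export
novelAmpliconSets <- function(reports) {
  lapply(reports, function(r) r$amplicon_id[r$otu_class == "env_only"])
}

#' Three-way overlap (Venn region) counts
#'
#' Cardinalities of the seven regions of a three-set Venn diagram: each
#' exclusive region, each pairwise-only region and the triple
#' intersection. Region counts partition the union of the three sets.
#'
#' @param sets named list of exactly three id sets (character vectors).
#' @return named integer vector with names `<A>_only`, `<B>_only`,
#'   `<C>_only`, `<A>_<B>`, `<A>_<C>`, `<B>_<C>`, `all_three`.
#' @examples
#' overlapCounts(list(a = c("x", "y"), b = c("y", "z"), c = "y"))
#' @export
overlapCounts <- function(sets) {
  if (length(sets) != 3)
    stop("exactly three sets are required, got ", length(sets))
  nm <- names(sets)
  if (is.null(nm)) nm <- c("A", "B", "C")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  pattern <- inA + 2L * inB + 4L * inC
  cnt <- tabulate(pattern, nbins = 7L)
  stats::setNames(cnt[c(1L, 2L, 4L, 3L, 5L, 6L, 7L)],
                  c(paste0(nm, "_only"),
                    paste0(nm[1], "_", nm[2]), paste0(nm[1], "_", nm[3]),
                    paste0(nm[2], "_", nm[3]), "all_three"))
}

#' Audit a novel amplicon set against the references
#'
#' Counts the amplicons of a "novel" set whose best-hit identity to the
#' reference set reaches the clustering threshold `t` -- amplicons that
#' were placed in exclusively environmental OTUs despite being at least
#' `t` similar to a reference, i.e. misclassified novelty. For the
#' network approach built at the same `t` this count is structurally 0:
#' an edge to the reference would have placed the amplicon in a mixed
#' component.
#'
#' @param novelSet character vector of environmental amplicon ids.
#' @param amplicons the clustered [AmpliconSet-class].
#' @param references [AmpliconSet-class] of references.
#' @param t identity threshold of the audit (default 0.97).
#' @param strict count only identities strictly greater than `t`
#'   (default `FALSE`, i.e. `>=`).
#' @param scoring an [alignScoring()] object.
#' @return list with `count` and `ids` (the audited amplicon ids) and
#'   `identities` (their best-hit identities).
#' @export
misclassificationAudit <- function(novelSet, amplicons, references,
                                   t = 0.97, strict = FALSE,
                                   scoring = alignScoring()) {
  stopifnot(methods::is(references, "AmpliconSet"))
  if (length(references) == 0) stop("reference set is empty")
  if (length(novelSet) == 0)
    return(list(count = 0L, ids = character(0), identities = numeric(0)))
  hits <- bestHits(amplicons[novelSet], references, floor = 0,
                   scoring = scoring)
  flag <- if (strict) hits$identity > t + 1e-9 else hits$identity >= t - 1e-9
  list(count = sum(flag), ids = hits$query_id[flag],
       identities = hits$identity[flag])
}

#' Summarize clustering results across approaches
#'
#' Builds the per-approach composition summary: OTU counts in total and
#' per composition class, and the number of environmental / reference
#' amplicons in each class; plus the seven overlap-region counts of the
#' three approaches' novel amplicon sets.
#'
#' @param results named list of [OTUSet-class] objects (after
#'   filtering), one per approach, all run on the same amplicon set.
#' @param reports named list of matching [noveltyReport()] data.frames.
#' @param amplicons the clustered [AmpliconSet-class].
#' @param t identity threshold used for the misclassification column
#'   (default 0.97): novel amplicons whose recorded best-hit identity
#'   reaches `t` are counted as misclassified.
#' @return list of class `comparison_summary` with elements `table`
#'   (data.frame, one row per approach) and `venn` (named integer
#'   vector from [overlapCounts()], `NULL` unless all three approaches
#'   are present).
#' @export
summarizeClusterings <- function(results, reports, amplicons, t = 0.97) {
  stopifnot(is.list(results), length(results) >= 1)
  universe <- lapply(results, function(r)
    sort(c(r@membership$member_id, r@removed)))
  if (length(unique(universe)) != 1)
    stop("all approaches must be run on the same amplicon set")
  org <- origins(amplicons)
  rows <- lapply(names(results), function(ap) {
    r <- results[[ap]]
    cls <- classifyOtus(r, amplicons)
    m <- r@membership
    mcls <- cls[m$otu_id]
    morg <- org[m$member_id]
    rep <- if (!is.null(reports)) reports[[ap]] else NULL
    audit <- if (is.null(rep)) NA_integer_ else
      sum(rep$otu_class == "env_only" &
            !is.na(rep$best_hit_identity) &
            rep$best_hit_identity >= t - 1e-9)
    data.frame(
      approach = ap,
      otus = length(cls),
      mixed_otus = sum(cls == "mixed"),
      mixed_env_amplicons = sum(mcls == "mixed" & morg == "environmental"),
      mixed_ref_amplicons = sum(mcls == "mixed" & morg == "reference"),
      ref_only_otus = sum(cls == "ref_only"),
      ref_only_ref_amplicons = sum(mcls == "ref_only"),
      env_only_otus = sum(cls == "env_only"),
      env_only_env_amplicons = sum(mcls == "env_only"),
      misclassified_novel = audit,
      retained_amplicons = nrow(m),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  venn <- NULL
  if (length(results) == 3 && !is.null(reports) && length(reports) == 3)
    venn <- overlapCounts(novelAmpliconSets(reports[names(results)]))
  structure(list(table = tab, venn = venn), class = "comparison_summary")
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Clustering comparison\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$venn)) {
    cat("\nOverlap of novel amplicon sets:\n")
    print(x$venn)
  }
  invisible(x)
}

#' Divergence profile of a novel amplicon set
#'
#' One row per novel amplicon: its read abundance and its best-hit
#' identity to the reference set (the y-axis of a divergence scatter).
#' Identities below `floor` are reported `NA` and flagged `below_floor`.
#'
#' @inheritParams misclassificationAudit
#' @param floor best-hit identity floor (default 0.70).
#' @return data.frame with columns `amplicon_id`, `abundance`,
#'   `best_hit_identity`, `below_floor`.
#' @export
divergenceProfile <- function(novelSet, amplicons, references, floor = 0.70,
                              scoring = alignScoring()) {
  if (length(novelSet) == 0)
    return(data.frame(amplicon_id = character(0), abundance = integer(0),
                      best_hit_identity = numeric(0), below_floor = logical(0),
                      stringsAsFactors = FALSE))
  hits <- bestHits(amplicons[novelSet], references, floor = floor,
                   scoring = scoring)
  data.frame(amplicon_id = hits$query_id,
             abundance = unname(abundances(amplicons)[hits$query_id]),
             best_hit_identity = hits$identity,
             below_floor = is.na(hits$identity),
             stringsAsFactors = FALSE)
}

#' Write the comparison summary as TSV files
#'
#' @param summary a `comparison_summary` from [summarizeClusterings()].
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
writeComparisonSummary <- function(summary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "summary.tsv")
  utils::write.table(summary$table, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary$venn)) {
    vp <- file.path(dir, "venn_counts.tsv")
    utils::write.table(data.frame(region = names(summary$venn),
                                  amplicons = as.integer(summary$venn)),
                       vp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, vp)
  }
  invisible(paths)
}
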