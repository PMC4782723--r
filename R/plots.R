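# Diagnostic plots: divergence scatter and path-distance histogram.

#' Divergence scatter of novel amplicons
#'
#' Abundance (x, log scale) against best-hit identity to the references
#' (y) for the amplicons each approach placed in exclusively
#' environmental OTUs. Points at or above the clustering threshold are
#' the misclassified ones.
#'
#' @param profiles named list of [divergenceProfile()] data.frames, one
#'   per approach.
#' @param t identity threshold drawn as a horizontal line
#'   (default 0.97).
#' @param floor identities below the best-hit floor are drawn at the
#'   floor (default 0.70).
#' @return a [ggplot2::ggplot] object.
#' @export
plotDivergence <- function(profiles, t = 0.97, floor = 0.70) {
  df <- do.call(rbind, lapply(names(profiles), function(ap) {
    p <- profiles[[ap]]
    if (nrow(p) == 0) return(NULL)
    p$approach <- ap
    p$best_hit_identity[is.na(p$best_hit_identity)] <- floor
    p
  }))
  if (is.null(df)) stop("no novel amplicons to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abundance,
                                   y = .data$best_hit_identity)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = t, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~approach) +
    ggplot2::labs(x = "amplicon abundance (reads)",
                  y = "best-hit identity to references") +
    ggplot2::theme_bw()
}

#' Histogram of shortest-path distances to references
#'
#' Distribution of the per-amplicon shortest-path distance to the
#' closest reference node for the approaches with internal OTU
#' topology; infinite distances (exclusively environmental OTUs) are
#' shown as their own bin.
#'
#' @param reports named list of [noveltyReport()] data.frames.
#' @return a [ggplot2::ggplot] object.
#' @export
plotPathDistances <- function(reports) {
  df <- do.call(rbind, lapply(names(reports), function(ap) {
    r <- reports[[ap]]
    r <- r[!is.na(r$path_distance), , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    data.frame(approach = ap,
               distance = ifelse(is.infinite(r$path_distance), "inf",
                                 as.character(r$path_distance)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) stop("no path distances to plot (greedy-only input?)")
  lev <- unique(df$distance)
  num <- suppressWarnings(as.numeric(lev))
  lev <- lev[order(is.na(num), num)]
  df$distance <- factor(df$distance, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~approach) +
    ggplot2::labs(x = "edges to closest reference amplicon",
                  y = "environmental amplicons") +
    ggplot2::theme_bw()
}
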