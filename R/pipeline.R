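# End-to-end orchestration: config, full comparison run, artifacts.

#' Pipeline run configuration
#'
#' Bundles every parameter of a full comparison run. All randomness in
#' a run flows from the single `seed`; no stage draws from global
#' entropy, so a config reproduces a run exactly.
#'
#' @param envFasta path to the environmental FASTA file.
#' @param refFasta path to the reference FASTA file.
#' @param outputDir directory for result TSVs, the manifest and the log.
#' @param t global identity threshold (default 0.97).
#' @param d swarm local threshold in differences (default 1).
#' @param fastidious swarm fastidious grafting (default `TRUE`).
#' @param boundary swarm light/heavy abundance boundary (default 3).
#' @param minOtuSize small-OTU filter (default 3: drop singletons and
#'   doubletons).
#' @param bestHitFloor best-hit identity floor (default 0.70).
#' @param approaches subset of `c("greedy", "network", "swarm")`.
#' @param dialect FASTA abundance dialect (see [readAmplicons()]).
#' @param seed integer seed (default 1).
#' @param nodeBudget all-vs-all node budget (default 5000).
#' @param force run the all-vs-all stage beyond `nodeBudget`.
#' @param allHits compute best hits for all environmental amplicons,
#'   not only those in env-only OTUs (default `TRUE`; needed for the
#'   coverage equivalence check and the path-distance/best-hit plots).
#' @return a named list of class `run_config`.
#' @export
runConfig <- function(envFasta, refFasta, outputDir,
                      t = 0.97, d = 1L, fastidious = TRUE, boundary = 3L,
                      minOtuSize = 3L, bestHitFloor = 0.70,
                      approaches = c("greedy", "network", "swarm"),
                      dialect = "size", seed = 1L, nodeBudget = 5000L,
                      force = FALSE, allHits = TRUE) {
  stopifnot(t > 0, t <= 1, d >= 1, boundary >= 1, minOtuSize >= 1,
            bestHitFloor >= 0, bestHitFloor <= 1)
  approaches <- match.arg(approaches, c("greedy", "network", "swarm"),
                          several.ok = TRUE)
  structure(list(envFasta = envFasta, refFasta = refFasta,
                 outputDir = outputDir, t = t, d = as.integer(d),
                 fastidious = fastidious, boundary = as.integer(boundary),
                 minOtuSize = as.integer(minOtuSize),
                 bestHitFloor = bestHitFloor, approaches = approaches,
                 dialect = dialect, seed = as.integer(seed),
                 nodeBudget = as.integer(nodeBudget), force = force,
                 allHits = allHits),
            class = "run_config")
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full clustering comparison
#'
#' Executes the whole analysis: read and dereplicate the environmental
#' and reference sets, cluster the combined set with each requested
#' approach, filter small OTUs, classify OTU composition, run shortest
#' paths (network and swarm), compute best hits, and write per-approach
#' membership and novelty TSVs plus the comparison summary, overlap
#' counts, audit table, a run manifest and a log.
#'
#' @param config a [runConfig()] object.
#' @return invisibly, a list with the in-memory results: `amplicons`,
#'   `references`, `graph` (when the network approach ran), `results`,
#'   `reports`, `summary`, `audits`, and `files` (paths written).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$outputDir, "run.log"), open = "wt")
  on.exit(close(logcon))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    .log_line(logcon, sprintf("[%s] done in %.1fs", name,
                              as.numeric(difftime(Sys.time(), s, units = "secs"))))
    res
  }

  env <- stage("read_env", {
    x <- dereplicate(readAmplicons(config$envFasta, "environmental",
                                   config$dialect))
    .log_line(logcon, "environmental amplicons: ", length(x))
    x
  })
  ref <- stage("read_ref", {
    x <- dereplicate(readAmplicons(config$refFasta, "reference",
                                   config$dialect))
    .log_line(logcon, "reference amplicons: ", length(x))
    x
  })
  combined <- c(env, ref)

  graph <- NULL
  results <- list()
  reports <- list()
  scoring <- alignScoring()
  for (ap in config$approaches) {
    if (ap == "network") {
      graph <- stage("similarity_graph",
                     buildSimilarityGraph(combined, t = config$t,
                                          scoring = scoring,
                                          nodeBudget = config$nodeBudget,
                                          force = config$force))
    }
    res <- stage(paste0("cluster_", ap), switch(ap,
      greedy = clusterGreedy(combined, t = config$t, scoring = scoring),
      network = clusterNetwork(graph),
      swarm = clusterSwarm(combined, d = config$d,
                           fastidious = config$fastidious,
                           boundary = config$boundary)))
    res <- filterSmallOtus(res, config$minOtuSize)
    .log_line(logcon, ap, ": ", length(res), " OTUs after size filter (",
              nrow(otuMembership(res)), " amplicons)")
    results[[ap]] <- res
    reports[[ap]] <- stage(paste0("novelty_", ap),
      noveltyReport(res, combined, ref, floor = config$bestHitFloor,
                    allHits = config$allHits, scoring = scoring))
  }

  summary <- stage("summarize",
                   summarizeClusterings(results, reports, combined,
                                        t = config$t))
  audits <- stage("audit", {
    sets <- novelAmpliconSets(reports)
    lapply(sets, misclassificationAudit, amplicons = combined,
           references = ref, t = config$t, scoring = scoring)
  })

  files <- character(0)
  out <- config$outputDir
  for (ap in names(results)) {
    mpath <- file.path(out, paste0("membership_", ap, ".tsv"))
    m <- otuMembership(results[[ap]])
    m$abundance <- unname(abundances(combined)[m$member_id])
    m$origin <- unname(origins(combined)[m$member_id])
    m$approach <- ap
    utils::write.table(
      m[, c("otu_id", "approach", "member_id", "abundance", "origin",
            "is_seed")],
      mpath, sep = "\t", quote = FALSE, row.names = FALSE)
    npath <- file.path(out, paste0("novelty_", ap, ".tsv"))
    writeNoveltyReport(reports[[ap]], npath)
    files <- c(files, mpath, npath)
    e <- edgeList(results[[ap]])
    if (nrow(e)) {
      epath <- file.path(out, paste0("edges_", ap, ".tsv"))
      utils::write.table(e, epath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, epath)
    }
  }
  if (!is.null(graph)) {
    gpath <- file.path(out, "similarity_edges.tsv")
    writeEdgeList(graph, gpath)
    files <- c(files, gpath)
  }
  files <- c(files, writeComparisonSummary(summary, out))
  audit_tab <- do.call(rbind, lapply(names(audits), function(ap)
    data.frame(approach = ap, misclassified = audits[[ap]]$count,
               stringsAsFactors = FALSE)))
  apath <- file.path(out, "audit.tsv")
  utils::write.table(audit_tab, apath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, apath)

  manifest <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("noveltynet"))),
    vapply(setdiff(names(config), c("approaches")),
           function(k) sprintf("%s\t%s", k, paste(format(config[[k]]),
                                                  collapse = ",")), ""),
    sprintf("approaches\t%s", paste(config$approaches, collapse = ",")))
  mpath <- file.path(out, "manifest.tsv")
  writeLines(manifest, mpath)
  files <- c(files, mpath)
  .log_line(logcon, sprintf("pipeline finished in %.1fs",
                            as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))))
  invisible(list(amplicons = combined, references = ref, graph = graph,
                 results = results, reports = reports, summary = summary,
                 audits = audits, files = files))
}

#' Simulate a dataset to disk
#'
#' Thin wrapper: generate references and a community with
#' [generateReferences()] / [generateCommunity()] and write the FASTA
#' and truth files plus a config echo.
#'
#' @param dir output directory.
#' @param seed integer seed; reference generation uses `seed` and the
#'   community `seed + 1`.
#' @param ... passed on to [generateCommunity()] (and `nRef`, `length`,
#'   `minDivergence` to [generateReferences()]).
#' @param nRef,length,minDivergence reference-set parameters.
#' @return named character vector of paths, invisibly.
#' @export
simulateDataset <- function(dir, seed = 1, nRef = 20, length = 380,
                            minDivergence = 0.20, ...) {
  refs <- generateReferences(nRef = nRef, length = length,
                             minDivergence = minDivergence, seed = seed)
  com <- generateCommunity(refs, seed = seed + 1, ...)
  paths <- writeSyntheticDataset(com, refs, dir)
  cfg <- c(sprintf("seed\t%d", as.integer(seed)),
           sprintf("nRef\t%d", as.integer(nRef)),
           sprintf("length\t%d", as.integer(length)),
           sprintf("minDivergence\t%s", format(minDivergence)),
           vapply(names(list(...)), function(k)
             sprintf("%s\t%s", k, paste(format(list(...)[[k]]),
                                        collapse = ",")), ""))
  cfg_path <- file.path(dir, "simulation_config.tsv")
  writeLines(cfg, cfg_path)
  invisible(c(paths, config = cfg_path))
}
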