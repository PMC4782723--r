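# Synthetic amplicon communities with known ground truth.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(length) {
  paste(sample(.BASES, length, replace = TRUE), collapse = "")
}

# Apply n_events mutations; a fraction indel_fraction of them are
# single-base indels, the rest substitutions at distinct positions.
.mutate_seq <- function(s, n_events, indel_fraction = 0.1) {
  if (n_events == 0) return(s)
  n_indel <- sum(stats::runif(n_events) < indel_fraction)
  n_sub <- n_events - n_indel
  chars <- strsplit(s, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(chars), min(n_sub, length(chars)))
    for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1)
  }
  if (n_indel > 0) {
    for (k in seq_len(n_indel)) {
      if (stats::runif(1) < 0.5 && length(chars) > 1) {
        chars <- chars[-sample(length(chars), 1)]          # deletion
      } else {
        p <- sample(length(chars) + 1, 1)                  # insertion
        chars <- append(chars, sample(.BASES, 1), after = p - 1)
      }
    }
  }
  paste(chars, collapse = "")
}

# Substitutions at positions not used before on this walk, so distances
# along a stepping-stone chain are additive.
.step_seq <- function(chars, n_sub, used) {
  free <- setdiff(seq_along(chars), used)
  pos <- sample(free, min(n_sub, length(free)))
  for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1)
  list(chars = chars, used = c(used, pos))
}

.norm_edit <- function(a, b) {
  cpp_edit_distance(a, b, -1L) / pmax(nchar(a), nchar(b))
}

#' Generate a set of reference "species" sequences
#'
#' Draws `nRef` random DNA sequences of the given length and keeps them
#' only if every pair is at normalized edit distance (edit distance over
#' the longer length) at least `minDivergence`, by rejection sampling.
#' References model distinct species entries of a curated database: one
#' sequence per species, abundance 1.
#'
#' @param nRef number of references (default 20).
#' @param length sequence length in bp (default 380, the typical 18S V4
#'   amplicon length).
#' @param minDivergence minimum pairwise normalized divergence between
#'   references (default 0.20).
#' @param seed integer random seed; the output is deterministic given
#'   the seed.
#' @return an [AmpliconSet-class] of references with ids `ref001`, ...
#' @export
generateReferences <- function(nRef = 20, length = 380,
                               minDivergence = 0.20, seed = 1) {
  stopifnot(nRef >= 1, length >= 50, minDivergence > 0, minDivergence < 0.5)
  len <- as.integer(length)
  .with_seed(seed, {
    seqs <- character(0)
    budget <- 50 * nRef
    while (base::length(seqs) < nRef && budget > 0) {
      budget <- budget - 1
      cand <- .random_seq(len)
      n_have <- base::length(seqs)
      if (n_have == 0 ||
          all(.norm_edit(rep(cand, n_have), seqs) >= minDivergence))
        seqs <- c(seqs, cand)
    }
    if (base::length(seqs) < nRef)
      stop("could not place ", nRef, " references at pairwise divergence >= ",
           minDivergence, " within the attempt budget; ",
           "reduce nRef or minDivergence")
    AmpliconSet(seqs, ids = sprintf("ref%03d", seq_len(nRef)),
                abundance = rep(1L, nRef), origin = "reference",
                taxonomy = sprintf("Lineage_%03d", seq_len(nRef)))
  })
}

#' Generate an environmental amplicon community with known truth
#'
#' Emulates the structure a clustering comparison has to cope with:
#' per reference species, a cloud of closely related environmental
#' amplicons (intraspecific variation around a database entry), and a
#' small number of truly novel lineages diverged beyond the clustering
#' threshold from every reference.
#'
#' Each known cloud consists of a dominant variant (the reference
#' mutated at the per-base rate `cloudDivergence`; most abundant), an
#' optional stepping-stone chain, and independent mutants at the same
#' rate. The chain starts at the reference and walks away in steps of
#' `chainStep` substitutions at previously untouched positions, long
#' enough that its terminal members exceed `noveltyMargin` divergence
#' from the reference while staying linked through intermediates --
#' the configuration that separates radius-capped clustering from
#' connected components. Chain abundances decrease along the chain.
#'
#' Each novel lineage is founded by a sequence evolved from a random
#' reference at a divergence drawn from `novelDivergenceRange`
#' (re-drawn until its distance to every reference exceeds the range
#' minimum) and surrounded by its own small cloud. Abundances are
#' Zipf-like within each lineage: the member of rank k gets
#' `round(maxAbundance * k^-abundanceExponent)` reads (at least 1), so
#' the community is heavy-tailed with founders on top.
#'
#' Truth records are computed by exhaustive edit-distance comparison of
#' every environmental amplicon against all references:
#' `true_divergence` is the normalized distance to the nearest
#' reference and `truth_label` is `novel_lineage` exactly when that
#' distance exceeds `noveltyMargin` for every reference.
#'
#' @param references an [AmpliconSet-class] from [generateReferences()].
#' @param cloudSize amplicons per known cloud (default 20).
#' @param cloudDivergence per-base mutation rate within clouds
#'   (default 0.01).
#' @param novelLineages number of novel lineages (default 5).
#' @param novelDivergenceRange divergence interval for novel founders
#'   (default `c(0.05, 0.15)`); must lie strictly above `noveltyMargin`.
#' @param novelCloudSize amplicons around each novel founder, founder
#'   included (default 8).
#' @param abundanceExponent Zipf exponent of within-lineage abundances
#'   (default 1.5).
#' @param maxAbundance abundance of each lineage's top member
#'   (default 100).
#' @param indelFraction fraction of mutation events that are
#'   single-base indels rather than substitutions (default 0.1).
#' @param steppingStones generate the within-cloud chains
#'   (default `TRUE`).
#' @param chainStep substitutions per chain step (default 2).
#' @param noveltyMargin divergence above which an amplicon counts as
#'   truly novel (default 0.03, the complement of the usual 97%
#'   clustering threshold).
#' @param seed integer random seed.
#' @return list with elements `amplicons` (environmental
#'   [AmpliconSet-class], ids `env00001`, ...) and `truth` (data.frame
#'   with columns `amplicon_id`, `lineage`, `role`, `nearest_ref_id`,
#'   `true_divergence`, `truth_label`).
#' @export
generateCommunity <- function(references,
                              cloudSize = 20,
                              cloudDivergence = 0.01,
                              novelLineages = 5,
                              novelDivergenceRange = c(0.05, 0.15),
                              novelCloudSize = 8,
                              abundanceExponent = 1.5,
                              maxAbundance = 100,
                              indelFraction = 0.1,
                              steppingStones = TRUE,
                              chainStep = 2,
                              noveltyMargin = 0.03,
                              seed = 1) {
  stopifnot(methods::is(references, "AmpliconSet"), length(references) >= 1,
            cloudSize >= 1, cloudDivergence >= 0, novelLineages >= 0,
            abundanceExponent > 0, chainStep >= 1)
  if (novelLineages > 0 && novelDivergenceRange[1] <= noveltyMargin)
    stop("novelDivergenceRange must lie strictly above noveltyMargin (",
         noveltyMargin, "), otherwise novel lineages are not resolvable")
  rseq <- as.character(ampliconSequences(references))
  rid <- ampliconIds(references)
  .with_seed(seed, {
    seqs <- character(0); lineage <- character(0); role <- character(0)
    rank <- integer(0)

    for (r in seq_along(rseq)) {
      len <- nchar(rseq[r])
      # The dominant variant is a distinct haplotype: at least two
      # substitutions from the database reference (a reference entry
      # rarely equals the locally dominant sequence exactly). Its
      # positions are substitution-only and kept disjoint from the
      # chain's, so all divergences within the cloud are additive.
      # With chains disabled the offset is not needed, and a zero
      # cloud divergence means a noise-free community.
      n_dom <- max(if (steppingStones) 2L else 0L,
                   stats::rbinom(1, len, cloudDivergence))
      if (cloudDivergence == 0 && !steppingStones) n_dom <- 0L
      dom <- .step_seq(strsplit(rseq[r], "")[[1]], n_dom, integer(0))
      members <- paste(dom$chars, collapse = "")
      roles <- "dominant"
      if (steppingStones && cloudSize >= 2) {
        # walk far enough that the terminal exceeds the novelty margin
        n_steps <- min(cloudSize - 1,
                       ceiling(len * noveltyMargin / chainStep) + 2)
        chars <- strsplit(rseq[r], "")[[1]]
        used <- dom$used
        for (k in seq_len(n_steps)) {
          st <- .step_seq(chars, chainStep, used)
          chars <- st$chars; used <- st$used
          members <- c(members, paste(chars, collapse = ""))
          roles <- c(roles, "chain")
        }
      }
      # satellites: single-substitution neighbours of the dominant
      # variant, the noise-like halo that local-threshold clustering
      # links at d = 1 (absent in a noise-free community)
      n_sat <- if (cloudDivergence > 0)
        min(4, max(0, cloudSize - length(members))) else 0L
      for (k in seq_len(n_sat)) {
        members <- c(members, .mutate_seq(members[1], 1L, 0))
        roles <- c(roles, "satellite")
      }
      while (length(members) < cloudSize) {
        members <- c(members,
                     .mutate_seq(rseq[r],
                                 stats::rbinom(1, len, cloudDivergence),
                                 indelFraction))
        roles <- c(roles, "cloud")
      }
      seqs <- c(seqs, members)
      lineage <- c(lineage, rep(rid[r], length(members)))
      role <- c(role, roles)
      rank <- c(rank, seq_along(members))
    }

    for (v in seq_len(novelLineages)) {
      src <- sample(length(rseq), 1)
      len <- nchar(rseq[src])
      founder <- NULL
      for (try in seq_len(200)) {
        div <- stats::runif(1, novelDivergenceRange[1], novelDivergenceRange[2])
        cand <- .mutate_seq(rseq[src], round(div * len), indelFraction)
        if (all(.norm_edit(rep(cand, length(rseq)), rseq) >
                novelDivergenceRange[1])) { founder <- cand; break }
      }
      if (is.null(founder))
        stop("could not evolve novel lineage ", v, " beyond divergence ",
             novelDivergenceRange[1], " from every reference; ",
             "the divergence constraints look infeasible")
      lab <- sprintf("novel%02d", v)
      members <- founder; roles <- "founder"
      n_sat <- min(4, max(0, novelCloudSize - 1))
      for (k in seq_len(n_sat)) {
        members <- c(members, .mutate_seq(founder, 1L, 0))
        roles <- c(roles, "satellite")
      }
      while (length(members) < novelCloudSize) {
        members <- c(members,
                     .mutate_seq(founder,
                                 stats::rbinom(1, nchar(founder),
                                               max(cloudDivergence, 0.005)),
                                 indelFraction))
        roles <- c(roles, "cloud")
      }
      seqs <- c(seqs, members)
      lineage <- c(lineage, rep(lab, length(members)))
      role <- c(role, roles)
      rank <- c(rank, seq_along(members))
    }

    abundance <- pmax(1L, as.integer(round(maxAbundance * rank^(-abundanceExponent))))
    ids <- sprintf("env%05d", seq_along(seqs))
    amps <- AmpliconSet(seqs, ids = ids, abundance = abundance,
                        origin = "environmental")

    # exhaustive truth computation against every reference
    nq <- length(seqs); nr <- length(rseq)
    qv <- rep(seqs, times = nr); rv <- rep(rseq, each = nq)
    dm <- matrix(cpp_edit_distance(qv, rv, -1L) /
                   pmax(nchar(qv), nchar(rv)), nrow = nq)
    nearest <- apply(dm, 1L, which.min)
    true_div <- dm[cbind(seq_len(nq), nearest)]
    truth <- data.frame(
      amplicon_id = ids,
      lineage = lineage,
      role = role,
      nearest_ref_id = rid[nearest],
      true_divergence = true_div,
      truth_label = ifelse(true_div > noveltyMargin + 1e-12,
                           "novel_lineage", "known_variant"),
      stringsAsFactors = FALSE)
    list(amplicons = amps, truth = truth)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the environmental and reference FASTA files (with the chosen
#' abundance dialect) plus the truth table as TSV, so a dataset is fully
#' reproducible from its config.
#'
#' @param community a list from [generateCommunity()].
#' @param references the matching [AmpliconSet-class] of references.
#' @param dir output directory (created if needed).
#' @param dialect abundance dialect; see [readAmplicons()].
#' @return named character vector of the written paths, invisibly.
#' @export
writeSyntheticDataset <- function(community, references, dir,
                                  dialect = "size") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  env_path <- file.path(dir, "environmental.fasta")
  ref_path <- file.path(dir, "references.fasta")
  truth_path <- file.path(dir, "truth.tsv")
  writeAmplicons(community$amplicons, env_path, dialect = dialect)
  writeAmplicons(references, ref_path, dialect = dialect)
  utils::write.table(community$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(environmental = env_path, references = ref_path,
              truth = truth_path))
}
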