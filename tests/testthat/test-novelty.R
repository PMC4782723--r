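# OTU composition classes, shortest paths to references, novelty classes.

make_otuset <- function(members, edges = NULL, approach = "network") {
  # members: named list otu_id -> member ids; edges: data.frame(id_a,id_b)
  m <- do.call(rbind, lapply(names(members), function(o)
    data.frame(otu_id = o, member_id = members[[o]], is_seed = FALSE,
               stringsAsFactors = FALSE)))
  e <- if (is.null(edges)) {
    data.frame(otu_id = character(0), id_a = character(0),
               id_b = character(0), stringsAsFactors = FALSE)
  } else {
    oid <- m$otu_id[match(edges$id_a, m$member_id)]
    data.frame(otu_id = oid, edges, stringsAsFactors = FALSE)
  }
  methods::new("OTUSet", approach = approach, parameters = list(),
               membership = m, edges = e, removed = character(0))
}

origin_set <- function(env_ids, ref_ids, len = 30) {
  n <- length(env_ids) + length(ref_ids)
  AmpliconSet(random_dna(n, len), ids = c(env_ids, ref_ids),
              origin = rep(c("environmental", "reference"),
                           c(length(env_ids), length(ref_ids))))
}

test_that("OTU composition classes follow the member origins", {
  set.seed(71)
  amps <- origin_set(c("e1", "e2", "e3"), c("r1", "r2"))
  res <- make_otuset(list(o1 = c("e1", "r1"), o2 = "r2",
                          o3 = c("e2", "e3")),
                     edges = data.frame(id_a = c("e1", "e2"),
                                        id_b = c("r1", "e3")))
  cls <- classifyOtus(res, amps)
  expect_equal(unname(cls[c("o1", "o2", "o3")]),
               c("mixed", "ref_only", "env_only"))
  # random assignments vs a direct set-membership oracle
  for (rep in 1:20) {
    ids <- sprintf("x%02d", 1:12)
    org <- sample(c("environmental", "reference"), 12, replace = TRUE)
    amps2 <- AmpliconSet(random_dna(12, 20), ids = ids, origin = org)
    grp <- sample(1:4, 12, replace = TRUE)
    members <- split(ids, paste0("o", grp))
    res2 <- make_otuset(members, approach = "greedy")
    cls2 <- classifyOtus(res2, amps2)
    for (o in names(members)) {
      oo <- org[match(members[[o]], ids)]
      expected <- if (all(oo == "reference")) "ref_only"
                  else if (all(oo == "environmental")) "env_only"
                  else "mixed"
      expect_equal(unname(cls2[o]), expected)
    }
  }
  expect_error(classifyOtus(make_otuset(list(o1 = "ghost")), amps),
               "missing")
})

test_that("path distances run a multi-source BFS from references", {
  amps <- origin_set(c("e1", "e2", "e3"), c("r1", "r2"))
  res <- make_otuset(list(o1 = c("e1", "e2", "r1")),
                     edges = data.frame(id_a = c("e1", "e2"),
                                        id_b = c("r1", "e1")))
  d <- referencePathDistances(res, amps)
  expect_equal(d[["e1"]], 1)
  expect_equal(d[["e2"]], 2)
  # env-only OTU: all infinite
  res2 <- make_otuset(list(o1 = c("e1", "e2")),
                      edges = data.frame(id_a = "e1", id_b = "e2"))
  d2 <- referencePathDistances(res2, amps)
  expect_true(all(is.infinite(d2)))
  # greedy rejected; topology-less multi-member OTU rejected
  expect_error(referencePathDistances(
    make_otuset(list(o1 = c("e1", "r1")), approach = "greedy"), amps),
    "topology")
  expect_error(referencePathDistances(
    make_otuset(list(o1 = c("e1", "r1"))), amps), "without internal edges")
})

test_that("path distances equal the Floyd-Warshall oracle", {
  set.seed(73)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    ids <- sprintf("v%02d", seq_len(n))
    org <- sample(c("environmental", "reference"), n, replace = TRUE,
                  prob = c(0.7, 0.3))
    amps <- AmpliconSet(random_dna(n, 20), ids = ids, origin = org)
    em <- which(upper.tri(matrix(0, n, n)) &
                  matrix(runif(n * n) < 0.15, n, n), arr.ind = TRUE)
    # restrict to one OTU: take the whole vertex set as a single OTU
    res <- make_otuset(stats::setNames(list(ids), "o1"),
                       edges = if (nrow(em)) data.frame(
                         id_a = ids[em[, 1]], id_b = ids[em[, 2]]) else NULL)
    if (n > 1 && nrow(em) == 0) next  # rejected as topology-less
    got <- referencePathDistances(res, amps)
    D <- oracle_fw_distances(n, em)
    refs <- which(org == "reference")
    for (e in which(org == "environmental")) {
      expected <- if (length(refs)) min(D[e, refs]) else Inf
      expect_equal(got[[ids[e]]], expected)
    }
  }
})

test_that("novelty classes encode the distance rules", {
  expect_equal(classifyNovelty("mixed", 1), "covered")
  expect_equal(classifyNovelty("mixed", 3), "novel_variant")
  expect_equal(classifyNovelty("env_only", Inf), "novel")
  expect_equal(classifyNovelty(c("mixed", "mixed", "env_only"),
                               c(1, 2, Inf)),
               c("covered", "novel_variant", "novel"))
  expect_error(classifyNovelty("env_only", 2), "inconsistent")
  expect_error(classifyNovelty("mixed", 0.5), ">= 1")
})

test_that("novelty report covers every retained environmental amplicon", {
  ds <- small_dataset(seed = 121)
  for (build in list(
    function() filterSmallOtus(clusterNetwork(
      buildSimilarityGraph(ds$combined, t = 0.97)), 3),
    function() filterSmallOtus(clusterGreedy(ds$combined, t = 0.97), 3),
    function() filterSmallOtus(clusterSwarm(ds$combined), 3))) {
    res <- build()
    rep <- noveltyReport(res, ds$combined, ds$refs)
    m <- otuMembership(res)
    env_retained <- m$member_id[origins(ds$combined)[m$member_id] ==
                                  "environmental"]
    expect_setequal(rep$amplicon_id, env_retained)
    expect_false(any(duplicated(rep$amplicon_id)))
    if (res@approach == "greedy") {
      expect_true(all(is.na(rep$path_distance)))
      expect_equal(rep$novelty_class,
                   ifelse(rep$otu_class == "env_only", "novel", "covered"))
    } else {
      expect_true(all(is.infinite(rep$path_distance[
        rep$otu_class == "env_only"])))
      expect_true(all(rep$path_distance[rep$otu_class == "mixed"] >= 1))
      expect_equal(rep$novelty_class == "covered", rep$path_distance == 1)
    }
    # best hits: computed only for env_only amplicons by default, and
    # either NA (below the floor) or at least the floor
    bh <- rep$best_hit_identity
    expect_true(all(is.na(bh[rep$otu_class != "env_only"])))
    expect_true(all(is.na(bh[rep$otu_class == "env_only"]) |
                      bh[rep$otu_class == "env_only"] >= 0.70 - 1e-9))
  }
})

test_that("a radius-capped amplicon identical to a reference is audited", {
  # An environmental twin of reference R joins an abundant centroid Z at
  # exactly the threshold; a later centroid C sits closer to R, so R
  # itself ends up elsewhere and the twin's OTU is exclusively
  # environmental despite containing a sequence identical to R.
  set.seed(79)
  len <- 300  # radius at t = 0.97 is 9 substitutions
  Z <- random_dna(1, len)
  subst_at <- function(s, pos) {
    chars <- strsplit(s, "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
    paste(chars, collapse = "")
  }
  X <- subst_at(Z, 1:8)          # twin of R, 8 subs from Z (0.9733)
  C <- subst_at(X, 9:10)         # 2 subs from X, 10 from Z (0.9667 < t)
  xs1 <- subst_at(X, 11)         # 9 subs from Z: identity exactly 0.97
  xs2 <- subst_at(X, 12)
  amps <- AmpliconSet(c(Z, X, xs1, xs2, C),
                      ids = c("Z", "X", "xs1", "xs2", "C"),
                      abundance = c(100L, 50L, 20L, 19L, 10L))
  refs <- AmpliconSet(X, ids = "R", abundance = 1L, origin = "reference")
  combined <- c(amps, refs)
  res <- clusterGreedy(combined, t = 0.97)
  m <- otuMembership(res)
  expect_equal(m$otu_id[m$member_id == "R"], m$otu_id[m$member_id == "C"])
  expect_equal(m$otu_id[m$member_id == "X"], m$otu_id[m$member_id == "Z"])
  res <- filterSmallOtus(res, 3)
  cls <- classifyOtus(res, combined)
  twin_otu <- otuMembership(res)$otu_id[otuMembership(res)$member_id == "X"]
  expect_equal(unname(cls[twin_otu]), "env_only")
  rep <- noveltyReport(res, combined, refs)
  twin_row <- rep[rep$amplicon_id == "X", ]
  expect_equal(twin_row$novelty_class, "novel")
  expect_equal(twin_row$best_hit_identity, 1.0)
  audit <- misclassificationAudit(
    novelAmpliconSets(list(greedy = rep))$greedy, combined, refs, t = 0.97)
  expect_gte(audit$count, 1L)
  expect_true("X" %in% audit$ids)
  # the same input under the network approach puts X next to R: no audit
  net <- filterSmallOtus(clusterNetwork(
    buildSimilarityGraph(combined, t = 0.97)), 1)
  nrep <- noveltyReport(net, combined, refs)
  expect_equal(misclassificationAudit(
    novelAmpliconSets(list(network = nrep))$network,
    combined, refs, t = 0.97)$count, 0L)
})

test_that("novelty TSV uses inf and NA sentinels", {
  ds <- small_dataset(seed = 131)
  res <- filterSmallOtus(clusterNetwork(
    buildSimilarityGraph(ds$combined, t = 0.97)), 3)
  rep <- noveltyReport(res, ds$combined, ds$refs)
  f <- tempfile(fileext = ".tsv")
  writeNoveltyReport(rep, f)
  lines <- readLines(f)
  expect_match(lines[1],
               "approach\tamplicon_id\totu_id\totu_class\tpath_distance")
  if (any(rep$otu_class == "env_only")) expect_true(any(grepl("\tinf\t", lines)))
})
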