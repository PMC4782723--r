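# Greedy centroid, network components, swarm, and the small-OTU filter.

test_that("greedy clustering shows the radius cap", {
  # B joins A at exactly the threshold; C is linked to B but beyond the
  # radius of centroid A, so it founds its own OTU
  set.seed(31)
  A <- random_dna(1, 100)
  B <- mutate_dna(A, n_sub = 3)
  chars <- strsplit(B, "")[[1]]
  diffpos <- which(chars != strsplit(A, "")[[1]])
  fresh <- setdiff(seq_along(chars), diffpos)[1:2]
  for (p in fresh) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  C <- paste(chars, collapse = "")
  expect_equal(pairIdentity(A, B), 0.97)
  expect_equal(pairIdentity(A, C), 0.95)
  amps <- AmpliconSet(c(A, B, C), ids = c("A", "B", "C"),
                      abundance = c(10L, 5L, 1L))
  res <- clusterGreedy(amps, t = 0.97)
  m <- otuMembership(res)
  expect_equal(length(res), 2L)
  expect_equal(m$otu_id[m$member_id == "A"], m$otu_id[m$member_id == "B"])
  expect_false(m$otu_id[m$member_id == "C"] == m$otu_id[m$member_id == "A"])
  expect_true(m$is_seed[m$member_id == "A"])
  expect_true(m$is_seed[m$member_id == "C"])
})

test_that("greedy clustering degenerate cases", {
  one <- toy_amplicons("ACGTACGTAC", ids = "solo")
  res <- clusterGreedy(one)
  expect_equal(length(res), 1L)
  expect_true(otuMembership(res)$is_seed)

  # all pairwise identities >= t -> a single OTU
  set.seed(37)
  base <- random_dna(1, 100)
  amps <- toy_amplicons(c(base, vapply(1:5, function(i)
    mutate_dna(base, n_sub = 1), "")), abundance = 6:1)
  res2 <- clusterGreedy(amps, t = 0.95)
  expect_equal(length(res2), 1L)

  expect_equal(length(clusterGreedy(toy_amplicons(character(0),
                                                  ids = character(0)))), 0L)
})

test_that("every greedy member is within the threshold of its centroid", {
  set.seed(41)
  ds <- small_dataset(seed = 101)
  res <- clusterGreedy(ds$combined, t = 0.97)
  m <- otuMembership(res)
  seqs <- stats::setNames(as.character(ampliconSequences(ds$combined)),
                          ampliconIds(ds$combined))
  for (oid in otuIds(res)) {
    mem <- m[m$otu_id == oid, ]
    centroid <- mem$member_id[mem$is_seed]
    expect_length(centroid, 1L)
    others <- setdiff(mem$member_id, centroid)
    if (length(others))
      expect_true(all(vapply(others, function(x)
        pairIdentity(seqs[[x]], seqs[[centroid]]), 0) >= 0.97 - 1e-9))
  }
  # centroids are pairwise below the threshold
  cents <- m$member_id[m$is_seed]
  if (length(cents) > 1) {
    for (i in seq_along(cents)[-1]) {
      expect_true(all(vapply(cents[seq_len(i - 1)], function(x)
        pairIdentity(seqs[[x]], seqs[[cents[i]]]), 0) < 0.97))
    }
  }
})

test_that("network components match the transitive-closure oracle", {
  # edgeless graph -> all singletons; path graph -> one OTU
  g0 <- methods::new("SimilarityGraph", nodes = c("a", "b", "c"),
                     edges = data.frame(id_a = character(0),
                                        id_b = character(0),
                                        identity = numeric(0)),
                     threshold = 0.97)
  r0 <- clusterNetwork(g0)
  expect_equal(length(r0), 3L)
  gp <- methods::new("SimilarityGraph", nodes = c("a", "b", "c"),
                     edges = data.frame(id_a = c("a", "b"),
                                        id_b = c("b", "c"),
                                        identity = c(0.98, 0.99)),
                     threshold = 0.97)
  rp <- clusterNetwork(gp)
  expect_equal(length(rp), 1L)
  expect_equal(nrow(edgeList(rp)), 2L)

  set.seed(43)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    em <- which(upper.tri(matrix(0, n, n)) &
                  matrix(runif(n * n) < 0.1, n, n), arr.ind = TRUE)
    nodes <- sprintf("n%02d", seq_len(n))
    g <- methods::new("SimilarityGraph", nodes = nodes,
                      edges = data.frame(
                        id_a = nodes[em[, 1]], id_b = nodes[em[, 2]],
                        identity = rep(0.99, nrow(em))),
                      threshold = 0.97)
    res <- clusterNetwork(g)
    comp <- oracle_components(n, em)
    m <- otuMembership(res)
    got <- stats::setNames(m$otu_id, m$member_id)[nodes]
    # same partition: equal label co-occurrence
    expect_equal(outer(got, got, "=="), outer(comp, comp, "=="),
                 ignore_attr = TRUE)
  }
})

test_that("network clustering is invariant to input order", {
  set.seed(47)
  ds <- small_dataset(seed = 55)
  g1 <- buildSimilarityGraph(ds$combined, t = 0.97)
  perm <- sample(length(ds$combined))
  g2 <- buildSimilarityGraph(ds$combined[perm], t = 0.97)
  p1 <- otuMembership(clusterNetwork(g1))
  p2 <- otuMembership(clusterNetwork(g2))
  s1 <- lapply(split(p1$member_id, p1$otu_id), sort)
  s2 <- lapply(split(p2$member_id, p2$otu_id), sort)
  expect_setequal(unname(s1), unname(s2))
})

test_that("swarm captures follow the local threshold and breaking rule", {
  set.seed(53)
  A <- random_dna(1, 50)
  B <- mutate_dna(A, n_sub = 1)
  # C at one further difference from B, at a fresh position
  chars <- strsplit(B, "")[[1]]
  p <- setdiff(seq_along(chars), which(chars != strsplit(A, "")[[1]]))[1]
  chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  C <- paste(chars, collapse = "")
  amps <- AmpliconSet(c(A, B, C), ids = c("A", "B", "C"),
                      abundance = c(10L, 5L, 2L))
  res <- clusterSwarm(amps, d = 1, fastidious = FALSE)
  expect_equal(length(res), 1L)   # chain A(10)-B(5)-C(2) is non-increasing

  # two amplicons at distance 3, no intermediates: unreachable
  D <- mutate_dna(A, n_sub = 3)
  res2 <- clusterSwarm(AmpliconSet(c(A, D), ids = c("A", "D"),
                                   abundance = c(5L, 4L)),
                       d = 1, fastidious = FALSE)
  expect_equal(length(res2), 2L)

  # breaking interrupts a chain at an abundance rise
  E <- mutate_dna(C, n_sub = 0)  # copy C then one more step up in abundance
  chars <- strsplit(C, "")[[1]]
  p2 <- setdiff(seq_along(chars), c(which(chars != strsplit(A, "")[[1]])))[2]
  chars[p2] <- sample(setdiff(BASES, chars[p2]), 1)
  E <- paste(chars, collapse = "")
  ampsE <- AmpliconSet(c(A, B, C, E), ids = c("A", "B", "C", "E"),
                       abundance = c(10L, 5L, 2L, 50L))
  # E is the most abundant seed; C is its first-generation capture, but
  # the chain cannot climb from C (2) to B (5) with breaking on
  resb <- clusterSwarm(ampsE, d = 1, breaking = TRUE, fastidious = FALSE)
  mb <- otuMembership(resb)
  expect_equal(sort(mb$member_id[mb$otu_id ==
                                   mb$otu_id[mb$member_id == "E"]]),
               c("C", "E"))
  resnb <- clusterSwarm(ampsE, d = 1, breaking = FALSE, fastidious = FALSE)
  expect_equal(length(resnb), 1L)
})

test_that("swarm without breaking equals single-linkage closure", {
  set.seed(59)
  base <- random_dna(8, 50)
  seqs <- unique(unlist(lapply(base, function(s) {
    out <- s
    for (k in 1:24) out <- c(out, mutate_dna(sample(out, 1),
                                             n_sub = sample(0:1, 1),
                                             n_indel = sample(0:1, 1)))
    unique(out)
  })))
  n <- length(seqs)
  expect_gte(n, 100)
  amps <- toy_amplicons(seqs, ids = sprintf("s%03d", seq_len(n)),
                        abundance = sample(1:50, n, replace = TRUE))
  res <- clusterSwarm(amps, d = 1, breaking = FALSE, fastidious = FALSE)
  # oracle: closure of the distance<=1 relation, by full DP on all pairs
  em <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (oracle_edit_distance(seqs[i], seqs[j]) <= 1)
        em[[length(em) + 1]] <- c(i, j)
    }
  }
  em <- do.call(rbind, c(em, list(matrix(0L, 0, 2))))
  comp <- oracle_components(n, em)
  m <- otuMembership(res)
  got <- stats::setNames(m$otu_id, m$member_id)[sprintf("s%03d", seq_len(n))]
  expect_equal(outer(got, got, "=="), outer(comp, comp, "=="),
               ignore_attr = TRUE)
})

test_that("fastidious grafts light OTUs within twice the local threshold", {
  set.seed(61)
  A <- random_dna(1, 60)
  sat <- vapply(1:3, function(i) mutate_dna(A, n_sub = 1), "")
  L <- mutate_dna(A, n_sub = 2)  # distance 2 from A: reachable by graft only
  far <- mutate_dna(A, n_sub = 6)
  amps <- AmpliconSet(c(A, sat, L, far),
                      ids = c("A", "s1", "s2", "s3", "L", "far"),
                      abundance = c(20L, 3L, 2L, 2L, 1L, 1L))
  res_off <- clusterSwarm(amps, d = 1, fastidious = FALSE)
  m_off <- otuMembership(res_off)
  expect_true(m_off$otu_id[m_off$member_id == "L"] !=
                m_off$otu_id[m_off$member_id == "A"])
  res_on <- clusterSwarm(amps, d = 1, fastidious = TRUE, boundary = 3)
  m_on <- otuMembership(res_on)
  expect_equal(m_on$otu_id[m_on$member_id == "L"],
               m_on$otu_id[m_on$member_id == "A"])
  # far (distance 6 > 2d) stays its own light OTU
  expect_false(m_on$otu_id[m_on$member_id == "far"] ==
                 m_on$otu_id[m_on$member_id == "A"])
  # the graft edge is recorded and connects the light member
  e <- edgeList(res_on)
  expect_true(any((e$id_a == "L" | e$id_b == "L")))
})

test_that("swarm members are reachable from the seed within d per step", {
  ds <- small_dataset(seed = 77)
  res <- clusterSwarm(ds$combined, d = 1, fastidious = FALSE)
  m <- otuMembership(res)
  seqs <- stats::setNames(as.character(ampliconSequences(ds$combined)),
                          ampliconIds(ds$combined))
  e <- edgeList(res)
  for (oid in unique(m$otu_id[duplicated(m$otu_id)])) {
    mem <- m$member_id[m$otu_id == oid]
    sub <- e[e$otu_id == oid, ]
    # every recorded edge is a distance<=1 pair
    expect_true(all(editDistance(seqs[sub$id_a], seqs[sub$id_b]) <= 1))
    # the edges connect the member set
    g <- igraph::graph_from_data_frame(sub[, c("id_a", "id_b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = mem))
    expect_true(igraph::is_connected(g))
  }
})

test_that("greedy OTUs never span network components at the same t", {
  ds <- small_dataset(seed = 91)
  t <- 0.97
  gre <- clusterGreedy(ds$combined, t = t)
  net <- clusterNetwork(buildSimilarityGraph(ds$combined, t = t))
  mg <- otuMembership(gre)
  mn <- otuMembership(net)
  comp_of <- stats::setNames(mn$otu_id, mn$member_id)
  for (oid in otuIds(gre)) {
    mem <- mg$member_id[mg$otu_id == oid]
    expect_equal(length(unique(comp_of[mem])), 1L, info = oid)
  }
  # ... and the network result therefore has at most as many OTUs
  expect_lte(length(net), length(gre))
})

test_that("the small-OTU filter removes singletons and doubletons", {
  set.seed(67)
  seqs <- c(random_dna(1, 40), random_dna(1, 40), random_dna(1, 40))
  amps <- toy_amplicons(c(seqs[1], mutate_dna(seqs[1], 1),
                          mutate_dna(seqs[1], 1),
                          seqs[2], mutate_dna(seqs[2], 1), seqs[3]),
                        abundance = c(9L, 4L, 3L, 8L, 2L, 5L))
  res <- clusterSwarm(amps, d = 1, fastidious = FALSE)
  sizes <- otuSizes(res)
  expect_setequal(unname(sizes), c(3L, 2L, 1L))
  expect_equal(otuMembership(filterSmallOtus(res, 1)),
               otuMembership(res))
  f3 <- filterSmallOtus(res, 3)
  expect_equal(unname(otuSizes(f3)), 3L)
  expect_length(f3@removed, 3L)
  # survivor count equals a direct size-count oracle on random results
  for (minA in 1:4) {
    expect_equal(length(filterSmallOtus(res, minA)),
                 sum(sizes >= minA))
  }
})
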