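# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with the package:
# plain-R dynamic programming, matrix transitive closure, recursive
# enumeration.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE), collapse = ""), "")
}

mutate_dna <- function(s, n_sub = 0, n_indel = 0) {
  chars <- strsplit(s, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(chars), n_sub)
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  for (k in seq_len(n_indel)) {
    if (runif(1) < 0.5 && length(chars) > 1) {
      chars <- chars[-sample(length(chars), 1)]
    } else {
      p <- sample(length(chars) + 1, 1)
      chars <- append(chars, sample(BASES, 1), after = p - 1)
    }
  }
  paste(chars, collapse = "")
}

# Exhaustive affine-gap global alignment score by memoized recursion
# over (position in a, position in b, previous move). Enumerates the
# whole alignment space; a gap of length k costs go + k * ge.
oracle_align_score <- function(a, b, match = 2, mismatch = -4,
                               go = -20, ge = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i == la && j == lb) return(0)
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i < la && j < lb) {
      s <- if (ca[i + 1] == cb[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "d"))
    }
    if (i < la) {
      open <- if (prev == "u") 0 else go
      best <- max(best, open + ge + rec(i + 1, j, "u"))
    }
    if (j < lb) {
      open <- if (prev == "l") 0 else go
      best <- max(best, open + ge + rec(i, j + 1, "l"))
    }
    memo[[key]] <- best
    best
  }
  rec(0, 0, "d")
}

# Plain full-matrix Levenshtein (base R's adist is used as a second,
# fully independent implementation where convenient).
oracle_edit_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  D <- matrix(0L, la + 1, lb + 1)
  D[, 1] <- 0:la
  D[1, ] <- 0:lb
  for (i in seq_len(la))
    for (j in seq_len(lb))
      D[i + 1, j + 1] <- min(D[i, j] + (ca[i] != cb[j]),
                             D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  D[la + 1, lb + 1]
}

# Connected components by boolean-matrix transitive closure.
oracle_components <- function(n, edges) {
  A <- diag(TRUE, n)
  if (nrow(edges)) {
    A[cbind(edges[, 1], edges[, 2])] <- TRUE
    A[cbind(edges[, 2], edges[, 1])] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- integer(n)
  nxt <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      nxt <- nxt + 1L
      comp[A[v, ] > 0] <- nxt
    }
  }
  comp
}

# All-pairs shortest paths (Floyd-Warshall) on an unweighted graph.
oracle_fw_distances <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (nrow(edges)) {
    D[cbind(edges[, 1], edges[, 2])] <- 1
    D[cbind(edges[, 2], edges[, 1])] <- 1
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
  D
}

# Small fixture: an AmpliconSet built in code.
toy_amplicons <- function(seqs, ids = sprintf("a%02d", seq_along(seqs)),
                          abundance = rep(1L, length(seqs)),
                          origin = "environmental") {
  AmpliconSet(seqs, ids = ids, abundance = abundance, origin = origin)
}

# Default small synthetic dataset used by several suites: fast but with
# the full structure (clouds, chains, satellites, novel lineages).
small_dataset <- function(seed, nRef = 5, len = 150, cloudSize = 8,
                          novelLineages = 2, novelCloudSize = 5,
                          steppingStones = TRUE) {
  refs <- generateReferences(nRef = nRef, length = len, seed = seed)
  com <- generateCommunity(refs, cloudSize = cloudSize,
                           novelLineages = novelLineages,
                           novelCloudSize = novelCloudSize,
                           steppingStones = steppingStones,
                           seed = seed + 1000)
  list(refs = refs, com = com, combined = c(com$amplicons, refs))
}

# Same alignment-space optimum as oracle_align_score, but row-vectorized
# so whole enumeration sets stay affordable. Verified against the
# recursive enumeration on short pairs in the alignment suite.
oracle_align_score_vec <- function(a, b, match = 2, mismatch = -4,
                                   go = -20, ge = -2) {
  ca <- utf8ToInt(a); cb <- utf8ToInt(b)
  la <- length(ca); lb <- length(cb)
  NEG <- -1e18
  M <- c(0, rep(NEG, lb)); X <- rep(NEG, lb + 1)
  Y <- c(NEG, go + (1:lb) * ge)
  for (i in 1:la) {
    Mp <- M; Xp <- X; Yp <- Y
    M <- rep(NEG, lb + 1); X <- rep(NEG, lb + 1); Y <- rep(NEG, lb + 1)
    s <- ifelse(ca[i] == cb, match, mismatch)
    M[-1] <- pmax(Mp[-(lb + 1)], Xp[-(lb + 1)], Yp[-(lb + 1)]) + s
    X[-1] <- pmax(Mp[-1] + go + ge, Xp[-1] + ge, Yp[-1] + go + ge)
    X[1] <- go + i * ge
    for (j in 1:lb) Y[j + 1] <- max(M[j] + go + ge, X[j] + go + ge,
                                    Y[j] + ge)
  }
  max(M[lb + 1], X[lb + 1], Y[lb + 1])
}
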