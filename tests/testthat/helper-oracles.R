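# Brute-force oracles and small fixture builders used across test files.

# coactivation by explicit double loop over frames
bruteCoactivation <- function(a) {
  n <- nrow(a)
  co <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0L
    for (f in seq_len(ncol(a))) if (a[i, f] == 1L && a[j, f] == 1L)
      cnt <- cnt + 1L
    co[i, j] <- cnt
  }
  co
}

# Jaccard via explicit set operations on the columns of x
bruteJaccard <- function(x) {
  m <- ncol(x)
  s <- matrix(0, m, m)
  for (u in seq_len(m)) for (v in seq_len(m)) {
    su <- which(x[, u] == 1)
    sv <- which(x[, v] == 1)
    s[u, v] <- length(intersect(su, sv)) / length(union(su, sv))
  }
  s
}

# ensemble network density by explicit pair enumeration
bruteDensity <- function(adj, members) {
  cnt <- 0L
  tot <- 0L
  for (i in seq_along(members)) for (j in seq_along(members)) {
    if (i >= j) next
    tot <- tot + 1L
    if (adj[members[i], members[j]]) cnt <- cnt + 1L
  }
  cnt / tot
}

randomRaster <- function(n, f, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(rbinom(n * f, 1L, p), n, f)
    # avoid degenerate all-zero rows for operations that dislike them
    for (i in which(rowSums(a) == 0L)) a[i, sample.int(f, 1L)] <- 1L
    a
  })
}

# best ground-truth Jaccard match for each detected ensemble's member set
memberRecovery <- function(ens, truthMembers) {
  vapply(seq_len(nEnsembles(ens)), function(j) {
    mem <- ensembleMembers(ens, j)
    max(vapply(truthMembers, function(m)
      length(intersect(m, mem)) / length(union(m, mem)), numeric(1)))
  }, numeric(1))
}

# an EnsembleSet built directly from member/frame lists (for matching and
# fate tests that do not need a detection run)
makeEnsembleSet <- function(members, frames = NULL, nFrames = 100,
                            ids = NULL) {
  if (is.null(frames))
    frames <- lapply(seq_along(members), function(j)
      ((j - 1L) * 10L + 1L):((j - 1L) * 10L + 3L))
  if (is.null(ids)) ids <- sort(unique(unlist(members)))
  methods::new("EnsembleSet",
               members = lapply(members, as.integer),
               frames = lapply(frames, as.integer),
               nFrames = as.integer(nFrames), neuronIds = as.integer(ids),
               sessionLabel = "fixture", config = list())
}

# a FunctionalNetwork wrapped around a given adjacency matrix
makeNetwork <- function(adj, co = NULL) {
  n <- nrow(adj)
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  if (is.null(co)) co <- matrix(10L, n, n)
  co[!adj] <- 0L
  diag(co) <- 10L
  thr <- matrix(5, n, n)
  co[adj] <- 10L
  methods::new("FunctionalNetwork", coactivation = co, threshold = thr,
               adjacency = adj, nSurrogates = 100L, alpha = 0.05,
               seed = 1L, mode = "shared_shift",
               neuronIds = seq_len(n), surrogates = NULL)
}
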