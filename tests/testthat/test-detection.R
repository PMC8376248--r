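test_that("Jaccard matrix matches hand counts and set-based brute force", {
  s <- jaccardMatrix(cbind(c(1, 1, 0), c(1, 0, 1)))
  expect_equal(s[1, 2], 1 / 3)
  expect_equal(diag(s), c(1, 1))
  same <- jaccardMatrix(cbind(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(same[1, 2], 1)
  disjoint <- jaccardMatrix(cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(disjoint[1, 2], 0)
  x <- randomRaster(20, 15, p = 0.4, seed = 31)
  expect_equal(jaccardMatrix(x), bruteJaccard(x), tolerance = 1e-12)
  s2 <- jaccardMatrix(x)
  expect_true(all(s2 >= 0 & s2 <= 1))
  expect_identical(s2, t(s2))
  bad <- x
  bad[, 7] <- 0L
  expect_error(jaccardMatrix(bad), "index 7")
})

test_that("vector selection keeps similar clusters and drops outliers", {
  v <- c(1, 1, 1, 1, 0, 0, 0, 0)
  outlier <- c(1, 1, 0, 0, 1, 1, 0, 0)  # similarity 1/3 to v
  sel <- selectSimilarVectors(jaccardMatrix(cbind(v, v, v, outlier)))
  expect_identical(as.integer(sel), 1:3)
  # exactly 2/3 similarity does not merge (strict threshold)
  u <- c(1, 1, 0, 0)
  w <- c(1, 1, 1, 0)  # J(u, w) = 2/3
  expect_warning(sel2 <- selectSimilarVectors(jaccardMatrix(cbind(u, w))),
                 "no vector cluster")
  expect_length(sel2, 0)
})

test_that("two planted vector patterns are both fully retained", {
  pat1 <- c(rep(1, 12), rep(0, 16))
  pat2 <- c(rep(0, 16), rep(1, 12))
  jitter <- function(p, drop) {
    q <- p
    q[which(q == 1)[drop]] <- 0
    q
  }
  cols <- cbind(pat1, jitter(pat1, 1), jitter(pat1, 2),
                pat2, jitter(pat2, 1), jitter(pat2, 2))
  s <- jaccardMatrix(cols)
  expect_true(all(s[1:3, 1:3] >= 0.8))
  expect_true(all(s[1:3, 4:6] <= 0.3))
  sel <- selectSimilarVectors(s)
  expect_identical(as.integer(sel), 1:6)
})

test_that("contrast index behaves analytically on block matrices", {
  blocks <- function(sizes, within, between) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    s <- matrix(between, n, n)
    for (g in seq_along(sizes)) s[lab == g, lab == g] <- within
    diag(s) <- 1
    list(s = s, labels = lab)
  }
  perfect <- blocks(c(4, 4), 1, 0)
  expect_equal(contrastIndex(perfect$s, perfect$labels), 1)
  uniform <- matrix(0.5, 6, 6)
  diag(uniform) <- 1
  expect_equal(contrastIndex(uniform, rep(1:2, each = 3)), 0)
  three <- blocks(c(5, 5, 5), 0.8, 0.2)
  expect_equal(contrastIndex(three$s, three$labels), 0.6)
  expect_error(contrastIndex(three$s, rep(1, 15)), "2 clusters")
  expect_equal(contrastIndex(diag(2), 1:2), -1)
})

test_that("the contrast index peaks at the planted number of blocks", {
  for (case in 1:20) {
    k <- withr::with_seed(case, sample(2:5, 1))
    sizes <- withr::with_seed(case + 50, sample(5:10, k, replace = TRUE))
    n <- sum(sizes)
    lab <- rep(seq_len(k), sizes)
    s <- withr::with_seed(case + 100, {
      s <- matrix(runif(n * n, 0.1, 0.3), n, n)
      s[outer(lab, lab, "==")] <- runif(sum(outer(lab, lab, "==")), 0.7, 0.9)
      s <- (s + t(s)) / 2
      diag(s) <- 1
      s
    })
    tree <- hclust(as.dist(1 - s), method = "ward.D")
    ciAt <- function(kk) contrastIndex(s, cutree(tree, k = kk))
    expect_gte(ciAt(k), ciAt(max(k - 1, 2)))
    expect_gte(ciAt(k), ciAt(k + 1))
  }
})

noiseFreeRaster <- function() {
  # two disjoint 6-neuron patterns, each repeated in 20 frames
  n <- 14
  f <- 60
  a <- matrix(0L, n, f)
  f1 <- seq(1, 39, by = 2)
  f2 <- seq(2, 40, by = 2)
  a[1:6, f1] <- 1L
  a[7:12, f2] <- 1L
  BinaryRaster(a)
}

test_that("noise-free patterns cluster into exactly their two ensembles", {
  r <- noiseFreeRaster()
  ens <- clusterEnsembles(r, retained = 1:40)
  expect_identical(nEnsembles(ens), 2L)
  expect_setequal(ensembleMembers(ens, 1), 1:6)
  expect_setequal(ensembleMembers(ens, 2), 7:12)
  expect_setequal(unlist(ensembleFrames(ens)), 1:40)
  expect_identical(sum(activityVector(ens, 1)),
                   length(ensembleFrames(ens, 1)))
  expect_error(clusterEnsembles(r, retained = 1:2), "insufficient")
})

test_that("detection is invariant to frame and neuron permutations", {
  r <- noiseFreeRaster()
  ens <- clusterEnsembles(r, retained = 1:40)
  perm <- withr::with_seed(5, sample.int(60))
  rPerm <- r[, perm]
  ensPerm <- clusterEnsembles(rPerm, retained = which(perm %in% 1:40))
  expect_identical(nEnsembles(ensPerm), 2L)
  membersA <- lapply(ensembleMembers(ens), sort)
  membersB <- lapply(ensembleMembers(ensPerm), sort)
  expect_setequal(membersA, membersB)
})

test_that("end-to-end detection recovers planted ensembles at low background", {
  # sparse background: every planted member is recovered; the per-pair 5%
  # membership test may admit a couple of chance co-firing neurons, which
  # bounds the member-set Jaccard from below without losing structure
  sim <- generateSession(sessionParams(nNeurons = 48, nFrames = 1500,
                                       nEnsembles = 3, ensembleSize = 12,
                                       eventsPerEnsemble = 200,
                                       participationProb = 0.9,
                                       backgroundRate = 0.01),
                         seed = 14)
  ens <- detectEnsembles(sim$raster, nSurrogates = 300, seed = 14)
  expect_identical(nEnsembles(ens), 3L)
  truth <- sim$truth@members[[1]]
  expect_true(all(memberRecovery(ens, truth) >= 0.75))
  for (j in seq_len(nEnsembles(ens))) {
    mem <- ensembleMembers(ens, j)
    best <- truth[[which.max(vapply(truth, function(m)
      length(intersect(m, mem)) / length(union(m, mem)), numeric(1)))]]
    expect_length(setdiff(best, mem), 0)  # no planted member is missed
  }
  # with and without vector selection the planted structure is identical
  ensAll <- detectEnsembles(sim$raster, nSurrogates = 300, seed = 14,
                            vectorSelection = FALSE)
  expect_identical(nEnsembles(ensAll), 3L)
  expect_setequal(lapply(ensembleMembers(ens), sort),
                  lapply(ensembleMembers(ensAll), sort))
})

test_that("independent neurons yield the insufficient-coactivity error path", {
  r <- BinaryRaster(matrix(withr::with_seed(9, rbinom(30 * 400, 1, 0.05)),
                           30, 400))
  expect_error(detectEnsembles(r, nSurrogates = 200, alpha = 0.001,
                               seed = 9),
               "insufficient coactivity")
})

test_that("shuffling a raster destroys the planted ensemble structure", {
  # circular shuffling fragments organized coactivity into small, weak
  # chance patterns: no planted member set survives, and the total
  # ensemble activation time collapses
  for (sd in 1:5) {
    sim <- generateSession(sessionParams(nNeurons = 60, nFrames = 1500,
                                         nEnsembles = 3, ensembleSize = 12,
                                         eventsPerEnsemble = 200,
                                         backgroundRate = 0.02),
                           seed = sd)
    ensOrig <- detectEnsembles(sim$raster, nSurrogates = 200, seed = sd)
    framesOrig <- sum(lengths(ensembleFrames(ensOrig)))
    shuf <- shuffleRaster(sim$raster, "circular_per_neuron", seed = sd + 40)
    ensShuf <- tryCatch(
      suppressWarnings(detectEnsembles(shuf, nSurrogates = 200, seed = sd)),
      error = function(e) NULL)
    if (is.null(ensShuf)) next  # nothing coactivates: structure destroyed
    expect_lt(sum(lengths(ensembleFrames(ensShuf))), framesOrig / 2)
    expect_true(all(memberRecovery(ensShuf, sim$truth@members[[1]]) < 0.5))
  }
})

test_that("coactivity-peak detection finds planted peaks and degenerates safely", {
  # noise-free construction: only the planted frames carry coactivity
  n <- 100
  f <- 1000
  a <- matrix(0L, n, f)
  planted <- withr::with_seed(3, sort(sample.int(f, 10)))
  a[1:20, planted] <- 1L
  ens <- detectCoactivityPeaks(BinaryRaster(a), nSurrogates = 200, seed = 3,
                               demix = FALSE)
  expect_setequal(unlist(ensembleFrames(ens)), planted)
  # constant raster: the null equals the observed coactivity everywhere
  const <- BinaryRaster(matrix(1L, 10, 50))
  expect_warning(empty <- detectCoactivityPeaks(const, nSurrogates = 100,
                                                seed = 1),
                 "no frame exceeds")
  expect_identical(nEnsembles(empty), 0L)
})

test_that("peak-based and connectivity-based detectors agree on planted data", {
  sim <- generateSession(sessionParams(nNeurons = 60, nFrames = 1500,
                                       nEnsembles = 3, ensembleSize = 12,
                                       eventsPerEnsemble = 200,
                                       backgroundRate = 0.01),
                         seed = 20)
  ensC <- detectEnsembles(sim$raster, nSurrogates = 300, seed = 20)
  ensP <- detectCoactivityPeaks(sim$raster, nSurrogates = 300, seed = 20)
  expect_identical(nEnsembles(ensP), 3L)
  for (j in seq_len(nEnsembles(ensP))) {
    mem <- ensembleMembers(ensP, j)
    best <- max(vapply(ensembleMembers(ensC), function(m)
      length(intersect(m, mem)) / length(union(m, mem)), numeric(1)))
    expect_gte(best, 0.8)
  }
})
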