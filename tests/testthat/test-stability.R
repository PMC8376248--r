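test_that("the 1/3 Jaccard boundary marks 50% member overlap as stable", {
  setA <- makeEnsembleSet(list(1:10), ids = 1:15)
  setB <- makeEnsembleSet(list(c(1:5, 11:15)), ids = 1:15)
  m <- matchEnsembles(setA, setB, threshold = 1 / 3)
  expect_equal(m$jaccard, 1 / 3)
  expect_true(m$stable)   # inclusive boundary: >= 1/3
  expect_false(matchEnsembles(setA, setB, threshold = 0.34)$stable)
})

test_that("identical and disjoint member sets match as expected", {
  a <- makeEnsembleSet(list(1:6, 11:16), ids = 1:20)
  bSame <- makeEnsembleSet(list(11:16, 1:6), ids = 1:20)
  m <- matchEnsembles(a, bSame)
  expect_equal(m$jaccard, c(1, 1))
  expect_identical(m$idSecond, c(2L, 1L))
  expect_true(all(m$stable))
  bDisjoint <- makeEnsembleSet(list(31:36), ids = c(1:20, 31:36))
  a2 <- makeEnsembleSet(list(1:6), ids = c(1:20, 31:36))
  m2 <- matchEnsembles(a2, bDisjoint)
  expect_false(m2$stable)
  expect_equal(m2$jaccard, 0)
  empty <- methods::new("EnsembleSet", members = list(), frames = list(),
                        nFrames = 100L, neuronIds = 1:20,
                        sessionLabel = "", config = list())
  expect_warning(m3 <- matchEnsembles(a, empty), "no ensembles")
  expect_false(any(m3$stable))
})

test_that("greedy matching is one-to-one by descending similarity", {
  a <- makeEnsembleSet(list(1:8, 5:12), ids = 1:20)
  b <- makeEnsembleSet(list(1:8), ids = 1:20)
  m <- matchEnsembles(a, b)
  expect_identical(m$idSecond, c(1L, NA_integer_))
  expect_false(any(duplicated(na.omit(m$idSecond))))
})

test_that("neuron fate is exact set algebra relative to day-1 size", {
  fate <- neuronFate(1:10, c(1:5, 11:15))
  expect_identical(fate$stable, 1:5)
  expect_identical(fate$lost, 6:10)
  expect_identical(fate$new, 11:15)
  expect_equal(unname(fate$fractions), c(0.5, 0.5, 0.5))
  same <- neuronFate(1:7, 1:7)
  expect_equal(unname(same$fractions), c(1, 0, 0))
  expect_error(neuronFate(1:5, 1:5, stable = FALSE), "stable")
  # partition identities: |stable| + |lost| = |A|, |stable| + |new| = |B|
  for (sd in 1:10) {
    sets <- withr::with_seed(sd, list(sample(1:30, 12), sample(1:30, 9)))
    f <- neuronFate(sets[[1]], sets[[2]])
    expect_identical(length(f$stable) + length(f$lost), 12L)
    expect_identical(length(f$stable) + length(f$new), 9L)
  }
})

test_that("ensemble density equals brute-force pair enumeration", {
  full <- makeNetwork(matrix(TRUE, 4, 4))
  expect_equal(ensembleDensity(full, 1:4), 1)
  adj <- matrix(FALSE, 4, 4)
  adj[1, 2] <- adj[2, 3] <- adj[3, 4] <- TRUE
  half <- makeNetwork(adj)
  expect_equal(ensembleDensity(half, 1:4), 0.5)
  for (sd in 1:10) {
    n <- 9
    rnd <- withr::with_seed(sd, matrix(runif(n * n) < 0.4, n, n))
    net <- makeNetwork(rnd)
    members <- withr::with_seed(sd + 5, sample.int(n, 5))
    expect_equal(ensembleDensity(net, members),
                 bruteDensity(adjacency(net), members))
  }
  expect_error(ensembleDensity(full, 2), "fewer than 2")
})

test_that("robustness multiplies mean pairwise similarity by activity", {
  ej <- matrix(rep(c(1L, 0L, 1L, 0L, 0L), 30), 5, 30)
  expect_equal(ensembleRobustness(ej, 300), 0.1)
  disjointCols <- diag(3L)
  expect_equal(ensembleRobustness(disjointCols, 100), 0)
  # hand-computed: columns {1,2}, {1,3}, {1,2,3,4} have pairwise Jaccard
  # 1/3, 1/2, 1/2 -> mean 4/9, activity 3/100
  cols <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 1))
  expect_equal(ensembleRobustness(cols, 100), (4 / 9) * (3 / 100),
               tolerance = 1e-12)
  single <- ensembleRobustness(matrix(c(1, 0), 2, 1), 50)
  expect_equal(as.numeric(single), 1 / 50)
  expect_true(attr(single, "flagged"))
  # transposing keeps every column nonzero (randomRaster fixes zero rows)
  expect_true(ensembleRobustness(t(randomRaster(9, 6, p = 0.4, seed = 3)),
                                 20) <= 1)
})

test_that("tuned neurons separate stimulus-locked from flat firing", {
  f <- 50 * 25 + 51 * 10  # 50 epochs of 25 frames, 10-frame gaps
  onsets <- seq(11, by = 35, length.out = 50)
  epochs <- StimEpochs(onsets, onsets + 25)
  stimFrames <- unlist(lapply(seq_along(onsets), function(i)
    onsets[i]:(onsets[i] + 24)))
  a <- matrix(0L, 3, f)
  a[1, stimFrames] <- 1L                       # fires every stimulus frame
  a[2, seq(1, f, by = 7)] <- 1L                # flat rate everywhere
  tuned <- tunedNeurons(BinaryRaster(a), epochs)
  expect_true(tuned[1])
  expect_false(tuned[2])
  expect_false(tuned[3])  # silent: degenerate test, flagged not tuned
  expect_true(is.na(attr(tuned, "pValue")[3]))
})

test_that("tuning detection has power at 0.3 versus 0.1 activity", {
  onsets <- seq(11, by = 35, length.out = 50)
  epochs <- StimEpochs(onsets, onsets + 25)
  f <- max(onsets) + 30
  stimFrames <- unlist(lapply(seq_along(onsets), function(i)
    onsets[i]:(onsets[i] + 24)))
  hits <- 0L
  for (sd in 1:100) {
    row <- withr::with_seed(sd, {
      x <- rbinom(f, 1L, 0.1)
      x[stimFrames] <- rbinom(length(stimFrames), 1L, 0.3)
      x
    })
    hits <- hits + tunedNeurons(BinaryRaster(matrix(row, 1)), epochs)[1]
  }
  expect_gte(hits, 95L)
})

test_that("a duplicated session makes every ensemble stable at Jaccard 1", {
  sim <- generateSession(sessionParams(nNeurons = 60, nFrames = 1200,
                                       nEnsembles = 3, ensembleSize = 12,
                                       eventsPerEnsemble = 180,
                                       backgroundRate = 0.02), seed = 6)
  rep <- stabilityAnalysis(list(sim$raster, sim$raster), nSurrogates = 200,
                           seed = 6)
  m <- ensembleMatches(rep)
  expect_true(all(m$stable))
  expect_equal(m$jaccard, rep(1, nrow(m)))
  expect_identical(nTransient(rep), 0L)
})

test_that("raising the matching threshold never adds stable ensembles", {
  lp <- longitudinalParams(
    session = sessionParams(nNeurons = 150, nFrames = 1500, nEnsembles = 4,
                            ensembleSize = 12, eventsPerEnsemble = 200),
    nStableEnsembles = 2, nTransientPerSession = 2)
  sim <- generateLongitudinal(lp, seed = 12)
  com <- commonRaster(sim$rasters[[1]], sim$rasters[[2]])
  ensA <- detectEnsembles(com[[1]], nSurrogates = 300, seed = 12)
  ensB <- detectEnsembles(com[[2]], nSurrogates = 300, seed = 12)
  nStableAt <- vapply(c(0, 1 / 3, 1 / 2, 1), function(thr)
    sum(suppressWarnings(matchEnsembles(ensA, ensB, thr))$stable),
    numeric(1))
  expect_true(all(diff(nStableAt) <= 0))
})

test_that("core neurons are more densely connected than rotated ones", {
  # core members join every event, rotated members only half of them
  n <- 40
  f <- 1200
  withr::with_seed(44, {
    ev <- sort(sample.int(f, 150))
    a <- matrix(rbinom(n * f, 1L, 0.03), n, f)
    a[1:8, ev] <- 1L                                    # core
    for (i in 9:12) a[i, sample(ev, 75)] <- 1L          # rotated
  })
  net <- significantConnections(BinaryRaster(a), nSurrogates = 300,
                                seed = 44)
  expect_gte(ensembleDensity(net, 1:8), ensembleDensity(net, 9:12))
})

test_that("stability analysis recovers planted stable and transient counts", {
  lp <- longitudinalParams(
    session = sessionParams(nNeurons = 150, nFrames = 1500, nEnsembles = 4,
                            ensembleSize = 12, eventsPerEnsemble = 200),
    nStableEnsembles = 2, nTransientPerSession = 2)
  sim <- generateLongitudinal(lp, seed = 18)
  rep <- suppressWarnings(stabilityAnalysis(sim$rasters, nSurrogates = 300,
                                            seed = 18))
  expect_identical(nStable(rep), 2L)
  expect_identical(nTransient(rep), 2L)
  cmp <- rep@comparisons[[1]]
  expect_identical(cmp$nStable + cmp$nTransient,
                   nEnsembles(cmp$ensemblesA))
  for (fate in cmp$fate) {
    expect_identical(length(fate$stable) + length(fate$lost),
                     length(ensembleMembers(cmp$ensemblesA, fate$idFirst)))
    expect_identical(length(fate$stable) + length(fate$new),
                     length(ensembleMembers(cmp$ensemblesB, fate$idSecond)))
  }
  expect_true(all(cmp$measures$density >= 0 & cmp$measures$density <= 1,
                  na.rm = TRUE))
  expect_true(all(cmp$measures$robustness >= 0 &
                    cmp$measures$robustness <= 1))
})
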