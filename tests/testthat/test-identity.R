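test_that("ensemble correlation matches the textbook Pearson formula", {
  v <- rep(c(1L, 0L), each = 10)
  r <- BinaryRaster(rbind(v, 1L - v, randomRaster(3, 20, seed = 41)))
  p <- ensembleCorrelation(r, v)
  expect_equal(p[1], 1)
  expect_equal(p[2], -1)
  pearson <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (i in 3:5)
    expect_equal(p[i], pearson(activityMatrix(r)[i, ], v),
                 tolerance = 1e-12)
  const <- BinaryRaster(rbind(v, rep(1L, 20)))
  pc <- ensembleCorrelation(const, v)
  expect_equal(pc[2], 0)
  expect_true(attr(pc, "constant")[2])
  expect_error(ensembleCorrelation(r, rep(1L, 20)), "constant")
})

test_that("ensemble weights multiply correlations with coactivations", {
  co <- matrix(c(3L, 5L, 5L, 4L), 2)
  expect_equal(ensembleWeights(c(1, 1), co)[1, 2], 5)
  expect_equal(ensembleWeights(c(0.5, 0.4), matrix(c(2L, 10L, 10L, 3L), 2))[1, 2],
               2)
  w <- ensembleWeights(c(0, 0.8), co)
  expect_true(all(w[1, ] == 0))
  # |W| <= Co since |P| <= 1
  p <- withr::with_seed(2, runif(6, -1, 1))
  co6 <- bruteCoactivation(randomRaster(6, 40, seed = 2))
  expect_true(all(abs(ensembleWeights(p, co6)) <= co6 + 1e-12))
})

# a session with one strongly planted ensemble: members fire exactly with
# the ensemble vector, other neurons are independent background
plantedSession <- function(nMembers = 8, n = 30, f = 600, nEvents = 60,
                           seed = 1) {
  withr::with_seed(seed, {
    ev <- sort(sample.int(f, nEvents))
    a <- matrix(rbinom(n * f, 1L, 0.1), n, f)
    a[seq_len(nMembers), ] <- 0L
    a[seq_len(nMembers), ev] <- 1L
    list(raster = BinaryRaster(a), events = ev,
         members = seq_len(nMembers))
  })
}

test_that("demixing recovers a noise-free planted member set exactly", {
  px <- plantedSession(seed = 17)
  ens <- makeEnsembleSet(list(px$members), frames = list(px$events),
                         nFrames = nFrames(px$raster),
                         ids = neuronIds(px$raster))
  mt <- demixMembership(px$raster, ens, nSurrogates = 500, seed = 17)
  expect_identical(which(membershipMatrix(mt)[1, ]), px$members)
  expect_identical(participationClass(mt)[px$members],
                   rep("single", length(px$members)))
})

test_that("a neuron uncorrelated with the ensemble is never a member", {
  px <- plantedSession(seed = 23)
  a <- activityMatrix(px$raster)
  # make neuron 20 fire only outside ensemble frames: P <= 0
  a[20, ] <- 0L
  a[20, setdiff(seq_len(ncol(a)), px$events)[1:60]] <- 1L
  r <- BinaryRaster(a)
  ens <- makeEnsembleSet(list(px$members), frames = list(px$events),
                         nFrames = nFrames(r), ids = neuronIds(r))
  mt <- demixMembership(r, ens, nSurrogates = 500, seed = 23)
  expect_false(membershipMatrix(mt)[1, 20])
})

test_that("a neuron shared between overlapping ensembles joins both", {
  n <- 30
  f <- 800
  withr::with_seed(31, {
    ev1 <- sort(sample.int(400, 50))
    ev2 <- sort(sample(401:800, 50))
    a <- matrix(rbinom(n * f, 1L, 0.08), n, f)
    a[1:8, ] <- 0L
    a[9:16, ] <- 0L
    a[1:8, ev1] <- 1L       # ensemble 1: neurons 1-8
    a[9:16, ev2] <- 1L      # ensemble 2: neurons 9-16
    a[8:9, c(ev1, ev2)] <- 1L  # neurons 8 and 9 shared between both
  })
  r <- BinaryRaster(a)
  ens <- makeEnsembleSet(list(1:8, 9:16), frames = list(ev1, ev2),
                         nFrames = f, ids = seq_len(n))
  mt <- demixMembership(r, ens, nSurrogates = 500, seed = 31)
  expect_true(all(membershipMatrix(mt)[, 8]))
  expect_true(all(membershipMatrix(mt)[, 9]))
  expect_identical(participationClass(mt)[8], "shared")
  cls <- classifyParticipation(mt)
  expect_equal(cls$fractions[["shared"]],
               mean(colSums(membershipMatrix(mt)) >= 2))
})

test_that("participation classes follow membership row sums", {
  m <- rbind(c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
  cls <- classifyParticipation(m)
  expect_identical(cls$class, c("single", "shared", "none"))
  expect_equal(unname(cls$fractions), c(1, 1, 1) / 3)
  expect_identical(classifyParticipation(diag(3) == 1)$class,
                   rep("single", 3))
})

test_that("a planted overlap design yields the planted shared fraction", {
  # 20 neurons: ensembles {1..10} and {7..16}; 7..10 shared (20%)
  n <- 20
  f <- 800
  withr::with_seed(37, {
    ev1 <- sort(sample.int(400, 60))
    ev2 <- sort(sample(401:800, 60))
    a <- matrix(0L, n, f)
    a[1:10, ev1] <- 1L
    a[7:16, ev2] <- 1L
    a[17:20, sample.int(f, 240)] <- 1L
  })
  r <- BinaryRaster(a)
  ens <- makeEnsembleSet(list(1:10, 7:16), frames = list(ev1, ev2),
                         nFrames = f, ids = seq_len(n))
  mt <- demixMembership(r, ens, nSurrogates = 500, seed = 37)
  shared <- classifyParticipation(mt)$fractions[["shared"]]
  expect_gte(shared, 0.15)
  expect_lte(shared, 0.25)
})

test_that("membership under the null stays near the nominal level", {
  rates <- vapply(1:5, function(sd) {
    r <- BinaryRaster(matrix(withr::with_seed(sd, rbinom(40 * 800, 1, 0.15)),
                             40, 800))
    frames <- withr::with_seed(sd + 10, sort(sample.int(800, 80)))
    ens <- makeEnsembleSet(list(seq_len(40)), frames = list(frames),
                           nFrames = 800, ids = seq_len(40))
    mt <- demixMembership(r, ens, nSurrogates = 300, seed = sd,
                          requirePositive = FALSE)
    sig <- sum(!is.na(mt@maxWeight[1, ]))
    sig / choose(40, 2)  # neurons with a significant pair / pairs tested
  }, numeric(1))
  expect_lte(mean(rates), 2 * 0.05)
})

test_that("demixing never adds a neuron silent in the ensemble frames", {
  px <- plantedSession(seed = 41)
  a <- activityMatrix(px$raster)
  a[25, px$events] <- 0L  # silence neuron 25 inside ensemble frames
  r <- BinaryRaster(a)
  ens <- makeEnsembleSet(list(px$members), frames = list(px$events),
                         nFrames = nFrames(r), ids = neuronIds(r))
  mt <- demixMembership(r, ens, nSurrogates = 300, seed = 41)
  expect_false(membershipMatrix(mt)[1, 25])
})
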