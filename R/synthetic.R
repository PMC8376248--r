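# Synthetic raster generation with planted ground-truth ensembles.
#
# The generator emulates the statistical structure of 5-min two-photon
# recordings from layer 2/3 visual cortex: ~15% per-neuron active-frame
# fraction, a handful of ensembles of coactive neurons per session,
# partial neuron overlap across sessions (~42% common neurons) and stable
# ensembles that retain ~68% of their members, on top of independent
# background spiking.

#' SessionParams: parameters of one synthetic session
#'
#' @slot nNeurons,nFrames raster dimensions (defaults 100 x 3704 frames).
#' @slot framePeriod frame period in seconds (default 0.081).
#' @slot nEnsembles number of planted ensembles.
#' @slot ensembleSize members per ensemble (scalar or one value per
#'   ensemble).
#' @slot eventsPerEnsemble expected number of activation frames per
#'   ensemble; events are placed by independent per-frame Bernoulli draws
#'   with probability \code{eventsPerEnsemble / nFrames}, so ensembles may
#'   co-occur in a frame.
#' @slot participationProb probability that a member fires in an ensemble
#'   event.
#' @slot backgroundRate per-neuron per-frame independent spike probability;
#'   \code{NA} (the default) calibrates it analytically per neuron so the
#'   expected active-frame fraction equals \code{targetActivity}.
#' @slot targetActivity per-neuron active-frame fraction the generator
#'   calibrates toward (default 0.15).
#' @slot membershipOverlap fraction of each ensemble's members re-drawn
#'   from previously assigned members (0 = disjoint ensembles).
#' @slot allowEventOverlap when FALSE (default) ensemble events occupy
#'   mutually exclusive frames, emulating alternating population events;
#'   when TRUE each ensemble's events are placed independently and frames
#'   may contain mixed ensemble activity.
#' @slot eventFrames optional list pinning the exact event frames per
#'   ensemble (used mainly by tests); overrides \code{eventsPerEnsemble}.
#' @export
setClass("SessionParams",
  slots = c(
    nNeurons = "integer", nFrames = "integer", framePeriod = "numeric",
    nEnsembles = "integer", ensembleSize = "integer",
    eventsPerEnsemble = "integer", participationProb = "numeric",
    backgroundRate = "numeric", targetActivity = "numeric",
    membershipOverlap = "numeric", allowEventOverlap = "logical",
    eventFrames = "list"
  )
)

setValidity("SessionParams", function(object) {
  if (object@nNeurons < 1L) return("nNeurons must be >= 1")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (object@framePeriod <= 0) return("framePeriod must be positive")
  if (object@nEnsembles < 0L) return("nEnsembles must be >= 0")
  if (any(object@ensembleSize < 1L)) return("ensembleSize must be positive")
  if (object@nEnsembles > 0L &&
      any(object@ensembleSize[seq_len(object@nEnsembles)] > object@nNeurons))
    return("ensembleSize cannot exceed nNeurons")
  for (p in c(object@participationProb, object@targetActivity,
              object@membershipOverlap))
    if (!is.na(p) && (p < 0 || p > 1)) return("probabilities must be in [0,1]")
  if (!is.na(object@backgroundRate) &&
      (object@backgroundRate < 0 || object@backgroundRate > 1))
    return("backgroundRate must be in [0,1] or NA")
  TRUE
})

#' Construct session parameters for the synthetic generator
#'
#' Defaults reproduce the emulation targets of the study conditions: 3704
#' frames at 81 ms, four ensembles of 20 neurons firing about 500 events
#' each with participation 0.9, and background spiking calibrated so the
#' mean per-neuron active-frame fraction is 15%.
#'
#' @param nNeurons,nFrames,framePeriod,nEnsembles,ensembleSize,eventsPerEnsemble,participationProb,backgroundRate,targetActivity,membershipOverlap,eventFrames
#'   see \linkS4class{SessionParams}.
#' @return A \linkS4class{SessionParams}.
#' @examples
#' p <- sessionParams(nNeurons = 50, nEnsembles = 2, ensembleSize = 10)
#' @export
sessionParams <- function(nNeurons = 100, nFrames = 3704, framePeriod = 0.081,
                          nEnsembles = 4, ensembleSize = 20,
                          eventsPerEnsemble = 500, participationProb = 0.9,
                          backgroundRate = NA_real_, targetActivity = 0.15,
                          membershipOverlap = 0, allowEventOverlap = FALSE,
                          eventFrames = list()) {
  methods::new("SessionParams",
    nNeurons = assertCount(nNeurons, "nNeurons", 1),
    nFrames = assertCount(nFrames, "nFrames", 1),
    framePeriod = assertNumber(framePeriod, "framePeriod", 1e-9),
    nEnsembles = assertCount(nEnsembles, "nEnsembles", 0),
    ensembleSize = vapply(rep(ensembleSize, length.out = max(nEnsembles, 1)),
                          assertCount, integer(1), name = "ensembleSize",
                          lower = 1),
    eventsPerEnsemble = assertCount(eventsPerEnsemble, "eventsPerEnsemble", 1),
    participationProb = assertNumber(participationProb, "participationProb",
                                     0, 1),
    backgroundRate = if (is.na(backgroundRate)) NA_real_ else
      assertNumber(backgroundRate, "backgroundRate", 0, 1),
    targetActivity = assertNumber(targetActivity, "targetActivity", 0, 1),
    membershipOverlap = assertNumber(membershipOverlap, "membershipOverlap",
                                     0, 1),
    allowEventOverlap = assertFlag(allowEventOverlap, "allowEventOverlap"),
    eventFrames = eventFrames)
}

#' LongitudinalParams: parameters of a multi-session synthetic experiment
#'
#' @slot session a \linkS4class{SessionParams} shared by all sessions.
#' @slot nSessions number of sessions (default 2).
#' @slot commonNeuronFraction fraction of day-1 neurons active again in a
#'   later session (default 0.42).
#' @slot nStableEnsembles ensembles that re-occur in every session.
#' @slot nTransientPerSession ensembles appearing in exactly one session.
#' @slot coreRetention fraction of a stable ensemble's members preserved
#'   across sessions (default 0.68); the core has
#'   \code{ceiling(coreRetention * size)} members.
#' @export
setClass("LongitudinalParams",
  slots = c(
    session = "SessionParams", nSessions = "integer",
    commonNeuronFraction = "numeric", nStableEnsembles = "integer",
    nTransientPerSession = "integer", coreRetention = "numeric"
  )
)

setValidity("LongitudinalParams", function(object) {
  if (object@nSessions < 2L) return("nSessions must be >= 2")
  tot <- object@nStableEnsembles + object@nTransientPerSession
  if (tot > object@session@nEnsembles)
    return("nStableEnsembles + nTransientPerSession exceeds session nEnsembles")
  if (object@commonNeuronFraction < 0 || object@commonNeuronFraction > 1)
    return("commonNeuronFraction must be in [0,1]")
  if (object@coreRetention < 0 || object@coreRetention > 1)
    return("coreRetention must be in [0,1]")
  if (any(object@coreRetention * object@session@ensembleSize[
        seq_len(object@nStableEnsembles)] < 1))
    return("coreRetention * ensembleSize < 1: stable ensembles need a nonempty core")
  TRUE
})

#' Construct parameters for a multi-session synthetic experiment
#'
#' Defaults emulate the study conditions at the longitudinal level: 42%
#' of day-1 neurons remain active in a later session and stable ensembles
#' keep 68% of their members, with all ensemble members drawn from the
#' common pool so the planted structure is fully visible to tracking.
#'
#' @param session a \linkS4class{SessionParams}; the default uses 250
#'   neurons and five ensembles of 16 so that stable and transient
#'   ensembles fit inside the common-neuron pool.
#' @param nSessions number of sessions.
#' @param commonNeuronFraction,coreRetention,nStableEnsembles,nTransientPerSession
#'   see \linkS4class{LongitudinalParams}.
#' @return A \linkS4class{LongitudinalParams}.
#' @export
longitudinalParams <- function(session = sessionParams(nNeurons = 250,
                                                       nEnsembles = 5,
                                                       ensembleSize = 16),
                               nSessions = 2,
                               commonNeuronFraction = 0.42,
                               nStableEnsembles = 3,
                               nTransientPerSession = 2,
                               coreRetention = 0.68) {
  methods::new("LongitudinalParams",
    session = session,
    nSessions = assertCount(nSessions, "nSessions", 2),
    commonNeuronFraction = assertNumber(commonNeuronFraction,
                                        "commonNeuronFraction", 0, 1),
    nStableEnsembles = assertCount(nStableEnsembles, "nStableEnsembles", 0),
    nTransientPerSession = assertCount(nTransientPerSession,
                                       "nTransientPerSession", 0),
    coreRetention = assertNumber(coreRetention, "coreRetention", 0, 1))
}

# Draw ensemble member sets over neurons 1..n (optionally from a restricted
# pool). With overlap > 0, each ensemble re-draws floor(overlap * size)
# members from the union of previously assigned members.
drawMembers <- function(pool, sizes, overlap) {
  members <- vector("list", length(sizes))
  assigned <- integer(0)
  free <- pool
  for (k in seq_along(sizes)) {
    nShared <- min(floor(overlap * sizes[k]), length(assigned))
    shared <- if (nShared > 0L) sample(assigned, nShared) else integer(0)
    nFresh <- sizes[k] - nShared
    if (nFresh > length(free))
      stop("not enough neurons to plant disjoint ensemble members; ",
           "reduce nEnsembles/ensembleSize or raise membershipOverlap")
    fresh <- if (nFresh > 0L) sample(free, nFresh) else integer(0)
    members[[k]] <- sort(c(shared, fresh))
    assigned <- union(assigned, members[[k]])
    free <- setdiff(free, fresh)
  }
  members
}

# Analytic background calibration (per neuron): the probability a neuron is
# active through its ensembles in a random frame is
#   pEns = 1 - prod_k (1 - (E_k / F) * participation)
# over the ensembles k containing it; solving
#   target = 1 - (1 - pEns) * (1 - bg)
# gives the per-neuron background rate, clipped to [0, 1].
calibrateBackground <- function(nNeurons, nFrames, members, eventRates,
                                participation, target) {
  pEns <- numeric(nNeurons)
  for (k in seq_along(members)) {
    idx <- members[[k]]
    pEns[idx] <- 1 - (1 - pEns[idx]) * (1 - eventRates[k] * participation)
  }
  bg <- 1 - (1 - target) / pmax(1 - pEns, .Machine$double.eps)
  if (any(bg < 0))
    warning("targetActivity unreachable for ", sum(bg < 0),
            " neuron(s): ensemble-driven activity already exceeds it; ",
            "using backgroundRate 0 for those neurons")
  pmin(pmax(bg, 0), 1)
}

# Core of the session generator, shared by generateSession and
# generateLongitudinal: plants given member sets and returns the raster
# plus bookkeeping. Seeds are split per sub-draw.
buildSessionRaster <- function(params, members, seed, label) {
  n <- params@nNeurons
  f <- params@nFrames
  nEns <- length(members)
  # event placement: binomially-thinned uniform frames. By default events
  # are mutually exclusive across ensembles (population events alternate;
  # two full ensembles superposed in one 81 ms frame would read as a fifth
  # coactivation pattern); allowEventOverlap = TRUE places each ensemble
  # independently instead.
  if (length(params@eventFrames)) {
    events <- lapply(params@eventFrames, function(x) sort(as.integer(x)))
    if (length(events) != nEns)
      stop("eventFrames must have one entry per ensemble")
  } else {
    rate <- min(params@eventsPerEnsemble / f, 1)
    events <- withSeed(subSeed(seed, 1), {
      if (params@allowEventOverlap || nEns <= 1L) {
        lapply(seq_len(nEns), function(k) which(stats::runif(f) < rate))
      } else {
        counts <- stats::rbinom(nEns, f, rate)
        if (sum(counts) > f) {
          warning("event load exceeds the session length; ",
                  "ensemble events scaled down to fit")
          counts <- floor(counts * f / sum(counts))
        }
        frames <- sample.int(f, sum(counts))  # distinct frames, random order
        unname(split(frames, rep.int(seq_len(nEns), counts)))
      }
    })
    events <- lapply(events, function(x) sort(as.integer(x)))
  }
  # member participation in events
  act <- matrix(0L, n, f)
  withSeed(subSeed(seed, 2), for (k in seq_len(nEns)) {
    m <- members[[k]]
    ev <- events[[k]]
    if (!length(ev)) next
    fires <- matrix(stats::runif(length(m) * length(ev)) <
                      params@participationProb, length(m), length(ev))
    act[m, ev] <- act[m, ev] | fires
  })
  # background
  if (is.na(params@backgroundRate)) {
    eventRates <- vapply(events, length, integer(1)) / f
    bg <- calibrateBackground(n, f, members, eventRates,
                              params@participationProb,
                              params@targetActivity)
  } else {
    bg <- rep(params@backgroundRate, n)
  }
  withSeed(subSeed(seed, 3), {
    noise <- matrix(stats::runif(n * f) < rep(bg, f), n, f)
    act <- act | noise
  })
  storage.mode(act) <- "integer"
  list(activity = act, events = events, backgroundRate = bg)
}

#' Generate one synthetic session with planted ensembles
#'
#' Plants \code{nEnsembles} coactive neuron groups: each ensemble fires in
#' Bernoulli-placed event frames, each member participates in an event with
#' probability \code{participationProb}, and independent background spikes
#' are added with per-neuron rates calibrated so the expected active-frame
#' fraction matches \code{targetActivity}. Output is bit-identical for the
#' same seed.
#'
#' @param params a \linkS4class{SessionParams}.
#' @param seed integer root seed; sub-draws (membership, events,
#'   participation, background) use documented sub-streams.
#' @param sessionLabel label stored in the raster.
#' @return A list with elements \code{raster} (\linkS4class{BinaryRaster})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' out <- generateSession(sessionParams(nNeurons = 40, nFrames = 500,
#'                                      nEnsembles = 2, ensembleSize = 8,
#'                                      eventsPerEnsemble = 60), seed = 1)
#' out$raster
#' @export
generateSession <- function(params, seed, sessionLabel = "synthetic") {
  stopifnot(methods::is(params, "SessionParams"))
  methods::validObject(params)
  members <- withSeed(subSeed(seed, 0),
                      drawMembers(seq_len(params@nNeurons),
                                  params@ensembleSize[seq_len(params@nEnsembles)],
                                  params@membershipOverlap))
  built <- buildSessionRaster(params, members, seed, sessionLabel)
  raster <- BinaryRaster(built$activity,
                         neuronIds = seq_len(params@nNeurons),
                         framePeriod = params@framePeriod,
                         sessionLabel = sessionLabel)
  truth <- methods::new("GroundTruth",
    members = list(members),
    eventFrames = list(built$events),
    stableFlags = logical(0),
    neuronFate = list(),
    commonNeurons = list(),
    backgroundRate = list(built$backgroundRate))
  list(raster = raster, truth = truth)
}

#' Generate a multi-session experiment with stable and transient ensembles
#'
#' Sessions share a global neuron registry. Each later session keeps
#' \code{commonNeuronFraction} of the day-1 neurons (the rest are replaced
#' by new cells, mirroring neurons that fall silent or leave the imaging
#' plane). Stable ensembles re-occur in every session, keeping a fixed core
#' of \code{ceiling(coreRetention * size)} members and re-sampling the
#' remainder; transient ensembles appear in exactly one session. All
#' ensemble members are drawn from the common pool, so the planted
#' structure is fully visible after cross-session tracking.
#'
#' @param params a \linkS4class{LongitudinalParams}.
#' @param seed integer root seed.
#' @return A list with \code{rasters} (list of \linkS4class{BinaryRaster},
#'   one per session, rows restricted to that session's active neurons) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @export
generateLongitudinal <- function(params, seed) {
  stopifnot(methods::is(params, "LongitudinalParams"))
  methods::validObject(params)
  sp <- params@session
  n <- sp@nNeurons
  nStable <- params@nStableEnsembles
  nTrans <- params@nTransientPerSession
  sizes <- sp@ensembleSize[seq_len(nStable + nTrans)]
  stableSizes <- sizes[seq_len(nStable)]
  nCommon <- round(params@commonNeuronFraction * n)

  day1 <- seq_len(n)
  # common pool (shared by all later sessions) and planted membership
  needed <- sum(sizes)
  if (needed > nCommon)
    stop("common pool too small for the planted ensembles: ",
         needed, " members needed but only ", nCommon, " common neurons; ",
         "increase nNeurons or reduce ensemble count/size")
  common <- withSeed(subSeed(seed, 10), sort(sample(day1, nCommon)))
  allMembers1 <- withSeed(subSeed(seed, 11),
                          drawMembers(common, sizes, sp@membershipOverlap))
  stableMembers1 <- allMembers1[seq_len(nStable)]
  cores <- withSeed(subSeed(seed, 12), lapply(seq_len(nStable), function(k) {
    sz <- ceiling(params@coreRetention * stableSizes[k])
    sort(sample(stableMembers1[[k]], sz))
  }))

  nextId <- n + 1L
  rasters <- vector("list", params@nSessions)
  membersBySession <- vector("list", params@nSessions)
  eventsBySession <- vector("list", params@nSessions)
  bgBySession <- vector("list", params@nSessions)
  commonBySession <- vector("list", params@nSessions - 1L)
  fate <- lapply(seq_len(nStable), function(k)
    list(core = cores[[k]], rotated = vector("list", params@nSessions)))

  for (s in seq_len(params@nSessions)) {
    if (s == 1L) {
      active <- day1
      members <- allMembers1
      for (k in seq_len(nStable))
        fate[[k]]$rotated[[1L]] <- setdiff(stableMembers1[[k]], cores[[k]])
    } else {
      fresh <- seq.int(nextId, length.out = n - nCommon)
      nextId <- nextId + length(fresh)
      active <- sort(c(common, fresh))
      commonBySession[[s - 1L]] <- common
      # stable ensembles: fixed core + per-session resampled remainder,
      # drawn from common neurons not already planted in another ensemble;
      # day-1 members outside the core are excluded so they are genuinely
      # "lost" and the cross-session member intersection equals the core
      members <- vector("list", nStable + nTrans)
      takenStable <- unlist(cores)
      for (k in seq_len(nStable)) {
        nRot <- stableSizes[k] - length(cores[[k]])
        pool <- setdiff(common, c(takenStable, stableMembers1[[k]],
                                  unlist(members)))
        rot <- withSeed(subSeed(seed, 100 * s + k),
                        if (nRot > 0L) sort(sample(pool, nRot)) else integer(0))
        members[[k]] <- sort(c(cores[[k]], rot))
        fate[[k]]$rotated[[s]] <- rot
      }
      # transient ensembles of this session: fresh draws from the common
      # pool, avoiding current stable members. Draws are rejected until
      # they stay clearly below the 1/3 stability threshold against every
      # day-1 ensemble, so a "transient" slot can never form a chance
      # stable match with the first session's planted structure.
      for (k in seq_len(nTrans)) {
        pool <- setdiff(common, unlist(members))
        members[[nStable + k]] <- withSeed(
          subSeed(seed, 100 * s + nStable + k), {
            for (try in 1:200) {
              cand <- sort(sample(pool, sizes[nStable + k]))
              worst <- max(vapply(allMembers1, setJaccard, numeric(1),
                                  a = cand))
              if (worst < 1 / 4) break
              cand <- NULL
            }
            if (is.null(cand))
              stop("could not place a transient ensemble distinct from ",
                   "the day-1 ensembles; enlarge nNeurons or shrink ",
                   "ensembles")
            cand
          })
      }
    }
    spSession <- sp
    spSession@nNeurons <- length(active)
    localMembers <- lapply(members, function(m) match(m, active))
    built <- buildSessionRaster(spSession, localMembers,
                                subSeed(seed, 1000 + s),
                                sprintf("session%d", s))
    rasters[[s]] <- BinaryRaster(built$activity, neuronIds = active,
                                 framePeriod = sp@framePeriod,
                                 sessionLabel = sprintf("session%d", s))
    membersBySession[[s]] <- members
    eventsBySession[[s]] <- built$events
    bgBySession[[s]] <- built$backgroundRate
  }

  truth <- methods::new("GroundTruth",
    members = membersBySession,
    eventFrames = eventsBySession,
    stableFlags = c(rep(TRUE, nStable), rep(FALSE, nTrans)),
    neuronFate = fate,
    commonNeurons = commonBySession,
    backgroundRate = bgBySession)
  list(rasters = rasters, truth = truth)
}

#' Shuffle a raster while preserving per-neuron spike counts
#'
#' \code{circular_per_neuron} applies an independent uniform nonzero
#' circular shift to each neuron's spike train (preserving rate and
#' autocorrelation while destroying cross-neuron timing);
#' \code{permute_per_neuron} permutes each neuron's frame labels
#' independently.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param mode \code{"circular_per_neuron"} or \code{"permute_per_neuron"}.
#' @param seed integer seed.
#' @return A \linkS4class{BinaryRaster} with identical per-neuron
#'   active-frame counts.
#' @export
shuffleRaster <- function(raster,
                          mode = c("circular_per_neuron",
                                   "permute_per_neuron"),
                          seed) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  mode <- match.arg(mode)
  a <- raster@activity
  n <- nrow(a)
  f <- ncol(a)
  shuffled <- withSeed(seed, {
    if (mode == "circular_per_neuron") {
      if (f < 2L) a
      else shiftRows(a, sample.int(f - 1L, n, replace = TRUE))
    } else {
      t(apply(a, 1L, function(row) row[sample.int(f)]))
    }
  })
  storage.mode(shuffled) <- "integer"
  BinaryRaster(shuffled, neuronIds = raster@neuronIds,
               framePeriod = raster@framePeriod,
               sessionLabel = paste0(raster@sessionLabel, "_shuffled"))
}
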