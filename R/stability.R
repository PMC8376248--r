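# Cross-session ensemble matching, neuron fate, ensemble measures and the
# end-to-end longitudinal stability analysis.

#' Match ensembles between two sessions
#'
#' Member-set Jaccard similarity between every ensemble of the first
#' session and every ensemble of the second, followed by greedy one-to-one
#' assignment by descending similarity (ties broken by the lower ensemble
#' index pair). A first-session ensemble is stable iff it is matched with
#' Jaccard >= \code{threshold} (default 1/3, i.e. at least 50% of the
#' neurons in common for equal-sized ensembles); all others are transient.
#'
#' @param setA,setB \linkS4class{EnsembleSet}s over a shared neuron-ID
#'   registry (common neurons).
#' @param threshold stability threshold on member-set Jaccard similarity
#'   (inclusive).
#' @return data.frame with one row per first-session ensemble: columns
#'   \code{idFirst}, \code{idSecond} (NA when unmatched), \code{jaccard}
#'   and \code{stable}.
#' @examples
#' # the 50%-overlap boundary: |A & B| = 5, |A | B| = 15 -> 1/3, stable
#' @export
matchEnsembles <- function(setA, setB, threshold = 1 / 3) {
  stopifnot(methods::is(setA, "EnsembleSet"), methods::is(setB, "EnsembleSet"))
  threshold <- assertNumber(threshold, "threshold", 0, 1)
  nA <- nEnsembles(setA)
  nB <- nEnsembles(setB)
  out <- data.frame(idFirst = seq_len(nA), idSecond = NA_integer_,
                    jaccard = 0, stable = FALSE)
  if (nA == 0L) {
    warning("first session has no ensembles")
    return(out)
  }
  if (nB == 0L) {
    warning("second session has no ensembles; all first-session ",
            "ensembles are transient")
    return(out)
  }
  jac <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB))
    jac[i, j] <- setJaccard(ensembleMembers(setA, i),
                            ensembleMembers(setB, j))
  ord <- order(-jac, slice.index(jac, 1L), slice.index(jac, 2L))
  takenA <- logical(nA)
  takenB <- logical(nB)
  for (pos in ord) {
    i <- (pos - 1L) %% nA + 1L
    j <- (pos - 1L) %/% nA + 1L
    if (takenA[i] || takenB[j]) next
    if (jac[i, j] <= 0) break
    takenA[i] <- TRUE
    takenB[j] <- TRUE
    out$idSecond[i] <- j
    out$jaccard[i] <- jac[i, j]
  }
  out$stable <- !is.na(out$idSecond) & out$jaccard >= threshold
  out
}

#' Neuron fate within a stable ensemble match
#'
#' Set algebra on the matched member sets: \code{stable = A & B} (present
#' in both sessions), \code{lost = A \\ B} (first session only),
#' \code{new = B \\ A} (second session only). All three fractions are
#' relative to the first-session ensemble size |A|.
#'
#' @param membersA,membersB member neuron-ID vectors of the matched
#'   ensembles.
#' @param stable logical: was the match classified stable? Calling this on
#'   a transient match is an error.
#' @return list with \code{stable}, \code{lost}, \code{new} ID vectors and
#'   \code{fractions} (named numeric, denominators |A|).
#' @export
neuronFate <- function(membersA, membersB, stable = TRUE) {
  if (!isTRUE(stable))
    stop("neuron fate is defined for stable ensemble matches only")
  membersA <- unique(membersA)
  membersB <- unique(membersB)
  st <- intersect(membersA, membersB)
  lost <- setdiff(membersA, membersB)
  new <- setdiff(membersB, membersA)
  nA <- length(membersA)
  list(stable = sort(st), lost = sort(lost), new = sort(new),
       fractions = c(stable = length(st) / nA, lost = length(lost) / nA,
                     new = length(new) / nA))
}

#' Ensemble network density
#'
#' Fraction of realized functional connections among an ensemble's
#' members: edges within the member set divided by
#' \code{|members| * (|members| - 1) / 2}.
#'
#' @param net a \linkS4class{FunctionalNetwork}.
#' @param members neuron-ID vector (at least 2).
#' @return density in [0, 1].
#' @export
ensembleDensity <- function(net, members) {
  stopifnot(methods::is(net, "FunctionalNetwork"))
  members <- unique(members)
  m <- length(members)
  if (m < 2L)
    stop("ensemble density undefined for fewer than 2 members")
  rows <- match(members, net@neuronIds)
  if (anyNA(rows)) stop("members reference neurons absent from the network")
  sub <- net@adjacency[rows, rows, drop = FALSE]
  sum(sub) / (m * (m - 1))
}

#' Ensemble robustness: activation similarity times activity fraction
#'
#' \code{robustness = similarity * activity}, where similarity is the mean
#' Jaccard similarity over all pairs of column vectors of the ensemble
#' raster \code{E_j} and activity is \code{F_j / F_total}, the fraction of
#' session frames in which the ensemble was active. Stable ensembles tend
#' to score higher than transient ones.
#'
#' @param ej binary ensemble raster (neurons by ensemble-active frames,
#'   each column with at least one active neuron).
#' @param fTotal total frames of the session.
#' @return robustness in [0, 1]. A single-column \code{ej} has no vector
#'   pairs; the similarity factor is then taken as 1 and the result is
#'   flagged through attribute \code{"flagged"}.
#' @export
ensembleRobustness <- function(ej, fTotal) {
  if (!is.matrix(ej)) stop("ej must be a matrix")
  fTotal <- assertCount(fTotal, "fTotal", 1)
  fj <- ncol(ej)
  if (fj < 1L) stop("ej must have at least one column")
  activity <- fj / fTotal
  if (fj == 1L) {
    out <- activity
    attr(out, "flagged") <- TRUE
    return(out)
  }
  s <- jaccardMatrix(ej, axis = "frames")
  similarity <- mean(s[upper.tri(s)])
  similarity * activity
}

#' Stimulus-tuned neurons
#'
#' A neuron is tuned when its per-epoch active-frame fraction during
#' stimulus presentations is significantly higher than during the
#' inter-stimulus intervals (one-tailed two-sample t-test at level
#' \code{alpha}). Baseline observations are the maximal stimulus-free
#' intervals of the session.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param epochs a \linkS4class{StimEpochs} (at least 2 epochs and 2
#'   stimulus-free gaps).
#' @param alpha significance level.
#' @return logical vector per neuron; attribute \code{"pValue"} carries
#'   the per-neuron p-values (NA where the test is degenerate: such
#'   neurons are not tuned).
#' @export
tunedNeurons <- function(raster, epochs, alpha = 0.05) {
  stopifnot(methods::is(raster, "BinaryRaster"),
            methods::is(epochs, "StimEpochs"))
  alpha <- assertNumber(alpha, "alpha", 1e-12, 1 - 1e-12)
  f <- nFrames(raster)
  on <- epochs@onsets
  off <- epochs@offsets
  if (any(off - 1L > f)) stop("epochs extend past the raster")
  if (length(on) < 2L) stop("at least 2 stimulus epochs are required")
  stimWindows <- lapply(seq_along(on), function(i) seq.int(on[i], off[i] - 1L))
  gapBounds <- rbind(
    if (on[1L] > 1L) c(1L, on[1L] - 1L),
    cbind(utils::head(off, -1L), utils::tail(on, -1L) - 1L),
    if (off[length(off)] <= f) c(off[length(off)], f))
  gapBounds <- gapBounds[gapBounds[, 2L] >= gapBounds[, 1L], , drop = FALSE]
  if (nrow(gapBounds) < 2L)
    stop("at least 2 stimulus-free gaps are required")
  gapWindows <- lapply(seq_len(nrow(gapBounds)), function(i)
    seq.int(gapBounds[i, 1L], gapBounds[i, 2L]))
  a <- raster@activity
  pvals <- vapply(seq_len(nrow(a)), function(r) {
    stim <- vapply(stimWindows, function(w) mean(a[r, w]), numeric(1))
    base <- vapply(gapWindows, function(w) mean(a[r, w]), numeric(1))
    if (stats::sd(stim) == 0 && stats::sd(base) == 0) {
      # zero variance in both groups: perfect separation is maximal
      # tuning, equal constants leave nothing to test (flagged NA)
      return(if (mean(stim) > mean(base)) 0 else NA_real_)
    }
    stats::t.test(stim, base, alternative = "greater")$p.value
  }, numeric(1))
  tuned <- !is.na(pvals) & pvals < alpha
  attr(tuned, "pValue") <- pvals
  tuned
}

# Detect ensembles, tolerating sessions in which nothing coactivates
# significantly (returns an empty EnsembleSet instead of failing); used by
# stabilityAnalysis, in particular for its shuffle-control branch.
detectOrEmpty <- function(raster, cfg) {
  tryCatch(
    if (identical(cfg$detector, "coactivity_peaks"))
      detectCoactivityPeaks(raster, nSurrogates = cfg$nSurrogates,
                            alpha = cfg$alpha, seed = cfg$seed,
                            kMax = cfg$kMax, demix = cfg$demix)
    else
      detectEnsembles(raster,
                      nSurrogates = cfg$nSurrogates, alpha = cfg$alpha,
                      seed = cfg$seed, minCoactive = cfg$minCoactive,
                      similarityThreshold = cfg$similarityThreshold,
                      minCluster = cfg$minCluster, kMax = cfg$kMax,
                      vectorSelection = cfg$vectorSelection,
                      demix = cfg$demix),
    error = function(e) {
      if (!grepl("insufficient coactivity", conditionMessage(e)))
        stop(e)
      warning("session '", sessionLabel(raster), "': ",
              conditionMessage(e), "; treating as zero ensembles")
      methods::new("EnsembleSet", members = list(), frames = list(),
                   nFrames = nFrames(raster), neuronIds = neuronIds(raster),
                   sessionLabel = sessionLabel(raster), config = cfg)
    })
}

stabilityConfig <- function(nSurrogates = 1000, alpha = 0.05, seed = 1L,
                            minCoactive = 3, similarityThreshold = 2 / 3,
                            minCluster = 2, kMax = 10,
                            vectorSelection = TRUE, demix = TRUE,
                            matchThreshold = 1 / 3, shuffleControl = FALSE,
                            detector = "connectivity") {
  list(nSurrogates = nSurrogates, alpha = alpha, seed = seed,
       minCoactive = minCoactive, similarityThreshold = similarityThreshold,
       minCluster = minCluster, kMax = kMax,
       vectorSelection = vectorSelection, demix = demix,
       matchThreshold = matchThreshold, shuffleControl = shuffleControl,
       detector = detector)
}

compareSessions <- function(rasterA, rasterB, cfg, pairLabel = c(1L, 2L)) {
  restricted <- commonRaster(rasterA, rasterB)
  ensA <- detectOrEmpty(restricted[[1L]], cfg)
  ensB <- detectOrEmpty(restricted[[2L]], cfg)
  matches <- if (nEnsembles(ensA) > 0L)
    suppressWarnings(matchEnsembles(ensA, ensB, cfg$matchThreshold))
  else data.frame(idFirst = integer(0), idSecond = integer(0),
                  jaccard = numeric(0), stable = logical(0))
  fate <- lapply(which(matches$stable), function(i)
    c(list(idFirst = matches$idFirst[i], idSecond = matches$idSecond[i]),
      neuronFate(ensembleMembers(ensA, matches$idFirst[i]),
                 ensembleMembers(ensB, matches$idSecond[i]))))
  measures <- NULL
  for (side in 1:2) {
    ens <- if (side == 1L) ensA else ensB
    net <- attr(ens, "network")
    # E_j is read from the connectivity-filtered raster when the detector
    # produced one (the clustered vectors live there), else from the input
    src <- attr(ens, "filteredRaster")
    if (is.null(src)) src <- restricted[[side]]
    for (j in seq_len(nEnsembles(ens))) {
      mem <- ensembleMembers(ens, j)
      dens <- if (length(mem) >= 2L && !is.null(net))
        ensembleDensity(net, mem) else NA_real_
      rob <- as.numeric(ensembleRobustness(
        ensembleRaster(ens, src, j), nFrames(ens)))
      measures <- rbind(measures, data.frame(
        session = pairLabel[side], ensemble = j, nMembers = length(mem),
        density = dens, robustness = rob))
    }
  }
  list(sessionPair = pairLabel,
       matches = matches,
       nStable = sum(matches$stable),
       nTransient = nEnsembles(ensA) - sum(matches$stable),
       fate = fate,
       measures = measures,
       ensemblesA = ensA, ensemblesB = ensB,
       commonNeurons = neuronIds(restricted[[1L]]))
}

#' Longitudinal ensemble stability analysis
#'
#' For the first session versus each later session: restrict both rasters
#' to their common neurons, detect ensembles independently in each
#' restricted raster, match them by member-set Jaccard similarity,
#' classify stable versus transient, and compute per-ensemble neuron fate,
#' network density and robustness. With \code{shuffleControl = TRUE} the
#' whole comparison is rerun on circularly shuffled copies of the rasters
#' and the resulting stable-ensemble count is reported alongside: shuffled
#' data should yield far fewer stable ensembles.
#'
#' @param sessions list of \linkS4class{BinaryRaster}s (>= 2) over a
#'   shared neuron-ID registry. Neurons are matched across sessions by ID;
#'   apply \code{\link{matchRois}} + \code{\link{commonRaster}} first when
#'   IDs are per-session.
#' @param nSurrogates,alpha,seed,minCoactive,similarityThreshold,minCluster,kMax,vectorSelection,demix
#'   detection parameters, as in \code{\link{detectEnsembles}}.
#' @param matchThreshold stability threshold on member-set Jaccard
#'   (default 1/3, inclusive).
#' @param shuffleControl also analyze circularly shuffled rasters.
#' @param detector \code{"connectivity"} (default) or
#'   \code{"coactivity_peaks"}.
#' @return A \linkS4class{StabilityReport}.
#' @export
stabilityAnalysis <- function(sessions, nSurrogates = 1000, alpha = 0.05,
                              seed = 1L, minCoactive = 3,
                              similarityThreshold = 2 / 3, minCluster = 2,
                              kMax = 10, vectorSelection = TRUE,
                              demix = TRUE, matchThreshold = 1 / 3,
                              shuffleControl = FALSE,
                              detector = c("connectivity",
                                           "coactivity_peaks")) {
  if (!is.list(sessions) || length(sessions) < 2L)
    stop("at least 2 sessions are required")
  for (s in sessions) stopifnot(methods::is(s, "BinaryRaster"))
  detector <- match.arg(detector)
  cfg <- stabilityConfig(nSurrogates, alpha, seed, minCoactive,
                         similarityThreshold, minCluster, kMax,
                         vectorSelection, demix, matchThreshold,
                         shuffleControl, detector)
  comparisons <- vector("list", length(sessions) - 1L)
  for (s in seq.int(2L, length(sessions))) {
    cmp <- tryCatch(
      compareSessions(sessions[[1L]], sessions[[s]], cfg, c(1L, s)),
      error = function(e) stageError(sprintf("compare sessions 1 vs %d", s),
                                     e))
    if (shuffleControl) {
      shufA <- shuffleRaster(sessions[[1L]], "circular_per_neuron",
                             seed = subSeed(cfg$seed, 900 + s))
      shufB <- shuffleRaster(sessions[[s]], "circular_per_neuron",
                             seed = subSeed(cfg$seed, 950 + s))
      shufCmp <- compareSessions(shufA, shufB, cfg, c(1L, s))
      cmp$shuffle <- list(nStable = shufCmp$nStable,
                          nTransient = shufCmp$nTransient,
                          matches = shufCmp$matches)
    }
    comparisons[[s - 1L]] <- cmp
  }
  methods::new("StabilityReport", comparisons = comparisons, config = cfg)
}
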