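# S4 classes for the ensemble-detection pipeline.

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' BinaryRaster: neurons-by-frames binary activity matrix
#'
#' The universal currency of the pipeline: an \code{N x F} 0/1 matrix where
#' rows are neurons and columns are imaging frames, together with stable
#' integer neuron identifiers, the frame period in seconds, and a session
#' label. One frame corresponds to one imaging volume (81 ms by default).
#'
#' @slot activity integer matrix of 0/1 entries, neurons in rows.
#' @slot neuronIds unique integer identifiers, one per row. They are stable
#'   across sessions so that the same cell can be tracked longitudinally.
#' @slot framePeriod frame period in seconds (default 0.081).
#' @slot sessionLabel free-text session identifier.
#' @export
setClass("BinaryRaster",
  slots = c(
    activity = "matrix",
    neuronIds = "integer",
    framePeriod = "numeric",
    sessionLabel = "character"
  )
)

setValidity("BinaryRaster", function(object) {
  a <- object@activity
  if (nrow(a) < 1L || ncol(a) < 1L)
    return("activity must have at least one neuron and one frame")
  if (!all(a == 0L | a == 1L))
    return("activity entries must be 0 or 1")
  if (length(object@neuronIds) != nrow(a))
    return("neuronIds must have one entry per row of activity")
  if (anyDuplicated(object@neuronIds))
    return("neuronIds must be unique")
  if (length(object@framePeriod) != 1L || object@framePeriod <= 0)
    return("framePeriod must be a single positive number")
  TRUE
})

#' Construct a BinaryRaster
#'
#' @param activity numeric or logical matrix with entries 0/1; neurons in
#'   rows, frames in columns.
#' @param neuronIds integer vector of unique neuron identifiers (default
#'   \code{1:N}).
#' @param framePeriod frame period in seconds.
#' @param sessionLabel session label.
#' @return A \linkS4class{BinaryRaster}.
#' @examples
#' r <- BinaryRaster(matrix(c(1, 0, 0, 1), 2, 2))
#' nNeurons(r)
#' @export
BinaryRaster <- function(activity, neuronIds = seq_len(nrow(activity)),
                         framePeriod = 0.081, sessionLabel = "") {
  if (is.logical(activity)) storage.mode(activity) <- "integer"
  if (is.double(activity)) {
    if (any(activity != 0 & activity != 1))
      stop("activity entries must be 0 or 1")
    storage.mode(activity) <- "integer"
  }
  methods::new("BinaryRaster", activity = activity,
               neuronIds = as.integer(neuronIds),
               framePeriod = as.double(framePeriod),
               sessionLabel = as.character(sessionLabel))
}

#' FunctionalNetwork: surrogate-tested pairwise coactivity
#'
#' Holds the observed coactivation counts \code{Co}, the per-pair surrogate
#' thresholds \code{T} (the \code{ceiling((1 - alpha) * nSurrogates)}-th
#' order statistic of the circular-shift surrogate coactivation counts) and
#' the significant-edge adjacency matrix (\code{Co > T}, strict).
#'
#' @slot coactivation symmetric integer matrix; the diagonal carries each
#'   neuron's active-frame count.
#' @slot threshold symmetric numeric matrix of surrogate thresholds.
#' @slot adjacency symmetric logical matrix with a FALSE diagonal.
#' @slot nSurrogates,alpha,seed,mode parameters of the surrogate test.
#' @slot neuronIds neuron identifiers matching the raster the network was
#'   built from.
#' @slot surrogates optional pairs-by-iterations matrix of surrogate
#'   coactivation counts (kept only when requested; reused by demixing).
#' @export
setClass("FunctionalNetwork",
  slots = c(
    coactivation = "matrix",
    threshold = "matrix",
    adjacency = "matrix",
    nSurrogates = "integer",
    alpha = "numeric",
    seed = "integer",
    mode = "character",
    neuronIds = "integer",
    surrogates = "matrixOrNULL"
  )
)

setValidity("FunctionalNetwork", function(object) {
  n <- nrow(object@coactivation)
  if (ncol(object@coactivation) != n) return("coactivation must be square")
  if (!isTRUE(all.equal(object@coactivation, t(object@coactivation))))
    return("coactivation must be symmetric")
  if (!identical(dim(object@adjacency), dim(object@coactivation)))
    return("adjacency dimensions must match coactivation")
  if (any(diag(object@adjacency)))
    return("adjacency diagonal must be FALSE (no self-edges)")
  if (!identical(object@adjacency, t(object@adjacency)))
    return("adjacency must be symmetric")
  if (any(object@adjacency & !(object@coactivation > object@threshold)))
    return("every edge must satisfy Co > T")
  if (length(object@neuronIds) != n)
    return("neuronIds must have one entry per neuron")
  TRUE
})

#' EnsembleSet: detected neuronal ensembles of one session
#'
#' Each ensemble is a set of member neurons plus the ordered frames in which
#' it was active. Frame assignments are disjoint across ensembles: every
#' retained population vector belongs to exactly one ensemble. The ensemble
#' raster \code{E_j} and activity vector \code{V_j} are derived on demand
#' via \code{\link{ensembleRaster}} and \code{\link{activityVector}}.
#'
#' @slot members list of integer neuron-ID vectors, one per ensemble.
#' @slot frames list of strictly increasing frame-index vectors.
#' @slot nFrames total frames F of the source session.
#' @slot neuronIds neuron-ID registry of the source raster.
#' @slot sessionLabel label of the source session.
#' @slot config named list snapshot of the detection parameters.
#' @export
setClass("EnsembleSet",
  slots = c(
    members = "list",
    frames = "list",
    nFrames = "integer",
    neuronIds = "integer",
    sessionLabel = "character",
    config = "list"
  )
)

setValidity("EnsembleSet", function(object) {
  if (length(object@members) != length(object@frames))
    return("members and frames must have the same length")
  for (fr in object@frames) {
    if (is.unsorted(fr, strictly = TRUE))
      return("ensemble frames must be strictly increasing")
    if (length(fr) && (min(fr) < 1L || max(fr) > object@nFrames))
      return("ensemble frames out of range")
  }
  allFrames <- unlist(object@frames, use.names = FALSE)
  if (anyDuplicated(allFrames))
    return("frame assignments must be disjoint across ensembles")
  for (m in object@members)
    if (!all(m %in% object@neuronIds))
      return("ensemble members must be drawn from neuronIds")
  TRUE
})

#' MembershipTable: demixed neuron-by-ensemble participation
#'
#' @slot membership logical matrix, ensembles in rows, neurons in columns.
#' @slot correlations Pearson correlations \code{P[j, a]} between each
#'   neuron's activity and each ensemble's activity vector.
#' @slot maxWeight per ensemble and neuron, the largest ensemble weight
#'   \code{W = P_a * P_b * Co_ab} over that neuron's significant pairs
#'   (NA where the neuron has none).
#' @slot participationClass per neuron: "single", "shared" or "none".
#' @slot neuronIds neuron identifiers (columns).
#' @export
setClass("MembershipTable",
  slots = c(
    membership = "matrix",
    correlations = "matrix",
    maxWeight = "matrix",
    participationClass = "character",
    neuronIds = "integer"
  )
)

setValidity("MembershipTable", function(object) {
  n <- ncol(object@membership)
  if (length(object@neuronIds) != n)
    return("neuronIds must match membership columns")
  if (length(object@participationClass) != n)
    return("participationClass must have one entry per neuron")
  counts <- colSums(object@membership)
  cls <- ifelse(counts == 0L, "none", ifelse(counts == 1L, "single", "shared"))
  if (!identical(unname(cls), unname(object@participationClass)))
    return("participationClass inconsistent with membership row sums")
  TRUE
})

#' StabilityReport: cross-session ensemble comparison
#'
#' One comparison per (first session, later session) pair. Each comparison
#' records the greedy one-to-one ensemble matches with their member-set
#' Jaccard similarity, the stable/transient split, per-ensemble neuron fate
#' (stable/lost/new), robustness and network density, and (optionally) the
#' same quantities recomputed on circularly shuffled rasters as a control.
#'
#' @slot comparisons list, one element per session pair.
#' @slot config named list snapshot of the analysis parameters.
#' @export
setClass("StabilityReport",
  slots = c(
    comparisons = "list",
    config = "list"
  )
)

#' StimEpochs: stimulus presentation windows
#'
#' Half-open frame windows \code{[onset, offset)} in 1-based frame indices:
#' a 2 s drifting-grating presentation starting at frame 10 with a 81 ms
#' frame period covers frames 10..33 and is encoded as onset 10, offset 34.
#'
#' @slot onsets strictly increasing 1-based frame indices.
#' @slot offsets frame indices with \code{offset > onset}; epochs must not
#'   overlap.
#' @export
setClass("StimEpochs",
  slots = c(onsets = "integer", offsets = "integer")
)

setValidity("StimEpochs", function(object) {
  on <- object@onsets; off <- object@offsets
  if (length(on) != length(off)) return("onsets and offsets must pair up")
  if (length(on) == 0L) return("at least one epoch is required")
  if (is.unsorted(on, strictly = TRUE)) return("onsets must strictly increase")
  if (any(off <= on)) return("each offset must exceed its onset")
  if (length(on) > 1L && any(on[-1L] < off[-length(off)]))
    return("epochs must not overlap")
  if (any(on < 1L)) return("onsets must be >= 1")
  TRUE
})

#' @rdname StimEpochs-class
#' @param onsets,offsets integer frame indices (half-open \code{[onset, offset)}).
#' @return A \linkS4class{StimEpochs}.
#' @export
StimEpochs <- function(onsets, offsets) {
  methods::new("StimEpochs", onsets = as.integer(onsets),
               offsets = as.integer(offsets))
}

#' RoiSet: ROI masks or centroids for cross-session neuron matching
#'
#' Supply either per-neuron binary pixel masks (all of the same image shape)
#' or an n-by-2 matrix of centroid coordinates in pixels. Inputs are assumed
#' pre-aligned to a common coordinate frame; registration is out of scope.
#'
#' @slot masks list of logical matrices (possibly empty).
#' @slot centroids numeric n-by-2 matrix of (x, y) pixel coordinates.
#' @slot ids integer ROI/neuron identifiers.
#' @export
setClass("RoiSet",
  slots = c(masks = "list", centroids = "matrix", ids = "integer")
)

setValidity("RoiSet", function(object) {
  hasMasks <- length(object@masks) > 0L
  hasCentroids <- nrow(object@centroids) > 0L
  if (!hasMasks && !hasCentroids)
    return("either masks or centroids must be supplied")
  n <- if (hasMasks) length(object@masks) else nrow(object@centroids)
  if (hasMasks) {
    shp <- dim(object@masks[[1L]])
    for (m in object@masks) {
      if (!is.logical(m) && !all(m == 0 | m == 1))
        return("masks must be binary")
      if (!identical(dim(m), shp)) return("masks must share one image shape")
    }
    if (hasCentroids && nrow(object@centroids) != n)
      return("centroids must align with masks")
  }
  if (hasCentroids && ncol(object@centroids) != 2L)
    return("centroids must be an n-by-2 matrix")
  if (length(object@ids) != n) return("ids must have one entry per ROI")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  TRUE
})

#' @rdname RoiSet-class
#' @param masks list of binary matrices, one per ROI (optional).
#' @param centroids n-by-2 matrix of (x, y) centroids in pixels (optional;
#'   computed from masks when missing).
#' @param ids ROI identifiers.
#' @return A \linkS4class{RoiSet}.
#' @export
RoiSet <- function(masks = list(), centroids = NULL, ids = NULL) {
  if (length(masks) && is.null(centroids)) {
    centroids <- t(vapply(masks, function(m) {
      w <- which(m != 0, arr.ind = TRUE)
      c(mean(w[, 2L]), mean(w[, 1L]))  # (x, y) = (col, row)
    }, numeric(2L)))
  }
  if (is.null(centroids)) centroids <- matrix(numeric(0), 0L, 2L)
  centroids <- as.matrix(centroids)
  if (is.null(ids))
    ids <- seq_len(if (length(masks)) length(masks) else nrow(centroids))
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  methods::new("RoiSet", masks = masks, centroids = centroids,
               ids = as.integer(ids))
}

#' GroundTruth: planted structure of a synthetic session or experiment
#'
#' Bookkeeping container written by the synthetic generators and consumed
#' by tests: which neurons were planted in which ensemble, at which frames
#' each ensemble fired, which ensembles are stable across sessions, the
#' per-neuron fate within stable ensembles (core members kept across
#' sessions vs. rotated ones) and the common-neuron set of each session
#' pair.
#'
#' @slot members per session, a list of integer member-ID vectors.
#' @slot eventFrames per session, a list of integer frame-index vectors.
#' @slot stableFlags logical, one per ensemble slot (TRUE = re-occurs in
#'   every session).
#' @slot neuronFate per stable ensemble, a list with elements \code{core}
#'   and, per session, the rotated members.
#' @slot commonNeurons per later session, the IDs active both on day 1 and
#'   in that session.
#' @slot backgroundRate per session, the calibrated per-neuron background
#'   spike probabilities.
#' @export
setClass("GroundTruth",
  slots = c(
    members = "list",
    eventFrames = "list",
    stableFlags = "logical",
    neuronFate = "list",
    commonNeurons = "list",
    backgroundRate = "list"
  )
)
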