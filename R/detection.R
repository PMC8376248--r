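# Ensemble detection: Jaccard similarity of population vectors, vector
# selection by single-linkage clustering, Ward clustering with a contrast
# index to choose the number of ensembles, and an alternative detector
# based on population coactivity peaks.

#' Jaccard similarity matrix of binary vectors
#'
#' \code{S[u, v] = |u & v| / |u | v|} for every pair of vectors; symmetric
#' with a unit diagonal. Vectors are the columns (\code{axis = "frames"},
#' population vectors) or rows (\code{axis = "neurons"}) of the supplied
#' binary matrix.
#'
#' @param x binary matrix.
#' @param axis which slices are the vectors.
#' @return numeric similarity matrix in [0, 1].
#' @examples
#' jaccardMatrix(cbind(c(1, 1, 0), c(1, 0, 1)))[1, 2]  # 1/3
#' @export
jaccardMatrix <- function(x, axis = c("frames", "neurons")) {
  axis <- match.arg(axis)
  if (axis == "neurons") x <- t(x)
  if (ncol(x) < 2L) stop("at least 2 vectors are required")
  if (!all(x == 0 | x == 1)) stop("x must be binary")
  sums <- colSums(x)
  if (any(sums == 0L))
    stop("all-zero vector at index ", which(sums == 0L)[1L],
         ": Jaccard similarity undefined")
  storage.mode(x) <- "double"
  inter <- crossprod(x)
  uni <- outer(sums, sums, "+") - inter
  s <- inter / uni
  dimnames(s) <- NULL
  s
}

#' Select mutually similar population vectors
#'
#' Builds a single-linkage tree on Jaccard distance (1 - similarity), cuts
#' it so that only merges at similarity strictly above \code{threshold}
#' survive (default 2/3), and pools every resulting cluster with at least
#' \code{minCluster} vectors. Vectors outside such clusters - infrequent
#' or dissimilar coactivations - are dropped.
#'
#' @param s Jaccard similarity matrix (e.g. from
#'   \code{\link{jaccardMatrix}}).
#' @param threshold similarity cut (strict: pairs at exactly the threshold
#'   do not merge).
#' @param minCluster minimum cluster size to retain.
#' @return integer vector of retained column indices (attribute
#'   \code{"cluster"} carries the single-linkage cluster labels); empty
#'   with a warning when no cluster reaches \code{minCluster}.
#' @export
selectSimilarVectors <- function(s, threshold = 2 / 3, minCluster = 2) {
  if (!is.matrix(s) || nrow(s) != ncol(s))
    stop("s must be a square similarity matrix")
  minCluster <- assertCount(minCluster, "minCluster", 1)
  tree <- stats::hclust(stats::as.dist(1 - s), method = "single")
  # cutree merges branches with height <= h; shaving epsilon off the cut
  # keeps exact-threshold pairs apart (strict inequality)
  labels <- stats::cutree(tree, h = (1 - threshold) - 1e-9)
  keepLabels <- which(tabulate(labels) >= minCluster)
  retained <- which(labels %in% keepLabels)
  if (length(retained) == 0L)
    warning("no vector cluster reaches size ", minCluster,
            "; session yields no ensembles")
  attr(retained, "cluster") <- labels[retained]
  retained
}

#' Contrast index of a clustering on a similarity matrix
#'
#' \code{CI = w - b}, the mean within-cluster pairwise similarity (pooled
#' over all within pairs) minus the mean between-cluster pairwise
#' similarity. Bounded in [-1, 1]; large for tight, well-separated
#' clusters; used to choose the number of ensembles. The unnormalized
#' contrast penalizes both under- and over-clustering: merging two
#' separated blocks dilutes \code{w} with their near-zero cross pairs,
#' while splitting a real block moves high similarities into \code{b}. (A
#' normalized variant \code{(w - b)/(w + b)} saturates near 1 whenever
#' \code{b} is close to 0, and so cannot detect mergers of well-separated
#' ensembles that share no neurons.)
#'
#' @param s similarity matrix.
#' @param labels integer cluster assignment (>= 2 clusters, each
#'   nonempty).
#' @return the contrast index; \code{-1} when no within-cluster pair
#'   exists (all-singleton clusterings).
#' @export
contrastIndex <- function(s, labels) {
  if (!is.matrix(s) || nrow(s) != ncol(s))
    stop("s must be a square similarity matrix")
  if (length(labels) != nrow(s))
    stop("labels must have one entry per vector")
  if (length(unique(labels)) < 2L)
    stop("contrast index requires at least 2 clusters")
  same <- outer(labels, labels, "==")
  ut <- upper.tri(s)
  withinVals <- s[ut & same]
  betweenVals <- s[ut & !same]
  if (length(withinVals) == 0L) return(-1)
  mean(withinVals) - mean(betweenVals)
}

#' Cluster retained population vectors into ensembles
#'
#' Ward-linkage hierarchical clustering on the Jaccard distance between
#' the retained population vectors (the linkage is applied to the Jaccard
#' distance matrix directly, a documented deviation from Ward's Euclidean
#' textbook setting). The number of clusters k is chosen by exhaustive
#' scan over \code{2..min(kMax, n - 1)} maximizing the contrast index,
#' taking the smallest k whose index comes within \code{ciTol} (relative)
#' of the maximum. The tolerance makes the parsimony tie-break effective
#' in floating point: once the true coactivation patterns are separated
#' the index plateaus, and further splits of chance micro-patterns buy
#' per-mille gains, while merging two real patterns costs percent-level
#' losses. Each coherent cluster becomes one ensemble:
#' its frames are the retained vectors' frame indices and its provisional
#' members are the neurons active in at least one of those frames
#' (refined later by \code{\link{demixMembership}}).
#'
#' Because Ward clustering partitions every retained vector, chance
#' micro-patterns (recurring coincidences of a few background neurons
#' that survived selection as tiny duplicate clusters) agglomerate into a
#' residual cluster of mutually dissimilar vectors. Such a cluster is not
#' a recurring coactivation pattern: its mean within-cluster similarity
#' sits an order of magnitude below that of a real ensemble (about 0.1
#' versus 0.5-0.8). Clusters whose mean internal Jaccard similarity is
#' not above \code{minCoherence} are therefore not reported as ensembles;
#' their frames are recorded in the result's config as
#' \code{unassignedFrames}. The default floor 1/3 is the same
#' minimal-identity similarity the stability analysis uses to say two
#' member sets describe one ensemble.
#'
#' @param filteredRaster the connectivity-filtered
#'   \linkS4class{BinaryRaster}.
#' @param retained frame indices of the retained population vectors.
#' @param kMax largest number of ensembles scanned (default 10).
#' @param ciTol relative contrast-index tolerance for the parsimony rule
#'   (default 0.01: smallest k within 1\% of the best index wins).
#' @param minCoherence minimum mean within-cluster Jaccard similarity for
#'   a cluster to be reported as an ensemble (default 1/3).
#' @param config optional named list stored in the result.
#' @return An \linkS4class{EnsembleSet}.
#' @export
clusterEnsembles <- function(filteredRaster, retained, kMax = 10,
                             ciTol = 0.01, minCoherence = 1 / 3,
                             config = list()) {
  stopifnot(methods::is(filteredRaster, "BinaryRaster"))
  kMax <- assertCount(kMax, "kMax", 2)
  ciTol <- assertNumber(ciTol, "ciTol", 0, 1)
  minCoherence <- assertNumber(minCoherence, "minCoherence", 0, 1)
  retained <- sort(as.integer(retained))
  if (length(retained) < 3L)
    stop("insufficient coactivity: fewer than 3 retained population vectors")
  cols <- filteredRaster@activity[, retained, drop = FALSE]
  s <- jaccardMatrix(cols, axis = "frames")
  tree <- stats::hclust(stats::as.dist(1 - s), method = "ward.D")
  ks <- seq.int(2L, min(kMax, length(retained) - 1L))
  ci <- vapply(ks, function(k) contrastIndex(s, stats::cutree(tree, k = k)),
               numeric(1))
  # smallest k on the contrast-index plateau (parsimony with tolerance)
  k <- ks[which(ci >= max(ci) - ciTol * abs(max(ci)))[1L]]
  labels <- stats::cutree(tree, k = k)
  coherence <- vapply(seq_len(k), function(j) {
    idx <- which(labels == j)
    if (length(idx) < 2L) return(1)
    sub <- s[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  keep <- which(coherence > minCoherence)
  if (length(keep) == 0L)
    stop("insufficient coactivity: no coherent vector cluster ",
         "(all mean within-cluster similarities <= ", round(minCoherence, 3),
         ")")
  members <- vector("list", length(keep))
  frames <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    frames[[i]] <- retained[labels == keep[i]]
    sub <- filteredRaster@activity[, frames[[i]], drop = FALSE]
    members[[i]] <- filteredRaster@neuronIds[rowSums(sub) > 0L]
  }
  # report ensembles by decreasing activation (stable presentation order)
  ord <- order(vapply(frames, length, integer(1)), decreasing = TRUE)
  methods::new("EnsembleSet",
    members = members[ord], frames = frames[ord],
    nFrames = ncol(filteredRaster@activity),
    neuronIds = filteredRaster@neuronIds,
    sessionLabel = filteredRaster@sessionLabel,
    config = c(config, list(k = k, kMax = kMax,
                            contrastIndex = max(ci),
                            coherence = coherence[keep][ord],
                            unassignedFrames = retained[!(labels %in% keep)])))
}

#' Detect neuronal ensembles from a binary raster
#'
#' End-to-end connectivity-based detector: significant functional
#' connections (circular-shift surrogate null) -> connectivity filtering
#' of the raster -> Jaccard similarity between the retained population
#' vectors -> single-linkage vector selection (> 2/3 similarity) -> Ward
#' clustering with contrast-index model selection -> membership demixing.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param nSurrogates,alpha,seed surrogate-null parameters (see
#'   \code{\link{significantConnections}}).
#' @param minCoactive minimum coactive neurons per retained frame.
#' @param similarityThreshold vector-selection cut (default 2/3, strict).
#' @param minCluster minimum vector-cluster size in the selection step.
#' @param kMax largest ensemble count scanned.
#' @param ciTol contrast-index plateau tolerance (see
#'   \code{\link{clusterEnsembles}}).
#' @param minCoherence ensemble coherence floor (see
#'   \code{\link{clusterEnsembles}}).
#' @param vectorSelection when \code{FALSE}, the single-linkage selection
#'   step is skipped and all filtered population vectors are clustered
#'   (the "all vectors" robustness variant).
#' @param demix refine provisional members with
#'   \code{\link{demixMembership}} (default TRUE).
#' @return An \linkS4class{EnsembleSet}; its \code{config} records all
#'   thresholds and the seed. The functional network is attached as
#'   attribute \code{"network"}, the demixed \linkS4class{MembershipTable}
#'   as attribute \code{"membership"}.
#' @examples
#' \donttest{
#' sim <- generateSession(sessionParams(nNeurons = 60, nFrames = 1200,
#'                                      nEnsembles = 3, ensembleSize = 12,
#'                                      eventsPerEnsemble = 200), seed = 7)
#' ens <- detectEnsembles(sim$raster, nSurrogates = 200, seed = 7)
#' nEnsembles(ens)
#' }
#' @export
detectEnsembles <- function(raster, nSurrogates = 1000, alpha = 0.05,
                            seed = 1L, minCoactive = 3,
                            similarityThreshold = 2 / 3, minCluster = 2,
                            kMax = 10, ciTol = 0.01, minCoherence = 1 / 3,
                            vectorSelection = TRUE, demix = TRUE) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  cfg <- list(detector = "connectivity", nSurrogates = nSurrogates,
              alpha = alpha, seed = seed, minCoactive = minCoactive,
              similarityThreshold = similarityThreshold,
              minCluster = minCluster, kMax = kMax,
              vectorSelection = vectorSelection)
  net <- tryCatch(
    significantConnections(raster, nSurrogates, alpha, seed),
    error = function(e) stageError("significantConnections", e))
  filt <- tryCatch(filterRaster(raster, net, minCoactive),
                   error = function(e) stageError("filterRaster", e))
  candidate <- which(filt$retained)
  if (length(candidate) < 3L)
    stop("insufficient coactivity: fewer than 3 frames survive ",
         "connectivity filtering")
  if (vectorSelection && length(candidate) >= 2L) {
    s <- tryCatch(
      jaccardMatrix(filt$raster@activity[, candidate, drop = FALSE]),
      error = function(e) stageError("jaccardMatrix", e))
    sel <- tryCatch(
      selectSimilarVectors(s, similarityThreshold, minCluster),
      error = function(e) stageError("selectSimilarVectors", e))
    retained <- candidate[sel]
  } else {
    retained <- candidate
  }
  ens <- tryCatch(clusterEnsembles(filt$raster, retained, kMax, ciTol,
                                          minCoherence, cfg),
                  error = function(e) stageError("clusterEnsembles", e))
  if (demix) {
    # the membership null draws its own surrogates: reusing the edge
    # test's draws would couple the two tests' Monte-Carlo errors and
    # bias the membership threshold low for chance hub neurons
    mt <- tryCatch(
      demixMembership(raster, ens, nSurrogates, alpha, seed),
      error = function(e) stageError("demixMembership", e))
    ens <- applyMembership(ens, mt)
    attr(ens, "membership") <- mt
  }
  attr(ens, "network") <- net
  attr(ens, "filteredRaster") <- filt$raster
  ens
}

# Replace provisional ensemble members by the demixed ones; ensembles whose
# demixed member set is empty are dropped with a warning.
applyMembership <- function(ens, mt) {
  k <- nEnsembles(ens)
  members <- lapply(seq_len(k), function(j)
    mt@neuronIds[mt@membership[j, ]])
  empty <- vapply(members, length, integer(1)) == 0L
  if (any(empty))
    warning(sum(empty), " ensemble(s) lost all members during demixing ",
            "and were dropped")
  methods::initialize(ens, members = members[!empty],
                      frames = ens@frames[!empty])
}

#' Detect ensembles from population coactivity peaks
#'
#' Alternative detector: the population coactivity \code{c(t)} (number of
#' active neurons per frame) is compared with a pooled null distribution
#' of per-frame coactivity from circular-shift surrogate rasters; frames
#' with \code{c(t)} strictly above the \code{1 - alpha} null quantile are
#' retained and clustered exactly as in \code{\link{clusterEnsembles}}.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param nSurrogates,alpha,seed null parameters.
#' @param kMax largest ensemble count scanned.
#' @param ciTol contrast-index plateau tolerance.
#' @param minCoherence ensemble coherence floor (see
#'   \code{\link{clusterEnsembles}}).
#' @param demix refine members with \code{\link{demixMembership}}.
#' @return An \linkS4class{EnsembleSet}; empty (zero ensembles) with a
#'   warning when no frame exceeds the threshold.
#' @export
detectCoactivityPeaks <- function(raster, nSurrogates = 1000, alpha = 0.05,
                                  seed = 1L, kMax = 10, ciTol = 0.01,
                                  minCoherence = 1 / 3, demix = TRUE) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  nSurrogates <- assertCount(nSurrogates, "nSurrogates", 100)
  alpha <- assertNumber(alpha, "alpha", 1e-12, 1 - 1e-12)
  a <- raster@activity
  n <- nrow(a)
  f <- ncol(a)
  if (f < 2L) stop("raster must have at least 2 frames")
  coact <- colSums(a)
  ad <- a
  storage.mode(ad) <- "double"
  nullCoact <- withSeed(seed, {
    out <- numeric(as.double(nSurrogates) * f)
    for (i in seq_len(nSurrogates)) {
      off <- sample.int(f - 1L, n, replace = TRUE)
      out[seq.int((i - 1L) * f + 1L, i * f)] <- colSums(shiftRows(ad, off))
    }
    out
  })
  kth <- ceiling((1 - alpha) * length(nullCoact))
  threshold <- sort.int(nullCoact, partial = kth)[kth]
  retained <- which(coact > threshold)
  cfg <- list(detector = "coactivity_peaks", nSurrogates = nSurrogates,
              alpha = alpha, seed = seed, kMax = kMax,
              coactivityThreshold = threshold)
  if (length(retained) == 0L) {
    warning("no frame exceeds the surrogate coactivity threshold (",
            threshold, "); returning an empty EnsembleSet")
    return(methods::new("EnsembleSet", members = list(), frames = list(),
                        nFrames = f, neuronIds = raster@neuronIds,
                        sessionLabel = raster@sessionLabel, config = cfg))
  }
  if (length(retained) < 3L)
    stop("insufficient coactivity: fewer than 3 frames above threshold")
  ens <- clusterEnsembles(raster, retained, kMax, ciTol, minCoherence, cfg)
  if (demix) {
    mt <- demixMembership(raster, ens, nSurrogates, alpha, seed)
    ens <- applyMembership(ens, mt)
    attr(ens, "membership") <- mt
  }
  ens
}
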