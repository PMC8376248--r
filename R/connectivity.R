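# Surrogate-tested pairwise functional connectivity and
# connectivity-based raster filtering.

#' Pairwise coactivation counts
#'
#' \code{Co[a, b]} is the number of frames in which neurons a and b are
#' both active; the diagonal carries each neuron's active-frame count.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @return symmetric integer matrix.
#' @examples
#' r <- BinaryRaster(rbind(c(1, 0, 1, 1), c(1, 1, 0, 1)))
#' coactivationMatrix(r)  # off-diagonal 2
#' @export
coactivationMatrix <- function(raster) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  co <- tcrossprod(raster@activity)
  storage.mode(co) <- "integer"
  co
}

# Surrogate coactivation counts under the circular-shift null.
# Returns a pairs-by-iterations integer matrix over the lower triangle of
# the coactivation matrix (pair order = column-major lower triangle).
# Each iteration shifts every neuron's row once by an independent uniform
# nonzero offset and computes all pairwise counts with one matrix product
# ("shared_shift"); the marginal null per pair is identical to shifting
# each pair independently.
surrogateCoactivations <- function(activity, nSurrogates, seed) {
  n <- nrow(activity)
  f <- ncol(activity)
  if (f < 2L) stop("at least 2 frames are required for circular surrogates")
  lt <- which(lower.tri(matrix(0, n, n)))
  a <- activity
  storage.mode(a) <- "double"
  withSeed(seed, {
    s <- matrix(0L, length(lt), nSurrogates)
    for (i in seq_len(nSurrogates)) {
      off <- sample.int(f - 1L, n, replace = TRUE)  # nonzero shifts only
      s[, i] <- as.integer(tcrossprod(shiftRows(a, off))[lt])
    }
    s
  })
}

# Literal per-pair variant: every pair gets its own independent surrogate
# stream (both rows shifted per iteration). O(N^2 K F); small rasters only.
surrogateCoactivationsPerPair <- function(activity, nSurrogates, seed) {
  n <- nrow(activity)
  f <- ncol(activity)
  if (f < 2L) stop("at least 2 frames are required for circular surrogates")
  nPairs <- n * (n - 1L) / 2L
  withSeed(seed, {
    s <- matrix(0L, nPairs, nSurrogates)
    p <- 0L
    for (b in seq_len(n - 1L)) for (a in seq.int(b + 1L, n)) {
      p <- p + 1L
      ra <- activity[a, ]
      rb <- activity[b, ]
      for (i in seq_len(nSurrogates)) {
        oa <- sample.int(f - 1L, 1L)
        ob <- sample.int(f - 1L, 1L)
        sa <- ra[((seq_len(f) - 1L - oa) %% f) + 1L]
        sb <- rb[((seq_len(f) - 1L - ob) %% f) + 1L]
        s[p, i] <- sum(sa * sb)
      }
    }
    s
  })
}

#' Significant functional connections under a circular-shift null
#'
#' For every neuron pair, builds the distribution of coactivation counts
#' over \code{nSurrogates} circular-shift surrogates (each iteration
#' displaces each neuron's spike train by an independent uniform nonzero
#' offset, preserving rate and autocorrelation while destroying
#' cross-neuron timing). The pair threshold \code{T} is the
#' \code{ceiling((1 - alpha) * nSurrogates)}-th order statistic of its
#' surrogate counts, and an edge is placed iff the observed count is
#' strictly greater than \code{T}. Neurons active in none or all frames
#' have shift-invariant rows, so their surrogate distribution is degenerate
#' at the observed count and they never gain edges.
#'
#' No multiple-testing correction is applied across the N(N-1)/2 pairs:
#' each pair is tested at its own \code{1 - alpha} level, a deliberately
#' liberal convention recorded in the object.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param nSurrogates number of surrogate iterations (>= 100).
#' @param alpha per-pair significance level in (0, 1).
#' @param seed integer seed for the surrogate stream.
#' @param mode \code{"shared_shift"} (default: one shift per neuron per
#'   iteration, all pairs from one matrix product) or \code{"per_pair"}
#'   (independent surrogate streams per pair; equal marginal null, much
#'   slower).
#' @param keepSurrogates keep the pairs-by-iterations surrogate count
#'   matrix in the result (reused by \code{\link{demixMembership}}).
#' @return A \linkS4class{FunctionalNetwork}.
#' @export
significantConnections <- function(raster, nSurrogates = 1000, alpha = 0.05,
                                   seed = 1L,
                                   mode = c("shared_shift", "per_pair"),
                                   keepSurrogates = FALSE) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  mode <- match.arg(mode)
  nSurrogates <- assertCount(nSurrogates, "nSurrogates", 100)
  alpha <- assertNumber(alpha, "alpha", 1e-12, 1 - 1e-12)
  a <- raster@activity
  n <- nrow(a)
  if (ncol(a) < 2L) stop("raster must have at least 2 frames")
  co <- coactivationMatrix(raster)
  s <- switch(mode,
    shared_shift = surrogateCoactivations(a, nSurrogates, seed),
    per_pair = surrogateCoactivationsPerPair(a, nSurrogates, seed))
  k <- ceiling((1 - alpha) * nSurrogates)
  tlow <- rowOrderStat(s, k)
  thr <- matrix(0, n, n)
  thr[lower.tri(thr)] <- tlow
  thr <- thr + t(thr)
  diag(thr) <- diag(co)  # self-pairs are never tested
  adj <- co > thr
  diag(adj) <- FALSE
  methods::new("FunctionalNetwork",
    coactivation = co, threshold = thr, adjacency = adj,
    nSurrogates = nSurrogates, alpha = alpha, seed = as.integer(seed),
    mode = mode, neuronIds = raster@neuronIds,
    surrogates = if (keepSurrogates) s else NULL)
}

#' Filter a raster by its functional connectivity
#'
#' Two-step cleanup of non-significant activity: (1) within each frame,
#' the activity of active neurons with no functional connection to any
#' other neuron active in that same frame is removed; (2) frames left with
#' fewer than \code{minCoactive} active neurons are emptied entirely.
#' Frames are zeroed rather than deleted, so frame indices stay valid for
#' ensemble activity vectors and stimulus epochs; the retained-frame mask
#' carries the "removed" semantics.
#'
#' @param raster the \linkS4class{BinaryRaster} the network was built from.
#' @param net a \linkS4class{FunctionalNetwork}.
#' @param minCoactive minimum coactive neurons for a frame to survive
#'   (default 3).
#' @return list with \code{raster} (filtered \linkS4class{BinaryRaster})
#'   and \code{retained} (logical mask over frames).
#' @export
filterRaster <- function(raster, net, minCoactive = 3) {
  stopifnot(methods::is(raster, "BinaryRaster"),
            methods::is(net, "FunctionalNetwork"))
  minCoactive <- assertCount(minCoactive, "minCoactive", 1)
  a <- raster@activity
  if (nrow(a) != nrow(net@adjacency))
    stop("network was built from a raster with a different neuron count")
  adj <- net@adjacency
  storage.mode(adj) <- "double"
  ad <- a
  storage.mode(ad) <- "double"
  connectedActive <- adj %*% ad      # active connected partners per frame
  filtered <- a * (connectedActive > 0)
  retained <- colSums(filtered) >= minCoactive
  filtered[, !retained] <- 0L
  storage.mode(filtered) <- "integer"
  list(raster = BinaryRaster(filtered, neuronIds = raster@neuronIds,
                             framePeriod = raster@framePeriod,
                             sessionLabel = raster@sessionLabel),
       retained = retained)
}

#' Export a functional network as an edge list
#'
#' @param net a \linkS4class{FunctionalNetwork}.
#' @param path optional TSV path; when supplied, the edge list is written
#'   there together with a JSON sidecar of the null parameters.
#' @return data.frame with columns \code{idA}, \code{idB}, \code{co},
#'   \code{threshold}.
#' @export
edgeList <- function(net, path = NULL) {
  stopifnot(methods::is(net, "FunctionalNetwork"))
  idx <- which(net@adjacency & lower.tri(net@adjacency), arr.ind = TRUE)
  df <- data.frame(idA = net@neuronIds[idx[, 2L]],
                   idB = net@neuronIds[idx[, 1L]],
                   co = net@coactivation[idx],
                   threshold = net@threshold[idx])
  df <- df[order(df$idA, df$idB), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    meta <- list(alpha = net@alpha, nSurrogates = net@nSurrogates,
                 seed = net@seed, mode = net@mode)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  df
}
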