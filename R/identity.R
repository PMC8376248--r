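# Demixing neuron membership per ensemble with the
# correlation-weighted coactivation test.

#' Correlation of each neuron with an ensemble activity vector
#'
#' Pearson correlation between each neuron's binary activity row and the
#' ensemble activity vector \code{V_j}. Neurons with constant rows get a
#' correlation of 0 and are flagged through the \code{"constant"}
#' attribute.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param v binary ensemble activity vector of length \code{nFrames}
#'   (see \code{\link{activityVector}}); must not be constant.
#' @return numeric vector of per-neuron correlations in [-1, 1].
#' @export
ensembleCorrelation <- function(raster, v) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  if (length(v) != nFrames(raster))
    stop("v must have one entry per frame")
  sv <- stats::sd(v)
  if (sv == 0)
    stop("ensemble activity vector is constant; correlation undefined")
  a <- raster@activity
  constant <- apply(a, 1L, function(r) min(r) == max(r))
  p <- rep(0, nrow(a))
  if (any(!constant))
    p[!constant] <- as.numeric(stats::cor(t(a[!constant, , drop = FALSE]),
                                          v))
  attr(p, "constant") <- constant
  p
}

#' Ensemble weight matrix W = P_a * P_b * Co_ab
#'
#' Combines each pair's coactivation count with both neurons' correlation
#' to the ensemble activity vector; symmetric, with \code{|W| <= Co}.
#'
#' @param p per-neuron ensemble correlations.
#' @param co coactivation matrix (same neuron order).
#' @return numeric matrix.
#' @examples
#' ensembleWeights(c(0.5, 0.4), matrix(c(2, 10, 10, 3), 2))[1, 2]  # 2
#' @export
ensembleWeights <- function(p, co) {
  if (length(p) != nrow(co) || nrow(co) != ncol(co))
    stop("p must have one entry per row/column of co")
  outer(as.numeric(p), as.numeric(p)) * co
}

#' Demix neuron membership per ensemble
#'
#' For each ensemble j and candidate neuron pair (a, b), the observed
#' weight \code{W = P_j,a * P_j,b * Co_ab} is compared with surrogate
#' weights \code{SW_i = P'_a,i * P'_b,i * S_ab,i}, where \code{S_ab,i} is
#' the circular-shift surrogate coactivation count and the \code{P'} are
#' drawn with replacement from the ensemble's empirical correlation
#' distribution. The pair is significant iff \code{W} strictly exceeds the
#' \code{ceiling((1 - alpha) * nSurrogates)}-th order statistic of its
#' surrogate weights. A neuron belongs to the ensemble iff it has at least
#' one significant within-ensemble pair (and, by default, a positive
#' correlation with the ensemble, since participation implies positive
#' engagement).
#'
#' Candidate neurons are those active in at least one of the ensemble's
#' frames; all other neurons have no within-scope coactivity to test.
#'
#' @param raster the session \linkS4class{BinaryRaster}.
#' @param ens an \linkS4class{EnsembleSet} derived from it.
#' @param nSurrogates,alpha,seed surrogate-null parameters.
#' @param surrogates optional precomputed surrogate coactivation matrix
#'   (from \code{\link{significantConnections}} with
#'   \code{keepSurrogates = TRUE}); recomputed when missing. The surrogate
#'   coactivations do not depend on the ensemble, so one set serves all.
#' @param requirePositive additionally require \code{P_j,a > 0} for
#'   membership (default TRUE; switchable).
#' @return A \linkS4class{MembershipTable}.
#' @export
demixMembership <- function(raster, ens, nSurrogates = 1000, alpha = 0.05,
                            seed = 1L, surrogates = NULL,
                            requirePositive = TRUE) {
  stopifnot(methods::is(raster, "BinaryRaster"),
            methods::is(ens, "EnsembleSet"))
  if (!identical(raster@neuronIds, ens@neuronIds))
    stop("ens was not derived from this raster (neuronIds differ)")
  nSurrogates <- assertCount(nSurrogates, "nSurrogates", 100)
  alpha <- assertNumber(alpha, "alpha", 1e-12, 1 - 1e-12)
  requirePositive <- assertFlag(requirePositive, "requirePositive")
  n <- nNeurons(raster)
  k <- nEnsembles(ens)
  co <- coactivationMatrix(raster)
  if (is.null(surrogates))
    surrogates <- surrogateCoactivations(raster@activity, nSurrogates,
                                         subSeed(seed, 7))
  if (ncol(surrogates) != nSurrogates)
    stop("surrogates has ", ncol(surrogates), " iterations, expected ",
         nSurrogates)
  # lower-triangle pair bookkeeping matching surrogateCoactivations
  pairIdx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  kth <- ceiling((1 - alpha) * nSurrogates)

  membership <- matrix(FALSE, k, n)
  correlations <- matrix(NA_real_, k, n)
  maxW <- matrix(NA_real_, k, n)
  for (j in seq_len(k)) {
    frames <- ensembleFrames(ens, j)
    v <- activityVector(ens, j)
    if (sum(v) == 0L || sum(v) == length(v)) next
    p <- ensembleCorrelation(raster, v)
    correlations[j, ] <- p
    candRows <- which(rowSums(
      raster@activity[, frames, drop = FALSE]) > 0L)
    if (length(candRows) < 2L) {
      warning("ensemble ", j, " has fewer than 2 candidate neurons; ",
              "membership left empty")
      next
    }
    inCand <- pairIdx[, 1L] %in% candRows & pairIdx[, 2L] %in% candRows
    rows <- which(inCand)
    if (!length(rows)) next
    aIdx <- pairIdx[rows, 1L]
    bIdx <- pairIdx[rows, 2L]
    w <- p[aIdx] * p[bIdx] * co[cbind(aIdx, bIdx)]
    # surrogate weights: fresh correlation draws per neuron and iteration
    pPrime <- withSeed(subSeed(seed, 13 + j), matrix(
      sample(p, n * nSurrogates, replace = TRUE), n, nSurrogates))
    sw <- pPrime[aIdx, , drop = FALSE] * pPrime[bIdx, , drop = FALSE] *
      surrogates[rows, , drop = FALSE]
    tw <- rowOrderStat(sw, kth)
    sig <- w > tw
    if (any(sig)) {
      sigNeurons <- unique(c(aIdx[sig], bIdx[sig]))
      if (requirePositive) sigNeurons <- sigNeurons[p[sigNeurons] > 0]
      membership[j, sigNeurons] <- TRUE
      for (a in sigNeurons) {
        wa <- w[sig & (aIdx == a | bIdx == a)]
        if (length(wa)) maxW[j, a] <- max(wa)
      }
    }
  }
  counts <- colSums(membership)
  cls <- ifelse(counts == 0L, "none", ifelse(counts == 1L, "single",
                                             "shared"))
  methods::new("MembershipTable", membership = membership,
               correlations = correlations, maxWeight = maxW,
               participationClass = unname(cls),
               neuronIds = raster@neuronIds)
}

#' Classify per-neuron ensemble participation
#'
#' Row sums of the membership matrix per neuron: 0 ensembles = "none",
#' exactly 1 = "single", 2 or more = "shared".
#'
#' @param membership logical matrix, ensembles in rows, neurons in
#'   columns, or a \linkS4class{MembershipTable}.
#' @return list with \code{class} (per-neuron factor-like character) and
#'   \code{fractions} (named numeric: single, shared, none).
#' @examples
#' classifyParticipation(rbind(c(TRUE, TRUE, FALSE),
#'                             c(FALSE, TRUE, FALSE)))$class
#' @export
classifyParticipation <- function(membership) {
  if (methods::is(membership, "MembershipTable"))
    membership <- membership@membership
  if (!is.matrix(membership)) stop("membership must be a matrix")
  counts <- colSums(membership != 0)
  cls <- ifelse(counts == 0L, "none", ifelse(counts == 1L, "single",
                                             "shared"))
  fractions <- c(single = mean(cls == "single"),
                 shared = mean(cls == "shared"),
                 none = mean(cls == "none"))
  list(class = unname(cls), fractions = fractions)
}
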