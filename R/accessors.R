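# Generics, accessors and show methods.

#' @rdname BinaryRaster-class
#' @param object,x a \linkS4class{BinaryRaster}.
#' @export
setGeneric("activityMatrix", function(object) standardGeneric("activityMatrix"))

#' @rdname BinaryRaster-class
#' @export
setMethod("activityMatrix", "BinaryRaster", function(object) object@activity)

#' @rdname BinaryRaster-class
#' @export
setGeneric("neuronIds", function(object) standardGeneric("neuronIds"))

#' @rdname BinaryRaster-class
#' @export
setMethod("neuronIds", "BinaryRaster", function(object) object@neuronIds)

setMethod("neuronIds", "FunctionalNetwork", function(object) object@neuronIds)
setMethod("neuronIds", "EnsembleSet", function(object) object@neuronIds)
setMethod("neuronIds", "MembershipTable", function(object) object@neuronIds)

#' @rdname BinaryRaster-class
#' @export
setGeneric("framePeriod", function(object) standardGeneric("framePeriod"))

#' @rdname BinaryRaster-class
#' @export
setMethod("framePeriod", "BinaryRaster", function(object) object@framePeriod)

#' @rdname BinaryRaster-class
#' @export
setGeneric("sessionLabel", function(object) standardGeneric("sessionLabel"))

#' @rdname BinaryRaster-class
#' @export
setMethod("sessionLabel", "BinaryRaster", function(object) object@sessionLabel)

#' @rdname BinaryRaster-class
#' @export
setGeneric("nNeurons", function(object) standardGeneric("nNeurons"))

#' @rdname BinaryRaster-class
#' @export
setMethod("nNeurons", "BinaryRaster", function(object) nrow(object@activity))

#' @rdname BinaryRaster-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname BinaryRaster-class
#' @export
setMethod("nFrames", "BinaryRaster", function(object) ncol(object@activity))

setMethod("nFrames", "EnsembleSet", function(object) object@nFrames)

#' Subset a BinaryRaster by neurons (i) and/or frames (j)
#'
#' @param i neuron (row) index, logical or positional.
#' @param j frame (column) index.
#' @param ... ignored.
#' @param drop ignored; the result is always a BinaryRaster.
#' @return A \linkS4class{BinaryRaster}.
#' @rdname BinaryRaster-class
#' @export
setMethod("[", "BinaryRaster", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@activity))
  if (missing(j)) j <- seq_len(ncol(x@activity))
  BinaryRaster(x@activity[i, j, drop = FALSE],
               neuronIds = x@neuronIds[i],
               framePeriod = x@framePeriod,
               sessionLabel = x@sessionLabel)
})

setMethod("show", "BinaryRaster", function(object) {
  a <- object@activity
  cat(sprintf("BinaryRaster: %d neurons x %d frames (%.0f ms/frame, %.1f s)\n",
              nrow(a), ncol(a), object@framePeriod * 1000,
              ncol(a) * object@framePeriod))
  if (nzchar(object@sessionLabel))
    cat("  session:", object@sessionLabel, "\n")
  cat(sprintf("  mean active-frame fraction: %.3f\n", mean(a)))
})

#' @rdname FunctionalNetwork-class
#' @param object a \linkS4class{FunctionalNetwork}.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname FunctionalNetwork-class
#' @export
setMethod("adjacency", "FunctionalNetwork", function(object) object@adjacency)

#' @rdname FunctionalNetwork-class
#' @export
setGeneric("coactivation", function(object) standardGeneric("coactivation"))

#' @rdname FunctionalNetwork-class
#' @export
setMethod("coactivation", "FunctionalNetwork",
          function(object) object@coactivation)

#' Number of significant functional connections
#' @rdname FunctionalNetwork-class
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @rdname FunctionalNetwork-class
#' @export
setMethod("nEdges", "FunctionalNetwork",
          function(object) sum(object@adjacency) / 2L)

setMethod("show", "FunctionalNetwork", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf("FunctionalNetwork: %d neurons, %d significant connections\n",
              n, nEdges(object)))
  cat(sprintf("  null: %d circular-shift surrogates, alpha = %g, mode = %s\n",
              object@nSurrogates, object@alpha, object@mode))
})

#' @rdname EnsembleSet-class
#' @param object an \linkS4class{EnsembleSet}.
#' @export
setGeneric("nEnsembles", function(object) standardGeneric("nEnsembles"))

#' @rdname EnsembleSet-class
#' @export
setMethod("nEnsembles", "EnsembleSet", function(object) length(object@members))

#' Member neurons of one ensemble (or all, as a list)
#' @rdname EnsembleSet-class
#' @param j ensemble index; when missing, a list over all ensembles.
#' @export
ensembleMembers <- function(object, j) {
  stopifnot(methods::is(object, "EnsembleSet"))
  if (missing(j)) object@members else object@members[[j]]
}

#' Active frames of one ensemble (or all, as a list)
#' @rdname EnsembleSet-class
#' @export
ensembleFrames <- function(object, j) {
  stopifnot(methods::is(object, "EnsembleSet"))
  if (missing(j)) object@frames else object@frames[[j]]
}

#' Binary ensemble activity vector V_j (length F)
#'
#' 1 in the frames where ensemble \code{j} was active, 0 elsewhere.
#' @param object an \linkS4class{EnsembleSet}.
#' @param j ensemble index.
#' @return integer vector of length \code{nFrames(object)}.
#' @export
activityVector <- function(object, j) {
  stopifnot(methods::is(object, "EnsembleSet"))
  v <- integer(object@nFrames)
  v[object@frames[[j]]] <- 1L
  v
}

#' Ensemble raster E_j (N x F_j)
#'
#' The columns of the session raster at the ensemble's active frames.
#' @param object an \linkS4class{EnsembleSet}.
#' @param raster the \linkS4class{BinaryRaster} the set was detected from.
#' @param j ensemble index.
#' @return integer matrix, neurons by ensemble-active frames.
#' @export
ensembleRaster <- function(object, raster, j) {
  stopifnot(methods::is(object, "EnsembleSet"),
            methods::is(raster, "BinaryRaster"))
  if (!identical(object@neuronIds, raster@neuronIds))
    stop("raster neuronIds do not match the EnsembleSet registry")
  raster@activity[, object@frames[[j]], drop = FALSE]
}

setMethod("show", "EnsembleSet", function(object) {
  k <- length(object@members)
  cat(sprintf("EnsembleSet: %d ensemble%s over %d neurons, %d frames\n",
              k, if (k == 1L) "" else "s", length(object@neuronIds),
              object@nFrames))
  for (j in seq_len(k))
    cat(sprintf("  ensemble %d: %d members, %d active frames\n", j,
                length(object@members[[j]]), length(object@frames[[j]])))
})

#' @rdname MembershipTable-class
#' @param object a \linkS4class{MembershipTable}.
#' @export
setGeneric("membershipMatrix",
           function(object) standardGeneric("membershipMatrix"))

#' @rdname MembershipTable-class
#' @export
setMethod("membershipMatrix", "MembershipTable",
          function(object) object@membership)

#' @rdname MembershipTable-class
#' @export
setGeneric("participationClass",
           function(object) standardGeneric("participationClass"))

#' @rdname MembershipTable-class
#' @export
setMethod("participationClass", "MembershipTable",
          function(object) object@participationClass)

setMethod("show", "MembershipTable", function(object) {
  tab <- table(factor(object@participationClass,
                      levels = c("single", "shared", "none")))
  cat(sprintf("MembershipTable: %d ensembles x %d neurons\n",
              nrow(object@membership), ncol(object@membership)))
  cat(sprintf("  single %d | shared %d | not participant %d\n",
              tab[["single"]], tab[["shared"]], tab[["none"]]))
})

#' Number of stable / transient first-session ensembles
#'
#' @param object a \linkS4class{StabilityReport}.
#' @param pair which session comparison (day 1 vs. later session), default 1.
#' @return integer count.
#' @export
setGeneric("nStable", function(object, pair = 1L) standardGeneric("nStable"))

#' @rdname nStable
#' @export
setMethod("nStable", "StabilityReport",
          function(object, pair = 1L) object@comparisons[[pair]]$nStable)

#' @rdname nStable
#' @export
setGeneric("nTransient",
           function(object, pair = 1L) standardGeneric("nTransient"))

#' @rdname nStable
#' @export
setMethod("nTransient", "StabilityReport",
          function(object, pair = 1L) object@comparisons[[pair]]$nTransient)

#' Ensemble match table of one session comparison
#' @rdname nStable
#' @export
setGeneric("ensembleMatches",
           function(object, pair = 1L) standardGeneric("ensembleMatches"))

#' @rdname nStable
#' @export
setMethod("ensembleMatches", "StabilityReport",
          function(object, pair = 1L) object@comparisons[[pair]]$matches)

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d session comparison%s\n",
              length(object@comparisons),
              if (length(object@comparisons) == 1L) "" else "s"))
  for (cmp in object@comparisons) {
    cat(sprintf("  sessions %d vs %d: %d stable, %d transient (threshold %.3f)\n",
                cmp$sessionPair[1L], cmp$sessionPair[2L],
                cmp$nStable, cmp$nTransient,
                object@config$matchThreshold))
    if (!is.null(cmp$shuffle))
      cat(sprintf("    shuffle control: %d stable\n", cmp$shuffle$nStable))
  }
})

setMethod("show", "GroundTruth", function(object) {
  ns <- length(object@members)
  cat(sprintf("GroundTruth: %d session%s, %d ensemble slot%s (%d stable)\n",
              ns, if (ns == 1L) "" else "s", length(object@stableFlags),
              if (length(object@stableFlags) == 1L) "" else "s",
              sum(object@stableFlags)))
})
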