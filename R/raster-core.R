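# Raster I/O, trace quality control (PSNR) and cross-session ROI matching.

#' Write / read a BinaryRaster as delimited text
#'
#' The TSV layout has neurons as rows and frames as columns: two comment
#' lines carry the frame period and session label, a header row names the
#' columns (\code{neuron_id} followed by \code{f1..fF}), and each data row
#' is a neuron ID followed by its 0/1 activity. \code{readRaster} is the
#' exact inverse of \code{writeRaster}: the round trip preserves the
#' activity matrix, neuron IDs and frame period bit-exactly.
#'
#' @param raster a \linkS4class{BinaryRaster}.
#' @param path file path.
#' @param format only \code{"tsv"} is supported.
#' @return \code{readRaster} returns a \linkS4class{BinaryRaster};
#'   \code{writeRaster} returns \code{invisible(path)}.
#' @export
writeRaster <- function(raster, path, format = c("tsv")) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# frame_period_s: %.17g", raster@framePeriod),
    sprintf("# session_label: %s", raster@sessionLabel),
    paste(c("neuron_id", paste0("f", seq_len(ncol(raster@activity)))),
          collapse = "\t")
  ), con)
  utils::write.table(cbind(raster@neuronIds, raster@activity), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeRaster
#' @export
readRaster <- function(path, format = c("tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L)
    stop("format error: empty raster file ", path)
  meta <- grep("^#", lines, value = TRUE)
  fp <- sub("^# frame_period_s:\\s*", "", grep("^# frame_period_s:", meta,
                                               value = TRUE))
  lab <- sub("^# session_label:\\s*", "", grep("^# session_label:", meta,
                                               value = TRUE))
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L)
    stop("format error: no data rows in ", path)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  nCols <- length(header)
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  ids <- integer(length(rows))
  act <- matrix(0L, length(rows), nCols - 1L)
  for (r in seq_along(rows)) {
    vals <- rows[[r]]
    if (length(vals) != nCols)
      stop(sprintf("format error: row %d has %d fields, expected %d",
                   r, length(vals), nCols))
    ids[r] <- as.integer(vals[1L])
    v <- suppressWarnings(as.integer(vals[-1L]))
    bad <- which(is.na(v) | (v != 0L & v != 1L))
    if (length(bad))
      stop(sprintf(
        "format error: non-binary value '%s' at neuron row %d, frame %d",
        vals[-1L][bad[1L]], r, bad[1L]))
    act[r, ] <- v
  }
  BinaryRaster(act, neuronIds = ids,
               framePeriod = if (length(fp)) as.double(fp[1L]) else 0.081,
               sessionLabel = if (length(lab)) lab[1L] else "")
}

#' Peak signal-to-noise ratio of a fluorescence trace
#'
#' \deqn{PSNR = 20 \log_{10}\left(\frac{\max(F_{raw} - F_n)}{\sigma_n}\right)}
#' where \eqn{F_{raw}} is the ROI fluorescence, \eqn{F_n} the local
#' neuropil fluorescence, and \eqn{\sigma_n} the neuropil standard
#' deviation. Traces with a PSNR above 18 dB are conventionally kept.
#'
#' @param traceRaw,traceNeuropil numeric vectors of equal length (>= 2).
#' @return PSNR in decibels. If the neuropil-corrected trace never rises
#'   above zero the result is \code{-Inf} with attribute
#'   \code{flagged = TRUE}.
#' @examples
#' computePSNR(c(0, 10, 0), c(0, 0, 0) + rnorm(3, 0, 1e-6) + c(1, -1, 0))
#' @export
computePSNR <- function(traceRaw, traceNeuropil) {
  if (length(traceRaw) != length(traceNeuropil))
    stop("traceRaw and traceNeuropil must have equal length")
  if (length(traceRaw) < 2L)
    stop("traces must have at least 2 samples")
  sigma <- stats::sd(traceNeuropil)
  if (!is.finite(sigma) || sigma == 0)
    stop("neuropil standard deviation is zero; PSNR undefined")
  peak <- max(traceRaw - traceNeuropil)
  if (peak <= 0) {
    out <- -Inf
    attr(out, "flagged") <- TRUE
    return(out)
  }
  20 * log10(peak / sigma)
}

#' Filter raster rows by PSNR quality
#'
#' Keeps neurons whose trace PSNR is strictly greater than the threshold
#' (18 dB by default; the boundary value is excluded), preserving row
#' order.
#'
#' @param psnr numeric vector of per-neuron PSNR values (dB), aligned with
#'   the raster rows.
#' @param raster a \linkS4class{BinaryRaster}.
#' @param thresholdDb keep threshold in dB.
#' @return The filtered \linkS4class{BinaryRaster}.
#' @export
filterByPSNR <- function(psnr, raster, thresholdDb = 18) {
  stopifnot(methods::is(raster, "BinaryRaster"))
  if (length(psnr) != nNeurons(raster))
    stop("psnr must have one value per raster row")
  keep <- psnr > thresholdDb
  if (!any(keep))
    stop(sprintf("no neurons pass PSNR > %g dB (0 of %d kept)",
                 thresholdDb, length(psnr)))
  raster[keep, ]
}

maskIntersection <- function(a, b) sum(a & b)

#' Match ROIs between two sessions
#'
#' With masks, pair (i, j) is accepted iff the mask intersection exceeds
#' \code{0.5 * pi * radiusPx^2} pixels and the centroid Euclidean distance
#' is strictly below \code{radiusPx}; matching is greedy one-to-one by
#' descending intersection (ties broken by smaller distance). With
#' centroids only, the distance criterion alone applies and matching is
#' greedy by ascending distance.
#'
#' @param a,b \linkS4class{RoiSet}s pre-aligned to one coordinate frame.
#' @param radiusPx matching radius in pixels (the reference protocol fixes
#'   the ROI radius at 4 microns; convert with the acquisition's
#'   microns-per-pixel factor).
#' @return data.frame with columns \code{idA}, \code{idB},
#'   \code{intersectionPx} (NA in centroid mode) and \code{distancePx}.
#' @export
matchRois <- function(a, b, radiusPx) {
  stopifnot(methods::is(a, "RoiSet"), methods::is(b, "RoiSet"))
  if (radiusPx <= 0) stop("radiusPx must be positive")
  useMasks <- length(a@masks) > 0L || length(b@masks) > 0L
  if (useMasks && (length(a@masks) == 0L || length(b@masks) == 0L))
    stop("mixed mask/centroid inputs: both RoiSets must carry masks, ",
         "or neither")
  na <- length(a@ids)
  nb <- length(b@ids)
  cand <- NULL
  if (useMasks) {
    minInter <- 0.5 * pi * radiusPx^2
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      inter <- maskIntersection(a@masks[[i]], b@masks[[j]])
      if (inter <= minInter) next
      d <- sqrt(sum((a@centroids[i, ] - b@centroids[j, ])^2))
      if (d < radiusPx)
        cand <- rbind(cand, c(i, j, inter, d))
    }
    if (!is.null(cand))
      cand <- cand[order(-cand[, 3L], cand[, 4L]), , drop = FALSE]
  } else {
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      d <- sqrt(sum((a@centroids[i, ] - b@centroids[j, ])^2))
      if (d < radiusPx)
        cand <- rbind(cand, c(i, j, NA_real_, d))
    }
    if (!is.null(cand))
      cand <- cand[order(cand[, 4L]), , drop = FALSE]
  }
  out <- data.frame(idA = integer(0), idB = integer(0),
                    intersectionPx = numeric(0), distancePx = numeric(0))
  if (is.null(cand)) return(out)
  takenA <- logical(na)
  takenB <- logical(nb)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (takenA[i] || takenB[j]) next
    takenA[i] <- TRUE
    takenB[j] <- TRUE
    out <- rbind(out, data.frame(idA = a@ids[i], idB = b@ids[j],
                                 intersectionPx = cand[r, 3L],
                                 distancePx = cand[r, 4L]))
  }
  out[order(out$idA), , drop = FALSE]
}

#' Restrict two rasters to their common (matched) neurons
#'
#' Returns both rasters with rows limited to the matched neuron pairs, in
#' the same pairwise order, so that row k of each output refers to the same
#' cell. When \code{pairs} is omitted, neurons are matched by shared
#' \code{neuronIds} (the convention of the synthetic generator's global
#' registry).
#'
#' @param rasterA,rasterB \linkS4class{BinaryRaster}s.
#' @param pairs optional data.frame with columns \code{idA}, \code{idB}
#'   (e.g. from \code{\link{matchRois}}).
#' @return list of two aligned \linkS4class{BinaryRaster}s.
#' @export
commonRaster <- function(rasterA, rasterB, pairs = NULL) {
  stopifnot(methods::is(rasterA, "BinaryRaster"),
            methods::is(rasterB, "BinaryRaster"))
  if (is.null(pairs)) {
    ids <- intersect(rasterA@neuronIds, rasterB@neuronIds)
    pairs <- data.frame(idA = ids, idB = ids)
  }
  if (nrow(pairs) == 0L)
    stop("no common neurons between the two sessions")
  if (anyDuplicated(pairs$idA) || anyDuplicated(pairs$idB))
    stop("duplicate neuron IDs in pairs: matching must be one-to-one")
  ia <- match(pairs$idA, rasterA@neuronIds)
  ib <- match(pairs$idB, rasterB@neuronIds)
  if (anyNA(ia) || anyNA(ib))
    stop("pairs reference neuron IDs absent from the rasters")
  list(rasterA[ia, ], rasterB[ib, ])
}
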