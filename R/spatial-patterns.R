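# Spatial activity patterns: per-event activation maps inside the ROI,
# clustered into recurrent configurations.
#
# Processing chain per the study: 2 x 2 pixel binning; pixelwise percent
# dF/F against a centred 400-frame (20 s) rolling mean with the video-wide
# minimum subtracted; per-event maps as the average of the peak frame +-1
# normalized to the in-ROI maximum, Gaussian filtered (sigma = 1) and
# thresholded at 0.5; K-means over the patterns of all analyzed segments.

#' @describeIn bin2x2 each output pixel is the mean of its 2 x 2 block;
#'   odd trailing rows/columns are cropped with a warning.
#' @export
setMethod("bin2x2", "Movie", function(x, ...) {
  d <- x@data
  h <- dim(d)[2L]
  w <- dim(d)[3L]
  if (h %% 2L || w %% 2L) {
    warning("odd movie dimensions: trailing row/column cropped before binning",
      call. = FALSE)
    d <- d[, seq_len(h - h %% 2L), seq_len(w - w %% 2L), drop = FALSE]
    h <- h - h %% 2L
    w <- w - w %% 2L
  }
  ro <- seq(1L, h, by = 2L)
  co <- seq(1L, w, by = 2L)
  out <- (d[, ro, co, drop = FALSE] + d[, ro + 1L, co, drop = FALSE] +
    d[, ro, co + 1L, drop = FALSE] + d[, ro + 1L, co + 1L, drop = FALSE]) / 4
  Movie(out, x@frameRate, x@pixelSize * 2)
})

#' @describeIn bin2x2 a binned mask pixel is in-ROI when any pixel of its
#'   2 x 2 block is.
#' @export
setMethod("bin2x2", "ROIMask", function(x, ...) {
  m <- x@mask
  h <- nrow(m) - nrow(m) %% 2L
  w <- ncol(m) - ncol(m) %% 2L
  m <- m[seq_len(h), seq_len(w)]
  ro <- seq(1L, h, by = 2L)
  co <- seq(1L, w, by = 2L)
  ROIMask(m[ro, co] | m[ro + 1L, co] | m[ro, co + 1L] | m[ro + 1L, co + 1L])
})

#' Pixelwise percent dF/F normalization of a movie
#'
#' Per-pixel percent dF/F against a centred rolling mean of
#' \code{windowFrames} frames (edge frames use shrinking windows), then the
#' global minimum over the whole video is subtracted so every value is
#' >= 0 while pixel intensity relationships are preserved.
#'
#' @param movie a \linkS4class{Movie} (typically 2 x 2 binned).
#' @param windowFrames rolling-mean window length (default 400 frames,
#'   20 s at 20 Hz).
#' @return a \linkS4class{Movie} holding the normalized values.
#' @export
pixelwiseDff <- function(movie, windowFrames = 400L) {
  stopifnot(is(movie, "Movie"))
  nT <- nFrames(movie)
  .assert(nT >= windowFrames, sprintf(
    "movie has %d frames but the rolling-mean window needs %d", nT,
    windowFrames))
  m <- matrix(movie@data, nrow = nT)
  half <- (windowFrames - 1L) %/% 2L
  lo <- pmax(1L, seq_len(nT) - half)
  hi <- pmin(nT, seq_len(nT) + (windowFrames - 1L - half))
  cs <- rbind(0, apply(m, 2L, cumsum))
  rm_ <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  if (any(rm_ <= 0)) {
    stop("rolling-mean baseline <= 0 for some pixel: pixelwise dF/F ",
      "is undefined; check the input intensities", call. = FALSE)
  }
  dff <- (m - rm_) / rm_ * 100
  dff <- dff - min(dff)
  out <- array(dff, dim = dim(movie@data))
  Movie(out, movie@frameRate, movie@pixelSize)
}

#' Extract the spatial activation pattern at one event peak
#'
#' The map is the average of frames \code{peakFrame - 1 .. peakFrame + 1},
#' cropped to the ROI bounding box, divided by its in-ROI maximum,
#' optionally Gaussian filtered (sigma pixels; skippable per animal),
#' re-normalized to the in-ROI maximum and thresholded: values below
#' \code{threshold} (and all out-of-ROI pixels) are set to 0.
#'
#' @param normMovie a normalized \linkS4class{Movie}
#'   (see \code{\link{pixelwiseDff}}).
#' @param peakFrame 0-based peak frame; must have one frame on either side.
#' @param roi \linkS4class{ROIMask} on the same (binned) grid.
#' @param sigma Gaussian filter SD in pixels (default 1).
#' @param threshold keep only values >= this (default 0.5).
#' @param gaussian apply the Gaussian filter (default TRUE).
#' @param source identifier stored with the pattern.
#' @return a \linkS4class{SpatialPattern}; when the in-ROI maximum is 0 an
#'   all-zero map is returned with a warning.
#' @export
extractPattern <- function(normMovie, peakFrame, roi, sigma = 1,
                           threshold = 0.5, gaussian = TRUE,
                           source = as.character(peakFrame)) {
  stopifnot(is(normMovie, "Movie"), is(roi, "ROIMask"))
  nT <- nFrames(normMovie)
  p <- as.integer(peakFrame) + 1L            # 1-based
  .assert(p - 1L >= 1L && p + 1L <= nT,
    "peakFrame must have one frame on either side within the movie")
  .assert(all(dim(maskMatrix(roi)) == frameDims(normMovie)),
    "ROI mask shape does not match the movie frame")
  avg <- (normMovie@data[p - 1L, , ] + normMovie@data[p, , ] +
    normMovie@data[p + 1L, , ]) / 3
  mask <- maskMatrix(roi)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  avg <- avg[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  roiCrop <- mask[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]
  avg[!roiCrop] <- 0
  mx <- max(avg[roiCrop])
  if (mx <= 0) {
    warning("in-ROI maximum is 0 at this peak: returning an empty pattern",
      call. = FALSE)
    return(new("SpatialPattern", map = avg * 0, roi = roiCrop,
      source = source, peakFrame = as.integer(peakFrame)))
  }
  map <- avg / mx
  if (gaussian) {
    map <- .gaussianBlur2d(map, sigma)
    map[!roiCrop] <- 0
    mx2 <- max(map[roiCrop])
    if (mx2 > 0) map <- map / mx2
  }
  map[map < threshold] <- 0
  map[!roiCrop] <- 0
  map <- pmin(pmax(map, 0), 1)
  new("SpatialPattern", map = map, roi = roiCrop, source = source,
    peakFrame = as.integer(peakFrame))
}

# Row-major vectorization of the in-ROI pixels of a pattern.
.patternVector <- function(pattern) {
  as.vector(t(pattern@map))[as.vector(t(pattern@roi))]
}

#' Cluster spatial patterns with K-means
#'
#' Patterns (vectorized over in-ROI pixels, row-major) are clustered with
#' K-means using \code{nstart} restarts under a fixed seed. When \code{k}
#' is \code{NULL} it is chosen from \code{kRange} by maximum mean
#' silhouette score.
#'
#' @param patterns list of \linkS4class{SpatialPattern} on a common grid.
#' @param k number of clusters, or \code{NULL} to select from
#'   \code{kRange}.
#' @param kRange candidate k values for silhouette selection (default 2:8).
#' @param nstart K-means restarts (default 10).
#' @param seed RNG seed for reproducible clustering.
#' @return a \linkS4class{PatternClustering}.
#' @export
clusterPatterns <- function(patterns, k = NULL, kRange = 2:8, nstart = 10L,
                            seed = 1L) {
  .assert(length(patterns) >= 1L, "no patterns to cluster")
  dims <- vapply(patterns, function(p) dim(p@map), integer(2L))
  .assert(all(dims[1L, ] == dims[1L, 1L]) && all(dims[2L, ] == dims[2L, 1L]),
    "patterns must share a common grid")
  X <- do.call(rbind, lapply(patterns, .patternVector))
  nP <- nrow(X)
  if (is.null(k)) {
    kRange <- kRange[kRange >= 2L & kRange < nP]
    .assert(length(kRange) >= 1L,
      "too few patterns to select k from kRange")
    D <- stats::dist(X)
    sil <- vapply(kRange, function(kk) {
      km <- .withSeed(seed, stats::kmeans(X, centers = kk, nstart = nstart,
        iter.max = 100L))
      mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
    }, numeric(1L))
    k <- kRange[which.max(sil)]
  }
  k <- as.integer(k)
  .assert(k >= 1L && k <= nP, sprintf(
    "need at least k = %d patterns, have %d", k, nP))
  if (k == nP) {
    # degenerate partition: every pattern is its own cluster
    km <- list(cluster = seq_len(nP), centers = X, tot.withinss = 0)
  } else {
    km <- .withSeed(seed, stats::kmeans(X, centers = k, nstart = nstart,
      iter.max = 100L))
  }
  memberD <- sqrt(rowSums((X - km$centers[km$cluster, , drop = FALSE])^2))
  new("PatternClustering", k = k, labels = as.integer(km$cluster),
    centroids = unname(km$centers), inertia = km$tot.withinss,
    memberDistances = memberD, gridDim = dim(patterns[[1L]]@map),
    roi = patterns[[1L]]@roi)
}

#' Assign stimulus-evoked patterns to spontaneous-activity clusters
#'
#' Each stimulus pattern is assigned to the nearest centroid (Euclidean
#' distance over in-ROI pixels). The match flag is TRUE when the distance
#' does not exceed the 95th percentile of the member-to-own-centroid
#' distances within that cluster -- i.e. the stimulus pattern looks like
#' one of the animal's recurrent spontaneous configurations.
#'
#' @param stimPatterns list of \linkS4class{SpatialPattern} on the same
#'   grid as the clustering.
#' @param clustering a \linkS4class{PatternClustering}.
#' @return data.frame with \code{source}, \code{cluster}, \code{distance}
#'   and \code{match}.
#' @export
assignStimulusPatterns <- function(stimPatterns, clustering) {
  stopifnot(is(clustering, "PatternClustering"))
  .assert(length(stimPatterns) >= 1L, "no stimulus patterns to assign")
  X <- do.call(rbind, lapply(stimPatterns, .patternVector))
  .assert(ncol(X) == ncol(clustering@centroids),
    "stimulus patterns are not on the clustering's grid")
  res <- lapply(seq_len(nrow(X)), function(i) {
    d <- sqrt(colSums((t(clustering@centroids) - X[i, ])^2))
    j <- which.min(d)
    members <- clustering@memberDistances[clustering@labels == j]
    cut <- if (length(members)) {
      unname(stats::quantile(members, 0.95, type = 7L))
    } else 0
    data.frame(source = stimPatterns[[i]]@source, cluster = as.integer(j),
      distance = unname(d[j]), match = unname(d[j]) <= cut,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write spatial patterns as a multi-page TIFF plus a CSV manifest
#'
#' @param patterns list of \linkS4class{SpatialPattern}.
#' @param tiffPath output TIFF path (one page per pattern, values in
#'   [0, 1]).
#' @param manifestPath output CSV path (pattern id, source, peak frame,
#'   cluster label when available).
#' @param labels optional integer cluster labels, one per pattern.
#' @return \code{tiffPath}, invisibly.
#' @export
writePatterns <- function(patterns, tiffPath, manifestPath,
                          labels = NULL) {
  .assert(length(patterns) >= 1L, "no patterns to write")
  tiff::writeTIFF(lapply(patterns, function(p) p@map), tiffPath,
    bits.per.sample = 16L)
  man <- data.frame(pattern = seq_along(patterns),
    source = vapply(patterns, function(p) p@source, character(1L)),
    peak_frame = vapply(patterns, function(p) p@peakFrame, integer(1L)),
    cluster = if (is.null(labels)) NA_integer_ else as.integer(labels))
  utils::write.csv(man, manifestPath, row.names = FALSE)
  invisible(tiffPath)
}
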