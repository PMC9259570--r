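#' @import methods
NULL

#' Movie: a T x H x W fluorescence image stack
#'
#' Container for a raw (or normalized) grayscale recording. Frames are stored
#' along the first array dimension in acquisition order; intensities are on
#' the 16-bit camera scale (0--65535) for raw movies.
#'
#' @slot data numeric array, dim \code{c(T, H, W)}, all values >= 0.
#' @slot frameRate acquisition frame rate in Hz.
#' @slot pixelSize pixel size in micrometres (may be \code{NA}).
#' @export
setClass("Movie",
  representation(data = "array", frameRate = "numeric", pixelSize = "numeric"),
  prototype(pixelSize = NA_real_)
)

setValidity("Movie", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a T x H x W array")
  if (dim(d)[1L] < 1L) return("movie must contain at least one frame (T >= 1)")
  if (anyNA(d) || any(d < 0)) return("movie intensities must be finite and >= 0")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0) {
    return("frameRate must be a single positive number")
  }
  TRUE
})

#' ROIMask: a binary region-of-interest mask
#'
#' @slot mask logical H x W matrix; TRUE marks in-ROI pixels.
#' @export
setClass("ROIMask", representation(mask = "matrix"))

setValidity("ROIMask", function(object) {
  m <- object@mask
  if (!is.logical(m) || length(dim(m)) != 2L) {
    return("mask must be a logical matrix")
  }
  if (!any(m)) return("ROI mask is empty: it must contain at least one TRUE pixel")
  TRUE
})

#' SegmentAnnotation: label and frame interval of an analyzed segment
#'
#' Frame indices are 0-based and the interval is half-open,
#' \code{[startFrame, endFrame)}; times in seconds are frame / frameRate.
#'
#' @slot label one of \code{"pre"}, \code{"ctx"}, \code{"pos"}, \code{"vds"},
#'   \code{"posvds"}, \code{"mec"}.
#' @slot startFrame,endFrame 0-based half-open frame interval.
#' @slot stimulusOnsets 0-based frame indices of stimulus onsets (vds: one
#'   per movement cycle; mec: the pulse onset; empty otherwise).
#' @slot stimulusDuration stimulus analysis-window duration in seconds
#'   (9 for vds, 1 for mec; \code{NA} otherwise).
#' @export
setClass("SegmentAnnotation",
  representation(label = "character", startFrame = "integer",
    endFrame = "integer", stimulusOnsets = "integer",
    stimulusDuration = "numeric"),
  prototype(stimulusOnsets = integer(0), stimulusDuration = NA_real_)
)

setValidity("SegmentAnnotation", function(object) {
  if (!(object@label %in% .segmentLabels)) {
    return(sprintf("label '%s' is not one of: %s", object@label,
      paste(.segmentLabels, collapse = ", ")))
  }
  if (object@startFrame < 0L || object@endFrame <= object@startFrame) {
    return("frame interval must satisfy 0 <= startFrame < endFrame")
  }
  if (length(object@stimulusOnsets) &&
      (any(object@stimulusOnsets < object@startFrame) ||
       any(object@stimulusOnsets >= object@endFrame))) {
    return("stimulusOnsets must lie inside [startFrame, endFrame)")
  }
  TRUE
})

#' FluorescenceTrace: per-frame mean ROI intensity for one segment
#'
#' @slot values per-frame mean in-ROI intensity (arbitrary units).
#' @slot frameRate frame rate in Hz.
#' @slot segment the \linkS4class{SegmentAnnotation} the trace covers.
#' @export
setClass("FluorescenceTrace",
  representation(values = "numeric", frameRate = "numeric",
    segment = "SegmentAnnotation")
)

setValidity("FluorescenceTrace", function(object) {
  if (anyNA(object@values) || any(!is.finite(object@values))) {
    return("trace values must be finite")
  }
  n <- object@segment@endFrame - object@segment@startFrame
  if (length(object@values) != n) {
    return(sprintf("trace length (%d) must equal segment length (%d frames)",
      length(object@values), n))
  }
  if (object@frameRate <= 0) return("frameRate must be positive")
  TRUE
})

#' DffTrace: relative fluorescence change (percent dF/F) for one segment
#'
#' @slot values percent dF/F per frame, \code{(F - F0)/F0 * 100}.
#' @slot f0 baseline fluorescence (same units as the raw trace), > 0.
#' @slot frameRate frame rate in Hz.
#' @slot filterBand band-pass corner frequencies (low, high) in Hz applied
#'   before the baseline was taken.
#' @slot segment the originating \linkS4class{SegmentAnnotation}.
#' @export
setClass("DffTrace",
  representation(values = "numeric", f0 = "numeric", frameRate = "numeric",
    filterBand = "numeric", segment = "SegmentAnnotation"),
  prototype(filterBand = c(0.025, 5))
)

setValidity("DffTrace", function(object) {
  if (anyNA(object@values) || any(!is.finite(object@values))) {
    return("percent dF/F values must be finite")
  }
  if (length(object@f0) != 1L || !is.finite(object@f0) || object@f0 <= 0) {
    return("f0 must be a single positive number")
  }
  if (length(object@filterBand) != 2L ||
      object@filterBand[1L] >= object@filterBand[2L]) {
    return("filterBand must be (low, high) with low < high")
  }
  TRUE
})

#' SpatialPattern: normalized activation map around one event peak
#'
#' The map covers the bounding box of the (binned) ROI; values are in
#' [0, 1], sub-threshold and out-of-ROI pixels are 0, and the in-ROI maximum
#' is 1 whenever any pixel survives thresholding.
#'
#' @slot map numeric matrix over the ROI bounding box.
#' @slot roi logical matrix, same shape as \code{map}: in-ROI pixels.
#' @slot source identifier of the originating event or stimulus trial.
#' @slot peakFrame 0-based peak frame the map was taken at.
#' @export
setClass("SpatialPattern",
  representation(map = "matrix", roi = "matrix", source = "character",
    peakFrame = "integer")
)

setValidity("SpatialPattern", function(object) {
  if (!all(dim(object@map) == dim(object@roi))) {
    return("map and roi must have the same dimensions")
  }
  v <- object@map
  if (anyNA(v) || any(v < 0) || any(v > 1)) {
    return("pattern values must lie in [0, 1]")
  }
  if (any(v[!object@roi] != 0)) return("out-of-ROI pixels must be 0")
  inroi <- v[object@roi]
  if (any(inroi > 0) && abs(max(inroi) - 1) > 1e-12) {
    return("in-ROI maximum must be 1 when any pixel survives thresholding")
  }
  TRUE
})

#' PatternClustering: K-means clustering of spatial patterns
#'
#' @slot k number of clusters.
#' @slot labels integer cluster id per pattern.
#' @slot centroids k x p matrix of cluster centres (row-major vectorized
#'   in-ROI pixels).
#' @slot inertia within-cluster sum of squared distances.
#' @slot memberDistances Euclidean distance of each pattern to its own
#'   centroid (used for the stimulus-assignment match criterion).
#' @slot gridDim dimensions of the pattern grid the vectors came from.
#' @slot roi logical matrix: the common in-ROI pixel set.
#' @export
setClass("PatternClustering",
  representation(k = "integer", labels = "integer", centroids = "matrix",
    inertia = "numeric", memberDistances = "numeric", gridDim = "integer",
    roi = "matrix")
)

setValidity("PatternClustering", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (length(object@labels) < object@k) {
    return("there must be at least k labeled patterns")
  }
  if (any(object@labels < 1L) || any(object@labels > object@k)) {
    return("labels must be in 1..k")
  }
  if (nrow(object@centroids) != object@k) return("centroids must have k rows")
  TRUE
})
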