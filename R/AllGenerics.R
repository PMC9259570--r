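# Generics, accessors, constructors and show() methods.

#' Number of frames
#' @param x a Movie, FluorescenceTrace or DffTrace
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame rate in Hz
#' @param x a Movie, FluorescenceTrace or DffTrace
#' @return frame rate (Hz)
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Per-frame values of a trace
#' @param x a FluorescenceTrace or DffTrace
#' @return numeric vector of per-frame values
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' Segment annotation attached to an object
#' @param x a FluorescenceTrace or DffTrace
#' @return the \linkS4class{SegmentAnnotation}
#' @export
setGeneric("segmentInfo", function(x) standardGeneric("segmentInfo"))

#' 2 x 2 spatial pixel binning
#' @param x a Movie or ROIMask
#' @param ... unused
#' @return an object of the same class with halved spatial dimensions
#' @export
setGeneric("bin2x2", function(x, ...) standardGeneric("bin2x2"))

#' @describeIn nFrames frames of a movie
#' @export
setMethod("nFrames", "Movie", function(x) dim(x@data)[1L])
#' @describeIn nFrames frames of a raw trace
#' @export
setMethod("nFrames", "FluorescenceTrace", function(x) length(x@values))
#' @describeIn nFrames frames of a percent dF/F trace
#' @export
setMethod("nFrames", "DffTrace", function(x) length(x@values))

#' @describeIn frameRate frame rate of a movie
#' @export
setMethod("frameRate", "Movie", function(x) x@frameRate)
#' @describeIn frameRate frame rate of a raw trace
#' @export
setMethod("frameRate", "FluorescenceTrace", function(x) x@frameRate)
#' @describeIn frameRate frame rate of a percent dF/F trace
#' @export
setMethod("frameRate", "DffTrace", function(x) x@frameRate)

#' @describeIn traceValues raw intensity values
#' @export
setMethod("traceValues", "FluorescenceTrace", function(x) x@values)
#' @describeIn traceValues percent dF/F values
#' @export
setMethod("traceValues", "DffTrace", function(x) x@values)

#' @describeIn segmentInfo annotation of a raw trace
#' @export
setMethod("segmentInfo", "FluorescenceTrace", function(x) x@segment)
#' @describeIn segmentInfo annotation of a percent dF/F trace
#' @export
setMethod("segmentInfo", "DffTrace", function(x) x@segment)

#' Pixel data of a movie
#' @param x a Movie
#' @return the T x H x W array
#' @export
movieData <- function(x) {
  stopifnot(is(x, "Movie"))
  x@data
}

#' Spatial dimensions (H, W) of a movie
#' @param x a Movie
#' @return integer vector c(H, W)
#' @export
frameDims <- function(x) {
  stopifnot(is(x, "Movie"))
  dim(x@data)[2:3]
}

#' Logical matrix of an ROI mask
#' @param x an ROIMask
#' @return logical H x W matrix
#' @export
maskMatrix <- function(x) {
  stopifnot(is(x, "ROIMask"))
  x@mask
}

#' Number of in-ROI pixels
#' @param x an ROIMask
#' @return integer pixel count
#' @export
roiArea <- function(x) {
  stopifnot(is(x, "ROIMask"))
  sum(x@mask)
}

#' Baseline fluorescence F0 of a percent dF/F trace
#' @param x a DffTrace
#' @return the baseline intensity (raw units)
#' @export
baselineF0 <- function(x) {
  stopifnot(is(x, "DffTrace"))
  x@f0
}

#' Activation map of a spatial pattern
#' @param x a SpatialPattern
#' @return numeric matrix over the ROI bounding box
#' @export
patternMap <- function(x) {
  stopifnot(is(x, "SpatialPattern"))
  x@map
}

#' Cluster labels of a pattern clustering
#' @param x a PatternClustering
#' @return integer vector of cluster ids
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "PatternClustering"))
  x@labels
}

#' Cluster centroids of a pattern clustering
#' @param x a PatternClustering
#' @return k x p matrix of centroids
#' @export
clusterCentroids <- function(x) {
  stopifnot(is(x, "PatternClustering"))
  x@centroids
}

#' Within-cluster sum of squares of a pattern clustering
#' @param x a PatternClustering
#' @return total within-cluster sum of squared distances
#' @export
clusterInertia <- function(x) {
  stopifnot(is(x, "PatternClustering"))
  x@inertia
}

#' Construct a Movie
#' @param data T x H x W numeric array of non-negative intensities
#' @param frameRate frame rate in Hz
#' @param pixelSize pixel size in micrometres (optional)
#' @return a \linkS4class{Movie}
#' @export
Movie <- function(data, frameRate, pixelSize = NA_real_) {
  new("Movie", data = data, frameRate = as.numeric(frameRate),
    pixelSize = as.numeric(pixelSize))
}

#' Construct an ROIMask
#' @param mask logical (or coercible) H x W matrix
#' @return an \linkS4class{ROIMask}
#' @export
ROIMask <- function(mask) {
  storage.mode(mask) <- "logical"
  new("ROIMask", mask = mask)
}

#' Construct a SegmentAnnotation
#' @param label segment label (pre, ctx, pos, vds, posvds, mec)
#' @param startFrame,endFrame 0-based half-open frame interval
#' @param stimulusOnsets 0-based stimulus onset frames (vds/mec)
#' @param stimulusDuration stimulus window duration in seconds
#' @return a \linkS4class{SegmentAnnotation}
#' @export
SegmentAnnotation <- function(label, startFrame, endFrame,
                              stimulusOnsets = integer(0),
                              stimulusDuration = NA_real_) {
  new("SegmentAnnotation", label = label,
    startFrame = as.integer(startFrame), endFrame = as.integer(endFrame),
    stimulusOnsets = as.integer(stimulusOnsets),
    stimulusDuration = as.numeric(stimulusDuration))
}

#' Construct a FluorescenceTrace
#' @param values per-frame mean ROI intensity
#' @param frameRate frame rate in Hz
#' @param segment a \linkS4class{SegmentAnnotation}; defaults to a full-length
#'   "pre" segment
#' @return a \linkS4class{FluorescenceTrace}
#' @export
FluorescenceTrace <- function(values, frameRate,
                              segment = SegmentAnnotation("pre", 0L,
                                length(values))) {
  new("FluorescenceTrace", values = as.numeric(values),
    frameRate = as.numeric(frameRate), segment = segment)
}

setMethod("show", "Movie", function(object) {
  d <- dim(object@data)
  cat(sprintf("Movie: %d frames of %d x %d px @ %g Hz (%.1f s)\n",
    d[1L], d[2L], d[3L], object@frameRate, d[1L] / object@frameRate))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
    min(object@data), max(object@data)))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask: %d x %d px, area %d px\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

setMethod("show", "SegmentAnnotation", function(object) {
  cat(sprintf("SegmentAnnotation '%s': frames [%d, %d)", object@label,
    object@startFrame, object@endFrame))
  if (length(object@stimulusOnsets)) {
    cat(sprintf(", %d stimulus onset(s), window %g s",
      length(object@stimulusOnsets), object@stimulusDuration))
  }
  cat("\n")
})

setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf("FluorescenceTrace '%s': %d frames @ %g Hz, mean %.1f\n",
    object@segment@label, length(object@values), object@frameRate,
    mean(object@values)))
})

setMethod("show", "DffTrace", function(object) {
  cat(sprintf(
    "DffTrace '%s': %d frames @ %g Hz, F0 = %.2f, band %g-%g Hz\n",
    object@segment@label, length(object@values), object@frameRate,
    object@f0, object@filterBand[1L], object@filterBand[2L]))
})

setMethod("show", "SpatialPattern", function(object) {
  cat(sprintf(
    "SpatialPattern '%s': %d x %d grid, peak frame %d, %d active px\n",
    object@source, nrow(object@map), ncol(object@map), object@peakFrame,
    sum(object@map > 0)))
})

setMethod("show", "PatternClustering", function(object) {
  cat(sprintf("PatternClustering: k = %d, %d patterns, inertia %.4g\n",
    object@k, length(object@labels), object@inertia))
  cat("  cluster sizes:", paste(tabulate(object@labels, object@k),
    collapse = ", "), "\n")
})
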