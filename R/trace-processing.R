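# Raw ROI trace -> band-pass filtered trace -> percent dF/F.

#' Extract the ROI-mean fluorescence trace from a movie
#'
#' \code{values[t]} is the arithmetic mean over in-ROI pixels of frame t,
#' restricted to the annotated segment.
#'
#' @param movie a \linkS4class{Movie}.
#' @param roi an \linkS4class{ROIMask} matching the movie frame.
#' @param segment a \linkS4class{SegmentAnnotation}; defaults to the full
#'   movie as a "pre" segment.
#' @return a \linkS4class{FluorescenceTrace}.
#' @export
extractRoiTrace <- function(movie, roi, segment = NULL) {
  stopifnot(is(movie, "Movie"), is(roi, "ROIMask"))
  .assert(all(dim(maskMatrix(roi)) == frameDims(movie)),
    "ROI mask shape does not match the movie frame")
  nT <- nFrames(movie)
  if (is.null(segment)) segment <- SegmentAnnotation("pre", 0L, nT)
  .assert(segment@endFrame <= nT,
    "segment interval extends beyond the movie")
  m <- matrix(movie@data, nrow = nT)
  sel <- as.vector(maskMatrix(roi))
  vals <- rowMeans(m[, sel, drop = FALSE])
  frames <- (segment@startFrame + 1L):segment@endFrame
  FluorescenceTrace(vals[frames], frameRate(movie), segment)
}

#' Zero-phase band-pass filter a fluorescence trace
#'
#' A 2nd-order Butterworth band-pass (default 0.025--5 Hz) applied
#' forward-backward (zero phase, so event onset and peak timing are
#' preserved), with reflective padding at the segment edges. Because the
#' high-pass corner removes the mean, the pre-filter segment mean is added
#' back afterwards so values stay on the raw intensity scale and the
#' percentile baseline remains meaningful (DC restoration).
#'
#' @param trace a \linkS4class{FluorescenceTrace} (or numeric vector with
#'   \code{frameRate} supplied).
#' @param lowHz,highHz band corners in Hz; require
#'   \code{0 < lowHz < highHz < frameRate/2}.
#' @param frameRate sampling rate, taken from the trace when omitted.
#' @param warnShort warn when the segment is shorter than three filter
#'   startup lengths (one startup length = one period of the low corner);
#'   reflective padding is applied either way.
#' @return the filtered trace, same class and units as the input.
#' @export
bandpassFilter <- function(trace, lowHz = 0.025, highHz = 5,
                           frameRate = NULL, warnShort = TRUE) {
  isTrace <- is(trace, "FluorescenceTrace")
  x <- if (isTrace) traceValues(trace) else as.numeric(trace)
  fs <- if (isTrace) methods::slot(trace, "frameRate") else frameRate
  .assert(!is.null(fs), "frameRate must be supplied for a bare numeric trace")
  .assert(lowHz > 0 && lowHz < highHz && highHz < fs / 2,
    "band corners must satisfy 0 < lowHz < highHz < frameRate / 2")
  n <- length(x)
  startup <- ceiling(fs / lowHz)
  if (warnShort && n < 3L * startup) {
    warning(sprintf(paste0(
      "segment of %d frames is shorter than 3 filter startup lengths ",
      "(%d frames); edge frames carry extra filter uncertainty"),
      n, 3L * startup), call. = FALSE)
  }
  mu <- mean(x)
  x0 <- x - mu                         # filter the zero-mean signal
  bf <- signal::butter(2L, c(lowHz, highHz) / (fs / 2), type = "pass")
  pad <- min(n - 1L, 3L * startup)
  xp <- c(rev(x0[2:(pad + 1L)]), x0, rev(x0[(n - pad):(n - 1L)]))
  y <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + n)]
  y <- y + mu                          # DC restoration
  if (isTrace) {
    FluorescenceTrace(y, fs, segmentInfo(trace))
  } else y
}

#' Compute the percent dF/F trace
#'
#' \code{F0} is the 8th percentile (linear interpolation between order
#' statistics) of the filtered trace over the whole segment, and
#' \code{values = (F - F0) / F0 * 100}. With this baseline at most 8\% of
#' frames fall below 0 percent dF/F, and the result is invariant under
#' multiplicative rescaling of the raw intensities.
#'
#' @param trace a band-pass filtered \linkS4class{FluorescenceTrace}.
#' @param percentile baseline percentile (default 8).
#' @param filterBand the (low, high) band recorded as provenance.
#' @return a \linkS4class{DffTrace}.
#' @export
computeDff <- function(trace, percentile = 8, filterBand = c(0.025, 5)) {
  stopifnot(is(trace, "FluorescenceTrace"))
  x <- traceValues(trace)
  f0 <- unname(stats::quantile(x, percentile / 100, type = 7L))
  if (!is.finite(f0) || f0 <= 0) {
    stop("baseline F0 <= 0: the filtered trace is not strictly positive; ",
      "inspect DC restoration of the band-pass filter", call. = FALSE)
  }
  new("DffTrace", values = (x - f0) / f0 * 100, f0 = f0,
    frameRate = frameRate(trace), filterBand = as.numeric(filterBand),
    segment = segmentInfo(trace))
}

#' Band-pass filter and normalize a raw trace in one call
#'
#' @param trace a raw \linkS4class{FluorescenceTrace}.
#' @param lowHz,highHz filter band corners (Hz).
#' @param percentile baseline percentile.
#' @param warnShort see \code{\link{bandpassFilter}}.
#' @return a \linkS4class{DffTrace}.
#' @export
processTrace <- function(trace, lowHz = 0.025, highHz = 5, percentile = 8,
                         warnShort = TRUE) {
  filtered <- bandpassFilter(trace, lowHz, highHz, warnShort = warnShort)
  computeDff(filtered, percentile, filterBand = c(lowHz, highHz))
}
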