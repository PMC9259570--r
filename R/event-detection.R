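# Rule-based calcium-event detection.
#
# Candidate transients show a quick rise followed by an exponential-like
# decay; a new event superimposed on a decay is split at the interior local
# minimum. From the candidates, events must (i) take at least 2 frames
# (100 ms at 20 Hz) from onset to peak, (ii) have a relative amplitude of
# at least 0.02 percent dF/F and at least 0.3 of the animal's pooled
# percent dF/F SD, with (iii) the peak taken as the first local maximum
# within 2 s of the onset.

#' Pooled percent dF/F standard deviation for one animal
#'
#' The population SD of the concatenation of all analyzed segments'
#' percent dF/F samples; it scales the per-animal amplitude threshold.
#'
#' @param dffTraces list of \linkS4class{DffTrace} (or numeric vectors) for
#'   one animal.
#' @return list with \code{sd_pct} and \code{n_samples}.
#' @export
pooledSd <- function(dffTraces) {
  .assert(length(dffTraces) >= 1L, "pooledSd needs at least one trace")
  vals <- unlist(lapply(dffTraces, function(x) {
    if (is(x, "DffTrace")) traceValues(x) else as.numeric(x)
  }), use.names = FALSE)
  .assert(length(vals) > 0L, "pooledSd needs non-empty traces")
  list(sd_pct = .popSd(vals), n_samples = length(vals))
}

#' Propose candidate event onsets
#'
#' Onsets are local minima that precede a contiguous rise, located on a
#' lightly smoothed copy of the trace (centred moving average of
#' \code{smoothWindow} frames, used for proposal only and never for
#' amplitude measurement) and refined to the raw-trace minimum within one
#' frame. Superimposed events are split naturally: the interior local
#' minimum between a decay and the next rise is itself a candidate onset.
#'
#' @param dffTrace a \linkS4class{DffTrace} or numeric percent dF/F vector.
#' @param smoothWindow odd moving-average window (frames) for proposal;
#'   1 disables smoothing.
#' @return integer vector of candidate onset frames (0-based).
#' @export
detectCandidates <- function(dffTrace, smoothWindow = 1L) {
  v <- if (is(dffTrace, "DffTrace")) traceValues(dffTrace) else
    as.numeric(dffTrace)
  n <- length(v)
  .assert(n >= 5L, "trace must be at least 5 frames long")
  s <- .rollMeanCentered(v, smoothWindow)
  # rise starts: s[i+1] > s[i] and not rising into i
  i <- seq_len(n - 1L)
  rising <- s[i + 1L] > s[i]
  prevNotRising <- c(TRUE, s[2:(n - 1L)] <= s[1:(n - 2L)])
  onsets <- which(rising & prevNotRising)
  if (!length(onsets)) return(integer(0))
  # refine each onset to the raw-trace minimum within +-1 frame; on ties
  # the latest frame wins (the frame where the rise actually starts)
  refined <- vapply(onsets, function(o) {
    cand <- intersect((o - 1L):(o + 1L), seq_len(n))
    mins <- which(v[cand] == min(v[cand]))
    cand[mins[length(mins)]]
  }, integer(1L))
  sort(unique(refined)) - 1L
}

#' Apply the printed event criteria and measure accepted events
#'
#' For every candidate onset the peak is the first local maximum (strictly
#' greater than both neighbours; plateaus take their first frame) within
#' \code{peakWindowS} seconds after onset, measured on the raw (unsmoothed)
#' percent dF/F trace. Candidates are kept when the rise takes at least
#' \code{minRiseFrames} frames and the relative amplitude
#' (\code{dff[peak] - dff[onset]}) reaches both \code{minAmpPct} and
#' \code{sdFactor * animalSd}. Candidates whose peak window crosses the
#' segment end are dropped with a warning.
#'
#' @param candidates 0-based candidate onset frames
#'   (from \code{\link{detectCandidates}}).
#' @param dffTrace the same trace the candidates came from.
#' @param animalSd the animal's pooled percent dF/F SD
#'   (see \code{\link{pooledSd}}).
#' @param frameRate frame rate in Hz (taken from the trace when omitted).
#' @param minAmpPct absolute amplitude threshold (percent dF/F).
#' @param sdFactor multiple of \code{animalSd} the amplitude must reach.
#' @param minRiseFrames minimum frames from onset to peak.
#' @param peakWindowS window after onset searched for the first peak (s).
#' @return data.frame of accepted events: onset_frame, peak_frame,
#'   onset_s, peak_s, amplitude_pct (0-based frames).
#' @export
filterAndMeasure <- function(candidates, dffTrace, animalSd,
                             frameRate = NULL, minAmpPct = 0.02,
                             sdFactor = 0.3, minRiseFrames = 2L,
                             peakWindowS = 2.0) {
  v <- if (is(dffTrace, "DffTrace")) traceValues(dffTrace) else
    as.numeric(dffTrace)
  if (is.null(frameRate)) {
    .assert(is(dffTrace, "DffTrace"),
      "frameRate must be supplied for a bare numeric trace")
    frameRate <- frameRate(dffTrace)
  }
  n <- length(v)
  W <- .framesFromSeconds(peakWindowS, frameRate)
  thr <- max(minAmpPct, sdFactor * animalSd)
  out <- data.frame(onset_frame = integer(0), peak_frame = integer(0),
    onset_s = numeric(0), peak_s = numeric(0), amplitude_pct = numeric(0))
  dropped <- 0L
  for (o0 in candidates) {
    o <- o0 + 1L                       # 1-based index
    if (o + W > n - 1L) {              # peak window crosses the segment end
      dropped <- dropped + 1L
      next
    }
    p <- .firstLocalMax(v, o, W)
    if (is.na(p)) next
    rise <- p - o
    amp <- v[p] - v[o]
    if (rise >= minRiseFrames && amp >= thr) {
      out <- rbind(out, data.frame(onset_frame = o - 1L, peak_frame = p - 1L,
        onset_s = (o - 1L) / frameRate, peak_s = (p - 1L) / frameRate,
        amplitude_pct = amp))
    }
  }
  if (dropped > 0L) {
    warning(sprintf(
      "%d candidate(s) dropped: peak window crosses the segment end",
      dropped), call. = FALSE)
  }
  if (nrow(out)) {
    # one event per peak: keep the earliest qualifying onset
    out <- out[!duplicated(out$peak_frame), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# First local maximum of v in (o, o + W] (1-based o): strictly greater than
# the previous value and not exceeded by the next distinct value (plateaus
# take their first frame). Requires p + 1 <= n.
.firstLocalMax <- function(v, o, W) {
  n <- length(v)
  hi <- min(o + W, n - 1L)
  p <- o + 1L
  while (p <= hi) {
    if (v[p] > v[p - 1L]) {
      # scan over a possible plateau
      q <- p
      while (q < n && v[q + 1L] == v[p]) q <- q + 1L
      if (q < n && v[q + 1L] < v[p]) return(p)
    }
    p <- p + 1L
  }
  NA_integer_
}

#' Detect calcium events in one percent dF/F trace
#'
#' Convenience wrapper: \code{\link{detectCandidates}} followed by
#' \code{\link{filterAndMeasure}}.
#'
#' @inheritParams filterAndMeasure
#' @inheritParams detectCandidates
#' @return data.frame of accepted events (see
#'   \code{\link{filterAndMeasure}}).
#' @export
detectEvents <- function(dffTrace, animalSd, smoothWindow = 1L,
                         minAmpPct = 0.02, sdFactor = 0.3,
                         minRiseFrames = 2L, peakWindowS = 2.0,
                         frameRate = NULL) {
  cand <- detectCandidates(dffTrace, smoothWindow)
  filterAndMeasure(cand, dffTrace, animalSd, frameRate = frameRate,
    minAmpPct = minAmpPct, sdFactor = sdFactor,
    minRiseFrames = minRiseFrames, peakWindowS = peakWindowS)
}

#' Event rate of a segment
#'
#' @param events data.frame of events detected in the segment.
#' @param segment the \linkS4class{SegmentAnnotation} (or a duration in
#'   seconds).
#' @param frameRate frame rate in Hz (needed when \code{segment} is an
#'   annotation).
#' @return list with \code{rate_hz} (= n_events / duration_s exactly),
#'   \code{n_events} and \code{duration_s}.
#' @export
eventRate <- function(events, segment, frameRate = NULL) {
  durS <- if (is(segment, "SegmentAnnotation")) {
    .assert(!is.null(frameRate), "frameRate needed with an annotation")
    (segment@endFrame - segment@startFrame) / frameRate
  } else as.numeric(segment)
  .assert(durS > 0, "segment duration must be positive")
  n <- if (is.data.frame(events)) nrow(events) else length(events)
  list(rate_hz = n / durS, n_events = n, duration_s = durS)
}
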