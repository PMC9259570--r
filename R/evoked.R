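# Stimulus-evoked responses as window summations.
#
# vds: summation of percent dF/F during the 9 s of stimulation versus the
# summation during the previous 9 s; mec: 1 s versus the previous 1 s.
# Sums are over frames (units percent x frame) at the fixed frame rate.

#' Evoked response by window summation
#'
#' Plain sums over the half-open frame windows
#' \code{[onset - w, onset)} (basal) and \code{[onset, onset + w)}
#' (stimulus), \code{w = round(duration * frameRate)} frames.
#'
#' @param dffTrace a \linkS4class{DffTrace} (or numeric vector with
#'   \code{frameRate}).
#' @param stimOnsetFrame 0-based frame of stimulus onset, relative to the
#'   trace start.
#' @param stimDurationS stimulus window duration in seconds (9 for vds,
#'   1 for mec).
#' @param frameRate frame rate in Hz (taken from the trace when omitted).
#' @return list with \code{sum_stim}, \code{sum_basal} and
#'   \code{delta = sum_stim - sum_basal} (percent x frame).
#' @export
evokedSum <- function(dffTrace, stimOnsetFrame, stimDurationS,
                      frameRate = NULL) {
  v <- if (is(dffTrace, "DffTrace")) traceValues(dffTrace) else
    as.numeric(dffTrace)
  if (is.null(frameRate)) {
    .assert(is(dffTrace, "DffTrace"),
      "frameRate must be supplied for a bare numeric trace")
    frameRate <- frameRate(dffTrace)
  }
  w <- .framesFromSeconds(stimDurationS, frameRate)
  o <- as.integer(stimOnsetFrame)
  .assert(o - w >= 0L, sprintf(
    "insufficient pre-stimulus frames: need %d before onset frame %d", w, o))
  .assert(o + w <= length(v), "stimulus window extends beyond the trace")
  sumStim <- sum(v[(o + 1L):(o + w)])
  sumBasal <- sum(v[(o - w + 1L):o])
  list(sum_stim = sumStim, sum_basal = sumBasal,
    delta = sumStim - sumBasal, window_frames = w)
}

#' Stimulus analysis window of a vds trial
#'
#' The vds is presented during the last nine seconds of a 27 s context
#' presentation; the window starts at the first movement-cycle onset and
#' spans 9 s.
#'
#' @param segment a vds \linkS4class{SegmentAnnotation} with annotated
#'   onsets.
#' @return list with \code{onset_frame} (0-based, relative to the segment
#'   start) and \code{duration_s = 9}.
#' @export
vdsTrialWindows <- function(segment) {
  stopifnot(is(segment, "SegmentAnnotation"))
  .assert(segment@label == "vds", "segment is not a vds trial")
  .assert(length(segment@stimulusOnsets) >= 1L,
    "vds segment lacks stimulus-onset annotations")
  list(onset_frame = min(segment@stimulusOnsets) - segment@startFrame,
    duration_s = 9)
}

#' Stimulus analysis window of a mec trial
#'
#' The air-puff response is analyzed over a 1 s window at the pulse onset.
#'
#' @param segment a mec \linkS4class{SegmentAnnotation} with an annotated
#'   onset.
#' @return list with \code{onset_frame} (0-based, relative to the segment
#'   start) and \code{duration_s = 1}.
#' @export
mecTrialWindows <- function(segment) {
  stopifnot(is(segment, "SegmentAnnotation"))
  .assert(segment@label == "mec", "segment is not a mec trial")
  .assert(length(segment@stimulusOnsets) >= 1L,
    "mec segment lacks a stimulus-onset annotation")
  list(onset_frame = min(segment@stimulusOnsets) - segment@startFrame,
    duration_s = 1)
}

#' Evoked response of an annotated stimulus trial
#'
#' Dispatches on the segment label to the vds (9 s) or mec (1 s) window
#' and computes \code{\link{evokedSum}}.
#'
#' @param dffTrace a \linkS4class{DffTrace} whose annotation carries
#'   stimulus onsets.
#' @return the \code{\link{evokedSum}} result.
#' @export
trialEvokedSum <- function(dffTrace) {
  stopifnot(is(dffTrace, "DffTrace"))
  ann <- segmentInfo(dffTrace)
  win <- switch(ann@label,
    vds = vdsTrialWindows(ann),
    mec = mecTrialWindows(ann),
    stop(sprintf("segment '%s' is not a stimulus trial", ann@label),
      call. = FALSE))
  evokedSum(dffTrace, win$onset_frame, win$duration_s)
}
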