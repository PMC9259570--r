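# Trace-level synthetic data: transient kernel and per-segment simulation.

#' Sampled calcium-transient kernel
#'
#' A calcium event template: zero before onset, monotone linear rise over
#' \code{riseFrames} frames to \code{amplitudePct}, then exponential decay
#' with time constant \code{decayTauS}.
#'
#' @param riseFrames integer >= 1, frames from onset to peak.
#' @param decayTauS decay time constant in seconds, > 0.
#' @param amplitudePct peak amplitude in percent dF/F, >= 0.
#' @param frameRateHz sampling rate in Hz.
#' @param lengthS kernel length in seconds; must cover at least 5 decay
#'   time constants (default exactly 6).
#' @return numeric vector; element 1 is the onset frame (value 0), element
#'   \code{riseFrames + 1} is the peak.
#' @examples
#' k <- makeKernel(riseFrames = 3, decayTauS = 1, amplitudePct = 1,
#'   frameRateHz = 20)
#' k[4]            # peak: 1
#' k[4 + 20]       # one tau after the peak: exp(-1)
#' @export
makeKernel <- function(riseFrames, decayTauS, amplitudePct, frameRateHz,
                       lengthS = 6 * decayTauS) {
  .assert(is.numeric(decayTauS) && decayTauS > 0,
    "decayTauS must be a positive number")
  .assert(is.numeric(frameRateHz) && frameRateHz > 0,
    "frameRateHz must be a positive number")
  .assert(riseFrames >= 1, "riseFrames must be >= 1")
  .assert(amplitudePct >= 0, "amplitudePct must be >= 0")
  .assert(lengthS >= 5 * decayTauS,
    "lengthS must cover at least 5 decay time constants")
  riseFrames <- as.integer(riseFrames)
  n <- as.integer(round(lengthS * frameRateHz)) + 1L
  .assert(n > riseFrames, "kernel too short for its rise")
  i <- 0:(n - 1L)
  k <- numeric(n)
  k[i <= riseFrames] <- amplitudePct * i[i <= riseFrames] / riseFrames
  post <- i > riseFrames
  k[post] <- amplitudePct * exp(-((i[post] - riseFrames) / frameRateHz) /
    decayTauS)
  k
}

# Add `amp * kernel` into `signal` starting at 0-based onset frame.
.addKernel <- function(signal, onsetFrame, amp, kernel) {
  n <- length(signal)
  i0 <- onsetFrame + 1L
  if (i0 > n) return(signal)
  len <- min(length(kernel), n - i0 + 1L)
  idx <- i0:(i0 + len - 1L)
  signal[idx] <- signal[idx] + amp * kernel[seq_len(len)]
  signal
}

#' Simulate one recording segment as an ROI-mean fluorescence trace
#'
#' Generates spontaneous transients as a homogeneous Poisson process at the
#' (segment, group) rate, adds stimulus-locked transients for vds (two, one
#' per movement cycle, during the last 9 s of the 27 s context) and mec
#' (one, at the air-puff onset), modulates the bleached baseline
#' multiplicatively and adds Gaussian noise:
#' \code{F(t) = B exp(-t/tau_bleach) (1 + s(t)/100) + noise}, clipped to the
#' 16-bit range.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param segmentLabel one of pre, ctx, pos, vds, posvds, mec.
#' @param group group label (keys the planted rate delta and evoked
#'   amplitudes).
#' @param seed RNG seed; defaults to \code{cfg$seed}.
#' @return list with \code{trace} (a \linkS4class{FluorescenceTrace} whose
#'   annotation carries the stimulus onsets) and \code{truth} (data.frame of
#'   planted events: onset_s, onset_frame, amplitude_pct, motif_id, kind).
#' @export
simulateTraceSegment <- function(cfg, segmentLabel, group = "NAIVE",
                                 seed = cfg$seed) {
  .assert(segmentLabel %in% .segmentLabels,
    sprintf("unknown segment label '%s'", segmentLabel))
  .assert(group %in% cfg$group_labels,
    sprintf("unknown group '%s'", group))
  fs <- cfg$frame_rate_hz
  durS <- unname(cfg$segment_durations_s[segmentLabel])
  .assert(is.finite(durS), sprintf("no duration configured for segment '%s'",
    segmentLabel))
  nF <- .framesFromSeconds(durS, fs)
  kernel <- makeKernel(cfg$kernel$rise_frames, cfg$kernel$decay_tau_s,
    1.0, fs)

  .withSeed(seed, {
    rate <- .segmentRate(cfg, segmentLabel, group)
    nEv <- stats::rpois(1L, rate * durS)
    onsetS <- sort(stats::runif(nEv, 0, durS))
    amp <- cfg$kernel$amplitude_pct *
      stats::runif(nEv, 1 - cfg$amp_jitter, 1 + cfg$amp_jitter)
    motif <- if (nEv > 0) ((seq_len(nEv) - 1L) %% cfg$n_motifs) + 1L else
      integer(0)
    truth <- data.frame(onset_s = onsetS,
      onset_frame = .framesFromSeconds(onsetS, fs),
      amplitude_pct = amp, motif_id = motif,
      kind = rep("spont", nEv), stringsAsFactors = FALSE)

    stimOnsets <- integer(0)
    stimDur <- NA_real_
    if (segmentLabel == "vds") {
      # two movement cycles (~2.2 s each) separated by 2 s, in the last 9 s
      # of the 27 s context
      cycleOnsetS <- cfg$ctx_onset_s + 18 + c(0, 2.2 + 2)
      stimOnsets <- .framesFromSeconds(cycleOnsetS, fs)
      stimDur <- 9
      evAmp <- unname(cfg$vds_evoked_amplitude_pct[group]) *
        stats::runif(2L, 1 - cfg$amp_jitter, 1 + cfg$amp_jitter)
      truth <- rbind(truth, data.frame(onset_s = cycleOnsetS,
        onset_frame = stimOnsets, amplitude_pct = evAmp,
        motif_id = rep(1L, 2L), kind = rep("evoked", 2L),
        stringsAsFactors = FALSE))
    } else if (segmentLabel == "mec") {
      stimOnsets <- .framesFromSeconds(cfg$mec_onset_s, fs)
      stimDur <- 1
      evAmp <- unname(cfg$mec_evoked_amplitude_pct[group]) *
        stats::runif(1L, 1 - cfg$amp_jitter, 1 + cfg$amp_jitter)
      truth <- rbind(truth, data.frame(onset_s = cfg$mec_onset_s,
        onset_frame = stimOnsets, amplitude_pct = evAmp,
        motif_id = 1L, kind = "evoked", stringsAsFactors = FALSE))
    }

    sig <- numeric(nF)
    if (nrow(truth)) {
      for (r in seq_len(nrow(truth))) {
        if (truth$amplitude_pct[r] > 0) {
          sig <- .addKernel(sig, truth$onset_frame[r],
            truth$amplitude_pct[r], kernel)
        }
      }
    }
    t <- (0:(nF - 1L)) / fs
    bleach <- if (is.finite(cfg$bleach_tau_s)) {
      exp(-t / cfg$bleach_tau_s)
    } else rep(1, nF)
    f <- cfg$baseline_intensity * bleach * (1 + sig / 100)
    if (cfg$noise_sd_pct > 0) {
      f <- f + stats::rnorm(nF, 0,
        cfg$noise_sd_pct / 100 * cfg$baseline_intensity)
    }
    f <- pmin(pmax(f, 0), 65535)

    ann <- SegmentAnnotation(segmentLabel, 0L, nF,
      stimulusOnsets = stimOnsets, stimulusDuration = stimDur)
    list(trace = FluorescenceTrace(f, fs, ann), truth = truth)
  })
}
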