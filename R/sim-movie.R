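# Movie-level synthetic data: recurrent spatial motifs inside an ROI.

# Default circular ROI mask centred in the frame.
.defaultRoiMask <- function(h, w, radius) {
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ROIMask((rr - cy)^2 + (cc - cx)^2 <= radius^2)
}

# Default motif centres: n points on a circle of half the ROI radius.
.defaultMotifCenters <- function(cfg) {
  h <- cfg$movie_height
  w <- cfg$movie_width
  r <- cfg$roi_radius_px / 2
  ang <- 2 * pi * (seq_len(cfg$n_motifs) - 1L) / cfg$n_motifs - pi / 2
  cbind(row = round((h + 1) / 2 + r * sin(ang)),
        col = round((w + 1) / 2 + r * cos(ang)))
}

# Gaussian blob footprint, max 1 at the centre, zero outside the ROI.
.motifFootprint <- function(center, sigma, mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  fp <- exp(-(((rr - center[1L])^2 + (cc - center[2L])^2) / (2 * sigma^2)))
  fp[!mask] <- 0
  fp
}

#' Simulate a calcium-imaging movie with recurrent spatial motifs
#'
#' Each planted event lights up one of \code{cfg$n_motifs} Gaussian blob
#' footprints inside the ROI, modulated in time by the transient kernel;
#' pixels outside the ROI carry baseline (bleached) intensity plus noise
#' only. Event times are Poisson at \code{cfg$movie_event_rate_hz}, thinned
#' to a minimum separation of \code{cfg$movie_min_event_sep_s} so each
#' peak-centred pattern is uncontaminated by its neighbours; motif
#' identities cycle round-robin so every motif recurs.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param seed RNG seed; defaults to \code{cfg$seed}.
#' @return list with \code{movie} (\linkS4class{Movie}), \code{roi}
#'   (\linkS4class{ROIMask}) and \code{truth} (data.frame with onset_s,
#'   onset_frame, peak_frame, amplitude_pct, motif_id).
#' @export
simulateMovie <- function(cfg, seed = cfg$seed) {
  fs <- cfg$frame_rate_hz
  h <- cfg$movie_height
  w <- cfg$movie_width
  nF <- .framesFromSeconds(cfg$movie_duration_s, fs)
  mask <- .defaultRoiMask(h, w, cfg$roi_radius_px)
  centers <- if (is.null(cfg$motif_centers)) .defaultMotifCenters(cfg) else
    cfg$motif_centers
  .assert(nrow(centers) == cfg$n_motifs,
    "motif_centers must have n_motifs rows")
  .assert(all(centers[, 1L] >= 1 & centers[, 1L] <= h &
              centers[, 2L] >= 1 & centers[, 2L] <= w),
    "motif centres must lie inside the frame bounds")
  .assert(all(maskMatrix(mask)[cbind(centers[, 1L], centers[, 2L])]),
    "motif centres must lie inside the ROI")
  footprints <- lapply(seq_len(cfg$n_motifs), function(i) {
    .motifFootprint(centers[i, ], cfg$motif_sigma_px, maskMatrix(mask))
  })
  kernel <- makeKernel(cfg$kernel$rise_frames, cfg$kernel$decay_tau_s, 1.0,
    fs)

  .withSeed(seed, {
    nEv <- stats::rpois(1L, cfg$movie_event_rate_hz * cfg$movie_duration_s)
    onsetS <- sort(stats::runif(nEv, 1, cfg$movie_duration_s - 2))
    if (length(onsetS) > 1L) {
      keep <- c(TRUE, diff(onsetS) >= cfg$movie_min_event_sep_s)
      # iterate: after dropping, re-check gaps to the last kept event
      while (!all(keep)) {
        onsetS <- onsetS[keep]
        keep <- c(TRUE, diff(onsetS) >= cfg$movie_min_event_sep_s)
      }
    }
    nEv <- length(onsetS)
    motif <- if (nEv > 0) ((seq_len(nEv) - 1L) %% cfg$n_motifs) + 1L else
      integer(0)
    amp <- cfg$movie_event_amplitude_pct *
      stats::runif(nEv, 1 - cfg$amp_jitter, 1 + cfg$amp_jitter)
    onsetF <- .framesFromSeconds(onsetS, fs)

    t <- (0:(nF - 1L)) / fs
    bleach <- if (is.finite(cfg$bleach_tau_s)) {
      exp(-t / cfg$bleach_tau_s)
    } else rep(1, nF)
    # fractional signal per pixel: sum of amp * kernel(t) * footprint(x, y)
    sig <- array(0, dim = c(nF, h, w))
    for (e in seq_len(nEv)) {
      i0 <- onsetF[e] + 1L
      len <- min(length(kernel), nF - i0 + 1L)
      if (len < 1L) next
      tk <- amp[e] * kernel[seq_len(len)]
      idx <- i0:(i0 + len - 1L)
      sig[idx, , ] <- sig[idx, , ] +
        outer(tk, footprints[[motif[e]]])
    }
    dat <- cfg$baseline_intensity * bleach * (1 + sig / 100)
    dim(dat) <- c(nF, h, w)
    if (cfg$movie_noise_sd > 0) {
      dat <- dat + stats::rnorm(length(dat), 0, cfg$movie_noise_sd)
    }
    dat <- pmin(pmax(dat, 0), 65535)
    dim(dat) <- c(nF, h, w)

    truth <- data.frame(onset_s = onsetS, onset_frame = onsetF,
      peak_frame = onsetF + cfg$kernel$rise_frames,
      amplitude_pct = amp, motif_id = motif, stringsAsFactors = FALSE)
    list(movie = Movie(dat, fs), roi = mask, truth = truth)
  })
}
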