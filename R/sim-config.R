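#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: recording
#' timeline, transient kernel shape, noise and bleaching, stimulus-evoked
#' amplitudes per group, spatial motifs, and the cohort design. Defaults
#' emulate the study conditions: 20 Hz acquisition, spontaneous-activity
#' segments of 139 s (the average analyzed-segment length; individual
#' durations are clipped to the 60--188 s range), vds trials with two
#' movement-cycle transients in the last 9 s of a 27 s context, mec trials
#' with a single 1 s air-puff transient, and a trained (TR) group carrying
#' an elevated post-context event rate and a suppressed vds response while
#' NAIVE and cycloheximide-treated (TR_CHX) animals carry neither effect.
#'
#' @param frame_rate_hz acquisition frame rate (Hz).
#' @param segment_durations_s named vector of segment durations in seconds;
#'   names from pre, ctx, pos, posvds, vds, mec. Durations must not exceed
#'   400 s (the maximum continuous recording length).
#' @param spont_rate_hz spontaneous calcium-event rate (events/s), common to
#'   all periods and groups before planted effects.
#' @param planted_rate_delta_hz named vector (NAIVE, TR, TR_CHX): the
#'   pos-minus-pre event-rate increase planted for each group (Hz).
#' @param kernel list with \code{rise_frames}, \code{decay_tau_s} and
#'   \code{amplitude_pct}: the spontaneous transient template (fast linear
#'   rise, exponential decay).
#' @param amp_jitter relative uniform jitter applied to every planted
#'   amplitude (0.2 = +-20\%).
#' @param noise_sd_pct additive Gaussian noise SD on the ROI-mean trace, as a
#'   percentage of the baseline intensity.
#' @param bleach_tau_s mono-exponential dye-bleaching time constant (s);
#'   \code{Inf} disables bleaching.
#' @param baseline_intensity baseline fluorescence in 16-bit camera units.
#' @param vds_evoked_amplitude_pct named vector per group: amplitude
#'   (percent dF/F) of each of the two vds movement-cycle transients.
#' @param mec_evoked_amplitude_pct named vector per group: amplitude of the
#'   single mec transient.
#' @param ctx_onset_s context onset within a vds segment (s); the vds is
#'   presented during the last 9 s of the 27 s context.
#' @param mec_onset_s air-puff onset within a mec segment (s).
#' @param n_motifs number of recurrent spatial activation motifs (movies).
#' @param motif_centers n_motifs x 2 matrix of (row, col) blob centres in
#'   unbinned pixels; \code{NULL} places them evenly inside the ROI.
#' @param motif_sigma_px Gaussian blob SD in pixels.
#' @param movie_height,movie_width movie dimensions in pixels.
#' @param movie_duration_s movie length in seconds.
#' @param movie_event_rate_hz event rate used for movie simulations.
#' @param movie_event_amplitude_pct event amplitude for movie simulations
#'   (percent dF/F at the motif centre).
#' @param movie_min_event_sep_s minimum separation enforced between movie
#'   events so each peak yields an uncontaminated pattern.
#' @param movie_noise_sd per-pixel additive Gaussian noise SD (camera units).
#' @param roi_radius_px radius of the default circular ROI.
#' @param group_labels cohort group labels.
#' @param n_per_group named vector of animals per group.
#' @param segments segments simulated per animal in a cohort.
#' @param seed default RNG seed used when none is passed to a simulator.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(
    frame_rate_hz = 20,
    segment_durations_s = c(pre = 139, ctx = 139, pos = 139, posvds = 139,
      vds = 139, mec = 60),
    spont_rate_hz = 0.06,
    planted_rate_delta_hz = c(NAIVE = 0, TR = 0.10, TR_CHX = 0),
    kernel = list(rise_frames = 2L, decay_tau_s = 0.8, amplitude_pct = 0.2),
    amp_jitter = 0.2,
    noise_sd_pct = 0.005,
    bleach_tau_s = 2000,
    baseline_intensity = 10000,
    vds_evoked_amplitude_pct = c(NAIVE = 1.0, TR = 0.0, TR_CHX = 1.0),
    mec_evoked_amplitude_pct = c(NAIVE = 1.0, TR = 1.0, TR_CHX = 1.0),
    ctx_onset_s = 60,
    mec_onset_s = 30,
    n_motifs = 3L,
    motif_centers = NULL,
    motif_sigma_px = 2.5,
    movie_height = 64L,
    movie_width = 64L,
    movie_duration_s = 60,
    movie_event_rate_hz = 0.25,
    movie_event_amplitude_pct = 2.0,
    movie_min_event_sep_s = 3,
    movie_noise_sd = 20,
    roi_radius_px = 24,
    group_labels = c("NAIVE", "TR", "TR_CHX"),
    n_per_group = c(NAIVE = 6L, TR = 5L, TR_CHX = 5L),
    segments = c("pre", "ctx", "pos", "vds", "mec"),
    seed = 1L) {
  cfg <- list(
    frame_rate_hz = frame_rate_hz,
    segment_durations_s = segment_durations_s,
    spont_rate_hz = spont_rate_hz,
    planted_rate_delta_hz = planted_rate_delta_hz,
    kernel = kernel, amp_jitter = amp_jitter,
    noise_sd_pct = noise_sd_pct, bleach_tau_s = bleach_tau_s,
    baseline_intensity = baseline_intensity,
    vds_evoked_amplitude_pct = vds_evoked_amplitude_pct,
    mec_evoked_amplitude_pct = mec_evoked_amplitude_pct,
    ctx_onset_s = ctx_onset_s, mec_onset_s = mec_onset_s,
    n_motifs = as.integer(n_motifs), motif_centers = motif_centers,
    motif_sigma_px = motif_sigma_px,
    movie_height = as.integer(movie_height),
    movie_width = as.integer(movie_width),
    movie_duration_s = movie_duration_s,
    movie_event_rate_hz = movie_event_rate_hz,
    movie_event_amplitude_pct = movie_event_amplitude_pct,
    movie_min_event_sep_s = movie_min_event_sep_s,
    movie_noise_sd = movie_noise_sd,
    roi_radius_px = roi_radius_px,
    group_labels = group_labels,
    n_per_group = n_per_group,
    segments = segments,
    seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#'
#' Checks the generator's invariants: non-negative rates, SDs and taus,
#' positive frame rate, segment durations within the 400 s recording cap,
#' and group-keyed parameters covering every group label.
#'
#' @param cfg a \code{SimulationConfig}
#' @return \code{cfg}, invisibly; errors name the offending field.
#' @export
validateSimulationConfig <- function(cfg) {
  .assert(cfg$frame_rate_hz > 0, "frame_rate_hz must be positive")
  .assert(all(cfg$segment_durations_s > 0),
    "segment_durations_s must be positive")
  .assert(all(cfg$segment_durations_s <= 400),
    "segment_durations_s must not exceed 400 s (maximum recording length)")
  .assert(all(names(cfg$segment_durations_s) %in% .segmentLabels),
    "segment_durations_s names must come from: ",
    paste(.segmentLabels, collapse = ", "))
  .assert(cfg$spont_rate_hz >= 0, "spont_rate_hz must be >= 0")
  .assert(all(cfg$planted_rate_delta_hz >= 0),
    "planted_rate_delta_hz must be >= 0")
  .assert(cfg$kernel$rise_frames >= 1, "kernel rise_frames must be >= 1")
  .assert(cfg$kernel$decay_tau_s > 0, "kernel decay_tau_s must be positive")
  .assert(cfg$kernel$amplitude_pct >= 0, "kernel amplitude_pct must be >= 0")
  .assert(cfg$noise_sd_pct >= 0, "noise_sd_pct must be >= 0")
  .assert(cfg$bleach_tau_s > 0, "bleach_tau_s must be positive")
  .assert(cfg$baseline_intensity > 0, "baseline_intensity must be positive")
  .assert(all(cfg$vds_evoked_amplitude_pct >= 0) &&
      all(cfg$mec_evoked_amplitude_pct >= 0),
    "evoked amplitudes must be >= 0")
  for (fld in c("planted_rate_delta_hz", "vds_evoked_amplitude_pct",
                "mec_evoked_amplitude_pct", "n_per_group")) {
    .assert(all(cfg$group_labels %in% names(cfg[[fld]])),
      fld, " must be named for every group label")
  }
  .assert(cfg$n_motifs >= 1, "n_motifs must be >= 1")
  .assert(all(cfg$segments %in% .segmentLabels),
    "segments must come from the fixed label vocabulary")
  invisible(cfg)
}

# Spontaneous event rate for one (segment, group) cell: the planted
# pos-minus-pre delta applies to the post-context periods only.
.segmentRate <- function(cfg, segmentLabel, group) {
  rate <- cfg$spont_rate_hz
  if (segmentLabel %in% c("pos", "posvds")) {
    rate <- rate + unname(cfg$planted_rate_delta_hz[group])
  }
  rate
}
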