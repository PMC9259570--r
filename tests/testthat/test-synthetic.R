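# Synthetic-data generator: kernel shape, trace statistics, determinism.

test_that("transient kernel has the prescribed rise, peak and decay", {
  k <- makeKernel(riseFrames = 3, decayTauS = 1, amplitudePct = 1,
    frameRateHz = 20)
  expect_equal(k[1], 0)
  expect_equal(k[4], 1)                       # peak at frame index riseFrames
  expect_equal(k[4 + 20], exp(-1))            # one tau after the peak
  expect_true(all(diff(k[1:4]) > 0))          # monotone rise
  expect_true(all(diff(k[4:length(k)]) < 0))  # monotone decay
  expect_true(all(k >= 0))

  expect_equal(makeKernel(3, 1, 0, 20), rep(0, length(k)))

  expect_error(makeKernel(3, -1, 1, 20), "decayTauS")
  expect_error(makeKernel(3, 1, 1, 0), "frameRateHz")
  expect_error(makeKernel(0, 1, 1, 20), "riseFrames")
  expect_error(makeKernel(3, 1, 1, 20, lengthS = 2), "decay time constants")
})

test_that("degenerate config yields a constant trace and empty truth", {
  cfg <- simulationConfig(spont_rate_hz = 0, noise_sd_pct = 0,
    bleach_tau_s = Inf)
  r <- simulateTraceSegment(cfg, "pre", "NAIVE", seed = 1)
  expect_equal(nrow(r$truth), 0L)
  expect_true(all(traceValues(r$trace) == cfg$baseline_intensity))
})

test_that("a single forced transient reproduces the baseline-modulated kernel", {
  cfg <- simulationConfig(spont_rate_hz = 0, noise_sd_pct = 0,
    bleach_tau_s = Inf, amp_jitter = 0,
    mec_evoked_amplitude_pct = c(NAIVE = 2, TR = 2, TR_CHX = 2))
  r <- simulateTraceSegment(cfg, "mec", "NAIVE", seed = 1)
  v <- traceValues(r$trace)
  k <- makeKernel(cfg$kernel$rise_frames, cfg$kernel$decay_tau_s, 1,
    cfg$frame_rate_hz)
  expected <- rep(cfg$baseline_intensity, length(v))
  o <- r$truth$onset_frame[r$truth$kind == "evoked"]
  idx <- (o + 1):(o + length(k))
  expected[idx] <- cfg$baseline_intensity * (1 + 2 * k / 100)
  expect_equal(v, expected, tolerance = 1e-12)
})

test_that("planted event counts follow the Poisson expectation", {
  cfg <- simulationConfig(spont_rate_hz = 0.1, noise_sd_pct = 0,
    segment_durations_s = c(pre = 200))
  counts <- vapply(1:100, function(s) {
    nrow(simulateTraceSegment(cfg, "pre", "NAIVE", seed = s)$truth)
  }, numeric(1))
  lambda <- 0.1 * 200
  se <- sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # variance consistent with Poisson within 3 SEs of the sample variance
  expect_lt(abs(var(counts) - lambda), 3 * lambda * sqrt(2 / 99))
})

test_that("generated intensities stay on the 16-bit scale and seeds fix output", {
  cfg <- simulationConfig()
  r1 <- simulateTraceSegment(cfg, "pos", "TR", seed = 7)
  r2 <- simulateTraceSegment(cfg, "pos", "TR", seed = 7)
  r3 <- simulateTraceSegment(cfg, "pos", "TR", seed = 8)
  v <- traceValues(r1$trace)
  expect_true(all(v >= 0 & v <= 65535))
  expect_identical(v, traceValues(r2$trace))
  expect_identical(r1$truth, r2$truth)
  expect_false(identical(v, traceValues(r3$trace)))

  expect_error(simulateTraceSegment(cfg, "oddball", "NAIVE"), "unknown")
})

test_that("vds and mec segments carry the stimulus-locked transients", {
  cfg <- simulationConfig(spont_rate_hz = 0, noise_sd_pct = 0,
    bleach_tau_s = Inf)
  rv <- simulateTraceSegment(cfg, "vds", "NAIVE", seed = 3)
  annV <- segmentInfo(rv$trace)
  expect_length(annV@stimulusOnsets, 2L)  # one per movement cycle
  expect_equal(annV@stimulusDuration, 9)
  expect_equal(sum(rv$truth$kind == "evoked"), 2L)
  # both cycles inside the 9 s window starting at the first onset
  w0 <- min(annV@stimulusOnsets)
  expect_true(all(rv$truth$onset_frame >= w0 &
    rv$truth$onset_frame < w0 + 9 * cfg$frame_rate_hz))

  rm_ <- simulateTraceSegment(cfg, "mec", "NAIVE", seed = 3)
  annM <- segmentInfo(rm_$trace)
  expect_length(annM@stimulusOnsets, 1L)
  expect_equal(annM@stimulusDuration, 1)

  # trained animals carry no vds transient but a full mec transient
  rvTR <- simulateTraceSegment(cfg, "vds", "TR", seed = 3)
  expect_true(all(traceValues(rvTR$trace) == cfg$baseline_intensity))
  rmTR <- simulateTraceSegment(cfg, "mec", "TR", seed = 3)
  expect_gt(max(traceValues(rmTR$trace)), cfg$baseline_intensity)
})

test_that("movies place events on their motif footprints inside the ROI", {
  cfg <- simulationConfig(movie_noise_sd = 0, n_motifs = 1L,
    movie_height = 32L, movie_width = 32L, roi_radius_px = 12,
    movie_duration_s = 25, movie_event_rate_hz = 0.2)
  sm <- simulateMovie(cfg, seed = 5)
  expect_s4_class(sm$movie, "Movie")
  expect_gt(nrow(sm$truth), 0L)
  for (i in seq_len(nrow(sm$truth))) {
    fr <- sm$truth$peak_frame[i] + 1L
    frame <- movieData(sm$movie)[fr, , ]
    amax <- which(frame == max(frame), arr.ind = TRUE)[1, ]
    expect_equal(unname(amax),
      unname(caevents:::.defaultMotifCenters(cfg)[1, ]))
  }
  # outside-ROI pixels carry baseline only (no noise, mild bleaching)
  outside <- !maskMatrix(sm$roi)
  fr1 <- movieData(sm$movie)[1, , ]
  expect_true(all(abs(fr1[outside] - cfg$baseline_intensity) <
    0.01 * cfg$baseline_intensity))

  badCfg <- simulationConfig(motif_centers = cbind(500, 500), n_motifs = 1L)
  expect_error(simulateMovie(badCfg), "frame bounds")
})

test_that("noiseless zero-event movies are constant up to bleaching", {
  cfg <- simulationConfig(movie_noise_sd = 0, movie_event_rate_hz = 0,
    movie_height = 16L, movie_width = 16L, roi_radius_px = 6,
    movie_duration_s = 25)
  sm <- simulateMovie(cfg, seed = 1)
  d <- movieData(sm$movie)
  t <- (0:(dim(d)[1] - 1)) / cfg$frame_rate_hz
  debleached <- d / exp(-t / cfg$bleach_tau_s)
  expect_equal(max(debleached) - min(debleached), 0, tolerance = 1e-8)
})

test_that("cohorts are reproducible and reject undersized groups", {
  cfg <- simulationConfig(
    segment_durations_s = c(pre = 60, pos = 60),
    n_per_group = c(NAIVE = 2L, TR = 2L, TR_CHX = 0L))
  c1 <- simulateCohort(cfg, seed = 4, groups = c("NAIVE", "TR"),
    segments = c("pre", "pos"))
  c2 <- simulateCohort(cfg, seed = 4, groups = c("NAIVE", "TR"),
    segments = c("pre", "pos"))
  expect_identical(
    lapply(c1$animals, function(a) lapply(a$recordings, function(r)
      traceValues(r$trace))),
    lapply(c2$animals, function(a) lapply(a$recordings, function(r)
      traceValues(r$trace))))
  expect_equal(length(c1$animals), 4L)

  cfgBad <- simulationConfig(n_per_group = c(NAIVE = 1L, TR = 5L,
    TR_CHX = 0L))
  expect_error(simulateCohort(cfgBad, groups = c("NAIVE", "TR")),
    "n_per_group")
})

test_that("recovered rate deltas track the planted TR effect", {
  # noiseless, detection-free check on the generator itself: ground-truth
  # event counts recover the planted pos - pre rate difference
  cfg <- simulationConfig(noise_sd_pct = 0)
  deltas <- vapply(1:50, function(s) {
    pre <- simulateTraceSegment(cfg, "pre", "TR", seed = 100 + s)
    pos <- simulateTraceSegment(cfg, "pos", "TR", seed = 7000 + s)
    dur <- unname(cfg$segment_durations_s["pre"])
    nrow(pos$truth) / dur - nrow(pre$truth) / dur
  }, numeric(1))
  planted <- unname(cfg$planted_rate_delta_hz["TR"])
  se <- sd(deltas) / sqrt(50)
  expect_lt(abs(mean(deltas) - planted), 3 * se)
})

test_that("config validation names the offending field", {
  expect_error(simulationConfig(frame_rate_hz = -1), "frame_rate_hz")
  expect_error(simulationConfig(segment_durations_s = c(pre = 500)),
    "400 s")
  expect_error(simulationConfig(spont_rate_hz = -0.1), "spont_rate_hz")
  expect_error(simulationConfig(noise_sd_pct = -1), "noise_sd_pct")
  expect_error(
    simulationConfig(planted_rate_delta_hz = c(NAIVE = 0, TR = 0.1)),
    "planted_rate_delta_hz")
})
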