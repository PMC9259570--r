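# Event detection: pooled SD, candidates, printed criteria, rates.

test_that("pooled SD concatenates all segments (population SD)", {
  expect_equal(pooledSd(list(rep(0, 50), rep(0, 30)))$sd_pct, 0)
  expect_equal(pooledSd(list(rep(c(-1, 1), 25)))$sd_pct, 1)

  set.seed(2)
  a <- rnorm(137)
  b <- rnorm(81, mean = 2)
  want <- sqrt(mean((c(a, b) - mean(c(a, b)))^2))
  expect_equal(pooledSd(list(a, b))$sd_pct, want)
  expect_error(pooledSd(list()), "at least one")
})

test_that("candidates sit at the onsets of planted kernels", {
  fs <- 20
  k <- makeKernel(2, 0.8, 1, fs)
  v <- numeric(200)
  v[51:(50 + length(k))] <- k
  cand <- detectCandidates(v)
  expect_true(50 %in% cand)          # 0-based onset of the kernel

  # two kernels 1 s apart: the superimposed onset splits the decay
  v2 <- numeric(200)
  v2[51:(50 + length(k))] <- k
  idx <- 71:min(200, 70 + length(k))
  v2[idx] <- v2[idx] + k[seq_along(idx)]
  cand2 <- detectCandidates(v2)
  expect_true(50 %in% cand2)
  expect_true(70 %in% cand2)
})

test_that("the printed criteria reject short rises and small amplitudes", {
  fs <- 20
  # rise of 1 frame to the peak -> rejected
  v <- c(rep(0, 10), 1, rep(0, 40), numeric(10))
  ev <- filterAndMeasure(9L, v, animalSd = 0, frameRate = fs)
  expect_equal(nrow(ev), 0L)

  # amplitude 0.01 with animal SD 0 -> below the 0.02 floor
  v2 <- c(rep(0, 10), 0.005, 0.01, rep(0, 50))
  ev2 <- detectEvents(v2, animalSd = 0, frameRate = fs)
  expect_equal(nrow(ev2), 0L)
  # same shape at amplitude 0.03 -> accepted
  v3 <- c(rep(0, 10), 0.015, 0.03, rep(0, 50))
  ev3 <- detectEvents(v3, animalSd = 0, frameRate = fs)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$amplitude_pct, 0.03)

  # peaks at 0.5 s and 1.5 s after onset: the first one wins
  v4 <- numeric(120)
  v4[21:31] <- seq(0, 1, length.out = 11)         # rise to peak at frame 30
  v4[32:40] <- seq(0.9, 0.5, length.out = 9)
  v4[41:51] <- seq(0.55, 1.5, length.out = 11)    # later, higher peak
  v4[52:70] <- seq(1.4, 0, length.out = 19)
  ev4 <- detectEvents(v4, animalSd = 0, frameRate = fs)
  expect_equal(ev4$peak_frame[1], 30L)            # 0.5 s, not 1.5 s

  # events whose 2 s window crosses the segment end are dropped, warning
  v5 <- c(numeric(100), seq(0, 1, length.out = 20))
  expect_warning(
    ev5 <- detectEvents(v5, animalSd = 0, frameRate = fs),
    "segment end")
  expect_equal(nrow(ev5), 0L)
})

test_that("thresholds act monotonically on the accepted-event count", {
  set.seed(13)
  for (i in 1:10) {
    v <- randomKernelTrace(400 + i)
    n0 <- nrow(suppressWarnings(detectEvents(v, animalSd = 0.05,
      frameRate = 20)))
    nLowAmp <- nrow(suppressWarnings(detectEvents(v, animalSd = 0.05,
      frameRate = 20, minAmpPct = 0.005)))
    nLowSd <- nrow(suppressWarnings(detectEvents(v, animalSd = 0.05,
      frameRate = 20, sdFactor = 0.1)))
    nHighSd <- nrow(suppressWarnings(detectEvents(v, animalSd = 0.5,
      frameRate = 20)))
    expect_gte(nLowAmp, n0)
    expect_gte(nLowSd, n0)
    expect_lte(nHighSd, n0)
  }
})

test_that("detection matches the brute-force printed-criteria scan", {
  suppressWarnings(for (s in 1:25) {
    v <- randomKernelTrace(s)
    sdv <- sqrt(mean((v - mean(v))^2))
    det <- detectEvents(v, sdv, frameRate = 20)
    orc <- bruteForceEvents(v, 20, sdv)
    expect_true(eventsMatch(det, orc),
      label = sprintf("trace seed %d matches the brute-force oracle", s))
  })
})

test_that("high-SNR simulated traces are recovered essentially perfectly", {
  cfg <- simulationConfig()   # amplitude 0.2% vs noise 0.005%
  r <- simulateTraceSegment(cfg, "pre", "NAIVE", seed = 31)
  d <- processTrace(r$trace)
  ev <- suppressWarnings(detectEvents(d, pooledSd(list(d))$sd_pct))
  m <- matchPlanted(ev$onset_frame, r$truth$onset_frame, tol = 5)
  expect_gte(m["tp"] / max(1, nrow(r$truth)), 0.9)
  expect_lte(m["fp"], 1)
})

test_that("event rate is count over duration", {
  ev <- data.frame(onset_frame = 1:5)
  er <- eventRate(ev, 100)
  expect_identical(er$rate_hz, 0.05)
  expect_identical(eventRate(ev[0, , drop = FALSE], 100)$rate_hz, 0)
  expect_error(eventRate(ev, 0), "positive")

  ann <- SegmentAnnotation("pre", 0L, 2780L)
  expect_equal(eventRate(ev, ann, frameRate = 20)$duration_s, 139)
})
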