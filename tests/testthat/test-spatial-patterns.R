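# Spatial activity patterns: binning, pixelwise normalization, pattern
# extraction, K-means clustering, stimulus assignment.

test_that("2x2 binning averages blocks and crops odd edges", {
  arr <- array(5, dim = c(3, 4, 4))
  expect_equal(movieData(bin2x2(Movie(arr, 20)))[1, , ],
    matrix(5, 2, 2))

  a1 <- array(0, dim = c(1, 2, 2))
  a1[1, , ] <- matrix(c(0, 50, 100, 50), 2, 2)
  expect_equal(movieData(bin2x2(Movie(a1, 20)))[1, , , drop = TRUE], 50)

  set.seed(8)
  a2 <- array(runif(2 * 8 * 8, 0, 100), dim = c(2, 8, 8))
  got <- movieData(bin2x2(Movie(a2, 20)))
  for (t in 1:2) for (r in 1:4) for (c in 1:4) {
    expect_equal(got[t, r, c],
      mean(a2[t, (2 * r - 1):(2 * r), (2 * c - 1):(2 * c)]))
  }

  odd <- Movie(array(1, dim = c(2, 5, 5)), 20)
  expect_warning(bo <- bin2x2(odd), "cropped")
  expect_equal(dim(movieData(bo))[2:3], c(2L, 2L))

  m <- matrix(FALSE, 4, 4)
  m[1, 2] <- TRUE                      # one pixel of a 2x2 block
  bm <- bin2x2(ROIMask(m))
  expect_true(maskMatrix(bm)[1, 1])
  expect_equal(roiArea(bm), 1L)
})

test_that("pixelwise dF/F matches a brute-force rolling mean", {
  # constant movie -> all-zero output
  cm <- Movie(array(100, dim = c(450, 4, 4)), 20)
  expect_true(all(movieData(pixelwiseDff(cm)) == 0))

  # single-pixel impulse against an explicit shrinking-window oracle
  arr <- array(100, dim = c(450, 3, 3))
  arr[230, 2, 2] <- 150
  got <- movieData(pixelwiseDff(Movie(arr, 20), windowFrames = 400L))
  x <- arr[, 2, 2]
  n <- length(x)
  half <- (400 - 1) %/% 2
  want <- numeric(n)
  for (t in 1:n) {
    lo <- max(1, t - half)
    hi <- min(n, t + (400 - 1 - half))
    want[t] <- (x[t] - mean(x[lo:hi])) / mean(x[lo:hi]) * 100
  }
  # the global minimum subtraction shifts all pixels equally; pixel (1,1)
  # is constant, so its value equals the shift
  shift <- got[1, 1, 1]
  expect_equal(got[, 2, 2] - shift, want, tolerance = 1e-9)

  # output global minimum is exactly 0
  expect_identical(min(got), 0)

  expect_error(pixelwiseDff(Movie(array(1, dim = c(100, 2, 2)), 20)),
    "rolling-mean")
  expect_error(pixelwiseDff(Movie(array(0, dim = c(450, 2, 2)), 20)),
    "baseline <= 0")
})

test_that("patterns are normalized, thresholded and ROI-restricted", {
  # uniform in-ROI activity: every in-ROI pixel is 1 after normalization
  arr <- array(1, dim = c(3, 8, 8))
  m <- matrix(FALSE, 8, 8)
  m[3:6, 3:6] <- TRUE
  p <- extractPattern(Movie(arr, 20), 1, ROIMask(m), gaussian = FALSE)
  expect_true(all(patternMap(p)[p@roi] == 1))
  expect_true(all(patternMap(p)[!p@roi] == 0))

  # single bright blob: argmax at the blob centre, value 1
  arr2 <- array(0.1, dim = c(3, 16, 16))
  for (r in 1:16) for (c in 1:16) {
    arr2[2, r, c] <- arr2[2, r, c] + 5 * exp(-(((r - 8)^2 + (c - 9)^2) / 8))
  }
  arr2[1, , ] <- arr2[2, , ]
  arr2[3, , ] <- arr2[2, , ]
  mask2 <- matrix(TRUE, 16, 16)
  p2 <- extractPattern(Movie(arr2, 20), 1, ROIMask(mask2))
  am <- which(patternMap(p2) == max(patternMap(p2)), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(8, 9))
  expect_equal(max(patternMap(p2)), 1)
  expect_true(all(patternMap(p2) >= 0 & patternMap(p2) <= 1))

  # thresholding is idempotent: re-applying changes nothing
  mp <- patternMap(p2)
  mp2 <- mp
  mp2[mp2 < 0.5] <- 0
  expect_identical(mp, mp2)

  # empty pattern warns and returns all-zero
  arr3 <- array(0, dim = c(3, 8, 8))
  expect_warning(p3 <- extractPattern(Movie(arr3, 20), 1, ROIMask(m)),
    "empty pattern")
  expect_true(all(patternMap(p3) == 0))
})

test_that("the two-blob pattern equals the hand-computed golden file", {
  h <- 12
  w <- 12
  blob <- function(cy, cx, sigma, amp) {
    mm <- matrix(0, h, w)
    for (r in 1:h) for (c in 1:w) {
      mm[r, c] <- amp * exp(-(((r - cy)^2 + (c - cx)^2) / (2 * sigma^2)))
    }
    mm
  }
  base <- blob(4, 4, 1.2, 1.0) + blob(9, 9, 1.0, 0.6)
  arr <- array(0, dim = c(3, h, w))
  arr[1, , ] <- base * 0.8
  arr[2, , ] <- base * 1.0
  arr[3, , ] <- base * 0.9
  mask <- matrix(FALSE, h, w)
  for (r in 1:h) for (c in 1:w) {
    mask[r, c] <- ((r - 6.5)^2 + (c - 6.5)^2) <= 25
  }
  p <- extractPattern(Movie(arr, 20), 1, ROIMask(mask), sigma = 1,
    threshold = 0.5)
  golden <- as.matrix(utils::read.csv(
    test_path("golden-two-blob-pattern.csv"), header = FALSE))
  dimnames(golden) <- NULL
  expect_equal(patternMap(p), golden, tolerance = 1e-9)
})

test_that("K-means clustering is reproducible and k-monotone", {
  set.seed(21)
  mkpat <- function(center, jitter = 0.02) {
    m <- matrix(0, 6, 6)
    m[center[1] + (-1:1), center[2] + (-1:1)] <- 1
    m <- m + matrix(abs(rnorm(36, 0, jitter)), 6, 6)
    m <- m / max(m)
    m[m < 0.5] <- 0
    new("SpatialPattern", map = m, roi = matrix(TRUE, 6, 6),
      source = "synthetic", peakFrame = 1L)
  }
  pats <- c(lapply(1:6, function(i) mkpat(c(2, 2))),
    lapply(1:6, function(i) mkpat(c(5, 5))),
    lapply(1:6, function(i) mkpat(c(2, 5))))

  # identical patterns, k = 1: inertia 0
  same <- lapply(1:4, function(i) mkpat(c(3, 3), jitter = 0))
  cl1 <- clusterPatterns(same, k = 1)
  expect_equal(clusterInertia(cl1), 0)

  cl <- clusterPatterns(pats, k = 3, seed = 5)
  clAgain <- clusterPatterns(pats, k = 3, seed = 5)
  expect_identical(clusterLabels(cl), clusterLabels(clAgain))
  truth <- rep(1:3, each = 6)
  expect_true(labelsAgreePerfectly(clusterLabels(cl), truth))

  # centroid of a cluster equals the mean of its members
  X <- do.call(rbind, lapply(pats, caevents:::.patternVector))
  for (j in seq_len(cl@k)) {
    expect_equal(unname(clusterCentroids(cl)[j, ]),
      unname(colMeans(X[clusterLabels(cl) == j, , drop = FALSE])))
  }

  # inertia is non-increasing in k
  inert <- vapply(1:5, function(k) {
    clusterInertia(clusterPatterns(pats, k = k, seed = 5))
  }, numeric(1))
  expect_true(all(diff(inert) <= 1e-8))

  # silhouette selection recovers k = 3 on well-separated motifs
  clAuto <- clusterPatterns(pats, k = NULL, kRange = 2:6, seed = 5)
  expect_equal(clAuto@k, 3L)

  expect_error(clusterPatterns(pats[1:2], k = 3), "at least k")
})

test_that("stimulus patterns are assigned to the nearest centroid", {
  set.seed(33)
  mkvec <- function(m) {
    new("SpatialPattern", map = m / max(m), roi = matrix(TRUE, 4, 4),
      source = "s", peakFrame = 1L)
  }
  g1 <- lapply(1:5, function(i) {
    m <- matrix(0, 4, 4)
    m[1:2, 1:2] <- 1
    m[4, 4] <- runif(1, 0.5, 0.8)
    mkvec(m)
  })
  g2 <- lapply(1:5, function(i) {
    m <- matrix(0, 4, 4)
    m[3:4, 1:2] <- 1
    m[1, 4] <- runif(1, 0.5, 0.8)
    mkvec(m)
  })
  cl <- clusterPatterns(c(g1, g2), k = 2, seed = 2)

  # a member pattern is assigned to its own cluster and matches
  asg <- assignStimulusPatterns(g1[1], cl)
  expect_equal(asg$cluster, clusterLabels(cl)[1])
  expect_true(asg$match)

  # a far-away orthogonal pattern is assigned but does not match
  far <- matrix(0, 4, 4)
  far[1:4, 3:4] <- 1
  asgFar <- assignStimulusPatterns(list(mkvec(far)), cl)
  expect_false(asgFar$match)

  # assignment equals a brute-force nearest-centroid search
  probes <- c(g1[2], g2[3], list(mkvec(far)))
  asgAll <- assignStimulusPatterns(probes, cl)
  for (i in seq_along(probes)) {
    v <- caevents:::.patternVector(probes[[i]])
    dists <- apply(clusterCentroids(cl), 1, function(ct)
      sqrt(sum((ct - v)^2)))
    expect_equal(asgAll$cluster[i], unname(which.min(dists)))
    expect_equal(asgAll$distance[i], unname(min(dists)))
  }

  expect_error(assignStimulusPatterns(list(), cl), "no stimulus")
})
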