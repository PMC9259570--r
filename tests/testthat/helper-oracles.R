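# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (explicit loops, definitional formulas) and share no
# code with the package implementation.

# Exhaustive brute-force event scan: every (onset, peak) pair is tested
# against the printed criteria. An onset is a frame where a rise starts
# (v[o+1] > v[o], not rising into o); its peak is the first local maximum
# (plateaus take their first frame) within the 2 s window; the event is
# kept when the rise takes >= minRiseFrames frames and the amplitude
# v[peak] - v[onset] reaches max(minAmpPct, sdFactor * animalSd).
bruteForceEvents <- function(v, frameRate, animalSd, minAmpPct = 0.02,
                             sdFactor = 0.3, minRiseFrames = 2,
                             peakWindowS = 2) {
  n <- length(v)
  W <- round(peakWindowS * frameRate)
  thr <- max(minAmpPct, sdFactor * animalSd)
  out <- NULL
  for (o in 1:(n - 1)) {
    if (!(v[o + 1] > v[o])) next
    if (o > 1 && v[o] > v[o - 1]) next
    if (o + W > n - 1) next            # peak window must fit in the segment
    p <- NA
    for (q in (o + 1):(o + W)) {
      if (v[q] > v[q - 1]) {
        r <- q
        while (r < n && v[r + 1] == v[q]) r <- r + 1
        if (r < n && v[r + 1] < v[q]) {
          p <- q
          break
        }
      }
    }
    if (is.na(p)) next
    if ((p - o) >= minRiseFrames && (v[p] - v[o]) >= thr) {
      out <- rbind(out, data.frame(onset_frame = o - 1, peak_frame = p - 1,
        amplitude_pct = v[p] - v[o]))
    }
  }
  if (is.null(out)) {
    return(data.frame(onset_frame = integer(0), peak_frame = integer(0),
      amplitude_pct = numeric(0)))
  }
  out[!duplicated(out$peak_frame), , drop = FALSE]
}

# Random smooth percent dF/F trace: a train of transient kernels with
# varied rise times, decay constants and amplitudes (some below the
# detection thresholds) on top of a slow sinusoidal drift. No white noise:
# these traces probe criteria application, not noise robustness.
randomKernelTrace <- function(seed, frameRate = 20) {
  set.seed(seed)
  n <- sample(120:200, 1)
  t <- (0:(n - 1)) / frameRate
  v <- runif(1, 0, 0.1) * sin(2 * pi * runif(1, 0.01, 0.05) * t +
    runif(1, 0, 2 * pi))
  m <- sample(0:5, 1)
  for (i in seq_len(m)) {
    rise <- sample(1:6, 1)
    tau <- runif(1, 0.3, 1.5)
    amp <- runif(1, 0.005, 0.6)
    onset <- sample(0:(n - 20), 1)
    len <- min(round(6 * tau * frameRate) + 1, n - onset)
    j <- 0:(len - 1)
    k <- ifelse(j <= rise, amp * j / rise,
      amp * exp(-((j - rise) / frameRate) / tau))
    v[(onset + 1):(onset + len)] <- v[(onset + 1):(onset + len)] + k
  }
  v
}

# Definitional mixed-ANOVA sums of squares from cell and marginal means.
ssOracle <- function(d) {
  GM <- mean(d$value)
  subj <- stats::aggregate(value ~ animal + group, d, mean)
  P <- length(unique(d$period))
  ssBetTotal <- P * sum((subj$value - GM)^2)
  gm <- stats::aggregate(value ~ group, d, mean)
  ng <- table(subj$group)
  ssGroup <- sum(P * ng[as.character(gm$group)] * (gm$value - GM)^2)
  pm <- stats::aggregate(value ~ period, d, mean)
  N <- nrow(subj)
  ssPeriod <- N * sum((pm$value - GM)^2)
  cellm <- stats::aggregate(value ~ group + period, d, mean)
  ssInter <- 0
  for (i in seq_len(nrow(cellm))) {
    g <- as.character(cellm$group[i])
    p <- cellm$period[i]
    ssInter <- ssInter + ng[g] * (cellm$value[i] -
      gm$value[gm$group == g] - pm$value[pm$period == p] + GM)^2
  }
  ssTotal <- sum((d$value - GM)^2)
  list(group = unname(ssGroup), subjects = ssBetTotal - ssGroup,
    period = unname(ssPeriod), interaction = unname(ssInter),
    within = unname(ssTotal - ssBetTotal - ssPeriod - ssInter),
    total = ssTotal)
}

# Random unbalanced 2x2 mixed-design dataset.
randomMixedData <- function(seed, nRange = 3:8) {
  set.seed(seed)
  n1 <- sample(nRange, 1)
  n2 <- sample(nRange, 1)
  d <- expand.grid(period = c("pre", "pos"), animal = seq_len(n1 + n2),
    stringsAsFactors = FALSE)
  d$group <- ifelse(d$animal <= n1, "A", "B")
  d$animal <- sprintf("s%02d", d$animal)
  d$value <- rnorm(nrow(d)) +
    ifelse(d$group == "B" & d$period == "pos", runif(1, 0, 2), 0)
  d
}

# Do detected events match the oracle events (peaks equal, onsets within
# +-1 frame)?
eventsMatch <- function(detected, oracle, onsetTol = 1) {
  if (nrow(detected) != nrow(oracle)) return(FALSE)
  if (nrow(detected) == 0) return(TRUE)
  det <- detected[order(detected$peak_frame), ]
  orc <- oracle[order(oracle$peak_frame), ]
  all(det$peak_frame == orc$peak_frame) &&
    all(abs(det$onset_frame - orc$onset_frame) <= onsetTol)
}

# Perfect one-to-one correspondence between cluster labels and true ids.
labelsAgreePerfectly <- function(labels, truth) {
  tab <- table(labels, truth)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Match detected events to planted onsets (greedy, within tol frames);
# returns c(tp, fp, fn).
matchPlanted <- function(detectedOnsets, plantedOnsets, tol = 3) {
  used <- logical(length(plantedOnsets))
  tp <- 0
  for (o in detectedOnsets) {
    d <- abs(plantedOnsets - o)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      tp <- tp + 1
    }
  }
  c(tp = tp, fp = length(detectedOnsets) - tp,
    fn = length(plantedOnsets) - tp)
}
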