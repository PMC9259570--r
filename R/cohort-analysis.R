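# From per-animal recordings to cohort tables and the full statistical
# report.

#' Process one animal's recordings into events, rates and evoked sums
#'
#' Runs the trace pipeline (band-pass filter, percent dF/F), pools the
#' percent dF/F SD over all of the animal's analyzed segments, detects
#' events per segment, and computes event rates (spontaneous periods) and
#' evoked window sums (vds/mec trials).
#'
#' @param recordings named list (by segment label) of
#'   \linkS4class{FluorescenceTrace} objects, or of \code{list(trace =
#'   ...)} entries as produced by \code{\link{simulateTraceSegment}}.
#' @param animal animal identifier stored in the event table.
#' @param lowHz,highHz filter band (Hz).
#' @param percentile baseline percentile.
#' @param minAmpPct,sdFactor,minRiseFrames,peakWindowS event criteria
#'   (see \code{\link{filterAndMeasure}}).
#' @param smoothWindow candidate-proposal smoothing window (frames).
#' @return list with \code{dff} (per-segment \linkS4class{DffTrace}),
#'   \code{sd_pct}, \code{events} (one data.frame), \code{rates}
#'   (data.frame period/rate_hz/n_events/duration_s) and \code{evoked}
#'   (data.frame segment/sum_stim/sum_basal/delta).
#' @export
processRecording <- function(recordings, animal = "animal",
                             lowHz = 0.025, highHz = 5, percentile = 8,
                             minAmpPct = 0.02, sdFactor = 0.3,
                             minRiseFrames = 2L, peakWindowS = 2.0,
                             smoothWindow = 1L) {
  traces <- lapply(recordings, function(r) {
    if (is(r, "FluorescenceTrace")) r else r$trace
  })
  dff <- lapply(traces, processTrace, lowHz = lowHz, highHz = highHz,
    percentile = percentile, warnShort = FALSE)
  sdPct <- pooledSd(dff)$sd_pct

  events <- NULL
  rates <- NULL
  evoked <- NULL
  for (seg in names(dff)) {
    tr <- dff[[seg]]
    ev <- withCallingHandlers(
      detectEvents(tr, sdPct, smoothWindow = smoothWindow,
        minAmpPct = minAmpPct, sdFactor = sdFactor,
        minRiseFrames = minRiseFrames, peakWindowS = peakWindowS),
      warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(ev)) {
      ev$animal <- animal
      ev$segment <- seg
      events <- rbind(events, ev)
    }
    if (seg %in% c("pre", "ctx", "pos", "posvds")) {
      er <- eventRate(ev, segmentInfo(tr), frameRate(tr))
      rates <- rbind(rates, data.frame(period = seg,
        rate_hz = er$rate_hz, n_events = er$n_events,
        duration_s = er$duration_s, stringsAsFactors = FALSE))
    }
    if (seg %in% c("vds", "mec")) {
      es <- trialEvokedSum(tr)
      evoked <- rbind(evoked, data.frame(segment = seg,
        sum_stim = es$sum_stim, sum_basal = es$sum_basal,
        delta = es$delta, stringsAsFactors = FALSE))
    }
  }
  if (is.null(events)) {
    events <- data.frame(onset_frame = integer(0), peak_frame = integer(0),
      onset_s = numeric(0), peak_s = numeric(0), amplitude_pct = numeric(0),
      animal = character(0), segment = character(0))
  }
  list(dff = dff, sd_pct = sdPct, events = events, rates = rates,
    evoked = evoked)
}

#' Build cohort tables from a simulated (or assembled) cohort
#'
#' Processes every animal and assembles the long-format tables the group
#' statistics consume: spontaneous event rates per period, and vds/mec
#' basal-versus-stimulus window sums.
#'
#' @param cohort a \code{"SimulatedCohort"}
#'   (see \code{\link{simulateCohort}}).
#' @param ... passed to \code{\link{processRecording}}.
#' @return list with \code{rates} (animal, group, period, value = rate in
#'   Hz), \code{vds} and \code{mec} (animal, group, period in bas/vds or
#'   bas/mec, value = percent x frame sum), and \code{events} (all detected
#'   events).
#' @export
buildCohortTables <- function(cohort, ...) {
  stopifnot(inherits(cohort, "SimulatedCohort"))
  rates <- NULL
  vds <- NULL
  mec <- NULL
  events <- NULL
  for (an in cohort$animals) {
    pr <- processRecording(an$recordings, animal = an$id, ...)
    if (!is.null(pr$rates)) {
      rates <- rbind(rates, data.frame(animal = an$id, group = an$group,
        period = pr$rates$period, value = pr$rates$rate_hz,
        stringsAsFactors = FALSE))
    }
    if (!is.null(pr$evoked)) {
      for (i in seq_len(nrow(pr$evoked))) {
        seg <- pr$evoked$segment[i]
        tab <- data.frame(animal = rep(an$id, 2L),
          group = rep(an$group, 2L), period = c("bas", seg),
          value = c(pr$evoked$sum_basal[i], pr$evoked$sum_stim[i]),
          stringsAsFactors = FALSE)
        if (seg == "vds") vds <- rbind(vds, tab) else mec <- rbind(mec, tab)
      }
    }
    events <- rbind(events, pr$events)
  }
  list(rates = rates, vds = vds, mec = mec, events = events)
}

#' Run the full group-level statistical battery on cohort tables
#'
#' Reproduces the study's design for two groups: (i) spontaneous event
#' rates: 2 (group) x 2 (pre, pos) mixed ANOVA, Holm-corrected two-tailed
#' paired post hoc t-tests per group, and a Welch independent t-test on
#' the pos-minus-pre difference scores; (ii) vds and (iii) mec evoked
#' sums: 2 x 2 (bas, stimulus) mixed ANOVA with Holm-corrected one-tailed
#' paired post hoc t-tests (an activity increase is the expected
#' direction); (iv) Pearson correlation between each animal's
#' post-context rate change and its vds-evoked delta. Each Holm family is
#' the set of pairwise tests following one omnibus and is recorded in the
#' report.
#'
#' @param tables list with \code{rates}, \code{vds}, \code{mec}
#'   (see \code{\link{buildCohortTables}}).
#' @param groups the two group labels to compare (default NAIVE vs TR).
#' @param alpha familywise error level for post hoc rejection flags.
#' @return list of class \code{"caCohortReport"}.
#' @export
analyzeCohort <- function(tables, groups = c("NAIVE", "TR"), alpha = 0.05) {
  .assert(length(groups) == 2L, "analyzeCohort compares exactly two groups")

  sel <- function(tab, periods) {
    tab <- tab[tab$group %in% groups & tab$period %in% periods, ,
      drop = FALSE]
    .assert(nrow(tab) > 0L, "no rows for the requested groups/periods")
    for (g in groups) {
      .assert(length(unique(tab$animal[tab$group == g])) >= 2L,
        sprintf("group '%s' has fewer than 2 animals", g))
    }
    tab
  }
  pairedDelta <- function(tab, periods) {
    wide <- merge(
      tab[tab$period == periods[1L], c("animal", "group", "value")],
      tab[tab$period == periods[2L], c("animal", "value")],
      by = "animal", suffixes = c("_a", "_b"))
    wide$delta <- wide$value_b - wide$value_a
    wide
  }
  posthocBattery <- function(tab, periods, tail) {
    wide <- pairedDelta(tab, periods)
    tests <- lapply(groups, function(g) {
      w <- wide[wide$group == g, , drop = FALSE]
      tTest(w$value_b, w$value_a, paired = TRUE, tail = tail)
    })
    names(tests) <- groups
    holm <- holmBonferroni(vapply(tests, `[[`, numeric(1L), "p"), alpha)
    posthoc <- data.frame(group = groups,
      comparison = sprintf("%s vs %s", periods[2L], periods[1L]),
      t = vapply(tests, `[[`, numeric(1L), "statistic"),
      df = vapply(tests, `[[`, numeric(1L), "df"),
      tail = tail, p = holm$p, p_adjusted = holm$p_adjusted,
      reject = holm$reject, stringsAsFactors = FALSE)
    rownames(posthoc) <- NULL
    list(posthoc = posthoc, wide = wide,
      family = sprintf("paired %s vs %s within each of %s", periods[2L],
        periods[1L], paste(groups, collapse = "/")))
  }

  report <- list(groups = groups, alpha = alpha)

  # (i) spontaneous rates, pre vs pos
  rt <- sel(tables$rates, c("pre", "pos"))
  report$rates <- local({
    an <- mixedAnova2x2(rt)
    ph <- posthocBattery(rt, c("pre", "pos"), tail = "two")
    gA <- ph$wide$delta[ph$wide$group == groups[1L]]
    gB <- ph$wide$delta[ph$wide$group == groups[2L]]
    list(anova = an, posthoc = ph$posthoc, holm_family = ph$family,
      welch_diff = tTest(gB, gA, paired = FALSE,
        welch = length(gA) != length(gB)),
      deltas = ph$wide)
  })

  # (ii) vds, bas vs vds (one-tailed: increase expected)
  if (!is.null(tables$vds)) {
    vt <- sel(tables$vds, c("bas", "vds"))
    ph <- posthocBattery(vt, c("bas", "vds"), tail = "greater")
    report$vds <- list(anova = mixedAnova2x2(vt), posthoc = ph$posthoc,
      holm_family = ph$family, deltas = ph$wide)
  }

  # (iii) mec, bas vs mec
  if (!is.null(tables$mec)) {
    mt <- sel(tables$mec, c("bas", "mec"))
    ph <- posthocBattery(mt, c("bas", "mec"), tail = "greater")
    report$mec <- list(anova = mixedAnova2x2(mt), posthoc = ph$posthoc,
      holm_family = ph$family, deltas = ph$wide)
  }

  # (iv) rate change after context vs vds-evoked activity
  if (!is.null(tables$vds)) {
    rd <- report$rates$deltas[, c("animal", "delta")]
    vd <- report$vds$deltas[, c("animal", "delta")]
    both <- merge(rd, vd, by = "animal", suffixes = c("_rate", "_vds"))
    if (nrow(both) >= 3L && stats::var(both$delta_rate) > 0 &&
        stats::var(both$delta_vds) > 0) {
      report$correlation <- c(
        pearsonCorrelation(both$delta_rate, both$delta_vds),
        list(pairs = both))
    }
  }
  class(report) <- "caCohortReport"
  report
}

#' @export
print.caCohortReport <- function(x, ...) {
  cat(sprintf("Cohort report: %s vs %s (alpha = %g)\n", x$groups[1L],
    x$groups[2L], x$alpha))
  blocks <- list(rates = "Spontaneous event rate (pre vs pos)",
    vds = "vds-evoked sums (bas vs vds)", mec = "mec-evoked sums (bas vs mec)")
  for (b in names(blocks)) {
    if (is.null(x[[b]])) next
    cat("\n", blocks[[b]], "\n", sep = "")
    print(x[[b]]$anova)
    ph <- x[[b]]$posthoc
    for (i in seq_len(nrow(ph))) {
      cat(sprintf("  post hoc %-6s %s: t(%.4g) = %.3f, p = %.4g (adj %.4g)%s\n",
        ph$group[i], ph$comparison[i], ph$df[i], ph$t[i], ph$p[i],
        ph$p_adjusted[i], ifelse(ph$reject[i], " *", "")))
    }
    if (b == "rates") {
      w <- x$rates$welch_diff
      cat(sprintf("  pos-pre between groups: Welch t(%.4g) = %.3f, p = %.4g\n",
        w$df, w$statistic, w$p))
    }
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("\nRate change vs vds delta: Pearson r = %.3f, p = %.4g (n = %d)\n",
      x$correlation$r, x$correlation$p, x$correlation$n))
  }
  invisible(x)
}

#' Simulate a cohort and run the full analysis
#'
#' One-call wrapper: \code{\link{simulateCohort}},
#' \code{\link{buildCohortTables}}, \code{\link{analyzeCohort}}.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param seed RNG seed.
#' @param groups two group labels to simulate and compare.
#' @param segments segments per animal.
#' @param ... passed to \code{\link{buildCohortTables}}.
#' @return list with \code{cohort}, \code{tables}, \code{report}.
#' @export
analyzeSimulatedCohort <- function(cfg = simulationConfig(),
                                   seed = cfg$seed,
                                   groups = c("NAIVE", "TR"),
                                   segments = cfg$segments, ...) {
  cohort <- simulateCohort(cfg, seed = seed, groups = groups,
    segments = segments)
  tables <- buildCohortTables(cohort, ...)
  report <- analyzeCohort(tables, groups = groups)
  list(cohort = cohort, tables = tables, report = report)
}
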