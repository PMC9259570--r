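# End-to-end orchestration: simulate -> process -> detect -> evoke ->
# patterns -> stats, persisted as one reproducible run.

#' Run the full analysis pipeline into a run directory
#'
#' Simulation-backed mode (default): simulates a cohort, writes every
#' trace and ground-truth table, runs event detection, evoked sums and the
#' group statistics, optionally simulates one movie and runs the spatial
#' pattern stage, and writes a manifest capturing config, seed, package
#' version and per-stage counts. Deterministic given the seed.
#'
#' File-backed mode: when \code{inputMovie} is given (with
#' \code{inputRoi} and \code{inputAnnotations}), the pipeline instead
#' reads the movie, ROI and segment annotations, extracts per-segment
#' traces and runs the single-animal stages (no group statistics). All
#' input paths are validated before any computation.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param outDir run directory (created; must not exist or be empty).
#' @param seed RNG seed for the whole run.
#' @param groups cohort groups to simulate and compare.
#' @param patterns run the movie/spatial-pattern stage (simulation mode).
#' @param inputMovie,inputRoi,inputAnnotations paths for file-backed mode.
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(cfg = simulationConfig(), outDir, seed = cfg$seed,
                        groups = c("NAIVE", "TR"), patterns = TRUE,
                        inputMovie = NULL, inputRoi = NULL,
                        inputAnnotations = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  fileMode <- !is.null(inputMovie)
  if (fileMode) {
    for (p in c(inputMovie, inputRoi, inputAnnotations)) {
      .assert(!is.null(p) && file.exists(p),
        sprintf("pipeline input not found: '%s'",
          if (is.null(p)) "(missing path)" else p))
    }
  }
  if (dir.exists(outDir) && length(list.files(outDir))) {
    stop(sprintf("output directory '%s' exists and is not empty", outDir),
      call. = FALSE)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("traces", "truth", "tables", "patterns")) {
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  }
  writeConfigYaml(cfg, file.path(outDir, "config.yaml"))
  manifest <- list(package = "caevents",
    version = as.character(utils::packageVersion("caevents")),
    seed = as.integer(seed), mode = if (fileMode) "files" else "simulation",
    groups = groups, stages = list())

  if (fileMode) {
    say("reading movie %s", inputMovie)
    movie <- readMovie(inputMovie, frameRate = cfg$frame_rate_hz)
    roi <- readRoiMask(inputRoi, frameDims(movie))
    anns <- readAnnotationsCsv(inputAnnotations)
    motionQc(movie)
    recs <- lapply(anns, function(a) extractRoiTrace(movie, roi, a))
    names(recs) <- vapply(anns, function(a) a@label, character(1L))
    for (seg in names(recs)) {
      writeTraceCsv(recs[[seg]], file.path(outDir, "traces",
        sprintf("input_%s.csv", seg)))
    }
    pr <- processRecording(recs, animal = "input")
    writeEventsCsv(pr$events, file.path(outDir, "events.csv"))
    if (!is.null(pr$rates)) {
      utils::write.csv(pr$rates, file.path(outDir, "tables", "rates.csv"),
        row.names = FALSE)
    }
    if (!is.null(pr$evoked)) {
      utils::write.csv(pr$evoked, file.path(outDir, "tables", "evoked.csv"),
        row.names = FALSE)
    }
    manifest$stages$traces <- length(recs)
    manifest$stages$events <- nrow(pr$events)
    say("detected %d events in %d segments", nrow(pr$events), length(recs))
  } else {
    say("simulating cohort (groups: %s)", paste(groups, collapse = ", "))
    cohort <- simulateCohort(cfg, seed = seed, groups = groups)
    nTr <- 0L
    truthAll <- NULL
    for (an in cohort$animals) {
      for (seg in names(an$recordings)) {
        writeTraceCsv(an$recordings[[seg]]$trace, file.path(outDir,
          "traces", sprintf("%s_%s.csv", an$id, seg)))
        tt <- an$recordings[[seg]]$truth
        if (nrow(tt)) {
          tt$animal <- an$id
          tt$segment <- seg
          truthAll <- rbind(truthAll, tt)
        }
        nTr <- nTr + 1L
      }
    }
    if (!is.null(truthAll)) {
      utils::write.csv(truthAll, file.path(outDir, "truth", "events.csv"),
        row.names = FALSE)
    }
    say("processing %d traces", nTr)
    tables <- buildCohortTables(cohort)
    writeEventsCsv(tables$events, file.path(outDir, "events.csv"))
    for (nm in c("rates", "vds", "mec")) {
      if (!is.null(tables[[nm]])) {
        utils::write.csv(tables[[nm]],
          file.path(outDir, "tables", sprintf("%s.csv", nm)),
          row.names = FALSE)
      }
    }
    say("running group statistics")
    report <- analyzeCohort(tables, groups = groups)
    .writeReport(report, outDir)
    manifest$stages$traces <- nTr
    manifest$stages$events <- nrow(tables$events)
    manifest$stages$animals <- length(cohort$animals)

    if (patterns) {
      say("simulating movie and extracting spatial patterns")
      sm <- simulateMovie(cfg, seed = .deriveSeed(seed, 999L))
      binned <- bin2x2(sm$movie)
      binnedRoi <- bin2x2(sm$roi)
      norm <- pixelwiseDff(binned,
        windowFrames = min(400L, nFrames(binned)))
      pk <- sm$truth$peak_frame %/% 1L
      pk <- pk[pk >= 1 & pk <= nFrames(binned) - 2L]
      if (length(pk) >= cfg$n_motifs) {
        pats <- lapply(seq_along(pk), function(i) {
          extractPattern(norm, pk[i], binnedRoi,
            source = sprintf("event_%d", i))
        })
        cl <- clusterPatterns(pats, k = cfg$n_motifs,
          seed = .deriveSeed(seed, 1000L))
        writePatterns(pats, file.path(outDir, "patterns", "patterns.tif"),
          file.path(outDir, "patterns", "manifest.csv"),
          labels = clusterLabels(cl))
        manifest$stages$patterns <- length(pats)
        manifest$stages$pattern_k <- cl@k
      } else {
        say("too few movie events for the pattern stage; skipped")
      }
    }
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("run complete: %s", outDir)
  invisible(manifest)
}

# Serialize the cohort report as JSON + a human-readable text file.
.writeReport <- function(report, outDir) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(outDir, "report.txt"))
  ser <- list(groups = report$groups, alpha = report$alpha)
  for (b in c("rates", "vds", "mec")) {
    if (is.null(report[[b]])) next
    an <- report[[b]]$anova
    ser[[b]] <- list(
      anova = as.data.frame(an),
      posthoc = report[[b]]$posthoc,
      holm_family = report[[b]]$holm_family)
    if (b == "rates") {
      w <- report$rates$welch_diff
      ser$rates$welch_diff <- list(t = w$statistic, df = w$df, p = w$p)
    }
  }
  if (!is.null(report$correlation)) {
    ser$correlation <- list(r = report$correlation$r,
      p = report$correlation$p, n = report$correlation$n)
  }
  jsonlite::write_json(ser, file.path(outDir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}
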