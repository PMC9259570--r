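# Reading and writing the standard formats the pipeline touches.
#
# Conventions: frame indices are 0-based, intervals half-open
# [start, end); times in seconds are frame / frame_rate. CSV files use "."
# as the decimal separator regardless of locale, with times printed to
# 3 decimals.

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' Frame-rate and pixel-size metadata are written to a YAML sidecar file
#' (\code{<path>.meta.yaml}) so that \code{\link{readMovie}} can recover
#' them.
#'
#' @param movie a \linkS4class{Movie}; intensities on the 16-bit scale.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeMovie <- function(movie, path) {
  stopifnot(is(movie, "Movie"))
  d <- movie@data
  pages <- lapply(seq_len(dim(d)[1L]), function(t) {
    round(d[t, , ]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(frame_rate_hz = movie@frameRate,
    pixel_size_um = if (is.na(movie@pixelSize)) NULL else movie@pixelSize),
    paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a movie from a single- or multi-page grayscale TIFF
#'
#' @param path TIFF path. If a \code{<path>.meta.yaml} sidecar exists its
#'   \code{frame_rate_hz}/\code{pixel_size_um} entries are used.
#' @param frameRate frame rate in Hz; required when no sidecar is present.
#' @param pixelSize pixel size in micrometres (optional).
#' @return a \linkS4class{Movie}; frames in acquisition order, intensities
#'   rescaled back to the 16-bit range.
#' @export
readMovie <- function(path, frameRate = NULL, pixelSize = NA_real_) {
  .assert(file.exists(path), sprintf("movie file not found: '%s'", path))
  sidecar <- paste0(path, ".meta.yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (is.null(frameRate)) frameRate <- meta$frame_rate_hz
    if (is.na(pixelSize) && !is.null(meta$pixel_size_um)) {
      pixelSize <- meta$pixel_size_um
    }
  }
  .assert(!is.null(frameRate),
    "frameRate missing: pass it explicitly or provide a .meta.yaml sidecar")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    .assert(length(dim(p)) == 2L,
      "non-grayscale TIFF page: expected a single channel per page")
  }
  dims <- vapply(pages, dim, integer(2L))
  .assert(all(dims[1L, ] == dims[1L, 1L]) && all(dims[2L, ] == dims[2L, 1L]),
    "ragged TIFF: pages differ in size")
  arr <- array(0, dim = c(length(pages), dims[1L, 1L], dims[2L, 1L]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * 65535
  Movie(round(arr), frameRate, pixelSize)
}

#' Read an ROI mask from a binary image or a polygon vertex file
#'
#' Binary images (TIFF or PNG) are thresholded at > 0. JSON polygon files
#' must contain a \code{vertices} field: a list of \code{[x, y]} pairs in
#' 0-based pixel coordinates; the polygon is rasterized with the
#' centre-inclusion rule (a pixel belongs to the ROI when its centre,
#' \code{(col - 0.5, row - 0.5)}, falls inside the polygon).
#'
#' @param path mask image (.tif/.tiff/.png) or polygon (.json) path.
#' @param movieShape integer c(H, W) the mask must match.
#' @return an \linkS4class{ROIMask}.
#' @export
readRoiMask <- function(path, movieShape) {
  .assert(file.exists(path), sprintf("ROI file not found: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  h <- movieShape[1L]
  w <- movieShape[2L]
  if (ext %in% c("tif", "tiff", "png")) {
    img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    mask <- img > 0
  } else if (ext == "json") {
    poly <- jsonlite::read_json(path, simplifyVector = TRUE)
    .assert(!is.null(poly$vertices),
      "polygon JSON must contain a 'vertices' field")
    v <- poly$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    .assert(is.matrix(v) && ncol(v) == 2L && nrow(v) >= 3L,
      "'vertices' must be a list of at least 3 [x, y] pairs")
    cx <- rep(seq_len(w) - 0.5, each = h)
    cy <- rep(seq_len(h) - 0.5, times = w)
    inside <- pracma::inpolygon(cx, cy, v[, 1L], v[, 2L],
      boundary = FALSE)
    mask <- matrix(inside, nrow = h, ncol = w)
  } else {
    stop(sprintf("unsupported ROI format '.%s' (use TIFF/PNG or JSON)", ext),
      call. = FALSE)
  }
  .assert(all(dim(mask) == c(h, w)), sprintf(
    "ROI mask shape (%d x %d) does not match the movie frame (%d x %d)",
    nrow(mask), ncol(mask), h, w))
  .assert(any(mask), "ROI mask is empty: no pixel is inside the ROI")
  ROIMask(mask)
}

#' Write an ROI mask as a binary PNG
#' @param roi an \linkS4class{ROIMask}
#' @param path output PNG path
#' @return \code{path}, invisibly
#' @export
writeRoiMask <- function(roi, path) {
  stopifnot(is(roi, "ROIMask"))
  png::writePNG(maskMatrix(roi) * 1, path)
  invisible(path)
}

.eventsHeader <- c("animal", "segment", "onset_frame", "peak_frame",
  "onset_s", "peak_s", "amplitude_pct")

#' Write detected calcium events to CSV
#'
#' Fixed header \code{animal,segment,onset_frame,peak_frame,onset_s,peak_s,
#' amplitude_pct}; times in seconds with 3-decimal precision, amplitudes
#' with 6 decimals, decimal point always "." regardless of locale.
#'
#' @param events data.frame with at least the header columns above.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeEventsCsv <- function(events, path) {
  missing <- setdiff(.eventsHeader, names(events))
  .assert(length(missing) == 0L,
    "events are missing required column(s): ", paste(missing, collapse = ", "))
  out <- events[, .eventsHeader, drop = FALSE]
  lines <- paste(.eventsHeader, collapse = ",")
  if (nrow(out)) {
    lines <- c(lines, sprintf("%s,%s,%d,%d,%.3f,%.3f,%.6f",
      out$animal, out$segment, as.integer(out$onset_frame),
      as.integer(out$peak_frame), out$onset_s, out$peak_s,
      out$amplitude_pct))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read calcium events from CSV
#' @param path CSV path written by \code{\link{writeEventsCsv}}.
#' @return data.frame with the documented event columns.
#' @export
readEventsCsv <- function(path) {
  .assert(file.exists(path), sprintf("events file not found: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.eventsHeader, names(d))
  .assert(length(missing) == 0L, sprintf(
    "events file '%s' is missing required column(s): %s", path,
    paste(missing, collapse = ", ")))
  d
}

#' Write a fluorescence or percent dF/F trace to CSV
#'
#' Columns \code{frame} (0-based) and \code{value}; segment metadata
#' (label, interval, frame rate, stimulus onsets) goes into a commented
#' header line so the trace round-trips losslessly.
#'
#' @param trace a \linkS4class{FluorescenceTrace} or \linkS4class{DffTrace}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTraceCsv <- function(trace, path) {
  ann <- segmentInfo(trace)
  extra <- if (is(trace, "DffTrace")) {
    sprintf(" type=dff f0=%.9g band=%.6g;%.6g", trace@f0,
      trace@filterBand[1L], trace@filterBand[2L])
  } else " type=raw"
  meta <- sprintf(
    "# label=%s start_frame=%d end_frame=%d frame_rate_hz=%.6g stim_onsets=%s stim_duration_s=%.6g%s",
    ann@label, ann@startFrame, ann@endFrame, frameRate(trace),
    if (length(ann@stimulusOnsets)) {
      paste(ann@stimulusOnsets, collapse = ";")
    } else "NA",
    ann@stimulusDuration, extra)
  v <- traceValues(trace)
  lines <- c(meta, "frame,value",
    sprintf("%d,%.9g", seq_along(v) - 1L + ann@startFrame, v))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trace CSV written by \code{\link{writeTraceCsv}}
#' @param path CSV path.
#' @return a \linkS4class{FluorescenceTrace}, or a \linkS4class{DffTrace}
#'   when the file was written from one (the metadata line records the type,
#'   baseline F0 and filter band).
#' @export
readTraceCsv <- function(path) {
  .assert(file.exists(path), sprintf("trace file not found: '%s'", path))
  first <- readLines(path, n = 1L)
  .assert(startsWith(first, "# label="),
    sprintf("trace file '%s' lacks the metadata header line", path))
  kv <- strsplit(sub("^# ", "", first), " ")[[1L]]
  meta <- stats::setNames(
    sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(c("frame", "value"), names(d))
  .assert(length(missing) == 0L, sprintf(
    "trace file '%s' is missing required column(s): %s", path,
    paste(missing, collapse = ", ")))
  onsets <- if (meta[["stim_onsets"]] == "NA") integer(0) else
    as.integer(strsplit(meta[["stim_onsets"]], ";")[[1L]])
  ann <- SegmentAnnotation(meta[["label"]],
    as.integer(meta[["start_frame"]]), as.integer(meta[["end_frame"]]),
    stimulusOnsets = onsets,
    stimulusDuration = as.numeric(meta[["stim_duration_s"]]))
  fs <- as.numeric(meta[["frame_rate_hz"]])
  if (!is.na(meta["type"]) && meta[["type"]] == "dff") {
    band <- as.numeric(strsplit(meta[["band"]], ";")[[1L]])
    new("DffTrace", values = d$value, f0 = as.numeric(meta[["f0"]]),
      frameRate = fs, filterBand = band, segment = ann)
  } else {
    FluorescenceTrace(d$value, fs, ann)
  }
}

#' Write segment annotations to CSV
#' @param annotations list of \linkS4class{SegmentAnnotation}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationsCsv <- function(annotations, path) {
  rows <- vapply(annotations, function(a) {
    sprintf("%s,%d,%d,%s,%.6g", a@label, a@startFrame, a@endFrame,
      if (length(a@stimulusOnsets)) {
        paste(a@stimulusOnsets, collapse = ";")
      } else "NA",
      a@stimulusDuration)
  }, character(1L))
  writeLines(c("label,start_frame,end_frame,stim_onsets,stim_duration_s",
    rows), path)
  invisible(path)
}

#' Read segment annotations from CSV
#' @param path CSV path written by \code{\link{writeAnnotationsCsv}}.
#' @return list of \linkS4class{SegmentAnnotation}.
#' @export
readAnnotationsCsv <- function(path) {
  .assert(file.exists(path), sprintf("annotation file not found: '%s'", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = c(stim_onsets = "character"))
  missing <- setdiff(c("label", "start_frame", "end_frame", "stim_onsets",
    "stim_duration_s"), names(d))
  .assert(length(missing) == 0L, sprintf(
    "annotation file '%s' is missing required column(s): %s", path,
    paste(missing, collapse = ", ")))
  lapply(seq_len(nrow(d)), function(i) {
    onsets <- if (is.na(d$stim_onsets[i]) || d$stim_onsets[i] == "NA") {
      integer(0)
    } else as.integer(strsplit(d$stim_onsets[i], ";")[[1L]])
    SegmentAnnotation(d$label[i], d$start_frame[i], d$end_frame[i],
      stimulusOnsets = onsets, stimulusDuration = d$stim_duration_s[i])
  })
}

#' Write a simulation / pipeline configuration as YAML
#' @param cfg a \code{SimulationConfig} (or plain list)
#' @param path output YAML path
#' @return \code{path}, invisibly
#' @export
writeConfigYaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$motif_centers <- if (!is.null(x$motif_centers)) {
    apply(x$motif_centers, 1L, as.list, simplify = FALSE)
  }
  for (f in c("segment_durations_s", "planted_rate_delta_hz",
              "vds_evoked_amplitude_pct", "mec_evoked_amplitude_pct",
              "n_per_group")) {
    # yaml drops names on atomic vectors; write named fields as maps
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#' @param path YAML path
#' @return a validated \code{SimulationConfig}
#' @export
readConfigYaml <- function(path) {
  .assert(file.exists(path), sprintf("config file not found: '%s'", path))
  x <- yaml::read_yaml(path)
  if (!is.null(x$motif_centers)) {
    x$motif_centers <- do.call(rbind, lapply(x$motif_centers, unlist))
  }
  for (f in c("segment_durations_s", "planted_rate_delta_hz",
              "vds_evoked_amplitude_pct", "mec_evoked_amplitude_pct",
              "n_per_group")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  do.call(simulationConfig, x)
}

#' Gross-motion quality-control check
#'
#' Flags frame-to-frame jumps of the whole-frame mean absolute intensity
#' difference: a spike above \code{median + nmads * mad} suggests residual
#' x-y motion. The check only warns; segments that cannot be stabilized
#' upstream should be discarded rather than corrected here.
#'
#' @param movie a \linkS4class{Movie} (assumed already motion-corrected).
#' @param nmads spike threshold in robust SDs (default 8).
#' @return integer vector of 0-based frame indices flagged (invisibly);
#'   emits a warning when any frame is flagged.
#' @export
motionQc <- function(movie, nmads = 8) {
  d <- movie@data
  nF <- dim(d)[1L]
  if (nF < 3L) return(invisible(integer(0)))
  m <- matrix(d, nrow = nF)
  fd <- rowMeans(abs(m[-1L, , drop = FALSE] - m[-nF, , drop = FALSE]))
  thr <- stats::median(fd) + nmads * stats::mad(fd)
  bad <- which(fd > thr)
  if (length(bad)) {
    warning(sprintf(
      "possible gross frame-to-frame motion at %d frame transition(s): %s",
      length(bad), paste(utils::head(bad, 10L), collapse = ", ")),
      call. = FALSE)
  }
  invisible(as.integer(bad))
}
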