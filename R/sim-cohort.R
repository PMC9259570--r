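# Whole-cohort simulation with known group-level ground truth.

#' Simulate a cohort of animals with planted group effects
#'
#' Generates, for every animal of every requested group, one
#' \code{\link{simulateTraceSegment}} recording per segment. Trained (TR)
#' animals carry the planted post-context event-rate increase and the
#' suppressed vds-evoked response; NAIVE and cycloheximide-treated (TR_CHX)
#' animals carry neither effect, and the mec-evoked response is identical
#' across groups.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param seed RNG seed; every animal/segment gets a deterministic sub-seed,
#'   so a fixed seed reproduces the cohort exactly.
#' @param groups group labels to include (default: all with
#'   \code{n_per_group > 0}).
#' @param segments segments to simulate per animal (default
#'   \code{cfg$segments}).
#' @return list of class \code{"SimulatedCohort"} with elements
#'   \code{animals} (named list; each animal is a list with \code{group} and
#'   per-segment \code{recordings}, each a \code{list(trace, truth)}),
#'   \code{groups}, \code{segments}, \code{config}, and \code{planted}
#'   (data.frame of planted per-group rate deltas and evoked amplitudes).
#' @export
simulateCohort <- function(cfg, seed = cfg$seed,
                           groups = NULL, segments = cfg$segments) {
  if (is.null(groups)) {
    groups <- cfg$group_labels[cfg$n_per_group[cfg$group_labels] > 0]
  }
  .assert(all(groups %in% cfg$group_labels), "unknown group label")
  .assert(all(cfg$n_per_group[groups] >= 2L),
    "n_per_group must be >= 2 for every simulated group ",
    "(group statistics are undefined otherwise)")
  counter <- 0L
  animals <- list()
  for (g in groups) {
    for (i in seq_len(cfg$n_per_group[[g]])) {
      id <- sprintf("%s_%02d", g, i)
      recs <- list()
      for (s in segments) {
        counter <- counter + 1L
        recs[[s]] <- simulateTraceSegment(cfg, s, group = g,
          seed = .deriveSeed(seed, counter))
      }
      animals[[id]] <- list(id = id, group = g, recordings = recs)
    }
  }
  planted <- data.frame(group = groups,
    rate_delta_hz = unname(cfg$planted_rate_delta_hz[groups]),
    vds_amplitude_pct = unname(cfg$vds_evoked_amplitude_pct[groups]),
    mec_amplitude_pct = unname(cfg$mec_evoked_amplitude_pct[groups]),
    stringsAsFactors = FALSE)
  structure(list(animals = animals, groups = groups, segments = segments,
    config = cfg, planted = planted), class = "SimulatedCohort")
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat(sprintf("SimulatedCohort: %d animals (%s), segments: %s\n",
    length(x$animals),
    paste(sprintf("%s n=%d", x$groups,
      unname(x$config$n_per_group[x$groups])), collapse = ", "),
    paste(x$segments, collapse = ", ")))
  invisible(x)
}
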