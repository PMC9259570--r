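# The group-level statistical design: mixed ANOVA omnibus, pairwise
# t-tests with Holm-Bonferroni correction (one-tailed paired t for
# stimulus-evoked transients, Welch adjustment for unequal n), and Pearson
# correlation.

#' Two-by-two mixed-design ANOVA
#'
#' Classical mixed-model decomposition for one between-subjects factor
#' (group) and one within-subjects factor (period), each with two levels:
#' the between-subjects sum of squares splits into the group effect and
#' subjects-within-groups error; the within-subjects sum of squares splits
#' into period, group x period, and period x subjects error; F ratios are
#' formed against the matching error terms. Groups may have unequal sizes.
#' Fitted via \code{stats::aov} with an \code{Error(animal)} stratum, which
#' realizes exactly this decomposition.
#'
#' @param table data.frame with columns \code{animal}, \code{group},
#'   \code{period}, \code{value}; every animal must appear in exactly one
#'   group and contribute both period levels.
#' @param between,within column names of the between- and within-subject
#'   factors (defaults \code{"group"}, \code{"period"}).
#' @param value column name of the measurement.
#' @return data.frame of class \code{"caAnovaTable"} with one row per
#'   effect (group, period, group:period): \code{ss}, \code{df},
#'   \code{ss_error}, \code{df_error}, \code{F}, \code{p}. The full SS
#'   decomposition (including \code{ss_subjects}, \code{ss_within_error}
#'   and \code{ss_total}) is attached as attributes.
#' @export
mixedAnova2x2 <- function(table, between = "group", within = "period",
                          value = "value") {
  d <- data.frame(animal = factor(table[["animal"]]),
    group = factor(table[[between]]), period = factor(table[[within]]),
    value = as.numeric(table[[value]]))
  .assert(nlevels(d$group) == 2L, "the between factor must have 2 levels")
  .assert(nlevels(d$period) == 2L, "the within factor must have 2 levels")
  tab <- table(d$animal, d$period)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[rowSums(tab != 1L) > 0][1L]
    stop(sprintf(
      "animal '%s' does not contribute exactly one value per period", bad),
      call. = FALSE)
  }
  gPerAnimal <- rowSums(table(d$animal, d$group) > 0)
  .assert(all(gPerAnimal == 1L), "each animal must belong to exactly one group")

  fit <- stats::aov(value ~ group * period + Error(animal), data = d)
  s <- summary(fit)
  between_ <- as.data.frame(s[["Error: animal"]][[1L]])
  within_ <- as.data.frame(s[["Error: Within"]][[1L]])
  rn <- function(x) trimws(rownames(x))
  ssB <- between_[, "Sum Sq"]
  ssW <- within_[, "Sum Sq"]
  out <- data.frame(
    effect = c("group", "period", "group:period"),
    ss = c(ssB[rn(between_) == "group"],
      ssW[rn(within_) == "period"],
      ssW[rn(within_) == "group:period"]),
    df = c(between_[rn(between_) == "group", "Df"],
      within_[rn(within_) == "period", "Df"],
      within_[rn(within_) == "group:period", "Df"]),
    ss_error = c(ssB[rn(between_) == "Residuals"],
      rep(ssW[rn(within_) == "Residuals"], 2L)),
    df_error = c(between_[rn(between_) == "Residuals", "Df"],
      rep(within_[rn(within_) == "Residuals", "Df"], 2L)),
    stringsAsFactors = FALSE)
  out$F <- (out$ss / out$df) / (out$ss_error / out$df_error)
  out$p <- stats::pf(out$F, out$df, out$df_error, lower.tail = FALSE)
  attr(out, "ss_subjects") <- ssB[rn(between_) == "Residuals"]
  attr(out, "ss_within_error") <- ssW[rn(within_) == "Residuals"]
  attr(out, "ss_total") <- sum((d$value - mean(d$value))^2)
  class(out) <- c("caAnovaTable", "data.frame")
  out
}

#' @export
print.caAnovaTable <- function(x, ...) {
  cat("Mixed-design ANOVA (2 x 2)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-13s F(%d,%d) = %.3f, p = %.4g\n", x$effect[i],
      x$df[i], x$df_error[i], x$F[i], x$p[i]))
  }
  invisible(x)
}

#' t-test with explicit tail, pairing and Welch flags
#'
#' Wraps \code{stats::t.test}. For unpaired comparisons the Welch
#' (unequal-variance) statistic with Welch--Satterthwaite degrees of
#' freedom is used by default whenever the sample sizes differ.
#'
#' @param x,y numeric samples.
#' @param paired paired test (requires equal lengths).
#' @param tail \code{"two"}, \code{"greater"} (x > y expected) or
#'   \code{"less"}.
#' @param welch Welch adjustment for unpaired tests; default: TRUE when
#'   sample sizes differ.
#' @return list of class \code{"caTestResult"}: \code{statistic},
#'   \code{df} (possibly fractional), \code{p}, \code{tail}, \code{paired},
#'   \code{welch}.
#' @export
tTest <- function(x, y, paired = FALSE, tail = c("two", "greater", "less"),
                  welch = NULL) {
  tail <- match.arg(tail)
  if (paired) {
    .assert(length(x) == length(y) && length(x) >= 2L,
      "paired test requires equal-length samples of size >= 2")
    welch <- FALSE
  } else {
    .assert(length(x) >= 2L && length(y) >= 2L,
      "each sample must have at least 2 values")
    if (is.null(welch)) welch <- length(x) != length(y)
  }
  alt <- switch(tail, two = "two.sided", greater = "greater", less = "less")
  if (paired && stats::var(x - y) == 0) {
    # identical paired samples: no effect and no variability around it
    if (mean(x - y) == 0) {
      return(structure(list(statistic = 0, df = length(x) - 1L,
        p = if (tail == "two") 1 else 0.5, tail = tail, paired = TRUE,
        welch = FALSE), class = "caTestResult"))
    }
    stop("undefined t statistic: constant nonzero paired differences",
      call. = FALSE)
  }
  ht <- tryCatch(
    stats::t.test(x, y, paired = paired, var.equal = !welch && !paired,
      alternative = alt),
    error = function(e) {
      stop("undefined t statistic: zero variance with equal means ",
        "(data are essentially constant)", call. = FALSE)
    })
  structure(list(statistic = unname(ht$statistic),
    df = unname(ht$parameter), p = ht$p.value, tail = tail,
    paired = paired, welch = isTRUE(welch)), class = "caTestResult")
}

#' @export
print.caTestResult <- function(x, ...) {
  cat(sprintf("%s%st-test (%s-tailed): t(%.4g) = %.3f, p = %.4g\n",
    if (x$welch) "Welch " else "", if (x$paired) "paired " else "",
    if (x$tail == "two") "two" else "one", x$df, x$statistic, x$p))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and compares the i-th smallest against
#' \code{alpha / (m - i + 1)}, stopping at the first failure; every later
#' hypothesis is retained. Adjusted p-values are the running maximum of
#' \code{(m - i + 1) * p_(i)}, capped at 1 (identical to
#' \code{stats::p.adjust(method = "holm")}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha familywise error level (default 0.05).
#' @return data.frame with \code{p}, \code{p_adjusted}, \code{reject}, in
#'   the input order.
#' @export
holmBonferroni <- function(p, alpha = 0.05) {
  .assert(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] < alpha / (m - i + 1L)) {
      reject[ord[i]] <- TRUE
    } else {
      break
    }
  }
  data.frame(p = p, p_adjusted = stats::p.adjust(p, method = "holm"),
    reject = reject)
}

#' Pearson product-moment correlation
#'
#' Wraps \code{stats::cor.test}; the p-value comes from the exact t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 3, nonzero variance).
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearsonCorrelation <- function(x, y) {
  .assert(length(x) == length(y), "x and y must have equal length")
  .assert(length(x) >= 3L, "Pearson correlation needs n >= 3")
  .assert(stats::var(x) > 0 && stats::var(y) > 0,
    "Pearson correlation is undefined for zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}
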