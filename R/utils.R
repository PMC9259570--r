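# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
.deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + 101 * k) %% 2147483629)
}

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(..., call. = call.)
  invisible(TRUE)
}

.framesFromSeconds <- function(seconds, frameRateHz) {
  as.integer(round(seconds * frameRateHz))
}

# Centered moving average with shrinking windows at the edges.
.rollMeanCentered <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  half <- (window - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (window - 1L - half))
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Population standard deviation (divisor n, not n - 1).
.popSd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Separable 2D Gaussian blur, reflect boundary. Kernel truncated at 3 sigma.
.gaussianBlur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    # reflect padding (no edge repeat), clamp for very short vectors
    idx <- c(pmin(n, pmax(1L, (r + 1):2)), 1:n, pmin(n, pmax(1L, (n - 1):(n - r))))
    vp <- v[idx]
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  out <- apply(m, 2L, blur1)
  t(apply(out, 1L, blur1))
}

.segmentLabels <- c("pre", "ctx", "pos", "vds", "posvds", "mec")
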