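#' Nearest-rank percentile
#'
#' The smallest observed value `v` such that at least `p` of the data are
#' `<= v` (inverse empirical CDF, no interpolation). Thresholds derived from
#' read counts stay on the integer bp grid and are reproducible across
#' platforms.
#'
#' @param x numeric vector, length >= 1.
#' @param p probability in (0, 1].
#' @return a single value from `x`.
#' @export
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1L, is.numeric(p), length(p) == 1L, p > 0, p <= 1)
  sort(x, method = "quick")[ceiling(p * length(x))]
}

#' Lower-middle median
#'
#' Median taking the lower of the two middle values for even-length input, so
#' interval endpoint estimates stay on observed coordinates.
#' @param x numeric vector.
#' @return a single value from `x`.
#' @keywords internal
median_lower <- function(x) {
  n <- length(x)
  stopifnot(n >= 1L)
  sort(x, method = "quick")[floor((n + 1L) / 2L)]
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps (seed, tag) to an integer in [1, 2^31 - 2] so every
#' stochastic stage of a run draws from its own stream while a single master
#' seed fixes the whole run.
#'
#' @param seed master integer seed.
#' @param tag character scalar naming the stage (and pool, etc.).
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647               # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer((abs(seed) %% m + h) %% (m - 1L) + 1L)
}

#' Weighted median of run-length encoded values
#' @param values run values.
#' @param lengths run lengths (non-negative).
#' @return weighted (lower) median.
#' @keywords internal
weighted_median_rle <- function(values, lengths) {
  keep <- lengths > 0
  values <- values[keep]; lengths <- as.numeric(lengths[keep])
  stopifnot(length(values) >= 1L)
  o <- order(values)
  values <- values[o]; lengths <- lengths[o]
  cum <- cumsum(lengths)
  total <- cum[length(cum)]
  values[which(cum >= total / 2)[1L]]
}

# internal: abort with a classed condition so callers/tests can match on class
cnd_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "cnvdisplace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
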