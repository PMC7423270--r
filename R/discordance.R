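#' Fit a per-pool insert-size profile
#'
#' Summarizes the outer-insert-size distribution of a pool's inward-facing
#' (properly oriented) read pairs and derives the distant-pair threshold as
#' the upper first percentile: the smallest insert value v such that at least
#' 99% of inward inserts are <= v (nearest-rank, no interpolation). Everted
#' and same-strand pairs are excluded from the fit so structural-variant
#' signal cannot inflate the threshold.
#'
#' @param pairs read-pair table (see [simulate_pool_reads()]).
#' @param pool_id optional pool label; defaults to the table's single pool.
#' @return object of class `insert_profile`: pool_id, n_pairs, mean, sd,
#'   upper1pct.
#' @export
fit_insert_profile <- function(pairs, pool_id = NULL) {
  pairs <- as.data.table(pairs)
  if (is.null(pool_id)) {
    pool_id <- unique(pairs$pool)
    if (length(pool_id) != 1L)
      cnd_stop("pairs contain several pools; give pool_id explicitly",
               "cnv_usage_error")
  } else {
    pairs <- pairs[pool == pool_id]
  }
  ins <- pairs[orientation == "INWARD", insert]
  if (length(ins) < 100L)
    cnd_stop(sprintf("pool %s: %d inward pairs; >= 100 required for an insert-size fit",
                     pool_id, length(ins)), "cnv_fit_error")
  widths <- pairs[orientation == "INWARD", left_end - left_start]
  structure(list(pool_id = as.character(pool_id), n_pairs = length(ins),
                 mean = mean(ins), sd = sd(ins),
                 upper1pct = nearest_rank(ins, 0.99),
                 read_length = as.integer(median_lower(widths))),
            class = "insert_profile")
}

#' @export
print.insert_profile <- function(x, ...) {
  cat(sprintf("insert_profile[%s]: n=%d mean=%.1f sd=%.1f upper1pct=%d\n",
              x$pool_id, x$n_pairs, x$mean, x$sd, as.integer(x$upper1pct)))
  invisible(x)
}

#' Classify read pairs as proper, distant, everted or other
#'
#' Pure, order-independent classification: everted orientation is
#' tandem-duplication evidence regardless of insert size; inward pairs whose
#' outer insert strictly exceeds the pool's upper-1% threshold are distant
#' (deletion evidence); remaining inward pairs are proper; same-strand pairs
#' are other and ignored downstream.
#'
#' @param pairs read-pair table for one pool.
#' @param profile matching `insert_profile`.
#' @return character vector ("PROPER"/"DISTANT"/"EVERTED"/"OTHER"), one per
#'   pair.
#' @export
classify_pairs <- function(pairs, profile) {
  stopifnot(inherits(profile, "insert_profile"))
  pairs <- as.data.table(pairs)
  if (nrow(pairs) > 0L && !all(pairs$pool == profile$pool_id))
    cnd_stop(sprintf("profile is for pool %s but pairs contain other pools",
                     profile$pool_id), "cnv_usage_error")
  cls <- rep("OTHER", nrow(pairs))
  cls[pairs$orientation == "EVERTED"] <- "EVERTED"
  inward <- pairs$orientation == "INWARD"
  cls[inward] <- ifelse(pairs$insert[inward] > profile$upper1pct,
                        "DISTANT", "PROPER")
  cls
}

#' Partition a pool's pairs into discordant streams
#'
#' @param pairs read-pair table for one pool.
#' @param profile matching `insert_profile`.
#' @return list with elements `distant`, `everted` (data.tables) and `counts`
#'   (named integer vector over all four classes).
#' @export
extract_discordant <- function(pairs, profile) {
  pairs <- as.data.table(pairs)
  cls <- classify_pairs(pairs, profile)
  counts <- c(PROPER = sum(cls == "PROPER"), DISTANT = sum(cls == "DISTANT"),
              EVERTED = sum(cls == "EVERTED"), OTHER = sum(cls == "OTHER"))
  list(distant = pairs[cls == "DISTANT"], everted = pairs[cls == "EVERTED"],
       counts = counts)
}
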