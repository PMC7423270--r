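# Dual-criterion divergence testing between two pools' CNV catalogues:
# (1) coverage-normalized supporting-pair difference above the empirical 95th
#     percentile of matched loci, and
# (2) local read-depth log2-ratio outside empirical 5th/95th cutoffs from
#     length-matched random unmasked regions,
# with the depth deviation required to implicate the same carrier pool as the
# support imbalance.

#' Length bins for the empirical depth-ratio null
#' @export
depth_length_bins <- function() c(50L, 100L, 150L, 200L, 500L, 1000L,
                                  2000L, 5000L, 8000L)

#' Half-mean-size comparability rule
#'
#' Two calls (on one chromosome, same type) are comparable between two pools
#' when both their start and their end coordinates differ by less than half
#' of their mean size. Vectorized.
#'
#' @param s1,e1,s2,e2 interval coordinates (0-based half-open).
#' @return logical vector.
#' @export
comparable_half_mean <- function(s1, e1, s2, e2) {
  ms <- ((e1 - s1) + (e2 - s2)) / 2
  abs(s1 - s2) < ms / 2 & abs(e1 - e2) < ms / 2
}

#' Match CNV calls between two pools
#'
#' Two calls are comparable when they share chromosome and type and their
#' coordinates differ by less than half of their mean size (both start and
#' end). Each call participates in at most one match: among qualifying
#' partners the pair minimizing `|start_a-start_b| + |end_a-end_b|` wins,
#' ties broken by leftmost coordinates. Unpartnered calls become
#' ONLY_A/ONLY_B loci; the partner pool's depth is still measured over the
#' present call's interval so the depth criterion remains testable.
#'
#' @param cat_a,cat_b `pool_cnv_catalog` objects on the same genome.
#' @param eps pseudocount on normalized depths before the log2 ratio, so
#'   zero-depth homozygous deletions stay representable.
#' @return data.table of matches: locus_id, comparison_id, status
#'   (BOTH/ONLY_A/ONLY_B), per-side call stats, chrom/start/end/size of the
#'   locus (the higher-support side for BOTH), mean_size, delta_support_norm,
#'   depth_log2ratio, depth_usable.
#' @export
match_between_pools <- function(cat_a, cat_b, eps = 0.01) {
  stopifnot(inherits(cat_a, "pool_cnv_catalog"),
            inherits(cat_b, "pool_cnv_catalog"))
  comparison_id <- paste0(cat_a$pool_id, "_vs_", cat_b$pool_id)
  a <- copy(cat_a$calls); b <- copy(cat_b$calls)
  gmd_a <- cat_a$genome_median_depth; gmd_b <- cat_b$genome_median_depth
  pairs <- data.table()
  if (nrow(a) > 0L && nrow(b) > 0L) {
    a2 <- a[, .(chrom, cnv_type, start, end, ia = .I)]
    b2 <- b[, .(chrom, cnv_type, start, end, ib = .I)]
    setkey(b2, chrom, cnv_type, start, end)
    # a BOTH match implies >= 1 bp overlap, so an overlap join is a complete
    # prefilter for the half-mean-size rule
    ov <- foverlaps(a2, b2, type = "any", nomatch = NULL,
                    by.x = c("chrom", "cnv_type", "start", "end"))
    if (nrow(ov) > 0L) {
      setnames(ov, c("start", "end", "i.start", "i.end"),
               c("start_b", "end_b", "start_a", "end_a"))
      ov[, `:=`(size_a = end_a - start_a, size_b = end_b - start_b)]
      ov[, mean_size := (size_a + size_b) / 2]
      ov <- ov[comparable_half_mean(start_a, end_a, start_b, end_b)]
      if (nrow(ov) > 0L) {
        ov[, dist := abs(start_a - start_b) + abs(end_a - end_b)]
        ov[, tie_lo := pmin(start_a, start_b)]
        ov[, tie_hi := pmax(start_a, start_b)]
        setorder(ov, dist, tie_lo, tie_hi)
        used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
        keep <- logical(nrow(ov))
        for (k in seq_len(nrow(ov))) {
          if (!used_a[ov$ia[k]] && !used_b[ov$ib[k]]) {
            keep[k] <- TRUE
            used_a[ov$ia[k]] <- TRUE; used_b[ov$ib[k]] <- TRUE
          }
        }
        pairs <- ov[keep]
      }
    }
  }
  both <- if (nrow(pairs) > 0L) {
    ca <- a[pairs$ia]; cb <- b[pairs$ib]
    carrier_a <- ca$support / gmd_a >= cb$support / gmd_b
    data.table(
      status = "BOTH", chrom = ca$chrom,
      start = ifelse(carrier_a, ca$start, cb$start),
      end = ifelse(carrier_a, ca$end, cb$end),
      cnv_type = ca$cnv_type, mean_size = pairs$mean_size,
      call_a = ca$call_id, call_b = cb$call_id,
      start_a = ca$start, end_a = ca$end, start_b = cb$start, end_b = cb$end,
      support_a = ca$support, support_b = cb$support,
      norm_depth_a = ca$norm_depth, norm_depth_b = cb$norm_depth,
      depth_usable = ca$depth_usable & cb$depth_usable)
  } else data.table()
  only_of <- function(calls, other_track, side) {
    if (nrow(calls) == 0L) return(data.table())
    od <- compute_depth(calls[, .(chrom, start, end)], other_track)
    data.table(
      status = if (side == "a") "ONLY_A" else "ONLY_B",
      chrom = calls$chrom, start = calls$start, end = calls$end,
      cnv_type = calls$cnv_type, mean_size = as.numeric(calls$size),
      call_a = if (side == "a") calls$call_id else NA_character_,
      call_b = if (side == "b") calls$call_id else NA_character_,
      start_a = if (side == "a") calls$start else NA_integer_,
      end_a = if (side == "a") calls$end else NA_integer_,
      start_b = if (side == "b") calls$start else NA_integer_,
      end_b = if (side == "b") calls$end else NA_integer_,
      support_a = if (side == "a") calls$support else 0L,
      support_b = if (side == "b") calls$support else 0L,
      norm_depth_a = if (side == "a") calls$norm_depth else od$norm_depth,
      norm_depth_b = if (side == "b") calls$norm_depth else od$norm_depth,
      depth_usable = calls$depth_usable & od$depth_usable)
  }
  ia_used <- if (nrow(pairs) > 0L) pairs$ia else integer(0)
  ib_used <- if (nrow(pairs) > 0L) pairs$ib else integer(0)
  m <- rbindlist(list(both,
                      only_of(a[!seq_len(nrow(a)) %in% ia_used], cat_b$depth, "a"),
                      only_of(b[!seq_len(nrow(b)) %in% ib_used], cat_a$depth, "b")),
                 use.names = TRUE, fill = TRUE)
  if (nrow(m) == 0L) return(m)
  m[, comparison_id := comparison_id]
  m[, pool_a := cat_a$pool_id]
  m[, pool_b := cat_b$pool_id]
  m[, supnorm_a := support_a / gmd_a]
  m[, supnorm_b := support_b / gmd_b]
  m[, delta_support_norm := abs(supnorm_a - supnorm_b)]
  m[, depth_log2ratio := ifelse(depth_usable,
                                log2((norm_depth_a + eps) /
                                       (norm_depth_b + eps)), NA_real_)]
  setorder(m, chrom, start, end)
  m[, locus_id := paste0(comparison_id, "_", seq_len(.N))]
  m[]
}

#' Sample fixed-length regions uniformly from unmasked sequence
#'
#' Draws regions uniformly at random among every position (on any chromosome)
#' where a region of length `len` fits entirely within unmasked sequence.
#' The caller controls the RNG state.
#'
#' @param genome a `genome_model`.
#' @param len region length (bp).
#' @param n number of regions.
#' @return data.table chrom, start, end.
#' @export
sample_unmasked_regions <- function(genome, len, n) {
  runs <- unmasked_runs(genome)
  cap <- pmax(runs$end - runs$start - len + 1, 0)
  total <- sum(as.numeric(cap))
  if (total < 1)
    cnd_stop(sprintf("no unmasked stretch can hold a region of %d bp", len),
             "cnv_placement_error")
  cum <- cumsum(as.numeric(cap))
  u <- floor(runif(n) * total)           # in [0, total)
  ri <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
  off <- u - c(0, cum)[ri]
  data.table(chrom = runs$chrom[ri],
             start = as.integer(runs$start[ri] + off),
             end = as.integer(runs$start[ri] + off + len))
}

# number of distinct valid placements for a region of length len
placement_capacity <- function(genome, len) {
  runs <- unmasked_runs(genome)
  sum(pmax(as.numeric(runs$end - runs$start) - len + 1, 0))
}

#' Build empirical divergence thresholds for one comparison
#'
#' The supporting-pair cutoff is the nearest-rank 95th percentile of the
#' coverage-normalized absolute support differences over loci called in both
#' pools. Depth-ratio cutoffs are estimated per length bin by drawing
#' `n_random` random unmasked regions of exactly that length, measuring the
#' two pools' normalized-depth log2 ratio as for calls, and taking the
#' nearest-rank 5th and 95th percentiles.
#'
#' The support percentile is taken over loci present in both pools when at
#' least `min_both` such loci exist; sparser catalogues (e.g. small genomes
#' with little shared variation) fall back to the percentile over all matched
#' loci, recorded in the returned object's `support_cutoff_basis`.
#'
#' @param matches output of [match_between_pools()].
#' @param cat_a,cat_b the two catalogues.
#' @param genome a `genome_model`.
#' @param n_random random regions per length bin.
#' @param seed integer seed (deterministic thresholds for a fixed seed).
#' @param eps pseudocount, as in [match_between_pools()].
#' @param min_both minimum BOTH loci for the BOTH-based support percentile.
#' @return object of class `divergence_thresholds`.
#' @export
build_thresholds <- function(matches, cat_a, cat_b, genome,
                             n_random = 10000L, seed = 1L, eps = 0.01,
                             min_both = 20L) {
  if (nrow(matches) == 0L)
    cnd_stop("no matched loci; cannot build divergence thresholds",
             "cnv_threshold_error")
  both <- matches[status == "BOTH"]
  if (nrow(both) >= min_both) {
    support_cutoff <- nearest_rank(both$delta_support_norm, 0.95)
    basis <- "both_matches"
  } else {
    support_cutoff <- nearest_rank(matches$delta_support_norm, 0.95)
    basis <- "all_matches"
  }
  set.seed(seed)
  bins <- depth_length_bins()
  regions <- vector("list", length(bins))
  for (i in seq_along(bins)) {
    len <- bins[i]
    if (placement_capacity(genome, len) < 100)
      cnd_stop(sprintf("length bin %d bp: fewer than 100 sampleable unmasked regions",
                       len), "cnv_threshold_error")
    regions[[i]] <- sample_unmasked_regions(genome, len, n_random)[, bin := len]
  }
  regions <- rbindlist(regions)
  da <- compute_depth(regions, cat_a$depth)
  db <- compute_depth(regions, cat_b$depth)
  regions[, ratio := log2((da$norm_depth + eps) / (db$norm_depth + eps))]
  cuts_dt <- regions[!is.na(ratio),
                     .(low = nearest_rank(ratio, 0.05),
                       high = nearest_rank(ratio, 0.95)), by = bin]
  cuts <- list(cuts_dt[order(bin)])
  structure(list(comparison_id = matches$comparison_id[1L],
                 support_cutoff = support_cutoff,
                 support_cutoff_basis = basis,
                 depth_cutoffs = rbindlist(cuts),
                 n_random = n_random, seed = seed, eps = eps),
            class = "divergence_thresholds")
}

# bin assignment: the bin minimizing |size - bin|, ties to the smaller bin
assign_length_bin <- function(sizes, bins = depth_length_bins()) {
  idx <- apply(abs(outer(as.numeric(sizes), as.numeric(bins), "-")), 1L,
               which.min)
  bins[idx]
}

#' Apply the dual significance criteria to matched loci
#'
#' A locus is significantly divergent when (1) its coverage-normalized
#' support difference exceeds the comparison's 95th-percentile cutoff, (2)
#' its depth log2 ratio falls outside the empirical cutoffs for its length
#' bin, and (3) the depth deviation implicates the same carrier pool as the
#' support imbalance (deletions: the carrier pool has lower relative depth;
#' duplications: higher). Loci called in only one pool take support 0 on the
#' absent side and the present call's length bin; significant ONLY loci are
#' fixed presence/absence, significant BOTH loci quantitative frequency
#' differences.
#'
#' @param matches output of [match_between_pools()].
#' @param thresholds matching `divergence_thresholds`.
#' @return data.table: matches columns plus length_bin, support_sig,
#'   depth_sig, concordant, significant, direction (carrier pool id), fixity.
#' @export
test_divergence <- function(matches, thresholds) {
  stopifnot(inherits(thresholds, "divergence_thresholds"))
  div <- copy(as.data.table(matches))
  if (nrow(div) == 0L) return(div)
  if (!identical(div$comparison_id[1L], thresholds$comparison_id))
    cnd_stop("thresholds were built for a different comparison",
             "cnv_usage_error")
  div[, length_bin := assign_length_bin(mean_size)]
  div <- merge(div, thresholds$depth_cutoffs,
               by.x = "length_bin", by.y = "bin", sort = FALSE)
  div[, support_sig := delta_support_norm > thresholds$support_cutoff]
  div[, depth_sig := !is.na(depth_log2ratio) &
        (depth_log2ratio < low | depth_log2ratio > high)]
  # carrier pool inferred from coverage-normalized support imbalance
  div[, carrier_support := fifelse(delta_support_norm == 0, NA_character_,
                                   fifelse(supnorm_a > supnorm_b,
                                           pool_a, pool_b))]
  div[, carrier_depth := fifelse(
    is.na(depth_log2ratio) | depth_log2ratio == 0, NA_character_,
    fifelse(cnv_type == "DEL",
            fifelse(depth_log2ratio < 0, pool_a, pool_b),
            fifelse(depth_log2ratio > 0, pool_a, pool_b)))]
  div[, concordant := !is.na(carrier_support) & !is.na(carrier_depth) &
        carrier_support == carrier_depth]
  div[, significant := support_sig & depth_sig & concordant]
  div[, direction := carrier_support]
  div[, fixity := fifelse(!significant, NA_character_,
                          fifelse(status == "BOTH", "QUANTITATIVE",
                                  "FIXED_PRESENCE_ABSENCE"))]
  div[, c("low", "high", "carrier_depth") := NULL]
  setorder(div, chrom, start, end)
  div[]
}

#' Run one full pairwise comparison
#'
#' Matches two catalogues, builds this comparison's empirical thresholds and
#' applies the dual significance criteria.
#'
#' @inheritParams build_thresholds
#' @return list: `matches`, `thresholds`, `divergence` (all loci with
#'   significance flags), `significant` (significant subset).
#' @export
compare_pools <- function(cat_a, cat_b, genome, n_random = 10000L,
                          seed = 1L, eps = 0.01) {
  matches <- match_between_pools(cat_a, cat_b, eps = eps)
  thresholds <- build_thresholds(matches, cat_a, cat_b, genome,
                                 n_random = n_random, seed = seed, eps = eps)
  div <- test_divergence(matches, thresholds)
  list(matches = matches, thresholds = thresholds, divergence = div,
       significant = div[significant == TRUE])
}
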