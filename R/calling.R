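#' @importFrom IRanges IRanges coverage
#' @importFrom S4Vectors Rle runValue runLength
NULL

# union-find with path halving; edges as integer vectors (from, to)
union_find <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1L))
}

#' Cluster one class of discordant pairs into putative CNV events
#'
#' Single-linkage clustering of a single pool's distant (deletion evidence)
#' or everted (tandem-duplication evidence) pairs. Each pair implies a CNV
#' interval: `[left_end, right_start)` for distant pairs (the unsequenced gap
#' spans the deletion) and `[left_start, right_end)` for everted pairs (both
#' mates sit inside the duplicated segment). Two pairs are linked when their
#' implied intervals overlap by >= 1 bp and corresponding endpoints each
#' differ by at most the pool's upper-1% insert threshold (pairs from one
#' event scatter by at most about one fragment length). Clusters supported by
#' fewer than `min_support` pairs are discarded.
#'
#' @param pairs single-class, single-pool read-pair table.
#' @param profile the pool's `insert_profile`.
#' @param cnv_type "DEL" (distant input) or "DUP" (everted input).
#' @param min_support minimum supporting pairs per retained cluster.
#' @return list: `clusters` (data.table: cluster id, chrom, member stats,
#'   support) with member assignment in `members` (per-pair cluster id, NA =
#'   in a discarded cluster), and `n_discarded` pairs.
#' @export
cluster_discordant <- function(pairs, profile, cnv_type, min_support = 5L) {
  stopifnot(cnv_type %in% c("DEL", "DUP"),
            inherits(profile, "insert_profile"))
  pairs <- as.data.table(pairs)
  if (nrow(pairs) > 0L && length(unique(pairs$orientation)) > 1L)
    cnd_stop("mixed pair classes in cluster_discordant input",
             "cnv_usage_error")
  u <- as.numeric(profile$upper1pct)
  if (cnv_type == "DEL") {
    iv <- pairs[, .(pair_id, chrom, start = left_end, end = right_start)]
  } else {
    iv <- pairs[, .(pair_id, chrom, start = left_start, end = right_end)]
  }
  iv <- iv[end > start]
  if (nrow(iv) == 0L)
    return(list(clusters = data.table(), members = integer(0),
                n_discarded = nrow(pairs)))
  setorder(iv, chrom, start, end)
  iv[, idx := .I]
  # candidate edges: same chrom, start within threshold (two-pointer window)
  edges <- iv[, {
    n <- .N
    if (n >= 2L) {
      hi <- findInterval(start + u, start)
      cnt <- pmax(hi - seq_len(n), 0L)
      from <- rep.int(seq_len(n), cnt)
      to <- sequence(cnt, from = seq_len(n) + 1L)
      keep <- abs(end[to] - end[from]) <= u & start[to] < end[from]
      .(from = idx[from[keep]], to = idx[to[keep]])
    } else .(from = integer(0), to = integer(0))
  }, by = chrom][, .(from, to)]
  comp <- union_find(nrow(iv), edges$from, edges$to)
  iv[, cluster := comp]
  supp <- iv[, .N, by = cluster]
  keep_ids <- supp[N >= min_support, cluster]
  iv[, keep := cluster %in% keep_ids]
  clusters <- iv[keep == TRUE,
                 .(chrom = chrom[1L], support = .N,
                   member_pair_ids = list(pair_id),
                   member_starts = list(start), member_ends = list(end)),
                 by = cluster]
  clusters[, cnv_type := cnv_type]
  list(clusters = clusters,
       members = iv[order(idx)][, ifelse(keep, cluster, NA_integer_)],
       n_discarded = nrow(pairs) - sum(clusters$support))
}

#' Estimate event coordinates from a discordant cluster
#'
#' Median-based, robust to outlier members: for deletions the event is
#' `[median(left_end), median(right_start))` over members; for duplications
#' `[median(left_start), median(right_end))`. Even-cardinality medians take
#' the lower middle value. Clusters whose estimated end does not exceed the
#' start are geometrically unresolvable and dropped.
#'
#' A raw implied interval systematically over-spans a deletion (each
#' supporting pair's unsequenced gap extends past the breakpoints by part of
#' the fragment's sequenced-free length) and under-spans a tandem
#' duplication by the same geometry. `adjust` shrinks deletion estimates and
#' expands duplication estimates by that many bp per side; [call_pool()]
#' sets it to half the pool's mean insert minus read lengths,
#' `(mean_insert - 2 * read_length) / 2`, the expected per-side overhang.
#'
#' @param clusters the `clusters` table from [cluster_discordant()].
#' @param adjust per-side fragment-geometry bias correction in bp
#'   (default 0: plain medians).
#' @return data.table chrom, start, end, cnv_type, support (dropped clusters
#'   removed; attribute `n_unresolvable` counts them).
#' @export
estimate_interval <- function(clusters, adjust = 0L) {
  if (nrow(clusters) == 0L) {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), cnv_type = character(),
                      support = integer())
    setattr(out, "n_unresolvable", 0L)
    return(out)
  }
  out <- clusters[, .(chrom, cnv_type, support,
                      start = vapply(member_starts, median_lower, numeric(1)),
                      end = vapply(member_ends, median_lower, numeric(1)))]
  if (adjust != 0L) {
    out[cnv_type == "DEL", `:=`(start = start + adjust, end = end - adjust)]
    out[cnv_type == "DUP", `:=`(start = pmax(start - adjust, 0),
                                end = end + adjust)]
  }
  n_bad <- sum(out$end <= out$start)
  out <- out[end > start]
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  setcolorder(out, c("chrom", "start", "end", "cnv_type", "support"))
  setattr(out, "n_unresolvable", n_bad)
  out[]
}

#' Per-base read coverage of a pool
#'
#' Builds per-chromosome run-length encoded depth from both mates of every
#' pair, plus the genome-wide median depth over unmasked bases (median, not
#' mean, so CNV-induced depth outliers do not shift the normalizer).
#'
#' @param pairs read-pair table for one pool.
#' @param genome a `genome_model`.
#' @return object of class `depth_track`: list of per-chromosome Rle
#'   (`depth`), per-chromosome 0/1 unmasked Rle (`unmasked`), and
#'   `genome_median` depth over unmasked bases.
#' @export
pool_depth_track <- function(pairs, genome) {
  pairs <- as.data.table(pairs)
  unmasked <- list(); depth_um <- list()
  vals <- list(); lens <- list()
  for (chr in names(genome$chromosomes)) {
    len <- genome$chromosomes[[chr]]
    pc <- pairs[chrom == chr]
    ir <- IRanges(start = c(pc$left_start, pc$right_start) + 1L,
                  end = c(pc$left_end, pc$right_end))
    depth_chr <- coverage(ir, width = len)
    m <- genome$masked[chrom == chr]
    um <- S4Vectors::Rle(1L, len)
    if (nrow(m) > 0L) {
      cov_m <- coverage(IRanges(m$start + 1L, m$end), width = len) == 0L
      um <- S4Vectors::Rle(as.integer(runValue(cov_m)), runLength(cov_m))
    }
    unmasked[[chr]] <- um
    depth_um[[chr]] <- depth_chr * um   # masked bases zeroed
    # unmasked bases per depth run, by prefix sums over the masked set
    # (exact, avoids materializing per-base vectors)
    d_rl <- runLength(depth_chr); d_rv <- runValue(depth_chr)
    ce <- cumsum(as.numeric(d_rl))
    cs <- ce - as.numeric(d_rl)            # run covers (cs, ce], 1-based
    if (nrow(m) > 0L) {
      ms1 <- m$start + 1; me <- m$end      # 1-based closed masked intervals
      cum_w <- cumsum(as.numeric(me - ms1 + 1))
      mprefix <- function(x) {             # masked bases at positions <= x
        i <- findInterval(x, ms1)
        out <- numeric(length(x))
        hit <- i >= 1L
        out[hit] <- cum_w[i[hit]] - pmax(0, me[i[hit]] - x[hit])
        out
      }
      unm <- (ce - cs) - (mprefix(ce) - mprefix(cs))
    } else {
      unm <- ce - cs
    }
    keep <- unm > 0
    vals[[chr]] <- d_rv[keep]; lens[[chr]] <- unm[keep]
  }
  agg <- data.table(v = unlist(vals, use.names = FALSE),
                    l = unlist(lens, use.names = FALSE))[, .(l = sum(l)),
                                                         by = v]
  gm <- weighted_median_rle(agg$v, agg$l)
  structure(list(unmasked = unmasked, depth_um = depth_um,
                 genome_median = gm, prefix = new.env(parent = emptyenv())),
            class = "depth_track")
}

# run-level prefix-sum structure for O(log n) interval sums over an Rle
rle_prefix <- function(r) {
  v <- as.numeric(runValue(r)); l <- as.numeric(runLength(r))
  ce <- cumsum(l)
  list(ce = ce, cp = cumsum(v * l), v = v, n = length(v))
}

# sum of Rle values over 1-based positions (a, b]; a, b vectors
prefix_interval_sum <- function(px, a, b) {
  P <- function(x) {
    i <- findInterval(x, px$ce)
    base <- ifelse(i >= 1L, px$cp[pmax(i, 1L)], 0)
    prev_end <- ifelse(i >= 1L, px$ce[pmax(i, 1L)], 0)
    part <- numeric(length(x))
    partial <- i < px$n & x > prev_end
    part[partial] <- px$v[i[partial] + 1L] * (x[partial] - prev_end[partial])
    base + part
  }
  P(b) - P(a)
}

# drop cached prefix structures (large) from a catalogue's depth track
clear_depth_cache <- function(catalog) {
  if (!is.null(catalog$depth))
    rm(list = ls(catalog$depth$prefix), envir = catalog$depth$prefix)
  invisible(catalog)
}

track_prefix <- function(track, chr, what = c("depth_um", "unmasked")) {
  what <- match.arg(what)
  key <- paste0(what, ".", chr)
  if (is.null(track$prefix[[key]]))
    track$prefix[[key]] <- rle_prefix(track[[what]][[chr]])
  track$prefix[[key]]
}

#' Mean unmasked depth over intervals
#'
#' Mean per-base depth over the unmasked bases of each interval; intervals
#' more than 90% masked are flagged unusable (depth NA). Normalized depth
#' divides by the pool's genome-wide median unmasked depth.
#'
#' @param intervals data.table with chrom, start, end (0-based half-open).
#' @param track a `depth_track`.
#' @return data.table local_depth, norm_depth, depth_usable aligned with
#'   `intervals` rows.
#' @export
compute_depth <- function(intervals, track) {
  stopifnot(inherits(track, "depth_track"))
  intervals <- as.data.table(intervals)
  n <- nrow(intervals)
  local <- rep(NA_real_, n); usable <- rep(FALSE, n)
  for (chr in unique(intervals$chrom)) {
    ii <- which(intervals$chrom == chr)
    if (!chr %in% names(track$depth))
      cnd_stop(paste("depth track does not cover chromosome", chr),
               "cnv_usage_error")
    s <- prefix_interval_sum(track_prefix(track, chr, "depth_um"),
                             intervals$start[ii], intervals$end[ii])
    cnt <- prefix_interval_sum(track_prefix(track, chr, "unmasked"),
                               intervals$start[ii], intervals$end[ii])
    width <- intervals$end[ii] - intervals$start[ii]
    ok <- cnt > 0.1 * width
    local[ii] <- ifelse(ok, s / cnt, NA_real_)
    usable[ii] <- ok
  }
  data.table(local_depth = local, norm_depth = local / track$genome_median,
             depth_usable = usable)
}

#' Call CNVs in one pool
#'
#' Full per-pool pipeline: classify pairs against the pool's insert profile,
#' cluster distant pairs into deletions and everted pairs into tandem
#' duplications (>= `min_support` supporting pairs), estimate event
#' coordinates, drop events smaller than `min_size` (below one read length,
#' pair geometry cannot resolve events), and attach the two allele-frequency
#' proxies: supporting-pair count and normalized local read depth.
#'
#' @param pairs read-pair table for one pool.
#' @param profile the pool's `insert_profile` (fitted if NULL).
#' @param genome a `genome_model`.
#' @param min_support minimum supporting pairs (default 5).
#' @param min_size minimum call size in bp (default 50).
#' @param track optional precomputed `depth_track` for this pool.
#' @return object of class `pool_cnv_catalog`: pool_id, genome_median_depth,
#'   `calls` (sorted data.table: call_id, chrom, start, end, size, cnv_type,
#'   support, local_depth, norm_depth, depth_usable), the `depth` track, and
#'   a `discarded` count ledger.
#' @export
call_pool <- function(pairs, profile = NULL, genome, min_support = 5L,
                      min_size = 50L, track = NULL) {
  pairs <- as.data.table(pairs)
  if (is.null(profile)) profile <- fit_insert_profile(pairs)
  streams <- extract_discordant(pairs, profile)
  cl_del <- cluster_discordant(streams$distant, profile, "DEL", min_support)
  cl_dup <- cluster_discordant(streams$everted, profile, "DUP", min_support)
  rl <- profile$read_length %||% 100L
  adjust <- max(0L, as.integer(round((profile$mean - 2 * rl) / 2)))
  est_del <- estimate_interval(cl_del$clusters, adjust = adjust)
  est_dup <- estimate_interval(cl_dup$clusters, adjust = adjust)
  ests <- rbind(est_del, est_dup)
  n_unres <- attr(est_del, "n_unresolvable") + attr(est_dup, "n_unresolvable")
  n_small <- sum(ests$end - ests$start < min_size)
  calls <- ests[end - start >= min_size]
  if (is.null(track)) track <- pool_depth_track(pairs, genome)
  if (nrow(calls) > 0L) {
    calls <- cbind(calls, compute_depth(calls, track))
  } else {
    calls[, `:=`(local_depth = numeric(0), norm_depth = numeric(0),
                 depth_usable = logical(0))]
  }
  setorder(calls, chrom, start, end)
  calls[, call_id := paste0(profile$pool_id, "_", seq_len(.N))]
  calls[, size := end - start]
  setcolorder(calls, c("call_id", "chrom", "start", "end", "size", "cnv_type",
                       "support", "local_depth", "norm_depth", "depth_usable"))
  structure(list(pool_id = profile$pool_id, profile = profile,
                 genome_median_depth = track$genome_median,
                 calls = calls[], depth = track,
                 discarded = list(
                   unclustered_distant = cl_del$n_discarded,
                   unclustered_everted = cl_dup$n_discarded,
                   unresolvable = n_unres, undersized = n_small)),
            class = "pool_cnv_catalog")
}

#' @export
print.pool_cnv_catalog <- function(x, ...) {
  cat(sprintf("pool_cnv_catalog[%s]: %d calls (%d DEL, %d DUP), median depth %.1f\n",
              x$pool_id, nrow(x$calls), sum(x$calls$cnv_type == "DEL"),
              sum(x$calls$cnv_type == "DUP"), x$genome_median_depth))
  invisible(x)
}
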