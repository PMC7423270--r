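# Masked-genome-aware permutation tests: candidate regions are re-placed
# uniformly at random among all positions (any chromosome) where they fit
# entirely in unmasked sequence, preserving lengths; placements independent.

#' Randomly re-place regions within unmasked sequence
#'
#' @param regions data.table chrom, start, end (each must fit in some
#'   unmasked stretch).
#' @param genome a `genome_model`.
#' @param seed integer seed (deterministic placements for a fixed seed).
#' @return data.table chrom, start, end of re-placed regions (lengths
#'   preserved, order as input).
#' @export
randomize_placement <- function(regions, genome, seed = 1L) {
  regions <- as.data.table(regions)
  set.seed(seed)
  lens <- regions$end - regions$start
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    if (placement_capacity(genome, lens[i]) < 1)
      cnd_stop(sprintf("region %s:[%d,%d) (%d bp) fits in no unmasked stretch",
                       regions$chrom[i], regions$start[i], regions$end[i],
                       lens[i]), "cnv_placement_error")
    out[[i]] <- sample_unmasked_regions(genome, lens[i], 1L)
  }
  rbindlist(out)
}

# batched permutations: n_perm independent placements per region, vectorized
# per distinct region length; returns list of matrices (chrom index, start)
permute_placements <- function(regions, genome, n_perm, seed) {
  set.seed(seed)
  lens <- regions$end - regions$start
  n <- length(lens)
  chrom_idx <- matrix(0L, nrow = n, ncol = n_perm)
  starts <- matrix(0L, nrow = n, ncol = n_perm)
  chroms <- names(genome$chromosomes)
  for (len in sort(unique(lens))) {
    ii <- which(lens == len)
    if (placement_capacity(genome, len) < 1)
      cnd_stop(sprintf("a region of %d bp fits in no unmasked stretch", len),
               "cnv_placement_error")
    draw <- sample_unmasked_regions(genome, len, length(ii) * n_perm)
    chrom_idx[ii, ] <- match(draw$chrom, chroms)
    starts[ii, ] <- draw$start
  }
  list(chrom_idx = chrom_idx, starts = starts, lens = lens)
}

empirical_p <- function(observed, null, tail) {
  n_perm <- length(null)
  p_ge <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_le <- (1 + sum(null <= observed)) / (n_perm + 1)
  switch(tail,
         greater = p_ge,
         less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

permutation_result <- function(statistic_name, observed, null, n_perm, seed,
                               tail) {
  null_mean <- mean(null); null_sd <- sd(null)
  structure(list(statistic_name = statistic_name, observed = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 z = if (isTRUE(null_sd > 0)) (observed - null_mean) / null_sd
                     else NA_real_,
                 degenerate = !isTRUE(null_sd > 0),
                 p_empirical = empirical_p(observed, null, tail),
                 n_perm = n_perm, seed = seed, tail = tail),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s: observed %.4g, null %.4g +/- %.4g, z = %.3f, p = %.4g (%s, %d permutations)\n",
              x$statistic_name, x$observed, x$null_mean, x$null_sd,
              if (is.na(x$z)) NA else x$z, x$p_empirical, x$tail, x$n_perm))
  invisible(x)
}

#' Spatial clustering test for candidate CNVs
#'
#' Statistic: the number of window-aligned bins (default 10 kb) containing
#' the start positions of two or more CNVs. Compared two-sided against the
#' permuted-placement null, so both excess clustering and excess dispersion
#' register.
#'
#' @param cnvs data.table chrom, start, end.
#' @param genome a `genome_model`.
#' @param window bin width, bp.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail "two_sided" (default), "greater" or "less".
#' @return a `permutation_result`.
#' @export
clustering_test <- function(cnvs, genome, window = 10000L, n_perm = 10000L,
                            seed = 1L, tail = "two_sided") {
  cnvs <- as.data.table(cnvs)
  if (nrow(cnvs) < 2L)
    cnd_stop("clustering test needs >= 2 CNVs", "cnv_usage_error")
  chroms <- names(genome$chromosomes)
  # global bin ids: per-chromosome offsets rounded up to whole windows
  n_bins <- ceiling(genome$chromosomes / window)
  offset <- setNames(c(0, cumsum(n_bins))[seq_along(chroms)], chroms)
  stat <- function(chrom_idx, starts) {
    bins <- offset[chroms[chrom_idx]] + starts %/% window
    length(unique(bins[duplicated(bins)]))   # bins holding >= 2 CNV starts
  }
  observed <- stat(match(cnvs$chrom, chroms), cnvs$start)
  perms <- permute_placements(cnvs, genome, n_perm, seed)
  null <- vapply(seq_len(n_perm), function(j)
    stat(perms$chrom_idx[, j], perms$starts[, j]), numeric(1))
  permutation_result(sprintf("bins_%dbp_with_2plus_cnvs", window), observed,
                     null, n_perm, seed, tail)
}

#' Annotation-track overlap enrichment test
#'
#' Statistic: the number of CNVs intersecting (>= 1 bp) track intervals
#' extended by `flank` bp on both sides — the proximity criterion used for
#' gene annotation (flank 1000) and recombination cold-/hot-spot tracks
#' (flank 0). The null re-places CNVs in unmasked sequence; a track covering
#' everything gives a degenerate null (flagged, z undefined).
#'
#' @param cnvs data.table chrom, start, end.
#' @param track data.table chrom, start, end (annotation intervals).
#' @param flank extension in bp applied to track intervals.
#' @param genome a `genome_model`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail "greater" for over-representation, "less" for
#'   under-representation, or "two_sided".
#' @param statistic_name label for the result.
#' @return a `permutation_result`.
#' @export
overlap_enrichment <- function(cnvs, track, flank = 0L, genome,
                               n_perm = 10000L, seed = 1L,
                               tail = "greater",
                               statistic_name = "cnvs_overlapping_track") {
  cnvs <- as.data.table(cnvs)
  track <- as.data.table(track)
  if (nrow(track) == 0L)
    cnd_stop("empty annotation track", "cnv_usage_error")
  chroms <- names(genome$chromosomes)
  ext <- track[, .(chrom,
                   start = pmax(start - flank, 0L),
                   end = pmin(end + flank, genome$chromosomes[chrom]))]
  ext <- normalize_intervals(ext)
  # flatten to one global axis so overlap queries are findInterval calls
  offs <- setNames(c(0, cumsum(as.numeric(genome$chromosomes))),
                   c(chroms, "..end"))
  ts <- offs[ext$chrom] + ext$start
  te <- offs[ext$chrom] + ext$end
  o <- order(ts); ts <- ts[o]; te <- te[o]
  overlaps_track <- function(gs, ge) {
    i <- findInterval(gs, ts)
    (i >= 1L & te[pmax(i, 1L)] > gs) | (i < length(ts) & ts[i + 1L] < ge)
  }
  lens <- cnvs$end - cnvs$start
  gs_obs <- offs[cnvs$chrom] + cnvs$start
  observed <- sum(overlaps_track(gs_obs, gs_obs + lens))
  perms <- permute_placements(cnvs, genome, n_perm, seed)
  gs <- offs[chroms][perms$chrom_idx] + perms$starts   # matrix-shaped
  hit <- overlaps_track(as.vector(gs), as.vector(gs + perms$lens))
  null <- colSums(matrix(hit, nrow = nrow(cnvs)))
  permutation_result(statistic_name, observed, null, n_perm, seed, tail)
}

#' Summarize candidate CNV sizes
#'
#' @param cnvs data.table with chrom, start, end.
#' @param binwidth histogram bin width in bp.
#' @return list: n, mean, se (sd/sqrt(n), 0 for n = 1), min, max,
#'   histogram (data.table bin_start, bin_end, count).
#' @export
summarize_sizes <- function(cnvs, binwidth = 500L) {
  cnvs <- as.data.table(cnvs)
  if (nrow(cnvs) == 0L)
    cnd_stop("no CNVs to summarize", "cnv_usage_error")
  sizes <- cnvs$end - cnvs$start
  n <- length(sizes)
  breaks <- seq(0L, (max(sizes) %/% binwidth + 1L) * binwidth, by = binwidth)
  counts <- tabulate(findInterval(sizes, breaks), nbins = length(breaks) - 1L)
  list(n = n, mean = mean(sizes),
       se = if (n > 1L) sd(sizes) / sqrt(n) else 0,
       min = min(sizes), max = max(sizes),
       histogram = data.table(bin_start = head(breaks, -1L),
                              bin_end = breaks[-1L], count = counts))
}
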