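#' @importFrom data.table data.table setkey setkeyv as.data.table := .N .SD .I
#'   setorder setorderv fwrite fread setnames copy rbindlist setDT foverlaps CJ
#'   setattr setcolorder fifelse
#' @importFrom stats rnorm runif sd pbinom setNames
#' @importFrom utils head tail
NULL

# All genomic intervals in this package are 0-based half-open [start, end),
# BED convention, on integer bp.

#' Merge and sort a set of intervals
#'
#' Normalizes an interval table to sorted, non-overlapping form (touching
#' intervals are merged).
#'
#' @param ivs data.frame/data.table with columns chrom, start, end.
#' @return data.table with columns chrom, start, end, sorted.
#' @export
normalize_intervals <- function(ivs) {
  ivs <- as.data.table(ivs)[, .(chrom = as.character(chrom),
                                start = as.integer(start),
                                end = as.integer(end))]
  if (nrow(ivs) == 0L) return(ivs)
  stopifnot(all(ivs$end > ivs$start))
  setorder(ivs, chrom, start, end)
  ivs[, grp := cumsum(c(1L, as.integer(
    chrom[-1L] != chrom[-.N] | start[-1L] > cummax(end)[-.N]
  )))]
  out <- ivs[, .(chrom = chrom[1L], start = start[1L], end = max(end)), by = grp]
  out[, grp := NULL]
  out[]
}

#' Construct a genome model
#'
#' A toy reference genome: chromosome lengths, a masked interval set (regions
#' excluded from depth computations and permutation placements, mimicking
#' repeat-masked / aberrant-coverage regions), and named annotation tracks
#' (genes, recombination cold-spots and hot-spots).
#'
#' @param chromosomes named integer vector of chromosome lengths (bp).
#' @param masked interval table (chrom, start, end) or NULL.
#' @param tracks named list of interval tables, or empty list.
#' @return object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, masked = NULL, tracks = list()) {
  stopifnot(is.numeric(chromosomes), length(chromosomes) >= 1L,
            !is.null(names(chromosomes)), !anyDuplicated(names(chromosomes)),
            all(chromosomes > 0))
  chromosomes <- setNames(as.integer(chromosomes), names(chromosomes))
  check_bounds <- function(ivs, what) {
    if (nrow(ivs) == 0L) return(invisible())
    if (!all(ivs$chrom %in% names(chromosomes)))
      cnd_stop(sprintf("%s intervals on unknown chromosome", what),
               "cnv_config_error")
    if (any(ivs$start < 0L) || any(ivs$end > chromosomes[ivs$chrom]))
      cnd_stop(sprintf("%s intervals out of chromosome bounds", what),
               "cnv_config_error")
    invisible()
  }
  masked <- normalize_intervals(
    if (is.null(masked)) data.table(chrom = character(), start = integer(),
                                    end = integer()) else masked)
  check_bounds(masked, "masked")
  tracks <- lapply(tracks, normalize_intervals)
  for (nm in names(tracks)) check_bounds(tracks[[nm]], nm)
  structure(list(chromosomes = chromosomes, masked = masked, tracks = tracks),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp total\n",
              length(x$chromosomes),
              format(sum(as.numeric(x$chromosomes)), big.mark = ",")))
  cat(sprintf("  masked: %d interval(s), %s bp\n", nrow(x$masked),
              format(sum(as.numeric(x$masked$end - x$masked$start)),
                     big.mark = ",")))
  for (nm in names(x$tracks))
    cat(sprintf("  track %-10s %d interval(s)\n", paste0(nm, ":"),
                nrow(x$tracks[[nm]])))
  invisible(x)
}

genome_size <- function(genome) sum(as.numeric(genome$chromosomes))

#' Maximal unmasked runs of a genome
#' @param genome a `genome_model`.
#' @return data.table chrom, start, end of unmasked stretches.
#' @keywords internal
unmasked_runs <- function(genome) {
  out <- vector("list", length(genome$chromosomes))
  for (i in seq_along(genome$chromosomes)) {
    chr <- names(genome$chromosomes)[i]
    len <- genome$chromosomes[[i]]
    m <- genome$masked[chrom == chr]
    bounds <- c(0L, rbind(m$start, m$end), len)
    starts <- bounds[seq(1L, length(bounds), by = 2L)]
    ends   <- bounds[seq(2L, length(bounds), by = 2L)]
    keep <- ends > starts
    out[[i]] <- data.table(chrom = chr, start = starts[keep], end = ends[keep])
  }
  rbindlist(out)
}

#' Simulate a toy genome with masked regions and annotation tracks
#'
#' Places non-overlapping masked intervals by rejection sampling until the
#' requested masked fraction is reached (within 10%), then lays down each
#' requested annotation track as non-overlapping intervals. Deterministic for
#' a fixed seed.
#'
#' @param n_chroms number of chromosomes (named chr1, chr2, ...).
#' @param chrom_length chromosome length in bp (>= 1e5).
#' @param masked_fraction target fraction of masked bases, in [0, 0.5).
#' @param track_spec named list; each element a list(n = count, len = bp)
#'   describing one annotation track (e.g. genes, cold_spots, hot_spots).
#' @param seed integer seed.
#' @param masked_len mean length of one masked interval (bp).
#' @return a `genome_model`.
#' @export
simulate_genome <- function(n_chroms, chrom_length, masked_fraction,
                            track_spec = list(), seed = 1L,
                            masked_len = 1000L) {
  if (n_chroms < 1L || chrom_length <= 0L)
    cnd_stop("n_chroms and chrom_length must be positive", "cnv_config_error")
  if (chrom_length < 1e5)
    cnd_stop("chrom_length must be >= 1e5 bp", "cnv_config_error")
  if (masked_fraction < 0 || masked_fraction >= 0.5)
    cnd_stop("masked_fraction must be in [0, 0.5)", "cnv_config_error")
  set.seed(seed)
  chroms <- setNames(rep(as.integer(chrom_length), n_chroms),
                     paste0("chr", seq_len(n_chroms)))

  place_nonoverlapping <- function(n, len, chroms) {
    # rejection-sample n fixed-length intervals, non-overlapping within the set
    placed <- vector("list", length(chroms))
    names(placed) <- names(chroms)
    got <- 0L
    res <- list()
    attempts <- 0L
    occupied <- lapply(chroms, function(l) data.table(start = integer(),
                                                      end = integer()))
    while (got < n && attempts < 50L) {
      attempts <- attempts + 1L
      need <- n - got
      chr_idx <- sample.int(length(chroms), need, replace = TRUE)
      starts <- floor(runif(need) * (chroms[chr_idx] - len))
      cand <- data.table(chrom = names(chroms)[chr_idx],
                         start = as.integer(starts),
                         end = as.integer(starts + len))
      for (k in seq_len(nrow(cand))) {
        occ <- occupied[[cand$chrom[k]]]
        if (nrow(occ) == 0L ||
            !any(cand$start[k] < occ$end & cand$end[k] > occ$start)) {
          occupied[[cand$chrom[k]]] <-
            rbind(occ, cand[k, .(start, end)])
          res[[length(res) + 1L]] <- cand[k]
          got <- got + 1L
        }
      }
    }
    if (length(res) == 0L)
      return(data.table(chrom = character(), start = integer(),
                        end = integer()))
    rbindlist(res)
  }

  n_masked <- round(masked_fraction * sum(as.numeric(chroms)) / masked_len)
  masked <- place_nonoverlapping(n_masked, as.integer(masked_len), chroms)
  tracks <- list()
  for (nm in names(track_spec)) {
    sp <- track_spec[[nm]]
    tracks[[nm]] <- place_nonoverlapping(as.integer(sp$n),
                                         as.integer(sp$len), chroms)
  }
  genome_model(chroms, masked, tracks)
}

#' Validate a set of truth CNVs to plant
#'
#' Truth CNVs are the ground-truth deletions/tandem duplications the simulator
#' plants, with one allele frequency per pool. Requests must be >= 50 bp,
#' mutually non-overlapping, within chromosome bounds and clear of masked
#' sequence.
#'
#' @param genome a `genome_model`.
#' @param truth data.frame with columns chrom, start, end, cnv_type
#'   ("DEL"/"DUP") and one numeric frequency column per pool id.
#' @return validated data.table (sorted by chrom, start) with class
#'   `truth_cnv_set`; attribute `pools` holds the pool id columns.
#' @export
plant_cnvs <- function(genome, truth) {
  truth <- as.data.table(truth)
  req <- c("chrom", "start", "end", "cnv_type")
  if (!all(req %in% names(truth)))
    cnd_stop("truth must have columns chrom, start, end, cnv_type",
             "cnv_validation_error")
  pools <- setdiff(names(truth), req)
  if (length(pools) == 0L)
    cnd_stop("truth must have at least one per-pool frequency column",
             "cnv_validation_error")
  truth[, chrom := as.character(chrom)]
  truth[, `:=`(start = as.integer(start), end = as.integer(end))]
  bad <- character()
  lab <- function(i) sprintf("%s:[%d,%d) %s", truth$chrom[i], truth$start[i],
                             truth$end[i], truth$cnv_type[i])
  for (i in seq_len(nrow(truth))) {
    if (!truth$cnv_type[i] %in% c("DEL", "DUP"))
      bad <- c(bad, paste(lab(i), "unknown cnv_type"))
    if (truth$end[i] - truth$start[i] < 50L)
      bad <- c(bad, paste(lab(i), "below 50 bp minimum size"))
    if (!truth$chrom[i] %in% names(genome$chromosomes) ||
        truth$start[i] < 0L ||
        truth$end[i] > genome$chromosomes[truth$chrom[i]])
      bad <- c(bad, paste(lab(i), "out of chromosome bounds"))
  }
  for (p in pools) {
    f <- truth[[p]]
    if (!is.numeric(f) || any(f < 0 | f > 1))
      bad <- c(bad, sprintf("pool %s: frequencies outside [0,1]", p))
  }
  # pairwise overlap within the request set
  if (nrow(truth) > 1L) {
    o <- order(truth$chrom, truth$start)
    for (k in seq_len(length(o) - 1L)) {
      i <- o[k]; j <- o[k + 1L]
      if (truth$chrom[i] == truth$chrom[j] && truth$end[i] > truth$start[j])
        bad <- c(bad, sprintf("overlapping requests: %s and %s", lab(i), lab(j)))
    }
  }
  # masked-sequence collisions
  if (nrow(genome$masked) > 0L) {
    for (i in seq_len(nrow(truth))) {
      m <- genome$masked[chrom == truth$chrom[i] &
                           start < truth$end[i] & end > truth$start[i]]
      if (nrow(m) > 0L)
        bad <- c(bad, paste(lab(i), "overlaps masked sequence"))
    }
  }
  if (length(bad) > 0L)
    cnd_stop(paste0("invalid CNV request(s):\n  ",
                    paste(bad, collapse = "\n  ")), "cnv_validation_error")
  setorder(truth, chrom, start)
  setattr(truth, "pools", pools)
  setattr(truth, "class", c("truth_cnv_set", class(truth)))
  truth[]
}
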