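#' Construct a pool sequencing profile
#'
#' Describes one pooled library: how many diploid individuals were pooled,
#' the behavioural class of the population, and the library geometry
#' (target raw coverage, insert-size distribution, read length). Defaults
#' follow a paired-end 100-bp, ~30X, ~480 +/- 50 bp insert design with 30
#' diploids per pool.
#'
#' @param pool_id pool label.
#' @param behaviour "Choosy" or "NonChoosy".
#' @param n_individuals diploid individuals in the pool (>= 1).
#' @param target_depth mean raw coverage (X, > 0).
#' @param insert_mean,insert_sd fragment (outer insert) size model, bp.
#' @param read_length read length, bp.
#' @return object of class `pool_profile`.
#' @export
pool_profile <- function(pool_id, behaviour, n_individuals = 30L,
                         target_depth = 30, insert_mean = 480,
                         insert_sd = 50, read_length = 100L) {
  if (!behaviour %in% c("Choosy", "NonChoosy"))
    cnd_stop("behaviour must be 'Choosy' or 'NonChoosy'", "cnv_config_error")
  if (n_individuals < 1L || target_depth <= 0 || read_length <= 0 ||
      insert_mean <= 2 * read_length)
    cnd_stop("invalid pool profile (need n_individuals >= 1, depth > 0, insert_mean > 2*read_length)",
             "cnv_config_error")
  structure(list(pool_id = as.character(pool_id), behaviour = behaviour,
                 n_individuals = as.integer(n_individuals),
                 target_depth = target_depth, insert_mean = insert_mean,
                 insert_sd = insert_sd, read_length = as.integer(read_length)),
            class = "pool_profile")
}

# fragment lengths ~ Normal(insert_mean, insert_sd) truncated to
# [2*read_length, insert_mean + 6*insert_sd], by rejection
draw_fragment_lengths <- function(n, profile) {
  lo <- 2 * profile$read_length
  hi <- profile$insert_mean + 6 * profile$insert_sd
  out <- rnorm(n, profile$insert_mean, profile$insert_sd)
  for (i in 1:20) {
    bad <- which(out < lo | out > hi)
    if (length(bad) == 0L) break
    out[bad] <- rnorm(length(bad), profile$insert_mean, profile$insert_sd)
  }
  pmin(pmax(round(out), lo), hi)
}

# Haplotype-to-reference segment map for one carrier class on one chromosome.
# A haplotype is the reference with its carried CNVs applied: deletions skip
# [s,e); tandem duplications emit [s,e) twice back-to-back. Returns ref
# segment starts/ends in haplotype order.
hap_segments <- function(chrom_len, cnvs) {
  if (is.null(cnvs) || nrow(cnvs) == 0L)
    return(data.table(ref_start = 0L, ref_end = as.integer(chrom_len)))
  ref_start <- integer(); ref_end <- integer()
  pos <- 0L
  for (i in seq_len(nrow(cnvs))) {
    s <- cnvs$start[i]; e <- cnvs$end[i]
    if (cnvs$cnv_type[i] == "DEL") {
      if (s > pos) { ref_start <- c(ref_start, pos); ref_end <- c(ref_end, s) }
    } else {                       # DUP: first copy up to e, then second copy
      ref_start <- c(ref_start, pos, s); ref_end <- c(ref_end, e, e)
    }
    pos <- e
  }
  if (pos < chrom_len) {
    ref_start <- c(ref_start, pos); ref_end <- c(ref_end, as.integer(chrom_len))
  }
  data.table(ref_start = ref_start, ref_end = ref_end)
}

#' Simulate pooled paired-end read-pair alignments
#'
#' Emulates mapping of pooled paired-end reads to the reference by coordinate
#' transformation (no sequence is synthesized). For each pool,
#' `2 * n_individuals` haplotypes are sampled; each haplotype carries each
#' truth CNV independently with that pool's allele frequency. Fragments are
#' drawn uniformly along each haplotype with truncated-normal lengths, and
#' each mate is mapped back to reference coordinates through the haplotype's
#' segment map. Read pairs spanning a deletion on a carrier haplotype map
#' inward-facing with the insert inflated by the deletion size; pairs spanning
#' the copy1/copy2 junction of a tandem duplication map everted; pairs whose
#' mate straddles a breakpoint are unmappable and dropped; fragments inside a
#' deleted segment yield no records (depth loss) and both copies of a
#' duplicated segment map to the single reference locus (depth gain).
#'
#' @param genome a `genome_model`.
#' @param truth a `truth_cnv_set` (or NULL for no variants) with a frequency
#'   column named after `profile$pool_id` (absent column = frequency 0).
#' @param profile a `pool_profile`.
#' @param seed integer seed; deterministic output for a fixed seed.
#' @return data.table of read-pair alignments sorted by (chrom, left_start):
#'   pair_id, pool, chrom, left_start, left_end, right_start, right_end,
#'   orientation ("INWARD"/"EVERTED"), insert (outer span, bp).
#' @export
simulate_pool_reads <- function(genome, truth, profile, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(profile, "pool_profile"))
  set.seed(seed)
  rl <- profile$read_length
  H <- 2L * profile$n_individuals
  # per-haplotype fragments per bp so pooled read-base depth ~= target_depth
  frag_rate <- profile$target_depth / (2 * rl) / H

  if (is.null(truth)) truth <- data.table(chrom = character(),
                                          start = integer(), end = integer(),
                                          cnv_type = character())
  truth <- as.data.table(truth)
  freq <- if (profile$pool_id %in% names(truth)) truth[[profile$pool_id]]
          else rep(0, nrow(truth))
  # carrier draw: H haplotypes x n CNVs, independent per CNV
  carriers <- matrix(FALSE, nrow = H, ncol = nrow(truth))
  if (nrow(truth) > 0L)
    for (j in seq_len(nrow(truth)))
      carriers[, j] <- runif(H) < freq[j]

  out <- list()
  for (ci in seq_along(genome$chromosomes)) {
    chr <- names(genome$chromosomes)[ci]
    chrom_len <- genome$chromosomes[[ci]]
    idx <- which(truth$chrom == chr)
    cnvs_c <- truth[idx]
    # group haplotypes carrying the same CNV subset on this chromosome
    keys <- if (length(idx) == 0L) rep("", H)
            else apply(carriers[, idx, drop = FALSE], 1L,
                       function(z) paste(as.integer(z), collapse = ""))
    for (key in unique(keys)) {
      n_hap <- sum(keys == key)
      carried <- if (length(idx) == 0L) cnvs_c[0]
                 else cnvs_c[as.logical(as.integer(strsplit(key, "")[[1L]]))]
      segs <- hap_segments(chrom_len, carried)
      seg_len <- segs$ref_end - segs$ref_start
      hap_len <- sum(as.numeric(seg_len))
      cs <- cumsum(c(0, as.numeric(seg_len)))      # hap-coordinate left edges
      left_edge <- cs[-length(cs)]
      n_frag <- round(n_hap * hap_len * frag_rate)
      if (n_frag < 1L) next
      L <- draw_fragment_lengths(n_frag, profile)
      fs <- floor(runif(n_frag) * (hap_len - L))
      fe <- fs + L
      i1 <- findInterval(fs, left_edge)
      i2 <- findInterval(fe - rl, left_edge)
      ok <- (fs + rl <= left_edge[i1] + seg_len[i1]) &
            (fe <= left_edge[i2] + seg_len[i2])
      if (!any(ok)) next
      i1 <- i1[ok]; i2 <- i2[ok]; fs <- fs[ok]; fe <- fe[ok]
      r1 <- segs$ref_start[i1] + (fs - left_edge[i1])   # mate 1 (fragment 5')
      r2 <- segs$ref_start[i2] + (fe - rl - left_edge[i2])
      left_start <- as.integer(pmin(r1, r2))
      right_end  <- as.integer(pmax(r1, r2) + rl)
      out[[length(out) + 1L]] <- data.table(
        pool = profile$pool_id, chrom = chr,
        left_start = left_start, left_end = left_start + rl,
        right_start = right_end - rl, right_end = right_end,
        orientation = ifelse(r2 < r1, "EVERTED", "INWARD"),
        insert = right_end - left_start)
    }
  }
  pairs <- if (length(out) == 0L)
    data.table(pool = character(), chrom = character(), left_start = integer(),
               left_end = integer(), right_start = integer(),
               right_end = integer(), orientation = character(),
               insert = integer())
  else rbindlist(out)
  setorder(pairs, chrom, left_start, right_start)
  pairs[, pair_id := seq_len(.N)]
  setcolorder(pairs, c("pair_id", "pool", "chrom", "left_start", "left_end",
                       "right_start", "right_end", "orientation", "insert"))
  pairs[]
}

#' Write a simulated fixture to disk
#'
#' Writes the read-pair stream as a sorted plain-text pair table and as a SAM
#' alignment file, the truth set as BED (name = DEL/DUP, per-pool frequencies
#' as extra columns), the genome as a chrom/length index and its masked
#' regions and annotation tracks as BED.
#'
#' @param pairs read-pair table from [simulate_pool_reads()] (one or several
#'   pools row-bound).
#' @param truth a `truth_cnv_set` or NULL.
#' @param genome a `genome_model`.
#' @param out_prefix path prefix for output files.
#' @return invisibly, the named vector of files written.
#' @export
write_fixture <- function(pairs, truth, genome, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir))
    cnd_stop(paste("output directory does not exist:", dir), "cnv_io_error")
  files <- c(pairs = paste0(out_prefix, ".pairs.tsv"),
             sam = paste0(out_prefix, ".sam"),
             genome = paste0(out_prefix, ".genome.tsv"),
             masked = paste0(out_prefix, ".masked.bed"))
  fwrite(pairs, files[["pairs"]], sep = "\t")
  write_sam(pairs, genome, files[["sam"]])
  fwrite(data.table(chrom = names(genome$chromosomes),
                    length = as.integer(genome$chromosomes)),
         files[["genome"]], sep = "\t", col.names = FALSE)
  fwrite(genome$masked, files[["masked"]], sep = "\t", col.names = FALSE)
  for (nm in names(genome$tracks)) {
    f <- paste0(out_prefix, ".", nm, ".bed")
    files[nm] <- f
    fwrite(genome$tracks[[nm]], f, sep = "\t", col.names = FALSE)
  }
  if (!is.null(truth)) {
    files["truth"] <- paste0(out_prefix, ".truth.bed")
    td <- as.data.table(truth)
    pools <- setdiff(names(td), c("chrom", "start", "end", "cnv_type"))
    bed <- td[, .(chrom, start, end, name = cnv_type)]
    for (p in pools) bed[[p]] <- td[[p]]
    fwrite(bed, files[["truth"]], sep = "\t", col.names = FALSE)
  }
  invisible(files)
}

#' Read a pair table written by [write_fixture()]
#' @param path path to a `.pairs.tsv` file.
#' @return data.table of read pairs.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path))
    cnd_stop(paste("no such pair table:", path), "cnv_io_error")
  fread(path, sep = "\t")
}

# SAM export: two records per pair, coordinate sorted. The leftmost-mapped
# mate is read1. INWARD pairs are +/- (flags 97/145); EVERTED pairs -/+
# (flags 81/161). SEQ/QUAL are omitted ('*'), CIGAR is full-length M.
write_sam <- function(pairs, genome, path) {
  rl_of <- function(p) p$left_end - p$left_start
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chromosomes),
                      as.integer(genome$chromosomes)))
  if (nrow(pairs) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  ev <- pairs$orientation == "EVERTED"
  rl <- pairs$left_end - pairs$left_start
  qname <- paste0(pairs$pool, "_", pairs$pair_id)
  cigar <- paste0(rl, "M")
  r1 <- data.table(qname = qname,
                   flag = ifelse(ev, 81L, 97L),
                   chrom = pairs$chrom, pos = pairs$left_start + 1L,
                   cigar = cigar, pnext = pairs$right_start + 1L,
                   tlen = pairs$insert)
  r2 <- data.table(qname = qname,
                   flag = ifelse(ev, 161L, 145L),
                   chrom = pairs$chrom, pos = pairs$right_start + 1L,
                   cigar = cigar, pnext = pairs$left_start + 1L,
                   tlen = -pairs$insert)
  recs <- rbind(r1, r2)
  setorder(recs, chrom, pos)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
                   recs$qname, recs$flag, recs$chrom, recs$pos, recs$cigar,
                   recs$pnext, recs$tlen)
  writeLines(c(header, lines), path)
  invisible(path)
}
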