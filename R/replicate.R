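#' Define the four-pool comparison plan
#'
#' Two between-class pairwise comparisons (the Focal Test: each one Choosy
#' vs one NonChoosy pool) and two within-class comparisons (the Control
#' Test: Choosy vs Choosy, NonChoosy vs NonChoosy), over four distinct pools
#' with each pool appearing in exactly one focal and one control pair.
#'
#' @param pools data.frame with columns pool_id, behaviour (two "Choosy",
#'   two "NonChoosy").
#' @param focal,control optional lists of two c(pool_a, pool_b) pairs;
#'   defaults pair pools in listed order (C1-N1, C2-N2; C1-C2, N1-N2).
#' @return object of class `comparison_plan`.
#' @export
comparison_plan <- function(pools, focal = NULL, control = NULL) {
  pools <- as.data.table(pools)
  if (nrow(pools) != 4L || anyDuplicated(pools$pool_id) ||
      sum(pools$behaviour == "Choosy") != 2L ||
      sum(pools$behaviour == "NonChoosy") != 2L)
    cnd_stop("plan needs exactly four distinct pools, two Choosy and two NonChoosy",
             "cnv_config_error")
  ch <- pools[behaviour == "Choosy", pool_id]
  nc <- pools[behaviour == "NonChoosy", pool_id]
  if (is.null(focal)) focal <- list(c(ch[1L], nc[1L]), c(ch[2L], nc[2L]))
  if (is.null(control)) control <- list(c(ch[1L], ch[2L]), c(nc[1L], nc[2L]))
  beh <- setNames(pools$behaviour, pools$pool_id)
  for (p in focal)
    if (length(unique(beh[p])) != 2L)
      cnd_stop("each focal pair must be one Choosy vs one NonChoosy pool",
               "cnv_config_error")
  for (p in control)
    if (length(unique(beh[p])) != 1L)
      cnd_stop("each control pair must be within one behavioural class",
               "cnv_config_error")
  used <- c(unlist(focal), unlist(control))
  if (!all(sort(unique(used)) == sort(pools$pool_id)) ||
      any(table(unlist(focal)) != 1L) || any(table(unlist(control)) != 1L))
    cnd_stop("each pool must appear in exactly one focal and one control pair",
             "cnv_config_error")
  structure(list(pools = pools, behaviour = beh, focal = focal,
                 control = control),
            class = "comparison_plan")
}

#' Identity-by-state classification of two overlapping loci
#'
#' IDENTICAL: equal start and end in both comparisons (divergence from
#' shared standing variation). NON_IDENTICAL: >= 1 bp overlap with sizes
#' differing by less than `tol` of their mean size (consistent with
#' convergent mutation). Anything else is DISCARDED as unmatched.
#' Vectorized.
#'
#' @param s1,e1,s2,e2 interval coordinates (0-based half-open).
#' @param tol size tolerance as a fraction of mean size (default 0.05).
#' @return character vector: "IDENTICAL", "NON_IDENTICAL" or "DISCARDED".
#' @export
ibs_class <- function(s1, e1, s2, e2, tol = 0.05) {
  sz1 <- e1 - s1; sz2 <- e2 - s2
  ms <- (sz1 + sz2) / 2
  fifelse(s1 == s2 & e1 == e2, "IDENTICAL",
          fifelse(s1 < e2 & s2 < e1 & abs(sz1 - sz2) < tol * ms,
                  "NON_IDENTICAL", "DISCARDED"))
}

#' Match significant divergence calls across the two replicate comparisons
#'
#' Pairs loci that diverge significantly in both independent pairwise
#' comparisons. Eligible partners share chromosome and type, overlap by at
#' least 1 bp, and are either identical by state (equal start and end in
#' both comparisons) or non-identical by state (sizes differing by less than
#' `ibs_tol` of their mean size). Pairing is one-to-one among eligible pairs
#' by minimal endpoint distance, ties to the leftmost partner; everything
#' unpaired is removed as inconsistent.
#'
#' @param div1,div2 significant-only divergence tables (see
#'   [test_divergence()]) from the two comparisons.
#' @param ibs_tol size tolerance for non-identical-by-state loci (default
#'   0.05 of mean size).
#' @return data.table: one row per cross-comparison CNV with union
#'   coordinates, ibs class, and per-comparison coordinates, direction and
#'   fixity.
#' @export
match_across_comparisons <- function(div1, div2, ibs_tol = 0.05) {
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), cnv_type = character(),
                      ibs = character())
  if (nrow(div1) == 0L || nrow(div2) == 0L) return(empty)
  a <- as.data.table(div1)[, .(chrom, cnv_type, start, end, locus_id,
                               direction, fixity, pool_a, pool_b)]
  b <- as.data.table(div2)[, .(chrom, cnv_type, start, end, locus_id,
                               direction, fixity, pool_a, pool_b)]
  a[, ia := .I]; b[, ib := .I]
  setkey(b, chrom, cnv_type, start, end)
  ov <- foverlaps(a, b, type = "any", nomatch = NULL,
                  by.x = c("chrom", "cnv_type", "start", "end"))
  if (nrow(ov) == 0L) return(empty)
  setnames(ov,
           c("start", "end", "locus_id", "direction", "fixity", "pool_a",
             "pool_b", "i.start", "i.end", "i.locus_id", "i.direction",
             "i.fixity", "i.pool_a", "i.pool_b"),
           c("start_2", "end_2", "locus_2", "direction_2", "fixity_2",
             "pool_a_2", "pool_b_2", "start_1", "end_1", "locus_1",
             "direction_1", "fixity_1", "pool_a_1", "pool_b_1"))
  ov[, size_1 := end_1 - start_1]
  ov[, size_2 := end_2 - start_2]
  ov[, mean_size := (size_1 + size_2) / 2]
  ov[, ibs_cls := ibs_class(start_1, end_1, start_2, end_2, tol = ibs_tol)]
  ov <- ov[ibs_cls != "DISCARDED"]
  if (nrow(ov) == 0L) return(empty)
  ov[, dist := abs(start_1 - start_2) + abs(end_1 - end_2)]
  ov[, tie_lo := pmin(start_1, start_2)]
  ov[, tie_hi := pmax(start_1, start_2)]
  setorder(ov, dist, tie_lo, tie_hi)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(ov))
  for (k in seq_len(nrow(ov))) {
    if (!used_a[ov$ia[k]] && !used_b[ov$ib[k]]) {
      keep[k] <- TRUE
      used_a[ov$ia[k]] <- TRUE; used_b[ov$ib[k]] <- TRUE
    }
  }
  out <- ov[keep]
  out[, `:=`(chrom = chrom, start = pmin(start_1, start_2),
             end = pmax(end_1, end_2), ibs = ibs_cls)]
  out[, c("ia", "ib", "dist", "tie_lo", "tie_hi", "ibs_cls") := NULL]
  setcolorder(out, c("chrom", "start", "end", "cnv_type", "ibs"))
  setorder(out, chrom, start, end)
  out[]
}

#' Keep cross-comparison CNVs divergent in the same direction
#'
#' Focal comparisons: retained when the higher-frequency (carrier) pool
#' belongs to the same behavioural class in both comparisons. Control
#' comparisons have no behavioural polarity, so "same direction" is
#' positional: the carrier is the first-listed pool of its pair in both
#' comparisons, or the second-listed in both.
#'
#' @param cross output of [match_across_comparisons()].
#' @param plan a `comparison_plan`.
#' @param test "focal" or "control".
#' @return the direction-consistent subset.
#' @export
enforce_direction <- function(cross, plan, test = c("focal", "control")) {
  test <- match.arg(test)
  if (nrow(cross) == 0L) return(cross)
  cross <- copy(cross)
  if (test == "focal") {
    keep <- plan$behaviour[cross$direction_1] ==
      plan$behaviour[cross$direction_2]
    cross[, direction_class := unname(plan$behaviour[direction_1])]
  } else {
    rank_1 <- fifelse(cross$direction_1 == cross$pool_a_1, 1L, 2L)
    rank_2 <- fifelse(cross$direction_2 == cross$pool_a_2, 1L, 2L)
    keep <- rank_1 == rank_2
    cross[, direction_class := NA_character_]
  }
  cross[keep]
}

#' Remove focal CNVs that repeat in the Control Test
#'
#' A focal cross-comparison CNV is a likely false positive when a control
#' cross-comparison CNV of the same type matches it under the same
#' across-comparison criteria (overlap plus identity or the size rule on
#' union coordinates). Type-restricted: a deletion and a duplication at one
#' locus are different alleles and never cancel each other.
#'
#' @param focal_consistent,control_consistent direction-consistent cross
#'   tables from [enforce_direction()].
#' @param ibs_tol size tolerance, as in [match_across_comparisons()].
#' @return list: `confirmed` (retained focal CNVs), `removed` (with
#'   control partner coordinates).
#' @export
subtract_control <- function(focal_consistent, control_consistent,
                             ibs_tol = 0.05) {
  if (nrow(focal_consistent) == 0L ||
      is.null(control_consistent) || nrow(control_consistent) == 0L)
    return(list(confirmed = focal_consistent,
                removed = focal_consistent[0]))
  f <- as.data.table(focal_consistent)[, .(chrom, cnv_type, start, end)]
  f[, i_f := .I]
  ctl <- as.data.table(control_consistent)[, .(chrom, cnv_type, start, end)]
  ctl[, i_c := .I]
  setkey(ctl, chrom, cnv_type, start, end)
  ov <- foverlaps(f, ctl, type = "any", nomatch = NULL,
                  by.x = c("chrom", "cnv_type", "start", "end"))
  removed_idx <- integer(0)
  partner <- integer(0)
  if (nrow(ov) > 0L) {
    ov <- ov[ibs_class(i.start, i.end, start, end, tol = ibs_tol) !=
               "DISCARDED"]
    removed_idx <- unique(ov$i_f)
    partner <- ov[!duplicated(i_f), setNames(i_c, i_f)]
  }
  removed <- focal_consistent[removed_idx]
  if (nrow(removed) > 0L) {
    ctl_rows <- control_consistent[partner[as.character(removed_idx)]]
    removed[, `:=`(control_chrom = ctl_rows$chrom,
                   control_start = ctl_rows$start,
                   control_end = ctl_rows$end)]
  }
  list(confirmed = focal_consistent[!seq_len(nrow(focal_consistent)) %in%
                                      removed_idx],
       removed = removed)
}

#' Classify confirmed CNVs by behavioural association
#'
#' The called structural allele is by construction the non-reference allele;
#' the reference is treated as the ancestral state (a configuration
#' assumption of the study design, not an inference). A confirmed CNV whose
#' carrier pools are the Choosy pools in both comparisons is
#' Choosiness-associated (the derived allele is at high frequency only where
#' the derived behaviour occurs: copy-number displacement); the mirror
#' pattern is Non-Choosiness-associated. Fixity is parallel-fixed only when
#' the locus is a fixed presence/absence difference in both comparisons;
#' mixed or quantitative patterns are quantitative.
#'
#' @param confirmed the `confirmed` table from [subtract_control()].
#' @param plan a `comparison_plan`.
#' @return data.table of candidates with `association`
#'   ("CHOOSINESS"/"NON_CHOOSINESS") and `fixity_class`
#'   ("PARALLEL_FIXED"/"QUANTITATIVE").
#' @export
classify_candidates <- function(confirmed, plan) {
  if (nrow(confirmed) == 0L) {
    out <- copy(confirmed)
    out[, `:=`(association = character(0), fixity_class = character(0))]
    return(out)
  }
  out <- copy(confirmed)
  out[, association := fifelse(unname(plan$behaviour[direction_1]) == "Choosy",
                               "CHOOSINESS", "NON_CHOOSINESS")]
  out[, fixity_class := fifelse(
    fixity_1 == "FIXED_PRESENCE_ABSENCE" & fixity_2 == "FIXED_PRESENCE_ABSENCE",
    "PARALLEL_FIXED", "QUANTITATIVE")]
  out[]
}

#' One-tailed binomial enrichment test for parallel divergence
#'
#' Exact upper-tail probability that at least `k` of `n` divergent loci from
#' one comparison repeat in the replicate comparison when each repeats
#' independently with probability `p0`.
#'
#' @param k observed parallel-divergent count.
#' @param n divergent count in the first comparison.
#' @param p0 expected success rate under the null (default 0.05).
#' @return exact P(X >= k), X ~ Binomial(n, p0).
#' @export
parallel_enrichment <- function(k, n, p0 = 0.05) {
  if (length(k) != 1L || length(n) != 1L || k < 0 || n < 0 || k > n ||
      p0 <= 0 || p0 >= 1)
    cnd_stop("need 0 <= k <= n and p0 in (0,1)", "cnv_usage_error")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}
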