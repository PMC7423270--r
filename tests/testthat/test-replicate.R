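demo_plan <- function() {
  comparison_plan(data.frame(pool_id = c("C1", "C2", "N1", "N2"),
                             behaviour = c("Choosy", "Choosy",
                                           "NonChoosy", "NonChoosy")))
}

# significant-divergence rows for cross-comparison tests
div_row <- function(comparison, pool_a, pool_b, chrom, start, end,
                    cnv_type = "DEL", direction = pool_a,
                    fixity = "FIXED_PRESENCE_ABSENCE") {
  data.table(locus_id = paste0(comparison, "_", start),
             comparison_id = comparison, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             cnv_type = cnv_type, pool_a = pool_a, pool_b = pool_b,
             direction = direction, fixity = fixity, significant = TRUE)
}

test_that("comparison plans are validated structurally", {
  expect_s3_class(demo_plan(), "comparison_plan")
  expect_error(
    comparison_plan(data.frame(pool_id = c("A", "B", "C"),
                               behaviour = c("Choosy", "Choosy",
                                             "NonChoosy"))),
    class = "cnv_config_error")
  expect_error(
    comparison_plan(data.frame(pool_id = c("C1", "C2", "N1", "N2"),
                               behaviour = c("Choosy", "Choosy",
                                             "NonChoosy", "NonChoosy")),
                    focal = list(c("C1", "C2"), c("N1", "N2"))),
    class = "cnv_config_error")
})

test_that("cross-comparison matching classifies identity by state per the size rule", {
  d1 <- div_row("focal_1", "C1", "N1", "chr1", 1000, 2000)
  # identical coordinates
  x <- match_across_comparisons(d1, div_row("focal_2", "C2", "N2", "chr1",
                                            1000, 2000))
  expect_equal(x$ibs, "IDENTICAL")
  # sizes 1000 vs 1040, diff 40 < 0.05 * 1020 = 51
  x2 <- match_across_comparisons(d1, div_row("focal_2", "C2", "N2", "chr1",
                                             1010, 2050))
  expect_equal(x2$ibs, "NON_IDENTICAL")
  expect_equal(x2$start, 1000L)   # union coordinates
  expect_equal(x2$end, 2050L)
  # sizes 1000 vs 1100, diff 100 >= 0.05 * 1050 = 52.5: removed
  x3 <- match_across_comparisons(d1, div_row("focal_2", "C2", "N2", "chr1",
                                             1000, 2100))
  expect_equal(nrow(x3), 0L)
  # type mismatch never matches
  x4 <- match_across_comparisons(d1, div_row("focal_2", "C2", "N2", "chr1",
                                             1000, 2000, cnv_type = "DUP"))
  expect_equal(nrow(x4), 0L)
})

test_that("the identity-by-state truth table matches an exhaustive brute-force oracle", {
  # every interval pair on a 100-bp toy chromosome
  iv <- CJ(s = 0:99, e = 1:100)[e > s]
  n <- nrow(iv)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 500))
  for (ch in chunks) {
    s1 <- rep(iv$s[ch], each = n); e1 <- rep(iv$e[ch], each = n)
    s2 <- rep(iv$s, times = length(ch)); e2 <- rep(iv$e, times = length(ch))
    got <- ibs_class(s1, e1, s2, e2, tol = 0.05)
    # independent oracle, written straight from the definitions
    sz1 <- e1 - s1; sz2 <- e2 - s2
    oracle <- ifelse(s1 == s2 & e1 == e2, "IDENTICAL",
                     ifelse(pmax(s1, s2) < pmin(e1, e2) &
                              abs(sz1 - sz2) < 0.05 * (sz1 + sz2) / 2,
                            "NON_IDENTICAL", "DISCARDED"))
    expect_identical(got, oracle)
    # and the half-mean-size comparability rule
    got_cmp <- comparable_half_mean(s1, e1, s2, e2)
    ms <- (sz1 + sz2) / 2
    expect_identical(got_cmp, abs(s1 - s2) < ms / 2 & abs(e1 - e2) < ms / 2)
  }
})

test_that("direction consistency is behavioural for focal and positional for control", {
  plan <- demo_plan()
  # higher in Choosy in both comparisons: retained
  x <- match_across_comparisons(
    div_row("f1", "C1", "N1", "chr1", 1000, 2000, direction = "C1"),
    div_row("f2", "C2", "N2", "chr1", 1000, 2000, direction = "C2"))
  expect_equal(nrow(enforce_direction(x, plan, "focal")), 1L)
  # higher in Choosy1 but higher in NonChoosy2: dropped
  x2 <- match_across_comparisons(
    div_row("f1", "C1", "N1", "chr1", 1000, 2000, direction = "C1"),
    div_row("f2", "C2", "N2", "chr1", 1000, 2000, direction = "N2"))
  expect_equal(nrow(enforce_direction(x2, plan, "focal")), 0L)
  # fixed in both NonChoosy pools: retained with NonChoosy direction
  x3 <- match_across_comparisons(
    div_row("f1", "C1", "N1", "chr1", 1000, 2000, direction = "N1",
            cnv_type = "DUP"),
    div_row("f2", "C2", "N2", "chr1", 1000, 2000, direction = "N2",
            cnv_type = "DUP"))
  kept <- enforce_direction(x3, plan, "focal")
  expect_equal(kept$direction_class, "NonChoosy")
  # control: same-rank convention
  xc <- match_across_comparisons(
    div_row("c1", "C1", "C2", "chr1", 1000, 2000, direction = "C1"),
    div_row("c2", "N1", "N2", "chr1", 1000, 2000, direction = "N1"))
  expect_equal(nrow(enforce_direction(xc, plan, "control")), 1L)
  xc2 <- match_across_comparisons(
    div_row("c1", "C1", "C2", "chr1", 1000, 2000, direction = "C1"),
    div_row("c2", "N1", "N2", "chr1", 1000, 2000, direction = "N2"))
  expect_equal(nrow(enforce_direction(xc2, plan, "control")), 0L)
})

test_that("control subtraction is type-restricted and rule-matched", {
  plan <- demo_plan()
  focal <- match_across_comparisons(
    div_row("f1", "C1", "N1", "chr1", 1000, 2000, direction = "C1"),
    div_row("f2", "C2", "N2", "chr1", 1000, 2000, direction = "C2"))
  # control deletion passing the 5% rule removes the focal deletion
  ctl <- match_across_comparisons(
    div_row("c1", "C1", "C2", "chr1", 1005, 2010, direction = "C1"),
    div_row("c2", "N1", "N2", "chr1", 1005, 2010, direction = "N1"))
  sub <- subtract_control(focal, ctl)
  expect_equal(nrow(sub$confirmed), 0L)
  expect_equal(nrow(sub$removed), 1L)
  expect_equal(sub$removed$control_start, 1005L)
  # no control partner: retained
  ctl_far <- match_across_comparisons(
    div_row("c1", "C1", "C2", "chr1", 500000, 501000, direction = "C1"),
    div_row("c2", "N1", "N2", "chr1", 500000, 501000, direction = "N1"))
  sub2 <- subtract_control(focal, ctl_far)
  expect_equal(nrow(sub2$confirmed), 1L)
  # overlapping control duplication does not remove a focal deletion
  ctl_dup <- match_across_comparisons(
    div_row("c1", "C1", "C2", "chr1", 1005, 2010, direction = "C1",
            cnv_type = "DUP"),
    div_row("c2", "N1", "N2", "chr1", 1005, 2010, direction = "N1",
            cnv_type = "DUP"))
  sub3 <- subtract_control(focal, ctl_dup)
  expect_equal(nrow(sub3$confirmed), 1L)
})

test_that("candidates are classified by association and fixity", {
  plan <- demo_plan()
  mk_cross <- function(fix1, fix2, dir1 = "C1", dir2 = "C2") {
    enforce_direction(match_across_comparisons(
      div_row("f1", "C1", "N1", "chr1", 1000, 2000, direction = dir1,
              fixity = fix1),
      div_row("f2", "C2", "N2", "chr1", 1000, 2000, direction = dir2,
              fixity = fix2)), plan, "focal")
  }
  # fixed in both Choosy pools, absent in both Non-Choosy pools
  c1 <- classify_candidates(mk_cross("FIXED_PRESENCE_ABSENCE",
                                     "FIXED_PRESENCE_ABSENCE"), plan)
  expect_equal(c1$association, "CHOOSINESS")
  expect_equal(c1$fixity_class, "PARALLEL_FIXED")
  # mirror pattern
  c2 <- classify_candidates(mk_cross("FIXED_PRESENCE_ABSENCE",
                                     "FIXED_PRESENCE_ABSENCE",
                                     dir1 = "N1", dir2 = "N2"), plan)
  expect_equal(c2$association, "NON_CHOOSINESS")
  # mixed fixity across comparisons maps to QUANTITATIVE
  c3 <- classify_candidates(mk_cross("FIXED_PRESENCE_ABSENCE",
                                     "QUANTITATIVE"), plan)
  expect_equal(c3$fixity_class, "QUANTITATIVE")
  c4 <- classify_candidates(mk_cross("QUANTITATIVE", "QUANTITATIVE"), plan)
  expect_equal(c4$fixity_class, "QUANTITATIVE")
})

test_that("the exact binomial enrichment test matches its closed forms and oracle", {
  expect_equal(parallel_enrichment(0L, 100L, 0.05), 1)
  expect_equal(parallel_enrichment(10L, 10L, 0.05), 0.05^10)
  # oracle by direct summation of the binomial mass
  for (k in c(1L, 3L, 7L)) {
    expect_equal(parallel_enrichment(k, 20L, 0.1),
                 sum(dbinom(k:20, 20L, 0.1)))
  }
  expect_error(parallel_enrichment(5L, 3L, 0.05), class = "cnv_usage_error")
  expect_error(parallel_enrichment(1L, 3L, 1.5), class = "cnv_usage_error")
})
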