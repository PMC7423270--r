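# synthetic catalogue on a uniformly covered maskless genome: depth 2X
# everywhere, so all depth ratios are exactly 1
uniform_catalog <- function(pool_id, calls_df, genome, seed_support = 10L) {
  tile <- make_pairs(pool_id, "chr1",
                     left_start = seq(0L, genome$chromosomes[[1L]] - 300L,
                                      by = 100L),
                     insert = 200L)
  track <- pool_depth_track(tile, genome)
  calls <- as.data.table(calls_df)
  calls[, `:=`(size = end - start, call_id = paste0(pool_id, "_", .I))]
  if (!"support" %in% names(calls_df)) calls[, support := seed_support]
  if (!"cnv_type" %in% names(calls_df)) calls[, cnv_type := "DEL"]
  dd <- compute_depth(calls[, .(chrom, start, end)], track)
  calls[, `:=`(local_depth = dd$local_depth, norm_depth = dd$norm_depth,
               depth_usable = dd$depth_usable)]
  setorder(calls, chrom, start, end)
  structure(list(pool_id = pool_id,
                 profile = synthetic_profile(pool_id),
                 genome_median_depth = track$genome_median,
                 calls = calls[], depth = track,
                 discarded = list()),
            class = "pool_cnv_catalog")
}

maskless_genome <- function() genome_model(c(chr1 = 1e6))

test_that("between-pool matching applies the half-mean-size rule", {
  g <- maskless_genome()
  a <- uniform_catalog("A", data.frame(chrom = "chr1",
                                       start = c(1000L, 50000L),
                                       end = c(2000L, 51000L)), g)
  # partner at distance 400 (< 500): BOTH; partner at 600: no match
  b <- uniform_catalog("B", data.frame(chrom = "chr1",
                                       start = c(1400L, 50600L),
                                       end = c(2400L, 51600L)), g)
  m <- match_between_pools(a, b)
  expect_setequal(m$status, c("BOTH", "ONLY_A", "ONLY_B"))
  expect_equal(m[status == "BOTH", start_a], 1000L)
  expect_equal(sum(m$status == "ONLY_A"), 1L)
  expect_equal(sum(m$status == "ONLY_B"), 1L)

  # identical coordinates: BOTH with zero deltas
  b2 <- uniform_catalog("B", data.frame(chrom = "chr1", start = 1000L,
                                        end = 2000L), g)
  a2 <- uniform_catalog("A", data.frame(chrom = "chr1", start = 1000L,
                                        end = 2000L), g)
  m2 <- match_between_pools(a2, b2)
  expect_equal(m2$status, "BOTH")
  expect_equal(m2$delta_support_norm, 0)
  expect_equal(m2$depth_log2ratio, 0)
})

test_that("the comparability rule itself follows the spec arithmetic", {
  expect_true(comparable_half_mean(1000, 2000, 1400, 2400))   # 400 < 500
  expect_false(comparable_half_mean(1000, 2000, 1600, 2600))  # 600 >= 500
  expect_true(comparable_half_mean(1000, 2000, 1000, 2000))
})

test_that("matching is symmetric under catalogue exchange", {
  g <- maskless_genome()
  set.seed(5)
  mk <- function(pool) {
    s <- sort(sample.int(9e5, 30L))
    uniform_catalog(pool, data.frame(chrom = "chr1", start = s,
                                     end = s + sample(200:3000, 30L)), g)
  }
  a <- mk("A"); b <- mk("B")
  m_ab <- match_between_pools(a, b)
  m_ba <- match_between_pools(b, a)
  expect_equal(sum(m_ab$status == "BOTH"), sum(m_ba$status == "BOTH"))
  expect_equal(m_ab[status == "BOTH", .(start_a, end_a, start_b, end_b)],
               m_ba[status == "BOTH", .(start_a = start_b, end_a = end_b,
                                        start_b = start_a, end_b = end_a)])
  expect_equal(m_ab[status == "ONLY_A", .(chrom, start, end)],
               m_ba[status == "ONLY_B", .(chrom, start, end)])
})

test_that("identical depth tracks yield symmetric null cutoffs at exactly zero", {
  g <- maskless_genome()
  s <- seq(10000L, 980000L, length.out = 25L)
  calls <- data.frame(chrom = "chr1", start = as.integer(s),
                      end = as.integer(s + 1000L))
  a <- uniform_catalog("A", calls, g)
  b <- uniform_catalog("B", calls, g)
  m <- match_between_pools(a, b)
  expect_equal(sum(m$status == "BOTH"), 25L)
  thr <- build_thresholds(m, a, b, g, n_random = 200L, seed = 3L)
  expect_equal(thr$support_cutoff_basis, "both_matches")
  expect_true(all(thr$depth_cutoffs$low == 0))
  expect_true(all(thr$depth_cutoffs$high == 0))
  expect_equal(nrow(thr$depth_cutoffs), 9L)
  # determinism
  thr2 <- build_thresholds(m, a, b, g, n_random = 200L, seed = 3L)
  expect_identical(thr$depth_cutoffs, thr2$depth_cutoffs)
  # a genome too small for a bin names the bin
  tiny <- genome_model(c(chr1 = 5000L))
  err <- tryCatch(build_thresholds(m, a, b, tiny, n_random = 200L, seed = 3L),
                  error = conditionMessage)
  expect_match(err, "5000")
})

# hand-built matches rows for direct significance-logic tests
mk_match <- function(status, cnv_type, supnorm_a, supnorm_b, ratio,
                     mean_size = 1000, usable = TRUE) {
  data.table(locus_id = "L1", comparison_id = "A_vs_B", status = status,
             chrom = "chr1", start = 1000L, end = 1000L + mean_size,
             cnv_type = cnv_type, mean_size = mean_size,
             pool_a = "A", pool_b = "B",
             support_a = round(supnorm_a * 30), support_b = round(supnorm_b * 30),
             supnorm_a = supnorm_a, supnorm_b = supnorm_b,
             delta_support_norm = abs(supnorm_a - supnorm_b),
             depth_log2ratio = ratio, depth_usable = usable)
}

mk_thresholds <- function(cutoff = 0.3, low = -0.5, high = 0.5) {
  structure(list(comparison_id = "A_vs_B", support_cutoff = cutoff,
                 support_cutoff_basis = "both_matches",
                 depth_cutoffs = data.table(bin = depth_length_bins(),
                                            low = low, high = high),
                 n_random = 100L, seed = 1L, eps = 0.01),
            class = "divergence_thresholds")
}

test_that("significance needs support, depth and concordance together", {
  thr <- mk_thresholds(cutoff = 0.3, low = -0.5, high = 0.5)
  # fixed presence/absence deletion: carrier A, depth collapsed in A
  d1 <- test_divergence(mk_match("ONLY_A", "DEL", 0.66, 0, -4), thr)
  expect_true(d1$significant)
  expect_equal(d1$direction, "A")
  expect_equal(d1$fixity, "FIXED_PRESENCE_ABSENCE")

  # support significant but ratio inside the null band
  d2 <- test_divergence(mk_match("ONLY_A", "DEL", 0.66, 0, -0.2), thr)
  expect_false(d2$significant)
  expect_true(d2$support_sig)
  expect_false(d2$depth_sig)

  # support favours A but depth implicates B (DEL: carrier has LOWER depth)
  d3 <- test_divergence(mk_match("BOTH", "DEL", 0.66, 0.1, +2), thr)
  expect_false(d3$significant)
  expect_false(d3$concordant)

  # duplications: carrier pool has HIGHER relative depth
  d4 <- test_divergence(mk_match("ONLY_A", "DUP", 0.66, 0, +1.2), thr)
  expect_true(d4$significant)
  d5 <- test_divergence(mk_match("ONLY_A", "DUP", 0.66, 0, -1.2), thr)
  expect_false(d5$concordant)

  # significant BOTH matches are quantitative
  d6 <- test_divergence(mk_match("BOTH", "DEL", 0.66, 0.1, -2), thr)
  expect_true(d6$significant)
  expect_equal(d6$fixity, "QUANTITATIVE")

  # unusable depth can never be significant
  d7 <- test_divergence(mk_match("ONLY_A", "DEL", 0.66, 0, NA_real_,
                                 usable = FALSE), thr)
  expect_false(d7$significant)
})

test_that("widening cutoffs never increases the significant count", {
  run <- demo_run(1L)
  m <- run$comparisons$focal_1$matches
  base <- run$comparisons$focal_1$thresholds
  count_sig <- function(cutoff_mult, band_mult) {
    thr <- base
    thr$support_cutoff <- base$support_cutoff * cutoff_mult
    thr$depth_cutoffs <- copy(base$depth_cutoffs)[, `:=`(
      low = low * band_mult, high = high * band_mult)]
    nrow(test_divergence(m, thr)[significant == TRUE])
  }
  counts <- c(count_sig(1, 1), count_sig(2, 1), count_sig(2, 2),
              count_sig(4, 4))
  expect_true(all(diff(counts) <= 0))
})

test_that("length-bin assignment minimizes distance with ties to the smaller bin", {
  bins <- depth_length_bins()
  assign_length_bin <- cnvdisplace:::assign_length_bin
  expect_equal(assign_length_bin(c(50, 74, 75, 76, 120, 8000, 20000), bins),
               c(50L, 50L, 50L, 100L, 100L, 8000L, 8000L))
})

test_that("the planted fixture comparison finds the planted variants and direction", {
  cats <- planted_catalogs()
  fx <- planted_fixture()
  cmp <- compare_pools(cats$C1, cats$N1, fx$genome, n_random = 2000L,
                       seed = 5L)
  sig <- cmp$significant
  for (i in seq_len(nrow(fx$truth))) {
    hit <- sig[chrom == fx$truth$chrom[i] & start < fx$truth$end[i] &
                 end > fx$truth$start[i] & cnv_type == fx$truth$cnv_type[i]]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$direction, "C1")
    expect_equal(hit$status, "ONLY_A")
    expect_equal(hit$fixity, "FIXED_PRESENCE_ABSENCE")
  }
})
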