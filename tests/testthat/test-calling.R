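# synthetic distant-pair cluster: n pairs implying a deletion at [s, e)
# with endpoint jitter
del_cluster_pairs <- function(n, s = 10000L, e = 12000L, jitter = 0L,
                              pool = "P") {
  off <- if (jitter > 0L) seq(-jitter, jitter, length.out = n) else rep(0L, n)
  left_end <- as.integer(round(s + off))
  right_start <- as.integer(round(e + rev(off)))
  data.table(pair_id = seq_len(n), pool = pool, chrom = "chr1",
             left_start = left_end - 100L, left_end = left_end,
             right_start = right_start, right_end = right_start + 100L,
             orientation = "INWARD",
             insert = right_start + 100L - (left_end - 100L))
}

test_that("the five-supporting-pair minimum is sharp", {
  prof <- synthetic_profile()
  p5 <- del_cluster_pairs(5L, jitter = 100L)
  out5 <- cluster_discordant(p5, prof, "DEL")
  expect_equal(nrow(out5$clusters), 1L)
  expect_equal(out5$clusters$support, 5L)
  # removing any single member removes the call
  for (drop in 1:5) {
    out4 <- cluster_discordant(p5[-drop], prof, "DEL")
    expect_equal(nrow(out4$clusters), 0L)
    expect_equal(out4$n_discarded, 4L)
  }
})

test_that("well-separated groups form separate clusters and pairs join at most one", {
  prof <- synthetic_profile()
  p <- rbind(del_cluster_pairs(5L, s = 10000L, e = 12000L, jitter = 100L),
             del_cluster_pairs(5L, s = 110000L, e = 112000L, jitter = 100L))
  p[, pair_id := seq_len(.N)]
  out <- cluster_discordant(p, prof, "DEL")
  expect_equal(nrow(out$clusters), 2L)
  ids <- unlist(out$clusters$member_pair_ids)
  expect_equal(sort(ids), 1:10)
  expect_equal(anyDuplicated(ids), 0L)
  # mixed-class stream is a usage error
  mixed <- rbind(p, make_pairs("P", "chr1", 0L, 400L,
                               orientation = "EVERTED"))
  expect_error(cluster_discordant(mixed, prof, "DEL"),
               class = "cnv_usage_error")
})

test_that("interval estimation takes lower-middle medians and drops degenerate geometry", {
  cl <- data.table(cluster = 1L, chrom = "chr1", support = 5L,
                   cnv_type = "DEL",
                   member_starts = list(c(998, 1000, 1002, 1000, 999)),
                   member_ends = list(c(1996, 2000, 2004, 2001, 2000)))
  est <- estimate_interval(cl)
  expect_equal(est$start, 1000L)
  expect_equal(est$end, 2000L)

  # even cardinality: lower middle value
  cl_even <- data.table(cluster = 1L, chrom = "chr1", support = 6L,
                        cnv_type = "DUP",
                        member_starts = list(c(10, 20, 30, 40)),
                        member_ends = list(c(100, 110, 120, 130)))
  est2 <- estimate_interval(cl_even)
  expect_equal(est2$start, 20L)
  expect_equal(est2$end, 110L)

  # duplication members spanning [5000,7000) with noise <= 50: the estimate
  # must match a sort-based median oracle and stay within [4950, 7050)
  set.seed(31)
  noise_s <- sample(-50:50, 9L); noise_e <- sample(-50:50, 9L)
  cl_dup <- data.table(cluster = 1L, chrom = "chr1", support = 9L,
                       cnv_type = "DUP",
                       member_starts = list(5000 + noise_s),
                       member_ends = list(7000 + noise_e))
  est3 <- estimate_interval(cl_dup)
  oracle_med <- function(x) sort(x)[ceiling(length(x) / 2)]
  expect_equal(est3$start, oracle_med(5000 + noise_s))
  expect_equal(est3$end, oracle_med(7000 + noise_e))
  expect_gte(est3$start, 4950L)
  expect_lte(est3$end, 7050L)

  # end <= start is unresolvable
  cl_bad <- data.table(cluster = 1L, chrom = "chr1", support = 5L,
                       cnv_type = "DEL",
                       member_starts = list(rep(2000, 5)),
                       member_ends = list(rep(1500, 5)))
  est4 <- estimate_interval(cl_bad)
  expect_equal(nrow(est4), 0L)
  expect_equal(attr(est4, "n_unresolvable"), 1L)
})

test_that("depth is averaged over unmasked bases only", {
  g <- genome_model(c(chr1 = 10000L),
                    masked = data.frame(chrom = "chr1", start = 1000L,
                                        end = 1400L))
  # uniform 30X outside nothing: tile reads end to end
  p <- make_pairs("P", "chr1", left_start = rep(seq(0L, 9500L, by = 100L),
                                                each = 15),
                  insert = 200L)
  track <- pool_depth_track(p, g)
  d <- compute_depth(data.table(chrom = "chr1", start = 1000L, end = 2000L),
                     track)
  # 400 of 1000 bp masked; unmasked bases still at uniform depth
  expect_equal(d$local_depth, 30)
  expect_equal(d$norm_depth, 1)
  expect_true(d$depth_usable)
  # an interval >90% masked is unusable
  g2 <- genome_model(c(chr1 = 10000L),
                     masked = data.frame(chrom = "chr1", start = 1000L,
                                         end = 1950L))
  track2 <- pool_depth_track(p, g2)
  d2 <- compute_depth(data.table(chrom = "chr1", start = 1000L, end = 2000L),
                      track2)
  expect_false(d2$depth_usable)
  expect_true(is.na(d2$local_depth))
})

test_that("homozygous planted deletions are recovered with accurate intervals", {
  run <- demo_run(1L)
  truth <- run$truth
  cat_c1 <- run$catalogs$C1
  carried <- truth[C1 == 1 & cnv_type == "DEL" & end - start >= 1000L]
  hits <- vapply(seq_len(nrow(carried)), function(i) {
    cand <- cat_c1$calls[cnv_type == "DEL" & chrom == carried$chrom[i] &
                           start < carried$end[i] & end > carried$start[i]]
    if (nrow(cand) == 0L) return(0)
    max(reciprocal_overlap(cand$start, cand$end, carried$start[i],
                           carried$end[i]))
  }, numeric(1L))
  expect_gte(mean(hits >= 0.8), 0.9)
  # homozygous deletion depth proxy collapses
  del_calls <- cat_c1$calls[overlaps_any(chrom, start, end,
                                         carried) & cnv_type == "DEL"]
  expect_lt(max(del_calls$local_depth), 2)
})

test_that("calling is deterministic", {
  fx <- planted_fixture()
  c1 <- call_pool(fx$pairsC, genome = fx$genome)
  c2 <- call_pool(fx$pairsC, genome = fx$genome)
  expect_identical(c1$calls, c2$calls)
  expect_identical(c1$genome_median_depth, c2$genome_median_depth)
})

test_that("catalogue VCF export is 1-based-safe and re-importable without drift", {
  cats <- planted_catalogs()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "calls.vcf")
  write_calls_vcf(cats$C1, planted_fixture()$genome, path)
  back <- read_calls_vcf(path)
  expect_equal(back$start, cats$C1$calls$start)
  expect_equal(back$end, cats$C1$calls$end)
  expect_equal(back$cnv_type, cats$C1$calls$cnv_type)
  expect_equal(back$support, cats$C1$calls$support)
  # VCF body POS column is the 0-based start (symbolic-allele padding base)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  pos <- as.integer(vapply(strsplit(body, "\t"), `[[`, "", 2L))
  expect_equal(pos, cats$C1$calls$start)
})
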