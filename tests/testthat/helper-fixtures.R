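library(data.table)

# memoized fixtures: heavy simulations are built once per test session
.fixtures <- new.env(parent = emptyenv())
cached_fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# 1 Mb single-chromosome genome with light masking and a gene track
small_genome <- function() cached_fixture("small_genome", {
  simulate_genome(1L, 1e6, 0.05,
                  track_spec = list(genes = list(n = 40L, len = 5000L)),
                  seed = 42L)
})

# planted two-variant fixture on the small genome: one homozygous deletion,
# one homozygous tandem duplication in pool C1; absent from pool N1
planted_fixture <- function() cached_fixture("planted_fixture", {
  g <- small_genome()
  truth <- plant_cnvs(g, data.frame(
    chrom = "chr1", start = c(300000L, 600000L), end = c(303000L, 602000L),
    cnv_type = c("DEL", "DUP"), C1 = c(1, 1), N1 = c(0, 0)))
  profC <- pool_profile("C1", "Choosy")
  profN <- pool_profile("N1", "NonChoosy")
  pairsC <- simulate_pool_reads(g, truth, profC, seed = 7L)
  pairsN <- simulate_pool_reads(g, truth, profN, seed = 8L)
  list(genome = g, truth = truth, profC = profC, profN = profN,
       pairsC = pairsC, pairsN = pairsN)
})

planted_catalogs <- function() cached_fixture("planted_catalogs", {
  fx <- planted_fixture()
  list(C1 = call_pool(fx$pairsC, genome = fx$genome),
       N1 = call_pool(fx$pairsN, genome = fx$genome))
})

# hand-built insert profile for synthetic-cluster tests
synthetic_profile <- function(pool_id = "P", upper1pct = 700L) {
  structure(list(pool_id = pool_id, n_pairs = 1000L, mean = 480,
                 sd = 50, upper1pct = upper1pct, read_length = 100L),
            class = "insert_profile")
}

# synthetic single-pool pair table builder
make_pairs <- function(pool, chrom, left_start, insert,
                       orientation = "INWARD", read_length = 100L) {
  n <- max(length(left_start), length(insert))
  left_start <- rep_len(as.integer(left_start), n)
  insert <- rep_len(as.integer(insert), n)
  data.table(pair_id = seq_len(n), pool = pool, chrom = chrom,
             left_start = left_start, left_end = left_start + read_length,
             right_start = left_start + insert - read_length,
             right_end = left_start + insert,
             orientation = rep_len(orientation, n), insert = insert)
}

# full demonstration run (the packaged four-pool scenario), cached
demo_run <- function(seed = 1L) cached_fixture(paste0("demo_run_", seed), {
  run_pipeline(demo_config(seed = seed))
})

null_run <- function(seed) cached_fixture(paste0("null_run_", seed), {
  run_pipeline(demo_config(seed = seed, null_run = TRUE),
               through = "candidates")
})

# does interval i overlap any interval in table tab (same chrom)?
overlaps_any <- function(chrom, start, end, tab) {
  vapply(seq_along(chrom), function(i)
    any(tab$chrom == chrom[i] & tab$start < end[i] & tab$end > start[i]),
    logical(1L))
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}
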