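#!/usr/bin/env Rscript

# Stage 4 — replicate consistency, control subtraction and candidates.
#
# Matches significant loci across the two focal comparisons (identical /
# non-identical by state under the 5%-of-mean-size rule), keeps only those
# diverging toward the same behavioural class in both, removes loci that
# repeat in the control test, and classifies the survivors as Choosiness- or
# Non-Choosiness-associated with their fixity. Also reports the one-tailed
# binomial check of whether parallel divergence exceeds the 5% background
# repeat rate, and the full count ledger.

suppressPackageStartupMessages({
  library(cnvdisplace)
  library(data.table)
})

cache <- "results/run_cache.rds"
if (!file.exists(cache))
  stop("run cache missing; run analysis/03_pairwise_divergence.R first")
run <- readRDS(cache)
r <- run$report

message(sprintf("focal matched: %d; direction-consistent: %d",
                r$focal_cross_matched, r$focal_consistent))
message(sprintf("control consistent: %d; focal loci removed by control: %d",
                r$control_consistent, r$control_removed))
message(sprintf("confirmed: %d = %d - %d (identity holds: %s)",
                r$confirmed, r$focal_consistent, r$control_removed,
                r$identity_subtraction))
message(sprintf("choosiness %d + non-choosiness %d; IBS identical %d / non-identical %d; parallel fixed %d",
                r$choosiness, r$non_choosiness, r$identical_by_state,
                r$non_identical_by_state, r$parallel_fixed))

# is parallel divergence enriched over a 5% background repeat rate?
k <- r$focal_consistent
n <- length(unique(run$comparisons$focal_1$significant$locus_id))
p <- parallel_enrichment(k, n, 0.05)
message(sprintf("parallel enrichment: k=%d of n=%d, one-tailed binomial p = %.4g",
                k, n, p))

write_run(run, "results/candidates")
jsonlite::write_json(list(k = k, n = n, p0 = 0.05, p = p),
                     "results/candidates/parallel_enrichment.json",
                     auto_unbox = TRUE, digits = NA)
message("wrote candidate tables and report under results/candidates")
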