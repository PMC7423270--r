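#!/usr/bin/env Rscript

# Stage 2 — per-pool CNV calling.
#
# Reads the simulated pair tables from stage 1, fits each pool's insert-size
# profile (mean, sd, upper first percentile of inward inserts), classifies
# pairs (proper / distant / everted), clusters discordant pairs into
# deletion and tandem-duplication calls with >= 5 supporting pairs, and
# attaches the two allele-frequency proxies. Writes per-pool catalogues
# (TSV + VCF) and profile summaries under results/calls/.

suppressPackageStartupMessages({
  library(cnvdisplace)
  library(data.table)
})

sim_dir <- "results/simulation"
out_dir <- "results/calls"
if (!dir.exists(sim_dir))
  stop("stage 1 outputs missing; run analysis/01_simulate.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

gi <- fread(file.path(sim_dir, "C1.genome.tsv"), header = FALSE,
            col.names = c("chrom", "length"))
masked <- fread(file.path(sim_dir, "C1.masked.bed"), header = FALSE,
                col.names = c("chrom", "start", "end"))
genome <- genome_model(setNames(gi$length, gi$chrom), masked = masked)

for (pool in c("C1", "C2", "N1", "N2")) {
  pairs <- read_pair_table(file.path(sim_dir, paste0(pool, ".pairs.tsv")))
  prof <- fit_insert_profile(pairs)
  print(prof)
  catalog <- call_pool(pairs, prof, genome)
  print(catalog)
  fwrite(catalog$calls, file.path(out_dir, paste0(pool, ".calls.tsv")),
         sep = "\t")
  write_calls_vcf(catalog, genome, file.path(out_dir, paste0(pool, ".vcf")))
  jsonlite::write_json(
    list(pool = prof$pool_id, n = prof$n_pairs, mean = prof$mean,
         sd = prof$sd, upper1pct = prof$upper1pct,
         genome_median_depth = catalog$genome_median_depth,
         discarded = catalog$discarded),
    file.path(out_dir, paste0(pool, ".profile.json")),
    auto_unbox = TRUE, digits = NA)
  rm(pairs, catalog); invisible(gc())
}
message("wrote per-pool catalogues under ", out_dir)
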