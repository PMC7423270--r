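#!/usr/bin/env Rscript

# Stage 5 — genomic context of the candidates.
#
# Masked-genome-aware permutation tests (10,000 placements) on the candidate
# set: spatial clustering per 10-kb bin, overlap with genes extended by 1 kb,
# and overlap with recombination cold-spots and hot-spots; plus the
# candidate size summary.

suppressPackageStartupMessages({
  library(cnvdisplace)
  library(data.table)
})

cache <- "results/run_cache.rds"
if (!file.exists(cache))
  stop("run cache missing; run analysis/03_pairwise_divergence.R first")
run <- readRDS(cache)

out_dir <- "results/context"
dir.create(out_dir, showWarnings = FALSE)

if (length(run$context) == 0L) {
  message("fewer than two candidates; no context tests to report")
} else {
  res <- list()
  for (nm in setdiff(names(run$context), "sizes")) {
    x <- run$context[[nm]]
    print(x)
    res[[nm]] <- list(statistic = x$statistic_name, observed = x$observed,
                      null_mean = x$null_mean, null_sd = x$null_sd,
                      z = x$z, p_empirical = x$p_empirical, tail = x$tail,
                      n_perm = x$n_perm, degenerate = x$degenerate)
  }
  s <- run$context$sizes
  message(sprintf("candidate sizes: n=%d mean=%.1f bp se=%.2f bp range [%d, %d]",
                  s$n, s$mean, s$se, s$min, s$max))
  res$sizes <- s[c("n", "mean", "se", "min", "max")]
  jsonlite::write_json(res, file.path(out_dir, "context.json"),
                       auto_unbox = TRUE, digits = NA)
  fwrite(s$histogram, file.path(out_dir, "size_histogram.tsv"), sep = "\t")
  # per-candidate track hits
  hits <- run$candidates[, .(chrom, start, end, cnv_type, association)]
  for (tr in names(run$genome$tracks)) {
    flank <- if (tr == "genes") run$config$params$gene_flank else 0L
    tt <- run$genome$tracks[[tr]]
    hits[[tr]] <- vapply(seq_len(nrow(hits)), function(i)
      any(tt$chrom == hits$chrom[i] & tt$start - flank < hits$end[i] &
            tt$end + flank > hits$start[i]), logical(1L))
  }
  fwrite(hits, file.path(out_dir, "candidate_track_hits.tsv"), sep = "\t")
}
message("wrote context results under ", out_dir)
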