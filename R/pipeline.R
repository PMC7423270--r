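#' Assemble and validate a run configuration
#'
#' One audited surface for every constant of a run: the genome simulation,
#' the four pools, the comparison plan, analysis thresholds and the master
#' seed. Stage seeds are all derived from the master seed, so a config fully
#' determines every output.
#'
#' @param genome_spec list(n_chroms, chrom_length, masked_fraction,
#'   track_spec, masked_len).
#' @param pools data.frame: pool_id, behaviour, and optionally
#'   n_individuals, target_depth, insert_mean, insert_sd, read_length.
#' @param truth_spec data.frame of CNVs to plant (see [plant_cnvs()]), a
#'   `truth_request` from [truth_request()], or NULL for a null run.
#' @param focal,control optional comparison pairs (see [comparison_plan()]).
#' @param params list overriding analysis defaults: min_support (5),
#'   min_size (50), n_random (10000), n_perm (10000), ibs_tol (0.05),
#'   eps (0.01), gene_flank (1000), clustering_window (10000).
#' @param seed master integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(genome_spec, pools, truth_spec = NULL, focal = NULL,
                       control = NULL, params = list(), seed = 1L) {
  defaults <- list(min_support = 5L, min_size = 50L, n_random = 10000L,
                   n_perm = 10000L, ibs_tol = 0.05, eps = 0.01,
                   gene_flank = 1000L, clustering_window = 10000L)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0L)
    cnd_stop(paste("unknown parameter(s):", paste(unknown, collapse = ", ")),
             "cnv_config_error")
  params <- utils::modifyList(defaults, params)
  if (params$min_support < 1L || params$ibs_tol <= 0 || params$ibs_tol >= 1 ||
      params$n_perm < 1L || params$n_random < 1L || params$eps <= 0)
    cnd_stop("parameter out of range", "cnv_config_error")
  pools <- as.data.table(pools)
  defaults_pool <- list(n_individuals = 30L, target_depth = 30,
                        insert_mean = 480, insert_sd = 50, read_length = 100L)
  for (nm in names(defaults_pool))
    if (!nm %in% names(pools)) pools[[nm]] <- defaults_pool[[nm]]
  plan <- comparison_plan(pools[, .(pool_id, behaviour)], focal, control)
  structure(list(genome_spec = genome_spec, pools = pools,
                 truth_spec = truth_spec, plan = plan, params = params,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Describe truth CNVs by size and frequency pattern
#'
#' A placement-free truth request: concrete non-overlapping coordinates in
#' unmasked sequence are drawn when the genome is known (deterministically,
#' from the run's master seed).
#'
#' @param sizes CNV sizes in bp.
#' @param cnv_type "DEL"/"DUP", recycled.
#' @param freq data.frame/matrix with one column per pool and one row per
#'   CNV (or a single row, recycled): allele frequencies in each pool.
#' @return object of class `truth_request`.
#' @export
truth_request <- function(sizes, cnv_type, freq) {
  freq <- as.data.table(freq)
  n <- length(sizes)
  cnv_type <- rep_len(cnv_type, n)
  if (nrow(freq) == 1L) freq <- freq[rep(1L, n)]
  stopifnot(nrow(freq) == n)
  structure(list(sizes = as.integer(sizes), cnv_type = cnv_type, freq = freq),
            class = "truth_request")
}

#' @export
c.truth_request <- function(...) {
  reqs <- list(...)
  structure(list(sizes = unlist(lapply(reqs, `[[`, "sizes")),
                 cnv_type = unlist(lapply(reqs, `[[`, "cnv_type")),
                 freq = rbindlist(lapply(reqs, `[[`, "freq"))),
            class = "truth_request")
}

# draw non-overlapping unmasked coordinates for a truth request; a margin
# keeps planted events at least one fragment length apart and off masked
# sequence so their read-pair signatures do not interact
place_truth <- function(genome, request, seed, margin = 5000L) {
  if (is.null(request)) return(NULL)
  if (is.data.frame(request)) return(plant_cnvs(genome, request))
  set.seed(seed)
  n <- length(request$sizes)
  placed <- data.table(chrom = character(n), start = integer(n),
                       end = integer(n))
  occupied <- data.table(chrom = character(), start = integer(),
                         end = integer())
  for (i in order(-request$sizes)) {
    len <- request$sizes[i]
    for (try in 1:200) {
      cand <- sample_unmasked_regions(genome, len + 2L * margin, 1L)
      cand[, `:=`(start = start + margin, end = end - margin)]
      clash <- occupied[chrom == cand$chrom &
                          start < cand$end + margin &
                          end > cand$start - margin]
      if (nrow(clash) == 0L) break
      cand <- NULL
    }
    if (is.null(cand))
      cnd_stop(sprintf("could not place a %d bp truth CNV", len),
               "cnv_placement_error")
    placed[i, `:=`(chrom = cand$chrom, start = cand$start, end = cand$end)]
    occupied <- rbind(occupied, cand)
  }
  truth <- cbind(placed, cnv_type = request$cnv_type, request$freq)
  plant_cnvs(genome, truth)
}

#' The packaged demonstration scenario
#'
#' A four-pool study at full library realism on a desk-scale genome: two 10
#' Mb chromosomes, 5% masked, gene/cold-spot/hot-spot tracks, four pools of
#' 30 diploids at 30X (100 bp paired-end reads, 480 +/- 50 bp inserts).
#' Planted variants cover the outcome classes of interest: ten deletions and
#' three tandem duplications fixed in both Choosy pools and absent in both
#' Non-Choosy pools (the copy-number displacement pattern), five deletions
#' with the mirror pattern, five single-pool decoys and five shared neutral
#' deletions.
#'
#' @param seed master seed.
#' @param null_run if TRUE, no CNVs are planted.
#' @param params analysis parameter overrides (see [run_config()]).
#' @return a `run_config`.
#' @export
demo_config <- function(seed = 1L, null_run = FALSE, params = list()) {
  genome_spec <- list(n_chroms = 2L, chrom_length = 1e7, masked_fraction = 0.05,
                      track_spec = list(genes = list(n = 400L, len = 5000L),
                                        cold_spots = list(n = 40L, len = 50000L),
                                        hot_spots = list(n = 60L, len = 2000L)),
                      masked_len = 1000L)
  pools <- data.table(pool_id = c("C1", "C2", "N1", "N2"),
                      behaviour = c("Choosy", "Choosy",
                                    "NonChoosy", "NonChoosy"))
  fr <- function(c1, c2, n1, n2)
    data.table(C1 = c1, C2 = c2, N1 = n1, N2 = n2)
  truth <- c(
    truth_request(seq(1000L, 8200L, length.out = 10L), "DEL", fr(1, 1, 0, 0)),
    truth_request(c(1500L, 3000L, 5000L), "DUP", fr(1, 1, 0, 0)),
    truth_request(seq(1200L, 6000L, length.out = 5L), "DEL", fr(0, 0, 1, 1)),
    truth_request(seq(1000L, 5000L, length.out = 5L), "DEL", fr(1, 0, 0, 0)),
    truth_request(seq(1100L, 5500L, length.out = 5L), "DEL", fr(1, 1, 1, 1)))
  run_config(genome_spec, pools,
             truth_spec = if (null_run) NULL else truth,
             params = params, seed = seed)
}

#' Run the full copy-number displacement pipeline
#'
#' simulate -> profile -> call -> compare -> candidates -> context, all
#' seeded from the config. Stages can be limited with `through` (one of
#' "simulate", "call", "compare", "candidates", "context").
#'
#' @param config a `run_config`.
#' @param through last stage to run (default "context").
#' @param verbose print stage progress.
#' @param keep_depth keep each pool's per-base depth track in the returned
#'   catalogues. Tracks are large (run-length coverage over the whole
#'   genome); by default they are released once the comparison stage has
#'   consumed them.
#' @return object of class `cnd_run`: genome, truth, catalogs, comparisons,
#'   focal/control cross tables, candidates, context results and the count
#'   ledger from [run_report()].
#' @export
run_pipeline <- function(config, through = "context", verbose = FALSE,
                         keep_depth = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- c("simulate", "call", "compare", "candidates", "context")
  through <- match.arg(through, stages)
  say <- function(...) if (verbose) message(sprintf(...))
  pr <- config$params
  run <- list(config = config)

  gs <- config$genome_spec
  genome <- simulate_genome(gs$n_chroms, gs$chrom_length, gs$masked_fraction,
                            track_spec = gs$track_spec,
                            seed = derive_seed(config$seed, "genome"),
                            masked_len = gs$masked_len %||% 1000L)
  truth <- place_truth(genome, config$truth_spec,
                       seed = derive_seed(config$seed, "truth"))
  run$genome <- genome; run$truth <- truth
  say("genome: %d chrom x %g bp; %d truth CNVs", gs$n_chroms, gs$chrom_length,
      if (is.null(truth)) 0L else nrow(truth))
  if (through == "simulate") return(structure(run, class = "cnd_run"))

  catalogs <- list()
  for (i in seq_len(nrow(config$pools))) {
    p <- config$pools[i]
    prof <- pool_profile(p$pool_id, p$behaviour, p$n_individuals,
                         p$target_depth, p$insert_mean, p$insert_sd,
                         p$read_length)
    pairs <- simulate_pool_reads(genome, truth, prof,
                                 seed = derive_seed(config$seed,
                                                    paste0("reads_", p$pool_id)))
    catalogs[[p$pool_id]] <- call_pool(pairs, genome = genome,
                                       min_support = pr$min_support,
                                       min_size = pr$min_size)
    say("pool %s: %d pairs -> %d calls", p$pool_id, nrow(pairs),
        nrow(catalogs[[p$pool_id]]$calls))
    rm(pairs); gc(verbose = FALSE)
  }
  run$catalogs <- catalogs
  if (through == "call") return(structure(run, class = "cnd_run"))

  all_pairs <- c(config$plan$focal, config$plan$control)
  names(all_pairs) <- c("focal_1", "focal_2", "control_1", "control_2")
  comparisons <- list()
  for (nm in names(all_pairs)) {
    pp <- all_pairs[[nm]]
    comparisons[[nm]] <- compare_pools(
      catalogs[[pp[1L]]], catalogs[[pp[2L]]], genome,
      n_random = pr$n_random,
      seed = derive_seed(config$seed, paste0("thresholds_", nm)),
      eps = pr$eps)
    say("%s (%s vs %s): %d significant", nm, pp[1L], pp[2L],
        nrow(comparisons[[nm]]$significant))
  }
  for (pid in names(catalogs)) {
    clear_depth_cache(catalogs[[pid]])
    if (!keep_depth) catalogs[[pid]]$depth <- NULL
  }
  run$catalogs <- catalogs
  gc(verbose = FALSE)
  run$comparisons <- comparisons
  if (through == "compare") return(structure(run, class = "cnd_run"))

  plan <- config$plan
  focal_cross <- match_across_comparisons(comparisons$focal_1$significant,
                                          comparisons$focal_2$significant,
                                          ibs_tol = pr$ibs_tol)
  focal_consistent <- enforce_direction(focal_cross, plan, "focal")
  control_cross <- match_across_comparisons(comparisons$control_1$significant,
                                            comparisons$control_2$significant,
                                            ibs_tol = pr$ibs_tol)
  control_consistent <- enforce_direction(control_cross, plan, "control")
  sub <- subtract_control(focal_consistent, control_consistent,
                          ibs_tol = pr$ibs_tol)
  candidates <- classify_candidates(sub$confirmed, plan)
  run$focal_cross <- focal_cross
  run$focal_consistent <- focal_consistent
  run$control_cross <- control_cross
  run$control_consistent <- control_consistent
  run$control_removed <- sub$removed
  run$candidates <- candidates
  say("focal consistent %d - control removed %d -> %d candidates",
      nrow(focal_consistent), nrow(sub$removed), nrow(candidates))
  if (through == "candidates") {
    run$report <- run_report(run)
    return(structure(run, class = "cnd_run"))
  }

  ctx <- list()
  if (nrow(candidates) >= 2L) {
    cc <- candidates[, .(chrom, start, end)]
    ctx$clustering <- clustering_test(cc, genome,
                                      window = pr$clustering_window,
                                      n_perm = pr$n_perm,
                                      seed = derive_seed(config$seed,
                                                         "perm_clustering"))
    for (tr in names(genome$tracks)) {
      flank <- if (tr == "genes") pr$gene_flank else 0L
      tail <- if (tr == "genes") "two_sided" else "greater"
      ctx[[tr]] <- overlap_enrichment(
        cc, genome$tracks[[tr]], flank = flank, genome = genome,
        n_perm = pr$n_perm, seed = derive_seed(config$seed,
                                               paste0("perm_", tr)),
        tail = tail,
        statistic_name = paste0("cnvs_overlapping_", tr))
    }
    ctx$sizes <- summarize_sizes(candidates)
  }
  run$context <- ctx
  run$report <- run_report(run)
  structure(run, class = "cnd_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count ledger for a run
#'
#' The walk from per-pool catalogues to candidates: per-pool call counts,
#' per-comparison significant counts, focal/control consistent counts,
#' control removals, confirmed candidates and their association / identity
#' by state / fixity splits, plus the ledger identities
#' `confirmed = focal_consistent - control_removed` and
#' `choosiness + non_choosiness = confirmed`.
#'
#' @param run a `cnd_run` (through the candidates stage).
#' @return named list of counts.
#' @export
run_report <- function(run) {
  cand <- run$candidates
  rep_ <- list(
    pool_calls = lapply(run$catalogs, function(ct)
      list(total = nrow(ct$calls),
           DEL = sum(ct$calls$cnv_type == "DEL"),
           DUP = sum(ct$calls$cnv_type == "DUP"))),
    comparison_significant = lapply(run$comparisons, function(cm)
      nrow(cm$significant)),
    focal_cross_matched = nrow(run$focal_cross),
    focal_consistent = nrow(run$focal_consistent),
    control_cross_matched = nrow(run$control_cross),
    control_consistent = nrow(run$control_consistent),
    control_removed = nrow(run$control_removed),
    confirmed = nrow(cand),
    choosiness = sum(cand$association == "CHOOSINESS"),
    non_choosiness = sum(cand$association == "NON_CHOOSINESS"),
    identical_by_state = sum(cand$ibs == "IDENTICAL"),
    non_identical_by_state = sum(cand$ibs == "NON_IDENTICAL"),
    parallel_fixed = sum(cand$fixity_class == "PARALLEL_FIXED"),
    quantitative = sum(cand$fixity_class == "QUANTITATIVE"))
  rep_$identity_subtraction <-
    rep_$confirmed == rep_$focal_consistent - rep_$control_removed
  rep_$identity_partition <-
    rep_$choosiness + rep_$non_choosiness == rep_$confirmed
  rep_
}

#' @export
print.cnd_run <- function(x, ...) {
  r <- x$report
  cat("copy-number displacement run\n")
  if (is.null(r)) {
    cat("  (candidates stage not reached)\n")
    return(invisible(x))
  }
  cat(sprintf("  focal consistent: %d; control removed: %d; confirmed: %d\n",
              r$focal_consistent, r$control_removed, r$confirmed))
  cat(sprintf("  choosiness: %d, non-choosiness: %d; identical-by-state: %d; parallel fixed: %d\n",
              r$choosiness, r$non_choosiness, r$identical_by_state,
              r$parallel_fixed))
  invisible(x)
}

#' Write the run's tables and report to a directory
#'
#' Candidate table as TSV and BED, per-comparison divergence tables as TSV,
#' thresholds and the count report as JSON, plus a manifest recording the
#' master seed and parameters.
#'
#' @param run a `cnd_run`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the files written.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  f <- file.path(out_dir, "candidates.tsv")
  fwrite(run$candidates, f, sep = "\t"); files <- c(files, f)
  if (nrow(run$candidates) > 0L) {
    f <- file.path(out_dir, "candidates.bed")
    fwrite(run$candidates[, .(chrom, start, end,
                              name = paste(cnv_type, association, ibs,
                                           sep = "|"))],
           f, sep = "\t", col.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(run$comparisons)) {
    f <- file.path(out_dir, paste0("divergence_", nm, ".tsv"))
    fwrite(run$comparisons[[nm]]$divergence, f, sep = "\t")
    files <- c(files, f)
    thr <- run$comparisons[[nm]]$thresholds
    f <- file.path(out_dir, paste0("thresholds_", nm, ".json"))
    jsonlite::write_json(list(comparison = thr$comparison_id,
                              support_cutoff = thr$support_cutoff,
                              support_cutoff_basis = thr$support_cutoff_basis,
                              depth_cutoffs = thr$depth_cutoffs,
                              n_random = thr$n_random, seed = thr$seed),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(run$report, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = run$config$seed,
                            params = run$config$params,
                            pools = run$config$pools,
                            package_version =
                              as.character(utils::packageVersion("cnvdisplace"))),
                       f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
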