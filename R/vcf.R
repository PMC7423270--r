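# Minimal symbolic-allele VCF export/import for per-pool CNV catalogues.
# Internal coordinates are 0-based half-open; VCF is 1-based inclusive with
# POS at the base before the event and END the last affected base, so
# POS = start (0-based start of the event = 1-based padding base) and
# END = end (0-based half-open end = 1-based last event base).

#' Export a CNV catalogue as VCF
#'
#' Symbolic `<DEL>`/`<DUP:TANDEM>` records with SVTYPE/END/SVLEN and
#' per-call SUPPORT and normalized-depth INFO keys.
#'
#' @param catalog a `pool_cnv_catalog`.
#' @param genome a `genome_model` (contig header lines).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_calls_vcf <- function(catalog, genome, path) {
  stopifnot(inherits(catalog, "pool_cnv_catalog"))
  calls <- catalog$calls
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$chromosomes),
            as.integer(genome$chromosomes)),
    "##ALT=<ID=DEL,Description=\"Deletion relative to the reference\">",
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication relative to the reference\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based end of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed variant length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting discordant read pairs\">",
    "##INFO=<ID=NDEPTH,Number=1,Type=Float,Description=\"Normalized local read depth\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t")))
  lines <- character(0)
  if (nrow(calls) > 0L) {
    alt <- ifelse(calls$cnv_type == "DEL", "<DEL>", "<DUP:TANDEM>")
    svlen <- ifelse(calls$cnv_type == "DEL", -calls$size, calls$size)
    nd <- ifelse(is.na(calls$norm_depth), ".",
                 sprintf("%.6g", calls$norm_depth))
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;SUPPORT=%d;NDEPTH=%s",
                    calls$cnv_type, calls$end, svlen, calls$support, nd)
    lines <- sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s",
                     calls$chrom, calls$start, calls$call_id, alt, info)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Import a catalogue VCF written by [write_calls_vcf()]
#'
#' @param path VCF path.
#' @return data.table: call_id, chrom, start, end, size, cnv_type, support,
#'   norm_depth (0-based half-open coordinates, drift-free round trip).
#' @export
read_calls_vcf <- function(path) {
  if (!file.exists(path))
    cnd_stop(paste("no such VCF:", path), "cnv_io_error")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L)
    return(data.table(call_id = character(), chrom = character(),
                      start = integer(), end = integer(), size = integer(),
                      cnv_type = character(), support = integer(),
                      norm_depth = numeric()))
  f <- data.table::tstrsplit(body, "\t")
  info_get <- function(info, key, as = as.integer) {
    m <- regmatches(info, regexpr(paste0("(?<=", key, "=)[^;]+"), info,
                                  perl = TRUE))
    m[m == "."] <- NA_character_
    as(m)
  }
  info <- f[[8L]]
  dt <- data.table(call_id = f[[3L]], chrom = f[[1L]],
                   start = as.integer(f[[2L]]),
                   end = info_get(info, "END"),
                   cnv_type = info_get(info, "SVTYPE", as.character),
                   support = info_get(info, "SUPPORT"),
                   norm_depth = info_get(info, "NDEPTH", as.numeric))
  dt[, size := end - start]
  setcolorder(dt, c("call_id", "chrom", "start", "end", "size", "cnv_type",
                    "support", "norm_depth"))
  dt[]
}
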