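.supported_exts <- "\\.(fq|fastq|fa|fasta)(\\.gz)?$|\\.bam$"

.default_prefix <- function(path) {
  sub("\\.(fq|fastq|fa|fasta)(\\.gz)?$|\\.bam$", "", basename(path),
      ignore.case = TRUE)
}

.write_manifest <- function(path, subcommand, options, inputs, outputs,
                            started, seed = NULL) {
  manifest <- list(
    tool = "hifiscrub",
    version = as.character(packageVersion("hifiscrub")),
    subcommand = subcommand,
    options = options,
    inputs = inputs,
    outputs = outputs,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(seed)) manifest$seed <- seed
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Filter adapter-contaminated reads from one or more files
#'
#' The full read-sanitation pipeline for each input file: scan every read for
#' adapter hits, apply the acceptance thresholds, write the blocklist, the
#' contaminant hit table, the filtered read set (whole-read removal,
#' surviving records byte-identical), the scan summary, and a run manifest.
#' With `inputs = NULL`, all files of supported type in the working directory
#' are processed.
#'
#' Output files per input, under `outdir`: `<prefix>.filt.fastq[.gz]` (or
#' `.filt.fasta[.gz]` for FASTA input), `<prefix>.blocklist`,
#' `<prefix>.contaminant.tsv`, `<prefix>.stats`, `<prefix>.stats.json`,
#' `<prefix>.manifest.json`. Output compression mirrors the input unless
#' `gzip` is set explicitly. BAM input is filtered into FASTQ.
#'
#' @param inputs Character vector of input paths, or `NULL` to scan the
#'   working directory.
#' @param outdir Output directory (created if missing).
#' @param prefix Output prefix; default is the input file's base name.
#'   Ignored (per-file defaults used) when several inputs are given.
#' @param min_length,min_identity Optional uniform threshold overrides
#'   (the `-l` / `-m` knobs); per-adapter defaults apply when `NULL`.
#' @param end_zone_fraction Positional-classification end zone, see
#'   [filter_config()].
#' @param adapter_fasta Optional FASTA of additional adapter sequences.
#' @param threads Accepted for interface compatibility; processing is
#'   sequential and outputs never depend on this value.
#' @param gzip `NULL` (mirror input), `TRUE` or `FALSE`.
#' @param verbose Log per-file progress to stderr.
#' @return Invisibly, a list of per-input results (`blocklist`, `hits`,
#'   `classifications`, `report`, `outputs`).
#' @export
run_filter <- function(inputs = NULL, outdir = ".", prefix = NULL,
                       min_length = NULL, min_identity = NULL,
                       end_zone_fraction = 0.10, adapter_fasta = NULL,
                       threads = 1L, gzip = NULL, verbose = TRUE) {
  started <- Sys.time()
  if (is.null(inputs)) {
    inputs <- list.files(".", pattern = .supported_exts, ignore.case = TRUE)
    if (length(inputs) == 0L)
      stop("no supported sequence files (fastq/fasta/bam) found in ",
           normalizePath("."))
  }
  stopifnot(length(inputs) >= 1L)
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  adapters <- builtin_adapters()
  if (!is.null(adapter_fasta))
    adapters <- rbind(adapters, read_adapter_fasta(adapter_fasta))
  config <- filter_config(min_length, min_identity, end_zone_fraction)
  results <- list()
  for (input in inputs) {
    fmt <- detect_format(input)
    pfx <- if (!is.null(prefix) && length(inputs) == 1L) prefix
           else .default_prefix(input)
    out_pfx <- file.path(outdir, pfx)
    if (verbose) message("[hifiscrub] scanning ", input)
    reads <- read_sequences(input, format = fmt)
    bl <- build_blocklist(reads, adapters, alignment_scoring(), config)
    report <- summarize_scan(reads, bl$blocklist, bl$hits, bl$classifications)

    in_gz <- grepl("\\.gz$", input)
    out_gz <- if (is.null(gzip)) in_gz && fmt != "bam" else isTRUE(gzip)
    filt_ext <- if (fmt == "fasta") ".filt.fasta" else ".filt.fastq"
    filt_path <- paste0(out_pfx, filt_ext, if (out_gz) ".gz" else "")
    if (fmt == "bam") {
      keep <- !(reads$read_id %in% bl$blocklist)
      write_sequences(reads[keep, , drop = FALSE], filt_path,
                      format = "fastq", gzip = out_gz)
      counts <- c(kept = sum(keep), removed = sum(!keep))
    } else {
      counts <- filter_reads(input, bl$blocklist, filt_path, format = fmt)
    }
    writeLines(bl$blocklist, paste0(out_pfx, ".blocklist"))
    write_hits_tsv(bl$hits, paste0(out_pfx, ".contaminant.tsv"))
    write_scan_report(report, out_pfx)
    outputs <- c(filt_path, paste0(out_pfx, ".blocklist"),
                 paste0(out_pfx, ".contaminant.tsv"),
                 paste0(out_pfx, ".stats"), paste0(out_pfx, ".stats.json"))
    .write_manifest(paste0(out_pfx, ".manifest.json"), "filter",
                    list(min_length = min_length, min_identity = min_identity,
                         end_zone_fraction = end_zone_fraction,
                         adapter_fasta = adapter_fasta, threads = threads,
                         gzip = out_gz, prefix = pfx, outdir = outdir),
                    list(list(path = input, n_records = nrow(reads))),
                    as.list(outputs), started)
    if (verbose)
      message(sprintf("[hifiscrub] %s: %d reads, %d contaminated (%.4f%%), %d retained",
                      input, report$reads_total, report$reads_contaminated,
                      100 * report$proportion_contaminated,
                      report$reads_retained))
    results[[input]] <- list(blocklist = bl$blocklist, hits = bl$hits,
                             classifications = bl$classifications,
                             report = report, counts = counts,
                             outputs = outputs)
  }
  invisible(results)
}

#' Screen an assembly and write the contig contamination table
#'
#' Runs [screen_contigs()] and writes `<prefix>.contigs.tsv` (the same
#' 12-column hit dialect as the read path, contig ids in the first column)
#' plus a run manifest. Intended for pipeline gating: the CLI wrapper exits
#' with status 3 when any contaminated contig is found.
#'
#' @inheritParams run_filter
#' @param assembly Path to the assembly FASTA.
#' @return Invisibly, the [screen_contigs()] result with an added
#'   `contaminated` flag and `outputs` paths.
#' @export
run_screen <- function(assembly, outdir = ".", prefix = NULL,
                       min_length = NULL, min_identity = NULL,
                       adapter_fasta = NULL, verbose = TRUE) {
  started <- Sys.time()
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  adapters <- builtin_adapters()
  if (!is.null(adapter_fasta))
    adapters <- rbind(adapters, read_adapter_fasta(adapter_fasta))
  config <- filter_config(min_length, min_identity)
  pfx <- if (is.null(prefix)) .default_prefix(assembly) else prefix
  out_pfx <- file.path(outdir, pfx)
  res <- screen_contigs(assembly, adapters, alignment_scoring(), config)
  tsv <- paste0(out_pfx, ".contigs.tsv")
  write_hits_tsv(res$hits, tsv)
  cat(sprintf("# contaminated_contigs: %d\n", nrow(res$findings)),
      file = tsv, append = TRUE)
  .write_manifest(paste0(out_pfx, ".manifest.json"), "screen",
                  list(min_length = min_length, min_identity = min_identity,
                       adapter_fasta = adapter_fasta, prefix = pfx,
                       outdir = outdir),
                  list(list(path = assembly,
                            n_records = length(unique(c(res$findings$contig_id,
                                                        character(0)))))),
                  list(tsv), started)
  if (verbose)
    message(sprintf("[hifiscrub] %s: %d contaminated contig(s)",
                    assembly, nrow(res$findings)))
  invisible(c(res, list(contaminated = nrow(res$findings) > 0L,
                        outputs = tsv)))
}

#' Generate a simulated dataset from the command line interface
#'
#' Thin wrapper around [generate_dataset()] that also writes a run manifest.
#'
#' @param outdir Output directory.
#' @param prefix Output prefix (default `"sim"`).
#' @param gzip Compress the FASTQ.
#' @param ... Passed to [sim_config()].
#' @return Invisibly, the [generate_dataset()] result.
#' @export
run_simulate <- function(outdir = ".", prefix = "sim", gzip = FALSE, ...) {
  started <- Sys.time()
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  config <- sim_config(...)
  fastq <- file.path(outdir, paste0(prefix, ".fastq", if (gzip) ".gz" else ""))
  truth <- file.path(outdir, paste0(prefix, ".truth.tsv"))
  res <- generate_dataset(config, fastq, truth)
  .write_manifest(file.path(outdir, paste0(prefix, ".manifest.json")),
                  "simulate", unclass(config), list(),
                  list(fastq, truth), started, seed = config$seed)
  invisible(res)
}
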