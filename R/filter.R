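#' Filtering stringency configuration
#'
#' The two stringency knobs mirror the screening tool convention of a
#' minimum aligned length (`-l`) and a minimum percent identity (`-m`).
#' When unset, each adapter's own defaults apply (44 bp / 97 pct for the
#' 45 bp blunt adapter, 34 bp / 97 pct for the 35 bp C2 primer); when set,
#' an override applies uniformly to every adapter.
#'
#' @param min_match_length Optional minimum number of alignment columns.
#' @param min_identity Optional minimum percent identity (0-100].
#' @param end_zone_fraction Fraction of the read length considered the
#'   5'/3' "end zone" for positional classification (default 0.10).
#' @return A list with class `"filter_config"`.
#' @export
filter_config <- function(min_match_length = NULL, min_identity = NULL,
                          end_zone_fraction = 0.10) {
  if (!is.null(min_match_length))
    stopifnot(min_match_length >= 1)
  if (!is.null(min_identity))
    stopifnot(min_identity > 0, min_identity <= 100)
  stopifnot(end_zone_fraction > 0, end_zone_fraction < 0.5)
  structure(list(
    min_match_length = if (is.null(min_match_length)) NULL else as.integer(min_match_length),
    min_identity = min_identity,
    end_zone_fraction = end_zone_fraction), class = "filter_config")
}

.effective_thresholds <- function(adapters, config) {
  L <- if (is.null(config$min_match_length)) adapters$min_match_length
       else rep(config$min_match_length, nrow(adapters))
  M <- if (is.null(config$min_identity)) adapters$min_identity
       else rep(config$min_identity, nrow(adapters))
  data.frame(name = adapters$name, min_length = L, min_identity = M,
             stringsAsFactors = FALSE)
}

#' Does a hit meet the acceptance thresholds?
#'
#' A hit is accepted as real contamination when its alignment spans at least
#' the minimum number of columns and its percent identity meets the minimum:
#' by default 44 of the 45 bp blunt adapter or 34 of the 35 bp C2 primer, at
#' 97 percent identity or greater.
#'
#' @param hit One row of a hit table from [find_adapter_hits()] (or any list
#'   with `adapter_name`, `alignment_columns`, `identity_pct`).
#' @param adapter The matching adapter row (from [builtin_adapters()] etc.).
#' @param config A [filter_config()].
#' @return `TRUE` or `FALSE`.
#' @export
hit_passes <- function(hit, adapter, config = filter_config()) {
  stopifnot(hit$adapter_name == adapter$name)
  L <- if (is.null(config$min_match_length)) adapter$min_match_length
       else config$min_match_length
  M <- if (is.null(config$min_identity)) adapter$min_identity
       else config$min_identity
  hit$alignment_columns >= L && hit$identity_pct >= M
}

.passing_hits <- function(hits, adapters, config) {
  if (nrow(hits) == 0L) return(hits)
  thr <- .effective_thresholds(adapters, config)
  i <- match(hits$adapter_name, thr$name)
  hits[hits$alignment_columns >= thr$min_length[i] &
         hits$identity_pct >= thr$min_identity[i], , drop = FALSE]
}

#' Classify a contaminated read by where its adapter hits fall
#'
#' Each passing hit is assigned a zone: `five_prime` if it starts within the
#' first `end_zone_fraction` of the read, `three_prime` if it ends within the
#' last `end_zone_fraction`, otherwise `internal` (a hit qualifying for both
#' ends, possible only on very short reads, counts as `five_prime`). The read
#' is labelled with the common zone when all hits agree, and `distributed`
#' when they do not. Reads whose passing hits cover more than 80 percent of
#' the read (adapter-dimer-like artifacts) are labelled `other`.
#'
#' @param read_length Read length in bp.
#' @param passing_hits Non-empty hit table for one read (passing hits only).
#' @param config A [filter_config()] (supplies `end_zone_fraction`).
#' @return A list with `category`, `n_hits`, `n_forward`, `n_reverse`.
#' @export
classify_read <- function(read_length, passing_hits,
                          config = filter_config()) {
  stopifnot(read_length > 0)
  if (is.null(passing_hits) || nrow(passing_hits) == 0L)
    stop("classify_read() requires at least one passing hit")
  f <- config$end_zone_fraction
  # union coverage for the 'other' (dimer-like) rule
  o <- order(passing_hits$read_start)
  st <- passing_hits$read_start[o]; en <- passing_hits$read_end[o]
  cov <- 0L; cur_s <- st[1L]; cur_e <- en[1L]
  for (i in seq_along(st)[-1L]) {
    if (st[i] <= cur_e) cur_e <- max(cur_e, en[i])
    else { cov <- cov + (cur_e - cur_s); cur_s <- st[i]; cur_e <- en[i] }
  }
  cov <- cov + (cur_e - cur_s)
  if (cov > 0.8 * read_length) {
    category <- "other"
  } else {
    zone <- ifelse(passing_hits$read_start < f * read_length, "five_prime",
                   ifelse(passing_hits$read_end > (1 - f) * read_length,
                          "three_prime", "internal"))
    category <- if (length(unique(zone)) == 1L) zone[1L] else "distributed"
  }
  list(category = category,
       n_hits = nrow(passing_hits),
       n_forward = sum(passing_hits$orientation == "forward"),
       n_reverse = sum(passing_hits$orientation == "reverse"))
}

# Lowest raw score a hit can have and still pass the thresholds: with L
# columns at identity M, matches >= ceiling(L*M/100) and each non-match
# column costs at most 6 (a single-base gap), so score >= 7*matches - 6*L.
# Used to lower the reporting floor when -l/-m overrides are loose.
.derived_floor <- function(adapters, config, cap = 20L) {
  thr <- .effective_thresholds(adapters, config)
  mmin <- ceiling(thr$min_length * thr$min_identity / 100)
  floors <- 7 * mmin - 6 * thr$min_length
  max(1L, min(cap, floors))
}

#' Scan reads and build the contaminated-read blocklist
#'
#' Runs the adapter detector over every read, applies the acceptance
#' thresholds, and returns the blocklist (ids of reads with at least one
#' passing hit), the full table of passing hits, and one positional
#' classification per contaminated read.
#'
#' @param reads A data.frame from [read_sequences()].
#' @param adapters Adapter table.
#' @param scoring An [alignment_scoring()].
#' @param config A [filter_config()].
#' @return A list with `blocklist` (character vector, input order), `hits`
#'   (passing hits, all reads) and `classifications` (data.frame with
#'   `read_id`, `category`, `n_hits`, `n_forward`, `n_reverse`).
#' @export
build_blocklist <- function(reads, adapters = builtin_adapters(),
                            scoring = alignment_scoring(),
                            config = filter_config()) {
  adapters <- .validate_adapters(adapters)
  dup <- duplicated(reads$read_id)
  if (any(dup))
    stop("duplicate read id(s) in input: ",
         paste(unique(reads$read_id[dup])[1:min(3, sum(dup))], collapse = ", "))
  floor <- .derived_floor(adapters, config)
  hit_list <- vector("list", nrow(reads))
  cls_list <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    h <- find_adapter_hits(reads$sequence[i], reads$read_id[i],
                           adapters, scoring, report_floor = floor)
    ph <- .passing_hits(h, adapters, config)
    if (nrow(ph) > 0L) {
      hit_list[[i]] <- ph
      cl <- classify_read(nchar(reads$sequence[i]), ph, config)
      cls_list[[i]] <- data.frame(read_id = reads$read_id[i],
                                  category = cl$category, n_hits = cl$n_hits,
                                  n_forward = cl$n_forward,
                                  n_reverse = cl$n_reverse,
                                  stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, c(list(.empty_hits()), hit_list))
  cls <- do.call(rbind, cls_list)
  if (is.null(cls))
    cls <- data.frame(read_id = character(0), category = character(0),
                      n_hits = integer(0), n_forward = integer(0),
                      n_reverse = integer(0), stringsAsFactors = FALSE)
  list(blocklist = unique(hits$read_id)[order(match(unique(hits$read_id),
                                                    reads$read_id))],
       hits = hits, classifications = cls)
}

#' Remove blocklisted reads from a sequence file
#'
#' Whole-read removal: the output contains exactly the input records whose id
#' is not on the blocklist, in input order and byte-identical to their input
#' serialization (records are selected at the text level, never re-parsed and
#' re-written). Ids are matched exactly and completely against the first
#' whitespace-delimited header token.
#'
#' @param input Input FASTQ or FASTA path (plain or gzip).
#' @param blocklist Character vector of read ids to remove.
#' @param output Output path. Written gzip-compressed when it ends in `.gz`.
#' @param format `"auto"`, `"fastq"` or `"fasta"` (of the input).
#' @return Named integer vector `c(kept = , removed = )`.
#' @export
filter_reads <- function(input, blocklist, output,
                         format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") format <- detect_format(input)
  if (format == "bam")
    stop("filter_reads() pass-through supports fastq/fasta; convert BAM first")
  blocklist <- unique(as.character(blocklist))
  inc <- .open_text(input)
  on.exit(close(inc), add = TRUE)
  outc <- if (grepl("\\.gz$", output)) gzfile(output, "wb") else file(output, "wb")
  on.exit(close(outc), add = TRUE)
  kept <- 0L; removed <- 0L
  seen <- character(0)
  if (format == "fastq") {
    repeat {
      lines <- readLines(inc, n = 200000L)
      if (length(lines) == 0L) break
      if (length(lines) %% 4L != 0L) stop("malformed FASTQ: ", input)
      idx <- seq(1L, length(lines), by = 4L)
      ids <- sub("\\s.*$", "", substring(lines[idx], 2L))
      drop <- ids %in% blocklist
      seen <- c(seen, ids[drop])
      removed <- removed + sum(drop)
      kept <- kept + sum(!drop)
      keep_rows <- rep(!drop, each = 4L)
      if (any(keep_rows)) writeLines(lines[keep_rows], outc, sep = "\n")
    }
  } else {
    drop_cur <- FALSE
    repeat {
      lines <- readLines(inc, n = 200000L)
      if (length(lines) == 0L) break
      is_hdr <- startsWith(lines, ">")
      ids <- sub("\\s.*$", "", substring(lines[is_hdr], 2L))
      drop_hdr <- ids %in% blocklist
      seen <- c(seen, ids[drop_hdr])
      kept <- kept + sum(!drop_hdr)
      removed <- removed + sum(drop_hdr)
      # propagate per-line keep/drop state across the chunk
      state <- cumsum(is_hdr)
      line_drop <- rep(drop_cur, length(lines))
      line_drop[state > 0L] <- drop_hdr[state[state > 0L]]
      if (any(!line_drop)) writeLines(lines[!line_drop], outc, sep = "\n")
      if (length(ids)) drop_cur <- drop_hdr[length(drop_hdr)]
    }
  }
  missing <- setdiff(blocklist, seen)
  if (length(missing))
    warning(length(missing), " blocklist id(s) not found in input, e.g.: ",
            paste(utils::head(missing, 3L), collapse = ", "))
  c(kept = kept, removed = removed)
}

#' Write the blocklist and the contaminant hit table
#'
#' The hit table is a 12-column TSV modeled on BLAST tabular output
#' (`outfmt 6`): read id, adapter name with an orientation suffix (`/fwd` or
#' `/rev`), percent identity (2 decimals), alignment columns, mismatches, gap
#' opens, 1-based inclusive read start/end, 1-based inclusive adapter
#' start/end, `.` as an E-value placeholder, and the raw score.
#'
#' @param hits Passing-hit table from [build_blocklist()].
#' @param path Output TSV path.
#' @return Invisibly, the number of rows written.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- data.frame(
    read_id = hits$read_id,
    subject = paste0(hits$adapter_name,
                     ifelse(hits$orientation == "forward", "/fwd", "/rev")),
    identity = sprintf("%.2f", hits$identity_pct),
    alignment_columns = hits$alignment_columns,
    mismatches = hits$mismatches,
    gap_opens = hits$gap_opens,
    read_start = hits$read_start + 1L,
    read_end = hits$read_end,
    adapter_start = hits$adapter_start + 1L,
    adapter_end = hits$adapter_end,
    evalue = rep(".", nrow(hits)),
    score = hits$score,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}
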