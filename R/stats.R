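#' GC content of a DNA sequence
#'
#' Percent G+C among called bases. `N` (and any non-ACGT character) is
#' excluded from both numerator and denominator so N-padded reads do not get
#' a deflated GC; an all-N sequence returns 0.
#'
#' @param sequence Character vector of sequences (case-insensitive).
#' @return Numeric vector of GC percentages.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(is.na(sequence)) || any(nchar(sequence) == 0L))
    stop("gc_content() requires non-empty sequences")
  up <- toupper(sequence)
  gc <- nchar(gsub("[^GC]", "", up))
  acgt <- nchar(gsub("[^ACGT]", "", up))
  ifelse(acgt == 0L, 0, 100 * gc / acgt)
}

# lower-median convention: for even n, the lower of the two middle values
.median_lower <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

.group_length_summary <- function(lens) {
  if (length(lens) == 0L)
    return(list(n = 0L, min = NA_real_, median = NA_real_,
                mean = NA_real_, max = NA_real_))
  list(n = length(lens), min = min(lens), median = .median_lower(lens),
       mean = mean(lens), max = max(lens))
}

#' Summarize an adapter-contamination scan
#'
#' Builds the dataset-level report: how many reads are contaminated and in
#' what proportion, the orientation split of the passing hits, the positional
#' category counts, and length / GC profiles of contaminated versus clean
#' reads. Medians use the lower-median convention for even counts.
#'
#' @param reads Read table from [read_sequences()].
#' @param blocklist Character vector of contaminated read ids.
#' @param hits Passing-hit table from [build_blocklist()].
#' @param classifications Classification table from [build_blocklist()].
#' @return A list with class `"scan_report"`.
#' @export
summarize_scan <- function(reads, blocklist, hits, classifications) {
  stopifnot(all(blocklist %in% reads$read_id))
  total <- nrow(reads)
  contam <- length(blocklist)
  is_contam <- reads$read_id %in% blocklist
  lens <- nchar(reads$sequence)
  gc <- if (total > 0L) gc_content(reads$sequence) else numeric(0)
  cats <- c("five_prime", "internal", "three_prime", "distributed", "other")
  cat_counts <- setNames(integer(5L), cats)
  if (nrow(classifications) > 0L) {
    tab <- table(factor(classifications$category, levels = cats))
    cat_counts[] <- as.integer(tab)
  }
  ori_counts <- c(
    forward = sum(hits$orientation == "forward"),
    reverse = sum(hits$orientation == "reverse"))
  report <- list(
    reads_total = total,
    reads_contaminated = contam,
    reads_retained = total - contam,
    proportion_contaminated = if (total == 0L) 0 else contam / total,
    hits_total = nrow(hits),
    orientation_counts = ori_counts,
    category_counts = as.list(cat_counts),
    length_summary = list(
      contaminated = .group_length_summary(lens[is_contam]),
      clean = .group_length_summary(lens[!is_contam])),
    gc_summary = list(
      contaminated = list(
        mean_gc_pct = if (any(is_contam)) mean(gc[is_contam]) else NA_real_,
        median_gc_pct = .median_lower(gc[is_contam])),
      clean = list(
        mean_gc_pct = if (any(!is_contam)) mean(gc[!is_contam]) else NA_real_,
        median_gc_pct = .median_lower(gc[!is_contam]))))
  class(report) <- "scan_report"
  report
}

#' @export
print.scan_report <- function(x, ...) {
  cat(format_scan_report(x), sep = "\n")
  invisible(x)
}

format_scan_report <- function(report) {
  fmt_na <- function(v, f = "%s") if (is.na(v)) "NA" else sprintf(f, v)
  ls <- report$length_summary; gs <- report$gc_summary
  c(sprintf("reads_total: %d", report$reads_total),
    sprintf("reads_contaminated: %d", report$reads_contaminated),
    sprintf("reads_retained: %d", report$reads_retained),
    sprintf("proportion_contaminated: %.6f", report$proportion_contaminated),
    sprintf("hits_total: %d", report$hits_total),
    sprintf("orientation_forward: %d", report$orientation_counts[["forward"]]),
    sprintf("orientation_reverse: %d", report$orientation_counts[["reverse"]]),
    sprintf("category_five_prime: %d", report$category_counts$five_prime),
    sprintf("category_internal: %d", report$category_counts$internal),
    sprintf("category_three_prime: %d", report$category_counts$three_prime),
    sprintf("category_distributed: %d", report$category_counts$distributed),
    sprintf("category_other: %d", report$category_counts$other),
    sprintf("length_contaminated_n: %d", ls$contaminated$n),
    sprintf("length_contaminated_min: %s", fmt_na(ls$contaminated$min, "%.0f")),
    sprintf("length_contaminated_median: %s", fmt_na(ls$contaminated$median, "%.0f")),
    sprintf("length_contaminated_mean: %s", fmt_na(ls$contaminated$mean, "%.1f")),
    sprintf("length_contaminated_max: %s", fmt_na(ls$contaminated$max, "%.0f")),
    sprintf("length_clean_n: %d", ls$clean$n),
    sprintf("length_clean_min: %s", fmt_na(ls$clean$min, "%.0f")),
    sprintf("length_clean_median: %s", fmt_na(ls$clean$median, "%.0f")),
    sprintf("length_clean_mean: %s", fmt_na(ls$clean$mean, "%.1f")),
    sprintf("length_clean_max: %s", fmt_na(ls$clean$max, "%.0f")),
    sprintf("gc_contaminated_mean: %s", fmt_na(gs$contaminated$mean_gc_pct, "%.2f")),
    sprintf("gc_contaminated_median: %s", fmt_na(gs$contaminated$median_gc_pct, "%.2f")),
    sprintf("gc_clean_mean: %s", fmt_na(gs$clean$mean_gc_pct, "%.2f")),
    sprintf("gc_clean_median: %s", fmt_na(gs$clean$median_gc_pct, "%.2f")))
}

#' Write a scan report to disk
#'
#' Writes the flat `key: value` text form to `<prefix>.stats` and a
#' machine-readable twin to `<prefix>.stats.json`.
#'
#' @param report A `"scan_report"` from [summarize_scan()].
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_scan_report <- function(report, prefix) {
  stats_path <- paste0(prefix, ".stats")
  json_path <- paste0(prefix, ".stats.json")
  writeLines(format_scan_report(report), stats_path)
  out <- unclass(report)
  out$orientation_counts <- as.list(out$orientation_counts)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(stats_path, json_path))
}
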