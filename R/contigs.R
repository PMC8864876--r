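#' Screen assembled contigs for adapter contamination
#'
#' Applies the same detector and acceptance thresholds used on reads to each
#' contig of an assembly. Long contigs are scanned in overlapping windows so
#' hit discovery is independent of contig size; the window overlap is at
#' least twice the longest adapter, which guarantees any hit straddling a
#' window boundary is contained whole in the next window. Coordinates are
#' mapped back to contig space and duplicate hits from the overlap removed.
#'
#' @param assembly Path to a FASTA assembly (plain or gzip).
#' @param adapters Adapter table.
#' @param scoring An [alignment_scoring()].
#' @param config A [filter_config()].
#' @param window_size Window length in bp for scanning long contigs.
#' @param window_overlap Overlap between consecutive windows in bp.
#' @return A list with `findings` (data.frame: `contig_id`, `contig_length`,
#'   `n_passing_hits`; one row per contaminated contig, in file order) and
#'   `hits` (the passing hits with contig coordinates). A clean assembly
#'   yields a 0-row `findings`.
#' @export
screen_contigs <- function(assembly, adapters = builtin_adapters(),
                           scoring = alignment_scoring(),
                           config = filter_config(),
                           window_size = 1e6, window_overlap = 100L) {
  adapters <- .validate_adapters(adapters)
  max_alen <- max(nchar(adapters$sequence))
  stopifnot(window_overlap >= 2L * max_alen, window_size > window_overlap)
  contigs <- read_sequences(assembly, format = "fasta")
  if (nrow(contigs) == 0L) {
    warning("empty assembly file: ", assembly)
    return(list(findings = data.frame(contig_id = character(0),
                                      contig_length = integer(0),
                                      n_passing_hits = integer(0),
                                      stringsAsFactors = FALSE),
                hits = .empty_hits()))
  }
  floor <- .derived_floor(adapters, config)
  hit_list <- list(); findings <- list()
  for (i in seq_len(nrow(contigs))) {
    s <- contigs$sequence[i]
    L <- nchar(s)
    starts <- if (L <= window_size) 0L
              else seq(0L, L - 1L, by = as.integer(window_size - window_overlap))
    hits_i <- list()
    for (w0 in starts) {
      w1 <- min(L, w0 + window_size)
      if (w1 <= w0) next
      h <- find_adapter_hits(substr(s, w0 + 1L, w1), contigs$read_id[i],
                             adapters, scoring, report_floor = floor)
      if (nrow(h) > 0L) {
        h$read_start <- h$read_start + w0
        h$read_end <- h$read_end + w0
        hits_i[[length(hits_i) + 1L]] <- h
      }
      if (w1 == L) break
    }
    if (length(hits_i) == 0L) next
    h <- do.call(rbind, hits_i)
    h <- h[!duplicated(h[c("adapter_name", "orientation",
                           "read_start", "read_end")]), , drop = FALSE]
    h <- h[order(h$read_start, h$adapter_name, h$orientation), , drop = FALSE]
    ph <- .passing_hits(h, adapters, config)
    if (nrow(ph) == 0L) next
    hit_list[[length(hit_list) + 1L]] <- ph
    findings[[length(findings) + 1L]] <- data.frame(
      contig_id = contigs$read_id[i], contig_length = L,
      n_passing_hits = nrow(ph), stringsAsFactors = FALSE)
  }
  list(findings = if (length(findings)) do.call(rbind, findings)
                  else data.frame(contig_id = character(0),
                                  contig_length = integer(0),
                                  n_passing_hits = integer(0),
                                  stringsAsFactors = FALSE),
       hits = do.call(rbind, c(list(.empty_hits()), hit_list)))
}
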