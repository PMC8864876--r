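#' VecScreen-style alignment scoring parameters
#'
#' The strict scoring regime used for vector/adapter screening: match +1,
#' mismatch -5, and affine gaps where a gap of length k costs
#' `gap_open + k * gap_extend` (BLAST convention; a single-base gap costs 6
#' at the defaults). With these rewards a high-scoring alignment is forced to
#' be near-exact, which is what makes a short adapter findable inside a long
#' read without E-value machinery.
#'
#' @param match_reward Score added per identical column (> 0).
#' @param mismatch_penalty Score added per mismatching column (< 0). `N` (and
#'   any non-ACGT letter) mismatches everything, including itself.
#' @param gap_open Cost charged once when a gap is opened (> 0).
#' @param gap_extend Cost charged per gapped base (> 0).
#' @return A list with class `"alignment_scoring"`.
#' @export
alignment_scoring <- function(match_reward = 1L, mismatch_penalty = -5L,
                              gap_open = 3L, gap_extend = 3L) {
  stopifnot(match_reward > 0, mismatch_penalty < 0,
            gap_open > 0, gap_extend > 0)
  structure(list(match_reward = as.integer(match_reward),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "alignment_scoring")
}

#' Best local alignment of a query within a target sequence
#'
#' Smith-Waterman local alignment with affine gap costs (Gotoh algorithm),
#' run in C. Returns `NULL` when no alignment scores above zero. Among
#' equal-scoring alignments the one ending leftmost on the target (then
#' leftmost on the query) is reported, and traceback prefers substitution
#' columns over gaps, so results are fully deterministic.
#'
#' @param query Query sequence (e.g. an adapter), uppercase ACGTN.
#' @param target Target sequence (e.g. a read), uppercase ACGTN.
#' @param scoring An [alignment_scoring()] object.
#' @return `NULL`, or a list with `score`, `target_start`/`target_end` and
#'   `query_start`/`query_end` (0-based, half-open), `alignment_columns`,
#'   `matches`, `mismatches`, `gap_opens`, `identity_pct`.
#' @examples
#' ad <- builtin_adapters()$sequence[1]
#' local_align(ad, ad)$score  # 45: one reward per matching base
#' @export
local_align <- function(query, target, scoring = alignment_scoring()) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(target), length(target) == 1L)
  if (nchar(query) == 0L || nchar(target) == 0L)
    stop("local_align() requires non-empty sequences")
  r <- .sw_local_align(target, query,
                       scoring$match_reward, scoring$mismatch_penalty,
                       scoring$gap_open, scoring$gap_extend)
  if (length(r) == 0L) return(NULL)
  list(score = r[1L],
       target_start = r[2L], target_end = r[3L],
       query_start = r[4L], query_end = r[5L],
       alignment_columns = r[6L], matches = r[7L], mismatches = r[8L],
       gap_opens = r[9L],
       identity_pct = 100 * r[7L] / r[6L])
}

.empty_hits <- function() {
  data.frame(read_id = character(0), adapter_name = character(0),
             orientation = character(0),
             read_start = integer(0), read_end = integer(0),
             adapter_start = integer(0), adapter_end = integer(0),
             score = integer(0), alignment_columns = integer(0),
             matches = integer(0), mismatches = integer(0),
             gap_opens = integer(0), identity_pct = numeric(0),
             stringsAsFactors = FALSE)
}

#' Find all adapter hits within one read
#'
#' For each adapter and each orientation (the adapter as given, and its
#' reverse complement) the best local alignment is located; its read interval
#' is then masked and the search repeated until the best score drops below
#' `report_floor`. Hits are therefore non-overlapping on the read per
#' (adapter, orientation) and are returned sorted by read position.
#' `orientation = "reverse"` means the reverse complement of the adapter
#' matched the read as given; read coordinates always refer to the read's
#' forward strand, and adapter coordinates refer to the oriented (possibly
#' reverse-complemented) adapter sequence.
#'
#' The read is uppercased before alignment; lowercase input bases are not a
#' special case. `N` scores as a mismatch against everything.
#'
#' @param sequence The read sequence (a single string).
#' @param read_id Identifier recorded in the hit table.
#' @param adapters Adapter table, as from [builtin_adapters()].
#' @param scoring An [alignment_scoring()] object.
#' @param report_floor Minimum raw score for a hit to be reported (>= 1).
#'   This floor only bounds the iterate-and-mask loop; acceptance of a hit as
#'   contamination is decided downstream by [hit_passes()].
#' @return A data.frame of hits (possibly 0-row) with 0-based half-open
#'   coordinates; columns as in [.empty_hits()]'s schema plus `identity_pct`.
#' @export
find_adapter_hits <- function(sequence, read_id = "read",
                              adapters = builtin_adapters(),
                              scoring = alignment_scoring(),
                              report_floor = 20L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            report_floor >= 1L)
  adapters <- .validate_adapters(adapters)
  if (is.na(sequence) || nchar(sequence) == 0L) return(.empty_hits())
  seq_up <- toupper(sequence)
  out <- list()
  for (k in seq_len(nrow(adapters))) {
    for (ori in c("forward", "reverse")) {
      aseq <- adapters$sequence[k]
      if (ori == "reverse") aseq <- reverse_complement(aseq)
      work <- seq_up
      repeat {
        al <- local_align(aseq, work, scoring)
        if (is.null(al) || al$score < report_floor) break
        out[[length(out) + 1L]] <- data.frame(
          read_id = read_id, adapter_name = adapters$name[k],
          orientation = ori,
          read_start = al$target_start, read_end = al$target_end,
          adapter_start = al$query_start, adapter_end = al$query_end,
          score = al$score, alignment_columns = al$alignment_columns,
          matches = al$matches, mismatches = al$mismatches,
          gap_opens = al$gap_opens, identity_pct = al$identity_pct,
          stringsAsFactors = FALSE)
        # mask the matched interval so the next-best disjoint hit surfaces
        substr(work, al$target_start + 1L, al$target_end) <-
          strrep("x", al$target_end - al$target_start)
      }
    }
  }
  if (length(out) == 0L) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits[order(hits$read_start, hits$adapter_name, hits$orientation), ,
       drop = FALSE]
}
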