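#' Built-in PacBio adapter and primer sequences
#'
#' Returns the two PacBio library artifacts screened for by default: the
#' 45 bp SMRTbell blunt adapter and the 35 bp C2 sequencing primer, each with
#' its default acceptance thresholds (minimum aligned length and minimum
#' percent identity). The defaults allow one missing or mismatched base:
#' at least 44 of 45 bp (blunt adapter) or 34 of 35 bp (C2 primer), both at
#' 97 percent identity or better.
#'
#' These sequences are part of the tool's contract and are stable across
#' releases.
#'
#' @return A data.frame with one row per adapter and columns `name`,
#'   `sequence`, `min_match_length`, `min_identity`.
#' @examples
#' builtin_adapters()
#' @export
builtin_adapters <- function() {
  data.frame(
    name = c("pacbio_blunt_adapter", "pacbio_c2_primer"),
    sequence = c(
      "ATCTCTCTCTTTTCCTCCTCCTCCGTTGTTGTTGTTGAGAGAGAT",
      "AAAAAAAAAAAAAAAAAATTAACGGAGGAGGAGGA"
    ),
    min_match_length = c(44L, 34L),
    min_identity = c(97, 97),
    stringsAsFactors = FALSE
  )
}

#' Load additional adapter sequences from a FASTA file
#'
#' User-supplied adapters are screened alongside the built-in ones. Each gets
#' the same one-missing-base default thresholds as the built-ins: minimum
#' match length `nchar(sequence) - 1` and 97 percent identity.
#'
#' @param path Path to a FASTA file of adapter sequences (uppercase ACGT).
#' @return A data.frame in the same shape as [builtin_adapters()].
#' @export
read_adapter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("no sequences in adapter FASTA: ", path)
  seqs <- toupper(as.character(x))
  if (any(grepl("[^ACGT]", seqs)))
    stop("adapter sequences must contain only A/C/G/T")
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  data.frame(
    name = ids,
    sequence = unname(seqs),
    min_match_length = pmax(1L, nchar(seqs) - 1L),
    min_identity = rep(97, length(seqs)),
    stringsAsFactors = FALSE
  )
}

.validate_adapters <- function(adapters) {
  stopifnot(is.data.frame(adapters),
            all(c("name", "sequence", "min_match_length", "min_identity") %in%
                  names(adapters)))
  if (any(!grepl("^[ACGT]+$", adapters$sequence)))
    stop("adapter sequences must be non-empty uppercase ACGT")
  if (any(adapters$min_match_length < 1L) ||
      any(adapters$min_match_length > nchar(adapters$sequence)))
    stop("min_match_length must be in [1, adapter length]")
  if (any(adapters$min_identity <= 0) || any(adapters$min_identity > 100))
    stop("min_identity must be in (0, 100]")
  adapters
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick complement, reversed. `N` maps to `N`; case is
#' preserved position-wise after reversal. Only the characters `ACGTN` (either
#' case) are accepted; other IUPAC codes are rejected.
#'
#' @param sequence A character vector of DNA sequences.
#' @return The reverse complement(s), same length as the input.
#' @examples
#' reverse_complement("AAAACC")  # "GGTTTT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence))
  if (any(grepl("[^ACGTNacgtn]", sequence)))
    stop("reverse_complement() supports only A/C/G/T/N (either case)")
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", sequence)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}
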