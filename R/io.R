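#' @title Sequence file input
#'
#' @description Read HiFi reads (or contigs) from FASTQ (plain or gzip),
#' FASTA (plain or gzip) or unaligned BAM into a data.frame with one row per
#' record: `read_id` (first whitespace-delimited token of the header),
#' `description` (remainder of the header, possibly empty), `sequence`, and
#' `quality` (`NA` for FASTA and for BAM records without base qualities).
#'
#' FASTQ is parsed record-wise (strict 4-line records, `+` separator line
#' required) so malformed files are reported with the index of the offending
#' record. For BAM input only primary, non-supplementary records are used;
#' records without a stored sequence are skipped with a warning. Note that
#' BAM stores no base case, and FASTQ parsing preserves case as read.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"fastq"`, `"fasta"`, `"bam"`. With
#'   `"auto"` the format is resolved from the file extension
#'   (.fq/.fastq\[.gz\] -> fastq, .fa/.fasta\[.gz\] -> fasta, .bam -> bam).
#' @return A data.frame with columns `read_id`, `description`, `sequence`,
#'   `quality`.
#' @export
read_sequences <- function(path, format = c("auto", "fastq", "fasta", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "auto") format <- detect_format(path)
  switch(format,
         fastq = read_fastq_records(path),
         fasta = read_fasta_records(path),
         bam = read_bam_records(path))
}

detect_format <- function(path) {
  base <- sub("\\.gz$", "", basename(path), ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", base))
  if (ext %in% c("fq", "fastq")) return("fastq")
  if (ext %in% c("fa", "fasta")) return("fasta")
  if (ext == "bam") return("bam")
  stop("cannot determine sequence format from extension of: ", path)
}

.open_text <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, mode)
  else file(path, mode)
}

split_header <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  list(id = id, desc = desc)
}

read_fastq_records <- function(path, chunk_records = 50000L) {
  con <- .open_text(path)
  on.exit(close(con))
  ids <- character(0); descs <- character(0)
  seqs <- character(0); quals <- character(0)
  rec_base <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_records)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      stop("malformed FASTQ: truncated record at record index ",
           rec_base + length(lines) %/% 4L + 1L, " in ", path)
    idx <- seq(1L, length(lines), by = 4L)
    hdr <- lines[idx]
    bad <- which(substr(hdr, 1L, 1L) != "@")
    if (length(bad))
      stop("malformed FASTQ: header does not start with '@' at record index ",
           rec_base + bad[1L], " in ", path)
    plus <- lines[idx + 2L]
    bad <- which(substr(plus, 1L, 1L) != "+")
    if (length(bad))
      stop("malformed FASTQ: missing '+' line at record index ",
           rec_base + bad[1L], " in ", path)
    sq <- lines[idx + 1L]; ql <- lines[idx + 3L]
    bad <- which(nchar(sq) != nchar(ql))
    if (length(bad))
      stop("malformed FASTQ: sequence/quality length mismatch at record index ",
           rec_base + bad[1L], " in ", path)
    ids <- c(ids, substring(hdr, 2L))
    seqs <- c(seqs, sq); quals <- c(quals, ql)
    rec_base <- rec_base + length(idx)
  }
  h <- split_header(ids)
  bad <- which(nchar(h$id) == 0L)
  if (length(bad))
    stop("malformed FASTQ: empty read id at record index ", bad[1L], " in ", path)
  data.frame(read_id = h$id, description = h$desc,
             sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

read_fasta_records <- function(path) {
  # BStringSet (not DNAStringSet) so base case and any letters survive intact
  x <- Biostrings::readBStringSet(path)
  h <- split_header(names(x))
  data.frame(read_id = as.character(h$id),
             description = as.character(h$desc),
             sequence = unname(as.character(x)),
             quality = rep(NA_character_, length(x)), stringsAsFactors = FALSE)
}

read_bam_records <- function(path) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  keep <- nchar(seqs) > 0L
  if (any(!keep))
    warning(sum(!keep), " BAM record(s) without a stored sequence skipped")
  quals[quals == "*" | nchar(quals) != nchar(seqs)] <- NA_character_
  data.frame(read_id = res$qname[keep], description = "",
             sequence = seqs[keep], quality = quals[keep],
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTQ or FASTA
#'
#' FASTQ records are written as strict 4-line records with a bare `+`
#' separator, reproducing header, sequence and quality exactly as stored
#' (no case changes, no wrapping). FASTA output wraps sequence lines at 80
#' columns.
#'
#' @param reads A data.frame as returned by [read_sequences()].
#' @param path Output path.
#' @param format `"fastq"` or `"fasta"`.
#' @param gzip Write gzip-compressed output.
#' @return Invisibly, the number of records written.
#' @export
write_sequences <- function(reads, path, format = c("fastq", "fasta"),
                            gzip = FALSE) {
  format <- match.arg(format)
  stopifnot(is.data.frame(reads))
  if (format == "fastq") {
    missing_q <- is.na(reads$quality)
    if (any(missing_q))
      stop("fastq output requires quality for every record; missing for: ",
           paste(utils::head(reads$read_id[missing_q], 3L), collapse = ", "))
  }
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- nrow(reads)
  if (n > 0L) {
    hdr <- ifelse(nchar(reads$description) > 0L,
                  paste(reads$read_id, reads$description),
                  reads$read_id)
    if (format == "fastq") {
      lines <- as.vector(rbind(paste0("@", hdr), reads$sequence,
                               "+", reads$quality))
    } else {
      lines <- unlist(lapply(seq_len(n), function(i) {
        s <- reads$sequence[i]
        starts <- seq(1L, nchar(s), by = 80L)
        c(paste0(">", hdr[i]), substring(s, starts, pmin(starts + 79L, nchar(s))))
      }), use.names = FALSE)
    }
    writeLines(lines, con, sep = "\n")
  }
  invisible(n)
}
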