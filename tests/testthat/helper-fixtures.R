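# Fixtures are built in code at test time; nothing is stored on disk.

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

make_reads <- function(n, len = 2000, ids = sprintf("read%03d", seq_len(n)),
                       gc = 0.4) {
  data.frame(read_id = ids, description = rep("", n),
             sequence = vapply(rep(len, n), random_dna, character(1), gc = gc),
             quality = rep(strrep("U", len), n), stringsAsFactors = FALSE)
}

write_fastq_text <- function(reads, path) {
  hdr <- ifelse(nchar(reads$description) > 0,
                paste(reads$read_id, reads$description), reads$read_id)
  writeLines(as.vector(rbind(paste0("@", hdr), reads$sequence,
                             "+", reads$quality)), path)
  path
}

# substitute bases of `seq` at 1-based positions `pos`
mutate_at <- function(seq, pos) {
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
  }
  seq
}

blunt_adapter <- function() builtin_adapters()$sequence[1L]
c2_primer <- function() builtin_adapters()$sequence[2L]

# a read with one or more adapter copies spliced in at known offsets (0-based)
spiked_read <- function(len, offsets, adapter = blunt_adapter(),
                        orientation = "forward", n_sub = 0L) {
  s <- random_dna(len)
  for (off in offsets) {
    copy <- adapter
    if (n_sub > 0L) copy <- mutate_at(copy, sample.int(nchar(copy), n_sub))
    if (orientation == "reverse") copy <- reverse_complement(copy)
    substr(s, off + 1L, off + nchar(copy)) <- copy
  }
  s
}

brute_force_score <- function(a, b, scoring = alignment_scoring()) {
  hifiscrub:::.sw_brute_force_score(a, b, scoring$match_reward,
                                    scoring$mismatch_penalty,
                                    scoring$gap_open, scoring$gap_extend)
}
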