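test_that("hit acceptance applies per-adapter length and identity thresholds", {
  ad <- builtin_adapters()
  blunt <- ad[1L, ]
  mk_hit <- function(cols, matches) {
    list(adapter_name = "pacbio_blunt_adapter", alignment_columns = cols,
         identity_pct = 100 * matches / cols)
  }
  expect_true(hit_passes(mk_hit(45L, 45L), blunt))
  expect_true(hit_passes(mk_hit(44L, 44L), blunt))       # one base missing
  expect_false(hit_passes(mk_hit(43L, 43L), blunt))      # 43 < 44
  expect_true(hit_passes(mk_hit(45L, 44L), blunt))       # 97.78 >= 97
  expect_false(hit_passes(mk_hit(45L, 43L), blunt))      # 95.56 < 97
  # overrides replace the per-adapter defaults uniformly
  loose <- filter_config(min_match_length = 30, min_identity = 90)
  expect_true(hit_passes(mk_hit(35L, 33L), blunt, loose)) # 94.3 >= 90
  strict <- filter_config(min_identity = 99.9)
  expect_false(hit_passes(mk_hit(45L, 44L), blunt, strict))
})

test_that("positional classification follows the end-zone rule", {
  h <- function(starts, ends, ori = "forward") {
    data.frame(read_start = starts, read_end = ends,
               orientation = rep(ori, length.out = length(starts)),
               stringsAsFactors = FALSE)
  }
  expect_identical(classify_read(10000, h(0L, 45L))$category, "five_prime")
  expect_identical(classify_read(10000, h(5000L, 5045L))$category, "internal")
  expect_identical(classify_read(10000, h(9900L, 9945L))$category, "three_prime")
  expect_identical(classify_read(10000, h(c(50L, 9900L), c(95L, 9945L)))$category,
                   "distributed")
  # both-ends qualification on a very short read counts as five_prime
  expect_identical(classify_read(60, h(2L, 58L))$category, "other")  # covers >80%
  expect_identical(classify_read(120, h(5L, 50L))$category, "five_prime")
  # dimer-like artifact: passing hits covering > 80% of the read
  expect_identical(classify_read(100, h(c(0L, 45L), c(45L, 90L)))$category,
                   "other")
  expect_error(classify_read(100, h(integer(0), integer(0))), "passing hit")
  cl <- classify_read(10000, h(c(10L, 700L), c(55L, 745L), c("forward", "reverse")))
  expect_equal(cl$n_hits, 2L)
  expect_equal(cl$n_forward, 1L)
  expect_equal(cl$n_reverse, 1L)
})

test_that("blocklist collects exactly the spiked reads and rejects duplicate ids", {
  set.seed(31)
  reads <- make_reads(10, len = 4000)
  spiked <- c(2L, 5L, 9L)
  for (i in spiked)
    reads$sequence[i] <- spiked_read(4000, sample(0:3950, 1))
  bl <- build_blocklist(reads)
  expect_setequal(bl$blocklist, reads$read_id[spiked])
  expect_equal(nrow(bl$classifications), 3L)
  expect_true(all(bl$hits$read_id %in% reads$read_id[spiked]))

  # a 43 bp perfect fragment is below the default length threshold; the
  # flanking bases are forced to mismatch so the alignment cannot extend
  reads2 <- make_reads(1, len = 4000)
  ad <- blunt_adapter()
  frag <- substr(ad, 1, 43)
  s <- reads2$sequence
  substr(s, 1001, 1043) <- frag
  substr(s, 1044, 1044) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ad, 44, 44))[1]
  substr(s, 1045, 1045) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ad, 45, 45))[1]
  reads2$sequence <- s
  expect_length(build_blocklist(reads2)$blocklist, 0L)

  dup <- make_reads(2, len = 600, ids = c("same", "same"))
  expect_error(build_blocklist(dup), "duplicate read id")
})

test_that("clean random reads are never blocklisted at default thresholds", {
  set.seed(32)
  reads <- make_reads(50, len = 8000)
  expect_length(build_blocklist(reads)$blocklist, 0L)
})

test_that("filtering removes whole reads and keeps survivors byte-identical", {
  set.seed(33)
  reads <- make_reads(10, len = 300)
  reads$description <- sprintf("ccs np=%d", 1:10)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_text(reads, fq)
  out <- withr::local_tempfile(fileext = ".fastq")
  bl <- reads$read_id[c(3, 7, 8)]
  counts <- filter_reads(fq, bl, out)
  expect_equal(unname(counts), c(7L, 3L))
  orig <- readLines(fq)
  expect_identical(readLines(out),
                   orig[rep(!(reads$read_id %in% bl), each = 4L)])

  # empty blocklist: output identical to input
  counts <- filter_reads(fq, character(0), out)
  expect_equal(unname(counts), c(10L, 0L))
  expect_identical(readLines(out), orig)

  # full blocklist: empty output
  counts <- filter_reads(fq, reads$read_id, out)
  expect_equal(unname(counts), c(0L, 10L))
  expect_equal(length(readLines(out)), 0L)

  # ids are matched exactly, not as prefixes (read001 must not drop read0010)
  tricky <- make_reads(2, len = 50, ids = c("read001", "read0010"))
  write_fastq_text(tricky, fq)
  counts <- filter_reads(fq, "read001", out)
  expect_equal(unname(counts), c(1L, 1L))
  expect_identical(sub("\\s.*", "", substring(readLines(out)[1], 2)), "read0010")

  expect_warning(filter_reads(fq, "absent_id", out), "not found")
})

test_that("FASTA filtering preserves multi-line records byte-exactly", {
  set.seed(34)
  seqs <- vapply(c(200, 90, 250), random_dna, character(1))
  fa <- withr::local_tempfile(fileext = ".fasta")
  df <- data.frame(read_id = c("c1", "c2", "c3"), description = "",
                   sequence = seqs, quality = NA_character_,
                   stringsAsFactors = FALSE)
  write_sequences(df, fa, format = "fasta")
  out <- withr::local_tempfile(fileext = ".fasta")
  counts <- filter_reads(fa, "c2", out)
  expect_equal(unname(counts), c(2L, 1L))
  orig <- readLines(fa)
  expect_identical(readLines(out), orig[-(5:7)])  # c2 = header + 2 seq lines
})

test_that("blocklist size is monotone in the length and identity thresholds", {
  set.seed(35)
  ad <- blunt_adapter()
  reads <- make_reads(40, len = 2000)
  # degraded spikes: full-length copies with 0-4 substitutions plus
  # perfect fragments of 30-44 bp
  for (i in 1:20)
    reads$sequence[i] <- spiked_read(2000, sample(0:1950, 1),
                                     n_sub = (i - 1L) %% 5L)
  for (i in 21:32) {
    frag <- substr(ad, 1, 29 + (i - 20L))
    s <- reads$sequence[i]
    substr(s, 501, 500 + nchar(frag)) <- frag
    reads$sequence[i] <- s
  }
  sizes <- matrix(NA_integer_, 3, 4,
                  dimnames = list(c("30", "40", "44"),
                                  c("90", "95", "97", "99")))
  for (l in rownames(sizes)) for (m in colnames(sizes)) {
    cfg <- filter_config(as.integer(l), as.numeric(m))
    sizes[l, m] <- length(build_blocklist(reads, config = cfg)$blocklist)
  }
  for (j in seq_len(ncol(sizes)))
    expect_true(all(diff(sizes[, j]) <= 0L))   # stricter length, fewer reads
  for (i in seq_len(nrow(sizes)))
    expect_true(all(diff(sizes[i, ]) <= 0L))   # stricter identity, fewer reads
  expect_gt(sizes["30", "90"], sizes["44", "99"])
})
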