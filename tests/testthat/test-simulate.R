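test_that("spike_adapter replaces bases in place and respects bounds", {
  set.seed(61)
  s <- random_dna(500)
  ad <- blunt_adapter()
  sp <- spike_adapter(s, ad, "forward", 100)
  expect_equal(nchar(sp$sequence), 500L)
  expect_identical(substr(sp$sequence, 101, 145), ad)
  expect_identical(substr(sp$sequence, 1, 100), substr(s, 1, 100))
  expect_identical(substr(sp$sequence, 146, 500), substr(s, 146, 500))
  expect_equal(sp$errors_introduced, 0L)

  rv <- spike_adapter(s, ad, "reverse", 0)
  expect_identical(substr(rv$sequence, 1, 45), reverse_complement(ad))

  expect_error(spike_adapter(s, ad, "forward", 456), "out of range")
  expect_error(spike_adapter(s, ad, "forward", -1), "out of range")

  # two calls at disjoint offsets leave both copies intact
  sp2 <- spike_adapter(sp$sequence, ad, "forward", 300)
  expect_identical(substr(sp2$sequence, 101, 145), ad)
  expect_identical(substr(sp2$sequence, 301, 345), ad)
})

test_that("spike errors are substitutions at the configured rate", {
  set.seed(62)
  ad <- blunt_adapter()
  nerr <- replicate(200, {
    sp <- spike_adapter(random_dna(100), ad, "forward", 10, error_rate = 1 / 45)
    expect_equal(nchar(sp$inserted), 45L)
    sp$errors_introduced
  })
  expect_gt(mean(nerr), 0.5)   # expectation is 1 substitution per copy
  expect_lt(mean(nerr), 1.6)
  # a copy with <= 1 substitution still passes the default thresholds
  sp <- spike_adapter(random_dna(200), ad, "forward", 50, error_rate = 1 / 45)
  if (sp$errors_introduced <= 1L) {
    bl <- build_blocklist(data.frame(read_id = "r", description = "",
                                     sequence = sp$sequence,
                                     quality = strrep("U", 200),
                                     stringsAsFactors = FALSE))
    expect_identical(bl$blocklist, "r")
  }
})

test_that("generated datasets are byte-identical for identical configs", {
  cfg <- sim_config(n_reads = 40, read_length_mean = 1500,
                    read_length_sd = 300, contamination_rate = 0.25,
                    seed = 77)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  r1 <- generate_dataset(cfg, f1, t1)
  r2 <- generate_dataset(cfg, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(r1$truth, r2$truth)
  # a different seed changes the data
  r3 <- generate_dataset(sim_config(n_reads = 40, read_length_mean = 1500,
                                    read_length_sd = 300,
                                    contamination_rate = 0.25, seed = 78), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(63)
  a <- runif(1)
  set.seed(63)
  invisible(generate_dataset(sim_config(n_reads = 5, read_length_mean = 600,
                                        read_length_sd = 50,
                                        contamination_rate = 0, seed = 9),
                             withr::local_tempfile(fileext = ".fastq")))
  expect_identical(runif(1), a)
})

test_that("spike counts, categories and placement match the configuration", {
  cfg <- sim_config(n_reads = 200, read_length_mean = 2000,
                    read_length_sd = 400, contamination_rate = 0.2, seed = 64)
  fq <- withr::local_tempfile(fileext = ".fastq")
  res <- generate_dataset(cfg, fq)
  truth <- res$truth
  expect_equal(length(unique(truth$read_id)), 40L)  # round(200 * 0.2)
  expect_true(all(truth$position_category %in%
                    c("five_prime", "internal", "three_prime", "distributed")))
  # distributed reads carry 2-4 copies, others exactly one
  per_read <- table(truth$read_id)
  dist_ids <- unique(truth$read_id[truth$position_category == "distributed"])
  expect_true(all(per_read[dist_ids] >= 2L & per_read[dist_ids] <= 4L))
  expect_true(all(per_read[setdiff(names(per_read), dist_ids)] == 1L))
  # placement: verify inserted copies sit at the recorded offsets
  reads <- read_sequences(fq)
  ad <- builtin_adapters()
  for (k in sample(nrow(truth), 10)) {
    row <- truth[k, ]
    aseq <- ad$sequence[ad$name == row$adapter_name]
    if (row$orientation == "reverse") aseq <- reverse_complement(aseq)
    s <- reads$sequence[reads$read_id == row$read_id]
    expect_identical(substr(s, row$insert_offset + 1,
                            row$insert_offset + nchar(aseq)), aseq)
  }
  # zero rate produces an empty truth table
  res0 <- generate_dataset(sim_config(n_reads = 10, read_length_mean = 700,
                                      read_length_sd = 50,
                                      contamination_rate = 0, seed = 1), fq)
  expect_equal(nrow(res0$truth), 0L)
  expect_warning(
    generate_dataset(sim_config(n_reads = 10, read_length_mean = 700,
                                read_length_sd = 50,
                                contamination_rate = 0.01, seed = 1), fq),
    "no reads spiked")
})

test_that("generated FASTQ has HiFi-like constant qualities and valid lengths", {
  cfg <- sim_config(n_reads = 30, read_length_mean = 800, read_length_sd = 600,
                    min_read_length = 500, contamination_rate = 0.1, seed = 65)
  fq <- withr::local_tempfile(fileext = ".fastq")
  generate_dataset(cfg, fq)
  reads <- read_sequences(fq)
  expect_equal(nrow(reads), 30L)
  expect_true(all(nchar(reads$sequence) >= 500L))
  expect_true(all(reads$quality == strrep("U", nchar(reads$sequence))))
})
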