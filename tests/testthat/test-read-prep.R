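test_that("leading poly(T) runs trim only at or above the threshold", {
  tr <- trim_read("TTTTTTTTACGTACGTACGTACGT")
  expect_equal(tr$sequence, "ACGTACGTACGTACGT")
  expect_equal(tr$trimmed_polyt, 8L)

  # run of 3 < min_t_run 4: untouched
  tr3 <- trim_read("TTTACGTACGTACGTACGTACGT")
  expect_equal(tr3$sequence, "TTTACGTACGTACGTACGTACGT")
  expect_equal(tr3$trimmed_polyt, 0L)

  # only the contiguous prefix goes; an interrupted run stays
  tri <- trim_read("TTTTATTTTCGTACGTACGTACGT")
  expect_equal(tr$trimmed_polyt, 8L)
  expect_equal(tri$sequence, "ATTTTCGTACGTACGTACGT")
})

test_that("3' adapter matches of >= 8 nt with <= 10% mismatch are removed", {
  ad <- "AGATCGGAAGAGC"
  core <- "ACGTACGTACGTACGTACGT"
  tr <- trim_read(paste0(core, ad), adapter_seq = ad)
  expect_equal(tr$sequence, core)
  expect_equal(tr$trimmed_adapter, nchar(ad))

  # one mismatch in a 13-nt overlap is within 10%
  ad_mm <- sub("GGA", "GCA", ad)
  expect_equal(trim_read(paste0(core, ad_mm), adapter_seq = ad)$sequence,
               core)
  # a 7-nt suffix match is below the minimum overlap
  expect_equal(trim_read(paste0(core, substr(ad, 1, 7)),
                         adapter_seq = ad)$trimmed_adapter, 0L)
})

test_that("short post-trim reads are flagged discard, not dropped", {
  tr <- trim_read(paste0(strrep("T", 10), "ACGTACGTAC",
                         "AGATCGGAAGAGC"))
  expect_equal(tr$sequence, "ACGTACGTAC")
  expect_true(tr$discard)
})

test_that("qualities track the sequence and mismatched lengths error", {
  tr <- trim_read("TTTTTTACGTACGTACGTACGTAA", qual = strrep("F", 24))
  expect_equal(nchar(tr$qual), nchar(tr$sequence))
  expect_error(trim_read("ACGT", qual = "III"), "mismatch")
})

test_that("trimming is idempotent", {
  set.seed(7)
  reads <- vapply(1:50, function(i) {
    body <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    paste0(strrep("T", sample(0:12, 1)), body,
           substr("AGATCGGAAGAGC", 1, sample(c(0, 8:13), 1)))
  }, character(1))
  once <- trim_read(reads)
  twice <- trim_read(once$sequence, once$qual)
  expect_equal(twice$sequence, once$sequence)
  expect_equal(twice$trimmed_polyt, rep(0L, 50))
  expect_equal(twice$trimmed_adapter, rep(0L, 50))
})

test_that("LAP follows the CIGAR strand-aware and ignores soft clips", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam,
                 pos = c(901L, 901L, 901L),
                 cigar = c("100M", "50M10D50M", "5S100M"),
                 flag = c(16L, 16L, 0L))
  laps <- extract_laps(sam)
  laps <- laps[order(laps$read_id), ]
  # r1: 901 + 100 - 1; r2: deletions consume reference -> 1010;
  # r3: + strand alignment, soft clip does not move the start
  expect_equal(laps$lap, c(1000L, 1010L, 901L))
  expect_equal(laps$align_strand, c("-", "-", "+"))
  expect_equal(laps$gene_strand, c("+", "+", "-"))
})

test_that("secondary alignments and low-MAPQ reads are skipped", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam,
                 pos = c(901L, 901L, 901L),
                 cigar = c("50M", "50M", "50M"),
                 flag = c(16L, 272L, 16L),   # 272 = reverse + secondary
                 mapq = c(60L, 60L, 5L))
  laps <- extract_laps(sam, min_mapq = 10)
  expect_equal(nrow(laps), 1L)
  expect_equal(laps$read_id, "r1")
})

test_that("simulated noiseless reads recover true cleavage sites exactly", {
  cfg <- sim_config(n_genes = 6, replicates = 1, reads_per_gene = 80,
                    jitter = list(model = "none"), background_frac = 0,
                    rho = 0, seed = 101)
  sim <- simulate_experiment(cfg, tempfile("simlap"))
  for (s in sim$design$sample) {
    laps <- extract_laps(sim$paths$sam[[s]])
    truth <- sim$read_truth[sim$read_truth$sample == s, ]
    m <- match(laps$read_id, truth$read_id)
    expect_false(anyNA(m))
    expect_equal(laps$lap, truth$cleavage[m])
    expect_equal(laps$gene_strand, truth$strand[m])
  }
})

test_that("FASTQ trimming strips the simulated poly(T) prefix", {
  cfg <- sim_config(n_genes = 4, replicates = 1, reads_per_gene = 40,
                    jitter = list(model = "none"), background_frac = 0,
                    rho = 0, seed = 5)
  sim <- simulate_experiment(cfg, tempfile("simfq"))
  fq_in <- sim$paths$fastq[[1]]
  fq_out <- tempfile(fileext = ".fastq")
  stats <- trim_fastq(fq_in, fq_out)
  expect_equal(stats$n_discarded, 0L)
  trimmed <- ShortRead::readFastq(fq_out)
  # the poly(T) prefix is always removed; genomic T runs bordering the
  # junction may extend the trim slightly, never the reverse
  expect_true(all(ShortRead::width(trimmed) <= cfg$read_len))
  expect_true(mean(ShortRead::width(trimmed) == cfg$read_len) > 0.8)
})
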