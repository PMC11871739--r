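test_that("the +/-24 nt PASS match is inclusive at the boundary", {
  pas <- make_pas(1000L)
  win <- make_windows(pas)
  asn24 <- assign_laps(make_laps(1024L), win, pas)
  expect_equal(asn24$pas_id, "p1")
  asn25 <- assign_laps(make_laps(1025L), win, pas)
  expect_true(is.na(asn25$pas_id))
})

test_that("a read inside a window but far from every PAS is not PASS", {
  pas <- make_pas(1000L)
  win <- make_windows(pas)
  # 1-based 930 is inside [900, 1025] but 70 nt from the PAS
  asn <- assign_laps(make_laps(930L), win, pas)
  expect_true(is.na(asn$pas_id))
})

test_that("nearest PAS wins; exact ties break toward the proximal site", {
  pas <- make_pas(c(1000L, 1030L))
  win <- make_windows(pas)
  expect_equal(assign_laps(make_laps(1010L), win, pas)$pas_id, "p1")
  expect_equal(assign_laps(make_laps(1015L), win, pas)$pas_id, "p1")
  expect_equal(assign_laps(make_laps(1016L), win, pas)$pas_id, "p2")
  # on the minus strand proximal is the larger coordinate
  pas_m <- make_pas(c(1000L, 1030L), strand = "-")
  asn_m <- assign_laps(make_laps(1015L, gene_strand = "-"),
                       make_windows(pas_m), pas_m)
  expect_equal(asn_m$pas_id, "p2")
})

test_that("strand-discordant reads are never assigned", {
  pas <- make_pas(1000L, strand = "+")
  asn <- assign_laps(make_laps(1000L, gene_strand = "-"),
                     make_windows(pas), pas)
  expect_true(is.na(asn$pas_id))
})

test_that("assignment matches brute-force enumeration on random instances", {
  set.seed(11)
  params <- apa_params()
  for (i in 1:100) {
    inst <- random_instance()
    win <- make_windows(inst$pas, params)
    got <- assign_laps(inst$laps, win, inst$pas, params)$pas_id
    expect_identical(got, assign_brute(inst$laps, inst$pas, params))
  }
})

test_that("counts conserve totals and RPM sums to one million", {
  pas <- make_pas(c(1000L, 2000L), gene_id = c("G1", "G1"))
  win <- make_windows(pas)
  laps <- list(A = make_laps(c(1000L, 1003L, 997L, 2000L, 5000L)),
               B = make_laps(c(2001L, 1999L)))
  tab <- count_pass(laps, win, pas)
  expect_equal(unname(tab$counts[, "A"]), c(3L, 1L))
  expect_equal(unname(tab$pass_total), c(4L, 2L))
  expect_equal(colSums(tab$counts), tab$pass_total)
  expect_equal(tab$qc$unassigned_frac, c(1 / 5, 0))
  tab <- to_rpm(tab)
  expect_equal(unname(colSums(tab$rpm)), c(1e6, 1e6), tolerance = 1e-6)
})

test_that("RPM arithmetic follows counts / total * 1e6", {
  m <- matrix(c(5L, 15L), ncol = 1, dimnames = list(c("p1", "p2"), "A"))
  tab <- to_rpm(pas_count_table(m))
  expect_equal(unname(tab$rpm[, "A"]), c(250000, 750000))
  # single PAS with all reads
  m1 <- matrix(7L, dimnames = list("p1", "A"))
  expect_equal(unname(to_rpm(pas_count_table(m1))$rpm[1, 1]), 1e6)
})

test_that("zero-PASS samples are retained with a warning and RPM 0", {
  pas <- make_pas(1000L)
  win <- make_windows(pas)
  laps <- list(A = make_laps(1000L), B = make_laps(9000L))
  expect_warning(tab <- count_pass(laps, win, pas), "zero PASS")
  expect_equal(unname(tab$pass_total["B"]), 0L)
  tab <- to_rpm(tab)
  expect_equal(unname(tab$rpm[, "B"]), 0)
  expect_equal(tab$empty_samples, "B")
})

test_that("assignment is deterministic across reruns and samples", {
  set.seed(23)
  inst <- random_instance()
  win <- make_windows(inst$pas)
  laps <- list(A = inst$laps, B = inst$laps)
  t1 <- count_pass(laps, win, inst$pas)
  t2 <- count_pass(laps, win, inst$pas)
  expect_identical(t1$counts, t2$counts)
  expect_identical(t1$counts[, "A"], t1$counts[, "B"])
})

test_that("bedGraph export is 0-based, sorted, split by strand", {
  pas <- rbind(make_pas(c(2000L, 1000L), "+", pas_id = c("p2", "p1")),
               make_pas(1500L, "-", pas_id = "m1"))
  m <- matrix(c(1L, 3L, 0L), ncol = 1,
              dimnames = list(c("p2", "p1", "m1"), "A"))
  tab <- to_rpm(pas_count_table(m))
  prefix <- tempfile("track")
  paths <- export_tracks(tab, pas, "A", prefix)
  plus <- readLines(paths[["+"]])
  expect_match(plus[1], "^track type=bedGraph")
  expect_equal(plus[2], "chr1\t999\t1000\t750000")
  expect_equal(plus[3], "chr1\t1999\t2000\t250000")
  minus <- readLines(paths[["-"]])
  expect_equal(minus[2], "chr1\t1499\t1500\t0")
  # empty strand set -> header-only file
  pas_p <- make_pas(1000L)
  mp <- matrix(5L, dimnames = list("p1", "A"))
  paths2 <- export_tracks(to_rpm(pas_count_table(mp)), pas_p, "A",
                          tempfile("track2"))
  expect_equal(length(readLines(paths2[["-"]])), 1L)
})

test_that("count tables round-trip through TSV", {
  m <- matrix(c(5L, 15L, 0L, 2L), ncol = 2,
              dimnames = list(c("p1", "p2"), c("A", "B")))
  path <- tempfile(fileext = ".tsv")
  write_count_table(pas_count_table(m), path)
  expect_identical(read_count_table(path)$counts, m)
})
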