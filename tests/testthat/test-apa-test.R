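make_two_pas_table <- function(counts_ctl, counts_trt,
                               gene_id = "G1", strand = "+") {
  # counts_* : matrix 2 x replicates (row 1 pPAS, row 2 dPAS)
  pas <- make_pas(c(1000L, 1400L), strand = strand, gene_id = gene_id)
  m <- cbind(counts_ctl, counts_trt)
  colnames(m) <- c(sprintf("ctl_%d", seq_len(ncol(counts_ctl))),
                   sprintf("trt_%d", seq_len(ncol(counts_trt))))
  rownames(m) <- pas$pas_id
  storage.mode(m) <- "integer"
  design <- data.frame(
    sample = colnames(m),
    condition = rep(c("control", "treatment"),
                    c(ncol(counts_ctl), ncol(counts_trt))))
  list(table = to_rpm(pas_count_table(m)), pas = pas,
       gene_sets = build_gene_sets(pas), design = design)
}

test_that("top-2 selection keeps the two most-used PASs, proximal first", {
  pas <- make_pas(c(1000L, 1400L, 1800L), gene_id = "G1")
  m <- matrix(c(10L, 500L, 400L), ncol = 1,
              dimnames = list(pas$pas_id, "A"))
  top2 <- select_top2(build_gene_sets(pas), to_rpm(pas_count_table(m)))
  expect_true(top2$testable)
  expect_equal(top2$ppas_id, "p2")
  expect_equal(top2$dpas_id, "p3")

  # mean-RPM tie for second place between #1 and #3: proximal (#1) wins
  mt <- matrix(c(100L, 500L, 100L), ncol = 1,
               dimnames = list(pas$pas_id, "A"))
  top2t <- select_top2(build_gene_sets(pas), to_rpm(pas_count_table(mt)))
  expect_equal(c(top2t$ppas_id, top2t$dpas_id), c("p1", "p2"))
})

test_that("genes without two expressed PASs are untestable", {
  pas <- make_pas(c(1000L, 1400L), gene_id = "G1")
  m <- matrix(c(50L, 0L), ncol = 1, dimnames = list(pas$pas_id, "A"))
  top2 <- select_top2(build_gene_sets(pas), to_rpm(pas_count_table(m)))
  expect_false(top2$testable)
})

test_that("RED evaluates the stated log2-ratio difference", {
  expect_equal(compute_red(100, 100, 100, 100, pseudocount = 0), 0)
  # ctl (pPAS 200, dPAS 100), trt (100, 200): log2(2) - log2(0.5) = 2
  expect_equal(compute_red(200, 100, 100, 200, pseudocount = 0), 2)
  # pseudocount keeps zero cells finite
  expect_true(is.finite(compute_red(0, 100, 100, 0, pseudocount = 1)))
  expect_equal(compute_red(0, 0, 0, 0, pseudocount = 1), 0)
})

test_that("RED is antisymmetric under condition swap", {
  set.seed(31)
  for (i in 1:200) {
    x <- runif(4, 0, 1000)
    expect_equal(compute_red(x[1], x[2], x[3], x[4]),
                 -compute_red(x[3], x[4], x[1], x[2]))
  }
})

test_that("fisher mode reproduces exhaustive hypergeometric enumeration", {
  expect_equal(test_usage(10, 10, 10, 10, mode = "fisher")$p_value, 1.0)
  expect_equal(test_usage(90, 10, 50, 50, mode = "fisher")$p_value,
               fisher_enum(90, 10, 50, 50))
  set.seed(13)
  for (i in 1:50) {
    k <- sample(0:60, 4, replace = TRUE)
    if (sum(k[c(1, 3)]) == 0 || sum(k[c(2, 4)]) == 0 ||
        sum(k[1:2]) == 0 || sum(k[3:4]) == 0) next
    expect_equal(test_usage(k[1], k[2], k[3], k[4], "fisher")$p_value,
                 fisher_enum(k[1], k[2], k[3], k[4]), tolerance = 1e-10)
  }
})

test_that("all-zero margins give p = 1 and an untestable flag", {
  r <- test_usage(0, 0, 0, 0, mode = "fisher")
  expect_equal(r$p_value, 1)
  expect_true(r$untestable)
  rb <- test_usage(c(0, 0), c(0, 0), c(0, 0), c(0, 0), "betabin_lrt")
  expect_true(rb$untestable)
})

test_that("beta-binomial LRT agrees with Fisher on binomial data", {
  # with ample replication and no true overdispersion the two tests see
  # the same information; compare at moderate p where both are stable
  set.seed(9)
  ratios <- c()
  for (i in 1:25) {
    R <- 8; n <- 100
    p0 <- runif(1, 0.3, 0.7)
    kc <- rbinom(R, n, p0)
    kt <- rbinom(R, n, p0 + runif(1, 0, 0.05))
    pf <- test_usage(n - kc, kc, n - kt, kt, "fisher")$p_value
    pb <- test_usage(n - kc, kc, n - kt, kt, "betabin_lrt")$p_value
    if (pf > 0.01 && pf < 0.9) ratios <- c(ratios, pb / pf)
  }
  expect_gt(length(ratios), 10)
  expect_lt(abs(log(stats::median(ratios))), log(1.1))
})

test_that("beta-binomial LRT detects shifts and respects the null", {
  set.seed(17)
  # a clear usage shift across replicates
  p_shift <- test_usage(c(120, 130, 125), c(80, 70, 75),
                        c(80, 75, 85), c(120, 125, 115),
                        "betabin_lrt")$p_value
  expect_lt(p_shift, 1e-4)
  # identical usage
  p_null <- test_usage(c(100, 101), c(100, 99), c(99, 100), c(101, 100),
                       "betabin_lrt")$p_value
  expect_gt(p_null, 0.5)
})

test_that("calls follow the strict RED threshold and the p gate", {
  params <- apa_params()
  calls <- call_apa(red = c(0.30, 0.30, -0.50, log2(1.2),
                            log2(1.2) + 1e-6, 0.1),
                    p_value = c(0.01, 0.20, 0.001, 1e-9, 0.01, 1e-9),
                    params = params)
  expect_equal(as.character(calls$call),
               c("lengthened", "unchanged", "shortened", "unchanged",
                 "lengthened", "unchanged"))
})

test_that("BH correction gates calls on the adjusted p-value", {
  red <- c(1, 1, 1, 1)
  p <- c(0.001, 0.04, 0.04, 0.04)
  raw <- call_apa(red, p, correction = "none")
  bh <- call_apa(red, p, correction = "BH")
  expect_equal(sum(raw$call == "lengthened"), 4L)
  expect_equal(bh$q_value, p.adjust(p, "BH"))
  expect_equal(as.character(bh$call[1]), "lengthened")
  expect_equal(sum(bh$call == "lengthened"),
               sum(p.adjust(p, "BH") <= 0.05 & red > log2(1.2)))
})

test_that("apa_test is antisymmetric under swapping condition labels", {
  set.seed(41)
  d <- make_two_pas_table(matrix(c(300L, 100L), 2), matrix(c(100L, 300L), 2))
  fwd <- apa_test(d$table, d$gene_sets, d$design, mode = "fisher")
  swp <- apa_test(d$table, d$gene_sets, d$design, mode = "fisher",
                  control = "treatment", treatment = "control")
  expect_equal(swp$red, -fwd$red)
  expect_equal(swp$p_value, fwd$p_value)
  expect_equal(as.character(fwd$call), "lengthened")
  expect_equal(as.character(swp$call), "shortened")
})

test_that("apa_test picks the test mode from the design", {
  d1 <- make_two_pas_table(matrix(c(300L, 100L), 2),
                           matrix(c(100L, 300L), 2))
  expect_equal(attr(apa_test(d1$table, d1$gene_sets, d1$design), "mode"),
               "fisher")
  d2 <- make_two_pas_table(matrix(c(300L, 100L, 290L, 110L), 2),
                           matrix(c(100L, 300L, 110L, 290L), 2))
  expect_equal(attr(apa_test(d2$table, d2$gene_sets, d2$design), "mode"),
               "betabin_lrt")
})
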