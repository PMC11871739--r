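# Shared fixtures and independent oracles for the test suite.

# A minimal PAS annotation data.frame.
make_pas <- function(position, strand = "+", gene_id = "G1", chrom = "chr1",
                     pas_id = sprintf("p%d", seq_along(position)),
                     region = "3UTR_last_exon") {
  data.frame(pas_id = pas_id, chrom = chrom, position = position,
             strand = strand, gene_id = gene_id, region = region,
             stringsAsFactors = FALSE)
}

# A LAP table as extract_laps() would emit (gene_strand given directly).
make_laps <- function(lap, gene_strand = "+", chrom = "chr1",
                      read_id = sprintf("r%d", seq_along(lap))) {
  data.frame(read_id = read_id, chrom = chrom, lap = lap,
             align_strand = ifelse(gene_strand == "+", "-", "+"),
             gene_strand = gene_strand, mapq = 60L,
             stringsAsFactors = FALSE)
}

# Write a tiny SAM file from alignment fields.
write_test_sam <- function(path, pos, cigar, flag = 16L, mapq = 60L,
                           chrom = "chr1", chrom_len = 100000L,
                           qname = sprintf("r%d", seq_along(pos))) {
  ref_len <- vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(ops, function(o) {
      n <- as.integer(sub("[MIDNSHP=X]$", "", o))
      if (grepl("[MDN=X]$", o)) n else 0L
    }, integer(1)))
  }, integer(1))
  read_len <- vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(ops, function(o) {
      n <- as.integer(sub("[MIDNSHP=X]$", "", o))
      if (grepl("[MIS=X]$", o)) n else 0L
    }, integer(1)))
  }, integer(1))
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     qname, flag, chrom, pos, mapq, cigar,
                     strrep("A", read_len), strrep("I", read_len)))
  writeLines(lines, path)
  invisible(ref_len)
}

# Independent oracle: exhaustive two-sided Fisher p by hypergeometric
# enumeration of all 2x2 tables with the observed margins.
fisher_enum <- function(ppas_ctl, dpas_ctl, ppas_trt, dpas_trt) {
  m <- ppas_ctl + dpas_ctl; n <- ppas_trt + dpas_trt
  k <- ppas_ctl + ppas_trt
  supp <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(supp, m, n, k)
  pobs <- stats::dhyper(ppas_ctl, m, n, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Independent oracle: brute-force PASS assignment enumerating every
# (read, PAS) pair; mirrors the written rule, not the implementation.
assign_brute <- function(laps, pas, params = apa_params()) {
  out <- rep(NA_character_, nrow(laps))
  for (i in seq_len(nrow(laps))) {
    best <- NA_character_; best_d <- Inf; best_key <- Inf
    for (j in seq_len(nrow(pas))) {
      if (pas$chrom[j] != laps$chrom[i] ||
          pas$strand[j] != laps$gene_strand[i]) next
      up <- if (pas$strand[j] == "+") params$upstream_len else
        params$downstream_len
      dn <- if (pas$strand[j] == "+") params$downstream_len else
        params$upstream_len
      lo <- max(1, pas$position[j] - up); hi <- pas$position[j] + dn
      if (laps$lap[i] < lo || laps$lap[i] > hi) next
      d <- abs(laps$lap[i] - pas$position[j])
      if (d > params$lap_tolerance) next
      key <- if (pas$strand[j] == "+") pas$position[j] else -pas$position[j]
      if (d < best_d || (d == best_d && key < best_key)) {
        best <- pas$pas_id[j]; best_d <- d; best_key <- key
      }
    }
    out[i] <- best
  }
  out
}

# Random small assignment instance for oracle-equivalence checks.
random_instance <- function() {
  n_pas <- sample(1:5, 1)
  strand <- sample(c("+", "-"), 1)
  pos <- sort(sample(500:2500, n_pas))
  pas <- make_pas(pos, strand = strand)
  n_reads <- sample(1:50, 1)
  laps <- make_laps(sample(400:2600, n_reads, replace = TRUE),
                    gene_strand = strand)
  list(pas = pas, laps = laps)
}
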