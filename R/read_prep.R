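#' Trim poly(T) and adapter from QuantSeq FWD reverse reads
#'
#' The reverse read (read 2) of a QuantSeq FWD library starts at the
#' poly(A) junction, so before alignment it carries a leading poly(T)
#' stretch (the complement of the tail) and possibly 3' adapter sequence.
#' `trim_read` removes the maximal *contiguous* leading run of T when that
#' run is at least `min_t_run` long (interrupted runs are not chased), then
#' removes a 3' adapter match of at least `min_adapter_match` nt with at
#' most `max_mismatch_frac` mismatches (leftmost match wins). Reads shorter
#' than `min_len` after trimming are flagged for discard, not removed.
#'
#' Trimming is idempotent: applying it to already-trimmed output changes
#' nothing.
#'
#' @param sequence Character vector of read sequences over A,C,G,T,N.
#' @param qual Optional character vector of per-base qualities, same
#'   lengths as `sequence`.
#' @param adapter_seq Adapter to search for at the 3' end.
#' @param min_t_run Minimum leading T-run length to trim (default 4).
#' @param min_adapter_match Minimum adapter overlap, nt (default 8).
#' @param max_mismatch_frac Maximum mismatch fraction in the adapter
#'   overlap (default 0.1).
#' @param min_len Minimum post-trim length; shorter reads are flagged
#'   `discard` (default 18).
#' @return A data.frame with columns `sequence`, `qual`, `trimmed_polyt`,
#'   `trimmed_adapter`, `discard`.
#' @examples
#' trim_read("TTTTTTTTACGTACGTACGTACGT")$sequence  # "ACGTACGTACGTACGT"
#' @export
trim_read <- function(sequence, qual = NULL,
                      adapter_seq = "AGATCGGAAGAGC", min_t_run = 4,
                      min_adapter_match = 8, max_mismatch_frac = 0.1,
                      min_len = 18) {
  n <- length(sequence)
  if (is.null(qual)) qual <- strrep("I", nchar(sequence))
  if (length(qual) != n || any(nchar(qual) != nchar(sequence)))
    stop("sequence/quality length mismatch")
  ad <- strsplit(adapter_seq, "")[[1]]
  out_seq <- character(n); out_qual <- character(n)
  n_polyt <- integer(n); n_adapter <- integer(n)
  for (i in seq_len(n)) {
    s <- sequence[i]; q <- qual[i]
    # leading contiguous poly(T)
    run <- attr(regexpr("^T*", s), "match.length")
    if (run >= min_t_run) {
      s <- substring(s, run + 1L); q <- substring(q, run + 1L)
      n_polyt[i] <- run
    }
    # leftmost 3' adapter match: adapter prefix vs read suffix
    sv <- strsplit(s, "")[[1]]
    L <- length(sv)
    hit <- 0L
    if (L >= min_adapter_match) {
      for (start in seq_len(L - min_adapter_match + 1L)) {
        ov <- min(L - start + 1L, length(ad))
        if (ov < min_adapter_match) break
        mm <- sum(sv[start:(start + ov - 1L)] != ad[seq_len(ov)])
        if (mm <= floor(max_mismatch_frac * ov)) { hit <- start; break }
      }
    }
    if (hit > 0L) {
      n_adapter[i] <- L - hit + 1L
      s <- substring(s, 1L, hit - 1L); q <- substring(q, 1L, hit - 1L)
    }
    out_seq[i] <- s; out_qual[i] <- q
  }
  data.frame(sequence = out_seq, qual = out_qual,
             trimmed_polyt = n_polyt, trimmed_adapter = n_adapter,
             discard = nchar(out_seq) < min_len, stringsAsFactors = FALSE)
}

#' Trim a FASTQ file of QuantSeq FWD reverse reads
#'
#' File-level wrapper around [trim_read()]: reads FASTQ (optionally
#' gzipped), trims, drops reads flagged discard, and writes trimmed FASTQ.
#'
#' @param fastq_in Input FASTQ path.
#' @param fastq_out Output FASTQ path.
#' @param ... Passed to [trim_read()].
#' @return Invisibly, a list with `n_in`, `n_out`, `n_discarded`.
#' @export
trim_fastq <- function(fastq_in, fastq_out, ...) {
  fq <- ShortRead::readFastq(fastq_in)
  tr <- trim_read(as.character(ShortRead::sread(fq)),
                  as.character(Biostrings::quality(Biostrings::quality(fq))),
                  ...)
  keep <- !tr$discard
  out <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(tr$sequence[keep]),
    quality = Biostrings::BStringSet(tr$qual[keep]),
    id = ShortRead::id(fq)[keep])
  if (file.exists(fastq_out)) file.remove(fastq_out)
  ShortRead::writeFastq(out, fastq_out, compress = grepl("\\.gz$", fastq_out))
  invisible(list(n_in = length(fq), n_out = sum(keep),
                 n_discarded = sum(!keep)))
}

#' Extract the last aligned position (LAP) of each read
#'
#' The LAP is the reference coordinate of the aligned base nearest the
#' mRNA cleavage site. A QuantSeq FWD read 2 runs from the poly(A)
#' junction into the transcript, so after poly(T) trimming its 5' end sits
#' at the cleavage site: for an alignment on the - strand (gene on +) the
#' LAP is the largest reference coordinate consumed by the CIGAR, and for
#' a + strand alignment the smallest. Soft-clipped bases consume no
#' reference and never move the LAP. Secondary, supplementary and unmapped
#' records are skipped, as are alignments below `min_mapq`.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param min_mapq Minimum mapping quality (default from [apa_params()]).
#' @return A data.frame with columns `read_id`, `chrom`, `lap` (1-based),
#'   `align_strand`, `gene_strand` (the transcript strand implied by the
#'   orientation, i.e. the opposite of `align_strand`), `mapq`.
#' @export
extract_laps <- function(path, min_mapq = apa_params()$min_mapq) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("qname", "mapq"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  mapq <- S4Vectors::mcols(aln)$mapq
  keep <- is.na(mapq) | mapq >= min_mapq
  aln <- aln[keep]
  w0 <- GenomicAlignments::width(aln) == 0L
  if (any(w0)) {
    warning(sum(w0), " alignment(s) consuming zero reference bases skipped")
    aln <- aln[!w0]
  }
  st <- as.character(BiocGenerics::strand(aln))
  lap <- ifelse(st == "-", BiocGenerics::end(aln), BiocGenerics::start(aln))
  data.frame(read_id = S4Vectors::mcols(aln)$qname,
             chrom = as.character(GenomicAlignments::seqnames(aln)),
             lap = as.integer(lap),
             align_strand = st,
             gene_strand = ifelse(st == "-", "+", "-"),
             mapq = S4Vectors::mcols(aln)$mapq,
             stringsAsFactors = FALSE)
}

#' Write a LAP table as TSV
#' @param laps Output of [extract_laps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lap_table <- function(laps, path) {
  utils::write.table(laps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
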