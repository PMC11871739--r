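#' Assign last aligned positions to annotated poly(A) sites
#'
#' Implements the two-stage PASS-read rule. A read is first required to
#' fall inside some PAS window on the concordant strand (only alignments
#' to annotated PAS regions are kept); it is then a PAS-supporting (PASS)
#' read iff its LAP lies within `lap_tolerance` nt (inclusive) of the PAS
#' position of at least one of those windows. Among several qualifying
#' PASs the nearest wins; an exact distance tie is broken toward the more
#' proximal PAS (transcription-5', i.e. the smaller coordinate on + and
#' the larger on -). A read inside a window but farther than the tolerance
#' from every PAS position is not a PASS read.
#'
#' @param laps LAP table from [extract_laps()] (needs `chrom`, `lap`,
#'   `gene_strand`).
#' @param windows Window table from [make_windows()].
#' @param pas PAS annotation data.frame.
#' @param params [apa_params()] object.
#' @return `laps` with an added `pas_id` column (`NA` = unassigned).
#' @export
assign_laps <- function(laps, windows, pas, params = apa_params()) {
  laps$pas_id <- rep(NA_character_, nrow(laps))
  if (!nrow(laps) || !nrow(windows)) return(laps)
  win_gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$win_start + 1L, end = windows$win_end),
    strand = windows$strand)
  lap_gr <- GenomicRanges::GRanges(
    laps$chrom, IRanges::IRanges(laps$lap, laps$lap),
    strand = laps$gene_strand)
  hits <- GenomicRanges::findOverlaps(lap_gr, win_gr, ignore.strand = FALSE)
  if (!length(hits)) return(laps)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pas_pos <- pas$position[match(windows$pas_id[si], pas$pas_id)]
  d <- abs(laps$lap[qi] - pas_pos)
  ok <- d <= params$lap_tolerance
  qi <- qi[ok]; si <- si[ok]; d <- d[ok]; pas_pos <- pas_pos[ok]
  if (!length(qi)) return(laps)
  # proximal = 5' in transcription direction: ascending position on +,
  # descending on -; order so the winner per read sorts first
  prox_key <- ifelse(windows$strand[si] == "+", 1, -1) * pas_pos
  o <- order(qi, d, prox_key)
  first <- !duplicated(qi[o])
  laps$pas_id[qi[o][first]] <- windows$pas_id[si[o][first]]
  laps
}

#' Count PASS reads per PAS per sample
#'
#' Runs [assign_laps()] on each sample's LAP table and tabulates PASS
#' reads per `(pas, sample)`. Every PASS read contributes to exactly one
#' PAS; unassigned reads are reported per sample in the QC slot.
#'
#' @param lap_list Named list of LAP tables, one per sample.
#' @param windows,pas,params As in [assign_laps()].
#' @return An object of class `pas_count_table`: a list with `samples`,
#'   `counts` (pas x sample integer matrix over all annotated PASs),
#'   `pass_total`, `rpm` (`NULL` until [to_rpm()]), and `qc`
#'   (per-sample total reads, PASS reads and unassigned fraction).
#' @export
count_pass <- function(lap_list, windows, pas, params = apa_params()) {
  stopifnot(length(lap_list) >= 1)
  samples <- names(lap_list)
  if (is.null(samples) || any(samples == ""))
    stop("lap_list must be a named list (names = sample names)")
  counts <- matrix(0L, nrow = nrow(pas), ncol = length(samples),
                   dimnames = list(pas$pas_id, samples))
  total <- integer(length(samples)); names(total) <- samples
  for (s in samples) {
    asn <- assign_laps(lap_list[[s]], windows, pas, params)
    total[s] <- nrow(asn)
    tab <- table(factor(asn$pas_id, levels = pas$pas_id))
    counts[, s] <- as.integer(tab)
  }
  pass_total <- colSums(counts)
  if (any(pass_total == 0))
    warning("sample(s) with zero PASS reads: ",
            paste(samples[pass_total == 0], collapse = ", "))
  qc <- data.frame(sample = samples, total_reads = as.integer(total),
                   pass_reads = as.integer(pass_total),
                   unassigned_frac = ifelse(total > 0,
                                            (total - pass_total) / total, 0),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(samples = samples, counts = counts,
                 pass_total = pass_total, rpm = NULL, qc = qc),
            class = "pas_count_table")
}

#' Build a PAS count table from a precomputed count matrix
#'
#' Entry point for count-level workflows (e.g. simulated counts or an
#' externally produced PASS matrix) that bypass read assignment.
#'
#' @param counts Integer matrix, rows = pas_id, columns = samples.
#' @return A `pas_count_table`.
#' @export
pas_count_table <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  structure(list(samples = colnames(counts),
                 counts = counts, pass_total = colSums(counts),
                 rpm = NULL, qc = NULL),
            class = "pas_count_table")
}

#' @export
print.pas_count_table <- function(x, ...) {
  cat(sprintf("PAS count table: %d PASs x %d samples\n",
              nrow(x$counts), length(x$samples)))
  cat("  PASS totals:", paste(sprintf("%s=%d", x$samples,
                                      x$pass_total), collapse = ", "), "\n")
  if (!is.null(x$rpm)) cat("  RPM: filled\n")
  invisible(x)
}

#' Normalize PASS counts to reads per million
#'
#' `rpm[p, s] = counts[p, s] / pass_total[s] * 1e6`; each non-empty
#' sample's RPM column sums to exactly one million. Samples with zero
#' PASS reads get RPM 0 and are flagged.
#'
#' @param table A `pas_count_table`.
#' @return The table with its `rpm` slot filled.
#' @export
to_rpm <- function(table) {
  stopifnot(inherits(table, "pas_count_table"))
  tot <- table$pass_total
  denom <- ifelse(tot > 0, tot, 1)
  table$rpm <- sweep(table$counts, 2, denom, "/") * 1e6
  table$empty_samples <- table$samples[tot == 0]
  table
}

#' Write the PASS count matrix as TSV
#' @param table A `pas_count_table`.
#' @param path Output path.
#' @param what `"counts"` or `"rpm"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path, what = c("counts", "rpm")) {
  what <- match.arg(what)
  m <- table[[what]]
  if (is.null(m)) stop(what, " not filled")
  df <- data.frame(pas_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PASS count matrix written by [write_count_table()]
#' @param path TSV path (first column `pas_id`).
#' @return A `pas_count_table`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  pas_count_table(m)
}

#' Export per-sample RPM tracks as bedGraph
#'
#' Writes one bedGraph interval per PAS (the 1-nt cleavage position) with
#' the sample's RPM as value, coordinate-sorted, one file per strand
#' (suffixes `.plus.bedGraph` / `.minus.bedGraph`).
#'
#' @param table A `pas_count_table` with RPM filled.
#' @param pas PAS annotation data.frame.
#' @param sample Sample name.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
export_tracks <- function(table, pas, sample, prefix) {
  stopifnot(inherits(table, "pas_count_table"))
  if (is.null(table$rpm)) stop("run to_rpm() first")
  if (!sample %in% table$samples) stop("unknown sample: ", sample)
  rpm <- table$rpm[match(pas$pas_id, rownames(table$rpm)), sample]
  paths <- character(2); names(paths) <- c("+", "-")
  for (st in c("+", "-")) {
    suffix <- if (st == "+") "plus" else "minus"
    path <- paste0(prefix, ".", suffix, ".bedGraph")
    sel <- which(pas$strand == st)
    sel <- sel[order(pas$chrom[sel], pas$position[sel])]
    lines <- sprintf("%s\t%d\t%d\t%s", pas$chrom[sel],
                     pas$position[sel] - 1L, pas$position[sel],
                     format(rpm[sel], trim = TRUE, scientific = FALSE))
    writeLines(c(sprintf("track type=bedGraph name=\"%s %s strand\"",
                         sample, suffix), lines), path)
    paths[st] <- path
  }
  invisible(paths)
}
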