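#' Load a poly(A)-site annotation table
#'
#' Reads PAS records from either the package's native tab-separated dialect
#' (columns `chrom`, `position` (1-based cleavage coordinate), `strand`,
#' `gene_id`, optional `region`, optional `pas_id`) or from BED6, where the
#' interval's end coordinate is taken as the 1-based PAS position and the
#' name field as `pas_id`.
#'
#' Duplicate `(chrom, position, strand)` rows are collapsed to one record
#' with a warning. Missing `pas_id`s are synthesized as
#' `chrom:position:strand`; missing `region` defaults to `3UTR_last_exon`.
#'
#' @param path Path to the annotation file.
#' @param format `"polyadb_tsv"` (native dialect, with header) or `"bed"`
#'   (BED6, no header).
#' @return A data.frame with columns `pas_id`, `chrom`, `position`,
#'   `strand`, `gene_id`, `region`.
#' @export
load_pas_table <- function(path, format = c("polyadb_tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "polyadb_tsv") {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    need <- c("chrom", "position", "strand", "gene_id")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
    pos <- suppressWarnings(as.integer(raw$position))
    bad <- which(is.na(pos) | pos < 1)
    if (length(bad))
      stop("malformed coordinate at line ", bad[1] + 1L,
           " of ", path, ": '", raw$position[bad[1]], "'")
    pas <- data.frame(
      pas_id = if ("pas_id" %in% names(raw)) raw$pas_id else
        paste(raw$chrom, pos, raw$strand, sep = ":"),
      chrom = raw$chrom, position = pos, strand = raw$strand,
      gene_id = raw$gene_id,
      region = if ("region" %in% names(raw)) raw$region else "3UTR_last_exon",
      stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 6) stop("BED input needs 6 columns, got ", ncol(raw))
    end <- suppressWarnings(as.integer(raw[[3]]))
    start <- suppressWarnings(as.integer(raw[[2]]))
    bad <- which(is.na(end) | is.na(start) | end < 1 | start < 0)
    if (length(bad))
      stop("malformed coordinate at line ", bad[1], " of ", path)
    # BED is 0-based half-open; a 1-nt PAS interval [p-1, p) has position p
    pas <- data.frame(
      pas_id = raw[[4]], chrom = raw[[1]], position = end,
      strand = raw[[6]], gene_id = sub("\\|.*$", "", raw[[4]]),
      region = "3UTR_last_exon", stringsAsFactors = FALSE)
  }
  bad_strand <- which(!pas$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("unknown strand symbol '", pas$strand[bad_strand[1]],
         "' at record ", bad_strand[1])
  key <- paste(pas$chrom, pas$position, pas$strand)
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    warning(ndup, " duplicate (chrom, position, strand) record(s) collapsed")
    pas <- pas[!duplicated(key), , drop = FALSE]
  }
  if (anyDuplicated(pas$pas_id))
    stop("pas_id values are not unique after deduplication")
  rownames(pas) <- NULL
  pas
}

#' Write a PAS table in the native dialect
#'
#' Inverse of [load_pas_table()] with `format = "polyadb_tsv"`: writing and
#' reloading yields an identical record set.
#'
#' @param pas PAS data.frame as returned by [load_pas_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pas_table <- function(pas, path) {
  utils::write.table(pas[, c("pas_id", "chrom", "position", "strand",
                             "gene_id", "region")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct strand-aware PAS windows
#'
#' Each annotated PAS gets a genomic window spanning `upstream_len` nt on
#' its transcription-5' side to `downstream_len` nt on its 3' side. On the
#' + strand the window covers 1-based positions
#' `[position - upstream_len, position + downstream_len]`; on the - strand
#' the mirror image. Windows are emitted as 0-based half-open intervals and
#' clipped at the chromosome start (with a warning) if they would run below
#' coordinate 1.
#'
#' @param pas PAS data.frame.
#' @param params [apa_params()] object.
#' @return A data.frame with columns `pas_id`, `chrom`, `win_start`,
#'   `win_end` (0-based half-open), `strand`.
#' @examples
#' pas <- data.frame(pas_id = "p1", chrom = "chr1", position = 1000,
#'                   strand = "+", gene_id = "G1", region = "3UTR_last_exon")
#' make_windows(pas)  # covers 1-based 900..1025
#' @export
make_windows <- function(pas, params = apa_params()) {
  up <- ifelse(pas$strand == "+", params$upstream_len, params$downstream_len)
  dn <- ifelse(pas$strand == "+", params$downstream_len, params$upstream_len)
  start1 <- pas$position - up      # 1-based inclusive start
  end1 <- pas$position + dn        # 1-based inclusive end
  if (any(start1 < 1)) {
    warning(sum(start1 < 1), " window(s) clipped at chromosome start")
    start1 <- pmax(start1, 1L)
  }
  data.frame(pas_id = pas$pas_id, chrom = pas$chrom,
             win_start = start1 - 1L, win_end = end1,
             strand = pas$strand, stringsAsFactors = FALSE)
}

#' Export PAS windows as BED6
#'
#' @param windows Output of [make_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
windows_to_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$win_start, windows$win_end,
                    windows$pas_id, 0L, windows$strand)
  bed <- bed[order(bed[[1]], bed[[2]]), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Order each gene's 3'UTR poly(A) sites along the transcript
#'
#' Restricts the annotation to last-exon 3'UTR PASs and ranks them 5' to 3'
#' in transcription direction (ascending genomic coordinate on +, descending
#' on -), so that rank 1 is the most proximal site (nearest the stop codon).
#' Genes with fewer than two such PASs are retained but flagged untestable;
#' genes whose PASs span multiple chromosomes are dropped with a warning.
#'
#' @param pas PAS data.frame (must carry `region`).
#' @param gene_model Optional data.frame `(gene_id, strand)` used to check
#'   strand consistency; when `NULL` the strand is taken from the PAS rows.
#' @return A data.frame with one row per retained 3'UTR PAS: `gene_id`,
#'   `strand`, `chrom`, `pas_id`, `position`, `pas_rank`, `n_pas`,
#'   `testable`.
#' @export
build_gene_sets <- function(pas, gene_model = NULL) {
  utr <- pas[pas$region == "3UTR_last_exon", , drop = FALSE]
  if (!is.null(gene_model)) {
    st <- gene_model$strand[match(utr$gene_id, gene_model$gene_id)]
    mism <- !is.na(st) & st != utr$strand
    if (any(mism)) {
      warning(sum(mism), " PAS record(s) on the wrong strand for their gene; dropped")
      utr <- utr[!mism, , drop = FALSE]
    }
  }
  nchrom <- tapply(utr$chrom, utr$gene_id, function(x) length(unique(x)))
  multi <- names(nchrom)[nchrom > 1]
  if (length(multi)) {
    warning("gene(s) with PASs on multiple chromosomes excluded: ",
            paste(multi, collapse = ", "))
    utr <- utr[!utr$gene_id %in% multi, , drop = FALSE]
  }
  if (!nrow(utr))
    return(data.frame(gene_id = character(), strand = character(),
                      chrom = character(), pas_id = character(),
                      position = integer(), pas_rank = integer(),
                      n_pas = integer(), testable = logical()))
  ord <- order(utr$gene_id, ifelse(utr$strand == "+", 1, -1) * utr$position)
  utr <- utr[ord, , drop = FALSE]
  rk <- stats::ave(utr$position, utr$gene_id, FUN = seq_along)
  np <- stats::ave(utr$position, utr$gene_id, FUN = length)
  data.frame(gene_id = utr$gene_id, strand = utr$strand, chrom = utr$chrom,
             pas_id = utr$pas_id, position = utr$position,
             pas_rank = as.integer(rk), n_pas = as.integer(np),
             testable = np >= 2, stringsAsFactors = FALSE, row.names = NULL)
}
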