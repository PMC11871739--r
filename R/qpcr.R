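#' ddCt relative expression
#'
#' Classic ddCt arithmetic under perfect (doubling-per-cycle)
#' amplification: replicate Ct values are averaged first, then
#' `dCt = Ct(target) - Ct(reference)` per condition,
#' `ddCt = dCt(treatment) - dCt(control)` and the fold change is
#' `2^(-ddCt)`.
#'
#' @param ct_target_trt,ct_ref_trt Ct replicates of target and reference
#'   gene in the treatment condition.
#' @param ct_target_ctl,ct_ref_ctl Same for the control condition.
#' @return A list with `ddct`, `fold` (linear), `log2_fold`, and `se_ddct`
#'   (delta-method standard error from the replicate Ct variances, for
#'   reporting only).
#' @examples
#' ddct_fold_change(20, 15, 22, 15)$fold  # ddCt = -2 -> fold 4
#' @export
ddct_fold_change <- function(ct_target_trt, ct_ref_trt,
                             ct_target_ctl, ct_ref_ctl) {
  vals <- list(ct_target_trt, ct_ref_trt, ct_target_ctl, ct_ref_ctl)
  if (any(vapply(vals, function(x) length(x) == 0 || any(!is.finite(x)),
                 TRUE)))
    stop("all Ct values must be present and finite")
  dct_trt <- mean(ct_target_trt) - mean(ct_ref_trt)
  dct_ctl <- mean(ct_target_ctl) - mean(ct_ref_ctl)
  ddct <- dct_trt - dct_ctl
  sem2 <- function(x) if (length(x) > 1) stats::var(x) / length(x) else 0
  se <- sqrt(sum(vapply(vals, sem2, numeric(1))))
  list(ddct = ddct, fold = 2^(-ddct), log2_fold = -ddct, se_ddct = se)
}

#' Change in the long/total isoform ratio
#'
#' The qPCR proxy for distal PAS usage: fold change of the long-isoform
#' amplicon (primers just upstream of the distal PAS) divided by the fold
#' change of the total-transcript amplicon. A ratio change below 1 means
#' relative 3'UTR shortening, above 1 lengthening.
#'
#' @param fold_long,fold_total Linear ddCt fold changes.
#' @return A list with `ratio_change` (linear) and `log2_ratio_change`.
#' @examples
#' long_total_ratio_change(0.5, 2)$ratio_change  # 0.25: shortening
#' @export
long_total_ratio_change <- function(fold_long, fold_total) {
  if (any(!is.finite(c(fold_long, fold_total))) ||
      any(c(fold_long, fold_total) <= 0))
    stop("fold changes must be positive and finite")
  r <- fold_long / fold_total
  list(ratio_change = r, log2_ratio_change = log2(r))
}

#' Read a Ct table
#'
#' Expected columns: `sample`, `condition`, `gene_id`, `target` (one of
#' `total`, `long`, `reference`), `ct`, and optionally `timepoint` and
#' `replicate`.
#'
#' @param path TSV/CSV path (separator sniffed from the extension).
#' @return A validated data.frame.
#' @export
read_qpcr_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "gene_id", "target", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("Ct values must be positive and finite")
  bad <- setdiff(unique(df$target), c("total", "long", "reference"))
  if (length(bad))
    stop("unknown target label(s): ", paste(bad, collapse = ", "))
  df
}

#' Per-gene qPCR APA validation
#'
#' For every gene in a Ct table, computes the ddCt fold change
#' (treatment vs control, normalized to the reference gene) of the
#' total-transcript and long-isoform amplicons and the resulting
#' long/total ratio change — the qPCR analogue of the RED sign.
#'
#' @param qpcr Ct table, see [read_qpcr_table()].
#' @param control,treatment Condition labels.
#' @return A data.frame per gene: `gene_id`, `fold_total`, `fold_long`,
#'   `log2_fold_total`, `log2_fold_long`, `ratio_change`,
#'   `log2_ratio_change`.
#' @export
qpcr_validate <- function(qpcr, control = "control",
                          treatment = "treatment") {
  genes <- setdiff(unique(qpcr$gene_id[qpcr$target != "reference"]), NA)
  get_ct <- function(cond, tgt, gene = NULL) {
    sel <- qpcr$condition == cond & qpcr$target == tgt
    if (!is.null(gene)) sel <- sel & qpcr$gene_id == gene
    qpcr$ct[sel]
  }
  for (cond in c(control, treatment))
    if (!length(get_ct(cond, "reference")))
      stop("no reference-gene Ct rows for condition '", cond, "'")
  out <- lapply(genes, function(g) {
    ft <- ddct_fold_change(get_ct(treatment, "total", g),
                           get_ct(treatment, "reference"),
                           get_ct(control, "total", g),
                           get_ct(control, "reference"))
    fl <- ddct_fold_change(get_ct(treatment, "long", g),
                           get_ct(treatment, "reference"),
                           get_ct(control, "long", g),
                           get_ct(control, "reference"))
    rc <- long_total_ratio_change(fl$fold, ft$fold)
    data.frame(gene_id = g, fold_total = ft$fold, fold_long = fl$fold,
               log2_fold_total = ft$log2_fold, log2_fold_long = fl$log2_fold,
               ratio_change = rc$ratio_change,
               log2_ratio_change = rc$log2_ratio_change,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Idealized Ct values from transcript abundances
#'
#' Maps abundances to Ct under perfect efficiency,
#' `Ct = c0 - log2(abundance)` — the bridge between simulated isoform
#' abundances and the qPCR arithmetic, used to check that the qPCR
#' long/total readout agrees in sign with the sequencing RED.
#'
#' @param abundance Positive abundances (arbitrary units).
#' @param c0 Ct of one abundance unit (default 30).
#' @return Numeric Ct values.
#' @export
idealized_ct <- function(abundance, c0 = 30) {
  stopifnot(all(abundance > 0))
  c0 - log2(abundance)
}
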