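#' Select the two most-used poly(A) sites per gene
#'
#' For each gene with at least two last-exon 3'UTR PASs, picks the two
#' PASs with the largest mean RPM across all samples of the comparison
#' (ties broken toward the more proximal PAS). Of the two, the one nearer
#' the stop codon in transcription direction is the proximal PAS (pPAS),
#' the other the distal PAS (dPAS). Genes with fewer than two PASs
#' carrying nonzero counts are untestable.
#'
#' @param gene_sets Output of [build_gene_sets()].
#' @param table A `pas_count_table` with RPM filled.
#' @param samples Samples to average over (default: all).
#' @return A data.frame `gene_id`, `ppas_id`, `dpas_id`, `testable`.
#' @export
select_top2 <- function(gene_sets, table, samples = table$samples) {
  stopifnot(inherits(table, "pas_count_table"))
  if (is.null(table$rpm)) stop("run to_rpm() first")
  rpm <- table$rpm[, samples, drop = FALSE]
  cnt <- table$counts[, samples, drop = FALSE]
  genes <- unique(gene_sets$gene_id)
  res <- data.frame(gene_id = genes, ppas_id = NA_character_,
                    dpas_id = NA_character_, testable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    gs <- gene_sets[gene_sets$gene_id == genes[i], , drop = FALSE]
    gs <- gs[gs$pas_id %in% rownames(rpm), , drop = FALSE]
    if (nrow(gs) < 2) next
    mean_rpm <- rowMeans(rpm[gs$pas_id, , drop = FALSE])
    nonzero <- rowSums(cnt[gs$pas_id, , drop = FALSE]) > 0
    if (sum(nonzero) < 2) next
    # argmax-2 by mean RPM, tie toward proximal (lower pas_rank)
    o <- order(-mean_rpm, gs$pas_rank)
    top2 <- gs[o[1:2], , drop = FALSE]
    top2 <- top2[order(top2$pas_rank), , drop = FALSE]
    res$ppas_id[i] <- top2$pas_id[1]
    res$dpas_id[i] <- top2$pas_id[2]
    res$testable[i] <- TRUE
  }
  res
}

#' Relative expression difference (RED) between conditions
#'
#' RED is the between-condition difference of the log2 distal/proximal
#' RPM ratio:
#' \deqn{RED = \log_2\frac{d_{trt}+\epsilon}{p_{trt}+\epsilon} -
#'             \log_2\frac{d_{ctl}+\epsilon}{p_{ctl}+\epsilon}}
#' with pseudocount \eqn{\epsilon} in RPM units. Positive RED means the
#' distal site gained relative usage in the treatment — 3'UTR
#' lengthening; negative RED means shortening. Vectorized over genes.
#'
#' @param ppas_ctl,dpas_ctl,ppas_trt,dpas_trt Mean RPM of the proximal and
#'   distal PAS in control and treatment.
#' @param pseudocount Pseudocount in RPM (default 1; use 0 for exact
#'   ground-truth arithmetic).
#' @return Numeric vector of RED values, log2 units.
#' @examples
#' compute_red(200, 100, 100, 200, pseudocount = 0)  # 2
#' @export
compute_red <- function(ppas_ctl, dpas_ctl, ppas_trt, dpas_trt,
                        pseudocount = 1) {
  stopifnot(all(c(ppas_ctl, dpas_ctl, ppas_trt, dpas_trt) >= 0))
  log2((dpas_trt + pseudocount) / (ppas_trt + pseudocount)) -
    log2((dpas_ctl + pseudocount) / (ppas_ctl + pseudocount))
}

# Beta-binomial log-likelihood for distal counts k of n trials, mean mu,
# precision phi ( = (1-rho)/rho; rho -> 0 recovers the binomial).
betabin_loglik <- function(k, n, mu, phi) {
  if (phi > 1e8) return(sum(stats::dbinom(k, n, mu, log = TRUE)))
  a <- mu * phi; b <- (1 - mu) * phi
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

# Fit shared-overdispersion beta-binomial models and return the LRT of
# per-condition vs shared distal-usage mean (1 df).
betabin_lrt <- function(k_ctl, n_ctl, k_trt, n_trt) {
  k <- c(k_ctl, k_trt); n <- c(n_ctl, n_trt)
  is_trt <- c(rep(FALSE, length(k_ctl)), rep(TRUE, length(k_trt)))
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; is_trt <- is_trt[keep]
  if (!length(k) || sum(k) == 0 || sum(k) == sum(n))
    return(list(p = 1, stat = 0, untestable = TRUE))
  sq <- function(x) 1 / (1 + exp(-x))           # logistic
  clamp <- function(m) pmin(pmax(m, 1e-9), 1 - 1e-9)
  nll_null <- function(par)
    -betabin_loglik(k, n, clamp(sq(par[1])), exp(par[2]))
  nll_alt <- function(par) {
    mu <- ifelse(is_trt, sq(par[2]), sq(par[1]))
    -betabin_loglik(k, n, clamp(mu), exp(par[3]))
  }
  p0 <- clamp(sum(k) / sum(n))
  p_ctl <- clamp(sum(k[!is_trt]) / max(sum(n[!is_trt]), 1))
  p_trt <- clamp(sum(k[is_trt]) / max(sum(n[is_trt]), 1))
  fit1 <- function(fn, par) {
    f <- try(stats::optim(par, fn, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10)),
             silent = TRUE)
    if (inherits(f, "try-error")) Inf else f$value
  }
  # phi start values span binomial-like and overdispersed regimes
  nll0 <- min(sapply(c(2, 6, 12), function(lp)
    fit1(nll_null, c(stats::qlogis(p0), lp))))
  nll1 <- min(sapply(c(2, 6, 12), function(lp)
    fit1(nll_alt, c(stats::qlogis(p_ctl), stats::qlogis(p_trt), lp))))
  stat <- max(0, 2 * (nll0 - nll1))
  list(p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       stat = stat, untestable = FALSE)
}

#' Test differential proximal/distal isoform usage
#'
#' Two modes. `fisher` (designed for unreplicated comparisons): a
#' two-sided Fisher exact test on the 2x2 table of pooled proximal and
#' distal PASS counts by condition. `betabin_lrt` (replicated designs): a
#' likelihood-ratio test of per-condition versus shared mean distal-usage
#' fraction under a beta-binomial with shared overdispersion, with the
#' p-value from a chi-square on 1 df. Counts enter untouched — no
#' pseudocount is ever applied here.
#'
#' @param ppas_ctl,dpas_ctl Integer PASS counts of the proximal and distal
#'   PAS per control replicate.
#' @param ppas_trt,dpas_trt Same for treatment replicates.
#' @param mode `"fisher"` or `"betabin_lrt"`.
#' @return A list with `p_value` and `untestable` (TRUE when a table
#'   margin is all zero, in which case `p_value` is 1).
#' @export
test_usage <- function(ppas_ctl, dpas_ctl, ppas_trt, dpas_trt,
                       mode = c("fisher", "betabin_lrt")) {
  mode <- match.arg(mode)
  stopifnot(all(c(ppas_ctl, dpas_ctl, ppas_trt, dpas_trt) >= 0),
            length(ppas_ctl) == length(dpas_ctl),
            length(ppas_trt) == length(dpas_trt),
            length(ppas_ctl) >= 1, length(ppas_trt) >= 1)
  if (mode == "fisher") {
    tab <- matrix(c(sum(ppas_ctl), sum(dpas_ctl),
                    sum(ppas_trt), sum(dpas_trt)), nrow = 2,
                  dimnames = list(c("pPAS", "dPAS"), c("ctl", "trt")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(list(p_value = 1, untestable = TRUE))
    list(p_value = stats::fisher.test(tab)$p.value, untestable = FALSE)
  } else {
    r <- betabin_lrt(dpas_ctl, ppas_ctl + dpas_ctl,
                     dpas_trt, ppas_trt + dpas_trt)
    list(p_value = r$p, untestable = r$untestable)
  }
}

#' Call lengthened / shortened genes from RED and p-values
#'
#' A gene is called lengthened iff `red > red_threshold` and
#' `p <= alpha`, shortened iff `red < -red_threshold` and `p <= alpha`,
#' otherwise unchanged. The RED comparison is strict: a gene at exactly
#' the threshold is not called. With `correction = "BH"` the
#' Benjamini-Hochberg adjusted p-value replaces the raw one in the rule.
#'
#' @param red Numeric vector of RED values.
#' @param p_value Numeric vector of p-values.
#' @param params [apa_params()] object.
#' @param correction `"none"` (default, raw p as printed rules go) or
#'   `"BH"`.
#' @param testable Logical vector; untestable genes stay untestable.
#' @return A data.frame with `red`, `p_value`, `q_value`, `call`.
#' @export
call_apa <- function(red, p_value, params = apa_params(),
                     correction = c("none", "BH"),
                     testable = rep(TRUE, length(red))) {
  correction <- match.arg(correction)
  q_value <- stats::p.adjust(p_value, method = "BH")
  p_gate <- if (correction == "BH") q_value else p_value
  call <- rep("unchanged", length(red))
  call[red > params$red_threshold & p_gate <= params$alpha] <- "lengthened"
  call[red < -params$red_threshold & p_gate <= params$alpha] <- "shortened"
  call[!testable | is.na(red) | is.na(p_value)] <- "untestable"
  data.frame(red = red, p_value = p_value, q_value = q_value,
             call = factor(call, levels = c("lengthened", "shortened",
                                            "unchanged", "untestable")),
             stringsAsFactors = FALSE)
}

#' Per-gene APA inference between two conditions
#'
#' Full gene-level analysis: select each gene's two most-used 3'UTR PASs,
#' compute RED from replicate-mean RPMs (treatment vs control), test the
#' usage shift, and call lengthened / shortened genes.
#'
#' @param table A `pas_count_table` (RPM is filled if absent).
#' @param gene_sets Output of [build_gene_sets()].
#' @param design data.frame with columns `sample`, `condition`.
#' @param control,treatment Condition labels in `design`.
#' @param params [apa_params()] object.
#' @param mode Usage test mode, see [test_usage()]. Default picks
#'   `betabin_lrt` when both conditions have replicates, else `fisher`.
#' @param correction Multiple-testing handling, see [call_apa()].
#' @return An `apa_result` data.frame: `gene_id`, `ppas_id`, `dpas_id`,
#'   `rpm_ppas_ctl`, `rpm_dpas_ctl`, `rpm_ppas_trt`, `rpm_dpas_trt`,
#'   `red`, `p_value`, `q_value`, `call`.
#' @export
apa_test <- function(table, gene_sets, design,
                     control = "control", treatment = "treatment",
                     params = apa_params(), mode = NULL,
                     correction = c("none", "BH")) {
  stopifnot(inherits(table, "pas_count_table"),
            all(c("sample", "condition") %in% names(design)))
  correction <- match.arg(correction)
  if (is.null(table$rpm)) table <- to_rpm(table)
  s_ctl <- design$sample[design$condition == control]
  s_trt <- design$sample[design$condition == treatment]
  if (!length(s_ctl) || !length(s_trt))
    stop("design must contain samples for both '", control,
         "' and '", treatment, "'")
  missing <- setdiff(c(s_ctl, s_trt), table$samples)
  if (length(missing))
    stop("design sample(s) absent from the count table: ",
         paste(missing, collapse = ", "))
  if (is.null(mode))
    mode <- if (length(s_ctl) > 1 && length(s_trt) > 1) "betabin_lrt"
            else "fisher"
  top2 <- select_top2(gene_sets, table, samples = c(s_ctl, s_trt))
  n <- nrow(top2)
  res <- data.frame(top2[, c("gene_id", "ppas_id", "dpas_id")],
                    rpm_ppas_ctl = NA_real_, rpm_dpas_ctl = NA_real_,
                    rpm_ppas_trt = NA_real_, rpm_dpas_trt = NA_real_,
                    red = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!top2$testable[i]) next
    pp <- top2$ppas_id[i]; dp <- top2$dpas_id[i]
    res$rpm_ppas_ctl[i] <- mean(table$rpm[pp, s_ctl])
    res$rpm_dpas_ctl[i] <- mean(table$rpm[dp, s_ctl])
    res$rpm_ppas_trt[i] <- mean(table$rpm[pp, s_trt])
    res$rpm_dpas_trt[i] <- mean(table$rpm[dp, s_trt])
    res$red[i] <- compute_red(res$rpm_ppas_ctl[i], res$rpm_dpas_ctl[i],
                              res$rpm_ppas_trt[i], res$rpm_dpas_trt[i],
                              pseudocount = params$pseudocount)
    tst <- test_usage(table$counts[pp, s_ctl], table$counts[dp, s_ctl],
                      table$counts[pp, s_trt], table$counts[dp, s_trt],
                      mode = mode)
    res$p_value[i] <- if (tst$untestable) NA_real_ else tst$p_value
  }
  calls <- call_apa(res$red, res$p_value, params, correction,
                    testable = top2$testable & !is.na(res$p_value))
  res$q_value <- calls$q_value
  res$call <- calls$call
  attr(res, "mode") <- mode
  attr(res, "summary") <- table(res$call)
  class(res) <- c("apa_result", "data.frame")
  res
}

#' @export
print.apa_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("APA results: %d genes (%s test): %d lengthened, %d shortened, %d unchanged, %d untestable\n",
              nrow(x), attr(x, "mode"), s[["lengthened"]], s[["shortened"]],
              s[["unchanged"]], s[["untestable"]]))
  NextMethod()
}

#' Write per-gene APA results as TSV
#' @param res An `apa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_apa_results <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
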