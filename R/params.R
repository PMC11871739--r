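#' Analysis parameters for PASS counting and APA calling
#'
#' Bundles the tunable constants of the pipeline. Defaults follow the
#' QuantSeq 3' end analysis convention: reads are kept only if they align
#' inside a window running 100 nt upstream to 25 nt downstream of an
#' annotated poly(A) site (PAS), the last aligned position must then match
#' the PAS within +/- 24 nt, and a gene is called lengthened or shortened
#' when |RED| exceeds log2(1.2) at p <= 0.05.
#'
#' @param upstream_len Window extent on the transcription-5' side of the
#'   PAS, in nt (default 100).
#' @param downstream_len Window extent on the transcription-3' side, in nt
#'   (default 25).
#' @param lap_tolerance Maximum |LAP - PAS| distance, in nt, for a read to
#'   count as PAS-supporting; the bound is inclusive (default 24).
#' @param red_threshold Minimum |RED|, in log2 units, for a lengthened or
#'   shortened call; the comparison is strict (default `log2(1.2)`).
#' @param alpha Significance level for the usage test (default 0.05).
#' @param pseudocount Pseudocount in RPM units added to all four mean RPMs
#'   when computing RED, so RED stays finite at zero cells (default 1).
#'   Never applied to the count-based test.
#' @param min_mapq Minimum mapping quality for LAP extraction (default 10).
#' @return An object of class `apa_params` (a named list).
#' @examples
#' p <- apa_params()
#' p$lap_tolerance
#' @export
apa_params <- function(upstream_len = 100, downstream_len = 25,
                       lap_tolerance = 24, red_threshold = log2(1.2),
                       alpha = 0.05, pseudocount = 1, min_mapq = 10) {
  stopifnot(upstream_len >= 0, downstream_len >= 0, lap_tolerance >= 0,
            red_threshold > 0, alpha > 0, alpha < 1, pseudocount >= 0,
            min_mapq >= 0)
  structure(list(upstream_len = as.integer(upstream_len),
                 downstream_len = as.integer(downstream_len),
                 lap_tolerance = as.integer(lap_tolerance),
                 red_threshold = red_threshold,
                 alpha = alpha,
                 pseudocount = pseudocount,
                 min_mapq = as.integer(min_mapq)),
            class = "apa_params")
}

#' @export
print.apa_params <- function(x, ...) {
  cat("APA analysis parameters\n")
  cat(sprintf("  PAS window       : -%d / +%d nt (transcription direction)\n",
              x$upstream_len, x$downstream_len))
  cat(sprintf("  LAP tolerance    : +/- %d nt (inclusive)\n", x$lap_tolerance))
  cat(sprintf("  RED threshold    : %.4f log2 units (strict)\n", x$red_threshold))
  cat(sprintf("  alpha            : %g\n", x$alpha))
  cat(sprintf("  RED pseudocount  : %g RPM\n", x$pseudocount))
  cat(sprintf("  min MAPQ         : %d\n", x$min_mapq))
  invisible(x)
}
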