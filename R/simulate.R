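#' Configuration for the 3' end sequencing simulator
#'
#' Describes a two-condition QuantSeq-style experiment over a generated
#' random genome: multi-PAS last-exon gene models, condition-dependent
#' proximal/distal usage with a known RED, positional jitter of cleavage
#' sites, off-PAS background reads, unequal library sizes and
#' beta-binomial replicate overdispersion. A fixed seed makes the whole
#' output bundle byte-identical across runs.
#'
#' @param n_genes Number of simulated genes (default 200, laid out on one
#'   ~2 Mb chromosome).
#' @param n_pas PASs per gene, transcription-ordered (default 2).
#' @param replicates Replicates per condition (default 3).
#' @param reads_per_gene Expected PASS reads per gene per replicate
#'   before library-size scaling (default 500).
#' @param true_red Target RED per gene in log2 units, recycled over genes
#'   (default 0 = null experiment).
#' @param distal_ctl Control-condition distal usage fraction per gene;
#'   `NULL` draws each uniformly from \[0.3, 0.7\].
#' @param jitter Cleavage-site scatter model: `list(model = "none")`,
#'   `list(model = "uniform", width = j)` (integer uniform on \[-j, j\])
#'   or `list(model = "normal", sd = s)` (rounded normal). Default
#'   rounded normal with sd 10 nt.
#' @param background_frac Expected off-PAS background reads as a fraction
#'   of signal reads (default 0.05).
#' @param lib_mult Library-size multipliers recycled across samples
#'   (default `c(1, 0.8, 1.25)`).
#' @param rho Beta-binomial overdispersion of replicate usage fractions,
#'   0 <= rho < 1; 0 recovers plain multinomial sampling (default 0.02).
#' @param pas_spacing Range (nt) for uniform PAS spacing within a gene
#'   (default 200–400; must stay >= 60 so jittered reads resolve).
#' @param read_len Aligned (post-trim) read length, nt (default 80).
#' @param polyt_len Leading poly(T) length on raw reads (default 18).
#' @param pre_trimmed Emit FASTQ without the poly(T) prefix (default
#'   FALSE).
#' @param seed RNG seed fixing the full bundle.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_pas = 2, replicates = 3,
                       reads_per_gene = 500, true_red = 0,
                       distal_ctl = NULL,
                       jitter = list(model = "normal", sd = 10),
                       background_frac = 0.05,
                       lib_mult = c(1, 0.8, 1.25), rho = 0.02,
                       pas_spacing = c(200, 400), read_len = 80,
                       polyt_len = 18, pre_trimmed = FALSE, seed = 1) {
  stopifnot(n_genes >= 1, n_pas >= 2, replicates >= 1,
            reads_per_gene > 0, rho >= 0, rho < 1,
            background_frac >= 0, all(lib_mult > 0),
            length(pas_spacing) == 2, pas_spacing[1] >= 60,
            pas_spacing[2] >= pas_spacing[1],
            read_len >= 20, polyt_len >= 4)
  jitter$model <- match.arg(jitter$model, c("none", "uniform", "normal"))
  if (jitter$model == "uniform" && is.null(jitter$width))
    stop("uniform jitter needs a 'width'")
  if (jitter$model == "normal" && is.null(jitter$sd))
    stop("normal jitter needs an 'sd'")
  structure(as.list(environment()), class = "sim_config")
}

# Treatment usage vector from the control vector and a target RED:
# the odds between the two main (first and last, i.e. most-used) PASs are
# multiplied by 2^red; minor middle PASs keep their usage.
usage_from_red <- function(usage_ctl, red) {
  if (red == 0) return(usage_ctl)
  n <- length(usage_ctl)
  i_p <- 1L; i_d <- n
  mass <- usage_ctl[i_p] + usage_ctl[i_d]
  odds <- (usage_ctl[i_d] / usage_ctl[i_p]) * 2^red
  usage_trt <- usage_ctl
  usage_trt[i_d] <- mass * odds / (1 + odds)
  usage_trt[i_p] <- mass / (1 + odds)
  usage_trt
}

#' Ground-truth RED of a simulated gene
#'
#' Applies the RED formula with zero pseudocount to the two PASs with the
#' highest mean usage across conditions (proximal = the transcription-5'
#' one of the pair).
#'
#' @param usage_ctl,usage_trt Usage probability vectors in transcription
#'   order (sum 1).
#' @return The true RED in log2 units; `NA` with a warning when a
#'   required usage cell is zero.
#' @examples
#' truth_red(c(2, 1) / 3, c(1, 2) / 3)  # 2
#' @export
truth_red <- function(usage_ctl, usage_trt) {
  stopifnot(length(usage_ctl) == length(usage_trt),
            length(usage_ctl) >= 2,
            abs(sum(usage_ctl) - 1) < 1e-9, abs(sum(usage_trt) - 1) < 1e-9)
  mean_u <- (usage_ctl + usage_trt) / 2
  top2 <- sort(order(-mean_u, seq_along(mean_u))[1:2])
  p <- top2[1]; d <- top2[2]
  if (any(c(usage_ctl[c(p, d)], usage_trt[c(p, d)]) == 0)) {
    warning("zero usage in a required cell; true RED undefined")
    return(NA_real_)
  }
  log2(usage_trt[d] / usage_trt[p]) - log2(usage_ctl[d] / usage_ctl[p])
}

# Gene layout, usage vectors and per-gene truth shared by the read-level
# and count-level simulators. Consumes RNG.
sim_gene_table <- function(config) {
  ng <- config$n_genes; np <- config$n_pas
  red <- rep_len(config$true_red, ng)
  d_ctl <- if (is.null(config$distal_ctl))
    stats::runif(ng, 0.3, 0.7) else rep_len(config$distal_ctl, ng)
  strand <- rep_len(c("+", "-"), ng)
  anchor <- 1000 + (seq_len(ng) - 1) * 10000
  spac <- matrix(round(stats::runif(ng * (np - 1), config$pas_spacing[1],
                                    config$pas_spacing[2])),
                 nrow = ng)
  minor <- if (np > 2) 0.05 else 0   # usage of each middle PAS
  main_mass <- 1 - minor * (np - 2)
  genes <- vector("list", ng)
  for (i in seq_len(ng)) {
    offs <- cumsum(c(0, spac[i, ]))
    pos <- as.integer(if (strand[i] == "+") anchor[i] + 2000 + offs
                      else anchor[i] + 2000 + max(offs) - offs)
    u_ctl <- c(main_mass * (1 - d_ctl[i]), rep(minor, np - 2),
               main_mass * d_ctl[i])
    u_trt <- usage_from_red(u_ctl, red[i])
    genes[[i]] <- list(gene_id = sprintf("g%03d", i), strand = strand[i],
                       position = pos,   # transcription order
                       usage_ctl = u_ctl, usage_trt = u_trt,
                       true_red = truth_red(u_ctl, u_trt))
  }
  genes
}

sim_pas_frame <- function(genes) {
  do.call(rbind, lapply(genes, function(g)
    data.frame(pas_id = sprintf("%s_pas%d", g$gene_id,
                                seq_along(g$position)),
               chrom = "chrS", position = g$position, strand = g$strand,
               gene_id = g$gene_id, region = "3UTR_last_exon",
               stringsAsFactors = FALSE)))
}

sim_design <- function(config) {
  samples <- c(sprintf("ctl_%d", seq_len(config$replicates)),
               sprintf("trt_%d", seq_len(config$replicates)))
  data.frame(sample = samples,
             condition = rep(c("control", "treatment"),
                             each = config$replicates),
             lib_mult = rep_len(config$lib_mult, length(samples)),
             stringsAsFactors = FALSE)
}

# Replicate-level PAS usage: Dirichlet around the gene's usage vector with
# beta-binomial-style overdispersion rho (rho = 0 -> the vector itself).
sim_replicate_usage <- function(usage, rho) {
  if (rho == 0) return(usage)
  conc <- usage * (1 - rho) / rho
  x <- stats::rgamma(length(usage), shape = conc)
  if (sum(x) == 0) return(usage)
  x / sum(x)
}

sim_jitter <- function(n, jitter) {
  switch(jitter$model,
         none = integer(n),
         uniform = sample(-jitter$width:jitter$width, n, replace = TRUE),
         normal = as.integer(round(stats::rnorm(n, 0, jitter$sd))))
}

#' Simulate PASS count matrices directly
#'
#' Count-level companion to [simulate_experiment()]: skips read and
#' alignment generation and draws per-replicate PAS counts straight from
#' the generative model (Poisson totals, Dirichlet-multinomial usage).
#' Suited to power and calibration studies at thousands of genes.
#'
#' @param config A [sim_config()].
#' @return A list: `table` (a `pas_count_table`), `pas`, `gene_sets`,
#'   `design`, `truth` (per-gene true RED and usage).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sim_gene_table(config)
  design <- sim_design(config)
  pas <- sim_pas_frame(genes)
  counts <- matrix(0L, nrow = nrow(pas), ncol = nrow(design),
                   dimnames = list(pas$pas_id, design$sample))
  for (s in seq_len(nrow(design))) {
    trt <- design$condition[s] == "treatment"
    for (g in genes) {
      u <- if (trt) g$usage_trt else g$usage_ctl
      n <- stats::rpois(1, config$reads_per_gene * design$lib_mult[s])
      w <- sim_replicate_usage(u, config$rho)
      ids <- sprintf("%s_pas%d", g$gene_id, seq_along(u))
      counts[ids, s] <- as.integer(stats::rmultinom(1, n, w))
    }
  }
  truth <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, strand = g$strand,
               true_red = g$true_red,
               distal_ctl = g$usage_ctl[length(g$usage_ctl)],
               distal_trt = g$usage_trt[length(g$usage_trt)],
               stringsAsFactors = FALSE)))
  list(table = pas_count_table(counts), pas = pas,
       gene_sets = build_gene_sets(pas), design = design, truth = truth)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Simulate a complete 3' end sequencing experiment
#'
#' Generates a random genome, lays out multi-PAS genes on both strands,
#' draws reads whose cleavage positions scatter around the true PASs, and
#' writes the full input bundle the pipeline consumes: PAS annotation
#' (native TSV), gene model TSV, per-sample FASTQ (QuantSeq FWD read-2
#' orientation, leading poly(T) unless `pre_trimmed`), per-sample SAM
#' encoding the true alignments, a design table and a ground-truth table.
#' Background reads are placed far from every PAS window. With the same
#' config (including seed) the bundle is byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `paths` (named file paths), `pas`,
#'   `gene_sets`, `design`, `truth`, `read_truth` (per-read true PAS and
#'   cleavage coordinate), `true_counts` (signal reads drawn per PAS and
#'   sample).
#' @export
simulate_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  genes <- sim_gene_table(config)
  pas <- sim_pas_frame(genes)
  design <- sim_design(config)
  chrom_len <- 1000 + config$n_genes * 10000 + 1000
  genome <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                  collapse = "")
  flen <- config$read_len
  polyt <- strrep("T", config$polyt_len)
  anchors <- 1000 + (seq_len(config$n_genes) - 1) * 10000
  true_counts <- matrix(0L, nrow = nrow(pas), ncol = nrow(design),
                        dimnames = list(pas$pas_id, design$sample))
  read_truth <- vector("list", nrow(design))
  paths <- list(
    pas = file.path(out_dir, "pas.tsv"),
    gene_model = file.path(out_dir, "gene_model.tsv"),
    design = file.path(out_dir, "design.tsv"),
    truth = file.path(out_dir, "truth_genes.tsv"),
    fastq = stats::setNames(file.path(out_dir, paste0(design$sample, ".fastq")),
                            design$sample),
    sam = stats::setNames(file.path(out_dir, paste0(design$sample, ".sam")),
                          design$sample))
  for (s in seq_len(nrow(design))) {
    smp <- design$sample[s]
    trt <- design$condition[s] == "treatment"
    pas_idx <- integer(0)
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      u <- if (trt) g$usage_trt else g$usage_ctl
      n <- stats::rpois(1, config$reads_per_gene * design$lib_mult[s])
      w <- sim_replicate_usage(u, config$rho)
      k <- as.integer(stats::rmultinom(1, n, w))
      ids <- match(sprintf("%s_pas%d", g$gene_id, seq_along(u)), pas$pas_id)
      true_counts[ids, s] <- k
      pas_idx <- c(pas_idx, rep(ids, k))
    }
    n_sig <- length(pas_idx)
    n_bg <- stats::rpois(1, config$background_frac * n_sig)
    # background cleavage sites sit >= ~2.5 kb from every PAS window
    bg_gene <- sample(seq_len(config$n_genes), n_bg, replace = TRUE)
    bg_pos <- anchors[bg_gene] + 6000 +
      sample.int(3000, n_bg, replace = TRUE)
    bg_strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    cleav <- c(pas$position[pas_idx] + sim_jitter(n_sig, config$jitter),
               bg_pos)
    strand <- c(pas$strand[pas_idx], bg_strand)
    src <- c(pas$pas_id[pas_idx], rep("background", n_bg))
    ord <- sample.int(length(cleav))          # shuffle read order
    cleav <- cleav[ord]; strand <- strand[ord]; src <- src[ord]
    rid <- sprintf("%s:%06d:%s:%d", smp, seq_along(cleav), src, cleav)
    plus <- strand == "+"
    frag_start <- ifelse(plus, cleav - flen + 1L, cleav)
    frag <- substring(genome, frag_start, frag_start + flen - 1L)
    # gene + -> read is revcomp of the fragment, aligns on -; gene - ->
    # read equals the fragment, aligns on +
    read_seq <- frag
    read_seq[plus] <- revcomp(frag[plus])
    fq_seq <- if (config$pre_trimmed) read_seq else paste0(polyt, read_seq)
    fq <- rbind(paste0("@", rid), fq_seq, "+",
                strrep("I", nchar(fq_seq)))
    writeLines(as.vector(fq), paths$fastq[[smp]])
    flag <- ifelse(plus, 16L, 0L)
    sam <- c(
      "@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:chrS\tLN:%d", chrom_len),
      sprintf("%s\t%d\tchrS\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
              rid, flag, frag_start, flen, frag, strrep("I", flen)))
    writeLines(sam, paths$sam[[smp]])
    read_truth[[s]] <- data.frame(sample = smp, read_id = rid,
                                  true_pas = src, cleavage = cleav,
                                  strand = strand, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, strand = g$strand,
               ppas_id = sprintf("%s_pas1", g$gene_id),
               dpas_id = sprintf("%s_pas%d", g$gene_id, length(g$position)),
               distal_ctl = g$usage_ctl[length(g$usage_ctl)],
               distal_trt = g$usage_trt[length(g$usage_trt)],
               true_red = g$true_red, stringsAsFactors = FALSE)))
  write_pas_table(pas, paths$pas)
  utils::write.table(unique(pas[, c("gene_id", "strand")]),
                     paths$gene_model, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(design, paths$design, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, pas = pas, gene_sets = build_gene_sets(pas),
                 design = design, truth = truth,
                 read_truth = do.call(rbind, read_truth),
                 true_counts = true_counts))
}

#' Run the PASS-counting pipeline on a simulated (or real) bundle
#'
#' Convenience driver: extracts LAPs from each sample's SAM/BAM, assigns
#' them to PAS windows, counts PASS reads and fills RPM.
#'
#' @param sam_paths Named character vector of SAM/BAM paths (names =
#'   samples).
#' @param pas PAS annotation data.frame.
#' @param params [apa_params()] object.
#' @return A `pas_count_table` with RPM filled.
#' @export
run_pass_pipeline <- function(sam_paths, pas, params = apa_params()) {
  windows <- make_windows(pas, params)
  laps <- lapply(sam_paths, extract_laps, min_mapq = params$min_mapq)
  to_rpm(count_pass(laps, windows, pas, params))
}
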