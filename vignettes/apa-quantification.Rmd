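---
title: "Quantifying alternative polyadenylation from 3' end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternative polyadenylation from 3' end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most human genes carry more than one poly(A) site (PAS) in the 3'UTR of
their last exon. Shifting cleavage from the distal to the proximal site
shortens the 3'UTR, removing regulatory elements and typically changing
mRNA stability and protein output; regulators of the cleavage and
polyadenylation machinery (CFIm25 being the canonical example) move
hundreds of genes between these isoforms. 3' end sequencing protocols
such as Lexogen's QuantSeq FWD read across the poly(A) junction, so the
position where a read's alignment ends is a direct observation of which
PAS a transcript used. `quantapa` turns such alignments into per-PAS
usage quantifications and per-gene lengthening/shortening calls.

## From reads to PASS counts

The reverse read (read 2) of a QuantSeq FWD library begins at the
poly(A) junction: its raw sequence is a poly(T) stretch (the complement
of the tail) followed by the reverse complement of the transcript's 3'
end. `trim_read()` removes the maximal contiguous leading T-run (when at
least `min_t_run = 4` long) and any 3' adapter match of >= 8 nt with
<= 10% mismatches, flagging reads shorter than 18 nt afterwards.

After alignment (the package consumes SAM/BAM; it does not align), the
**last aligned position (LAP)** of each primary alignment is the
reference coordinate of the aligned base nearest the cleavage site.
Because read 2 runs 3'-to-5' along the transcript, that base is the
read's 5' end after trimming: the largest reference coordinate consumed
by the CIGAR when the alignment strand is `-` (gene on `+`), and the
smallest when the alignment strand is `+`. Soft clips consume no
reference and never move the LAP; deletions and skips do. The alignment
orientation therefore implies the transcript strand (the opposite of the
alignment strand), and all downstream matching is strand-concordant.

A read becomes a **PAS-supporting (PASS) read** in two stages, applied
in sequence:

1. *Window filter.* Its LAP must fall inside some annotated PAS window
   spanning 100 nt upstream to 25 nt downstream of the cleavage site in
   transcription direction (126 positions). Windows running off the
   chromosome start are clipped, not discarded.
2. *Positional match.* Among the PASs whose windows contain the LAP, at
   least one must lie within +/- 24 nt of it (inclusive at 24 — a read
   at distance exactly 24 is matched, at 25 it is not). The nearest PAS
   wins; an exact tie goes to the more proximal (transcription-5') PAS,
   a deterministic rule chosen so that re-running the assignment always
   reproduces the same table. A read inside a window but farther than
   24 nt from every PAS is *not* a PASS read.

PASS counts per PAS and sample are normalized to **reads per million
(RPM)** against each sample's total PASS count, so every non-empty RPM
column sums to exactly 1e6. Per-PAS RPM values export as strand-split
bedGraph for genome-browser inspection.

## The RED statistic and significance

For each gene the two 3'UTR PASs with the highest mean RPM across the
samples of the comparison are selected (tie toward the proximal site);
the one nearer the stop codon is the proximal PAS (pPAS), the other the
distal PAS (dPAS). The **relative expression difference** between a
treatment and a control condition is

$$\mathrm{RED} \;=\; \log_2\frac{d_{trt}+\epsilon}{p_{trt}+\epsilon}
\;-\; \log_2\frac{d_{ctl}+\epsilon}{p_{ctl}+\epsilon},$$

with $p$, $d$ the replicate-mean RPM of the pPAS and dPAS and
$\epsilon = 1$ RPM a pseudocount that keeps RED finite when a cell is
empty. The pseudocount enters RED only — the count-based test below
always sees raw integers. Positive RED means the distal site gained
relative usage under treatment (3'UTR lengthening); swapping the
condition labels negates RED exactly.

Significance comes from one of two implemented tests on the pPAS/dPAS
counts:

* **`fisher`** — a two-sided Fisher exact test on the 2x2 table of
  pooled proximal/distal counts by condition. Appropriate for
  unreplicated designs; with replicates it treats biological variation
  as sampling noise and is anti-conservative when replicates truly
  vary.
* **`betabin_lrt`** — a likelihood-ratio test of per-condition versus
  shared mean distal-usage fraction under a beta-binomial with a single
  shared overdispersion, p-value from $\chi^2_1$. The overdispersion
  parameter is profiled out by direct likelihood maximisation
  (Nelder-Mead over logit-mean and log-precision, multiple starts
  spanning binomial-like and overdispersed regimes). On binomial data
  with ample replication it converges to the Fisher/chi-square answer;
  with 2–3 replicates the dispersion estimate is noisy and the test
  retains some anti-conservatism — an inherent small-sample property,
  visible in the workflow example below.

A gene is called **lengthened** when $\mathrm{RED} > \log_2 1.2$ and
$p \le 0.05$, **shortened** when $\mathrm{RED} < -\log_2 1.2$ and
$p \le 0.05$, otherwise unchanged. The RED comparison is strict: a gene
at exactly $\log_2 1.2$ is never called. Raw p-values gate the calls by
default, matching how such thresholds are usually printed;
Benjamini-Hochberg adjustment is available (`correction = "BH"`) and
substitutes the q-value in the same rule.

```{r, eval = FALSE}
library(quantapa)
pas <- load_pas_table("pas.tsv")
tab <- run_pass_pipeline(c(ctl_1 = "ctl_1.bam", trt_1 = "trt_1.bam"), pas)
res <- apa_test(tab, build_gene_sets(pas),
                design = data.frame(sample = c("ctl_1", "trt_1"),
                                    condition = c("control", "treatment")))
```

## qPCR validation arithmetic

The orthogonal wet-lab check uses two primer pairs per gene: one
amplifying all isoforms (*total*) and one just upstream of the distal
PAS (*long*, long isoforms only), each normalized to a reference gene
by the ddCt method under perfect doubling per cycle:
$\Delta C_t = C_t^{target} - C_t^{ref}$ per condition,
$\Delta\Delta C_t$ their treatment-minus-control difference, fold change
$2^{-\Delta\Delta C_t}$. Replicate Cts are averaged before differencing
(the delta-method SE is reported but not tested on). The **long/total
ratio change** — fold(long) / fold(total) — is the qPCR analogue of the
RED sign: below 1 means relative shortening. Note the two scales differ:
RED is a log-odds difference while the long/total ratio is a ratio of
distal *fractions*, so a true RED of 1.5 maps to a smaller log2 ratio
change; only the sign is directly comparable, and `idealized_ct()` plus
the simulator verify that sign agreement holds whenever
$|\mathrm{RED}| \ge 0.5$.

## What the simulator emulates

`simulate_experiment()` builds a complete ground-truth experiment with
no external data: a random-base genome (one chromosome, ~10 kb per
gene), two-condition designs with per-gene true RED, and per-sample
FASTQ (read-2 orientation, leading poly(T)) plus SAM encoding the true
alignments, so trimming, LAP extraction and assignment are all
exercised end to end. Its statistical structure is the one the analysis
assumes:

* per-gene, per-replicate totals are Poisson with library-size
  multipliers (default `1, 0.8, 1.25` recycled — unequal libraries are
  the normal case for 3' end data);
* replicate usage fractions are Dirichlet-multinomial around the
  condition's usage vector with overdispersion `rho` (`rho = 0` recovers
  multinomial; the default 0.02 gives distal-fraction scatter of a few
  percentage points, a typical magnitude for cell-line biological
  replicates);
* cleavage positions scatter around the annotated PAS under a chosen
  jitter model (default rounded normal, sd 10 nt, so most but not all
  reads fall within the +/- 24 nt match — heterogeneous cleavage is a
  known feature of 3' end data);
* a configurable fraction of background reads (default 5%) is placed
  kilobases away from every window, emulating internal priming and
  stray alignments only in the sense that they must be rejected.

The generator does **not** model base-call errors, true internal-priming
A-rich sites, fragment-length effects, or annotation errors (every
simulated PAS is annotated, every annotated PAS is real). Passing tests
on simulated data therefore demonstrates correctness of the
quantification and inference rules under the stated noise model, not
robustness to annotation mismatch on real tissue data.

`simulate_counts()` draws per-PAS count matrices from the same gene
model without rendering reads, which is what the calibration and
power checks use at thousands of genes. Both generators are
byte-deterministic given the config seed.

## Numerical and design choices

* Internal coordinates are 0-based half-open; 1-based conventions (SAM,
  PAS positions) convert at the boundary.
* The -100/+25 window is strand-aware (upstream = transcription-5'),
  matching the pile-up of 3' end reads upstream of the cleavage site.
* The +/- 24 nt match is inclusive; the |RED| threshold is strict; the
  p-value gate is `<=`.
* Duplicate annotation rows collapse with a warning; windows clip at
  coordinate 1 with a warning; zero-PASS samples are kept (RPM 0,
  flagged) rather than dropped.
* `min_mapq = 10` by default — enough to suppress multi-mappers without
  biting into signal; configurable, and MAPQ-less records pass.
* Degenerate test inputs (an all-zero margin) return p = 1 with an
  untestable flag instead of erroring, so genome-wide loops never stop
  on an empty gene.

## Problem sizes and verification

The test suite validates the assignment rule against brute-force
enumeration on hundreds of random small instances, the Fisher mode
against exhaustive hypergeometric enumeration, null calibration on
2,000 simulated null genes (observed positive rate ~4% at the nominal
5%), RED recovery on 200 genes per level for true RED in
{-2, -1, 0, 1, 2} at 2,000 reads per gene and condition (mean absolute
error ~0.08 log2 units, >= 95% correct calls at |RED| >= 1), and jitter
rejection under integer-uniform +/- 30 nt scatter, where the inclusive
+/- 24 rule leaves exactly 12/61 of reads unassigned. The workflow
scripts under `analysis/` run a 50-gene, 3-replicate experiment with 2
lengthened and 8 shortened genes planted; these sizes keep every check
under a few minutes on one core while leaving the Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* The usage test is a two-isoform test on the top-2 PASs; genes whose
  regulation moves a third site are summarized only through the top
  pair. Intronic APA is out of scope.
* The beta-binomial LRT needs >= 3 replicates per condition before its
  dispersion estimate stabilizes; with fewer, expect some excess
  false-positive calls on genuinely variable genes (the Fisher mode has
  the same issue for a different reason — it ignores the variability
  entirely).
* qPCR arithmetic assumes perfect amplification efficiency; no
  efficiency correction is implemented.
* bigWig export is delegated to external tools; the package writes
  bedGraph only.
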