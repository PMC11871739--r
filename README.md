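# quantapa

Alternative polyadenylation (APA) analysis from QuantSeq-style 3′ end
sequencing, for transcriptomics researchers who want poly(A)-site (PAS)
level quantification and gene-level 3′UTR lengthening/shortening calls
from aligned reads — plus a ground-truth simulator so the whole
pipeline can be exercised and validated without any external data.

## What it computes

Most genes have several PASs in the last exon's 3′UTR. 3′ end reads end
at the poly(A) junction, so each read's **last aligned position (LAP)**
observes the PAS its transcript used. The pipeline:

1. **PASS calling** — a read is a PAS-supporting (PASS) read when its
   LAP falls inside a strand-aware window −100/+25 nt around an
   annotated PAS *and* within ±24 nt (inclusive) of the PAS position;
   the nearest PAS wins, ties break proximal.
2. **Quantification** — PASS counts per PAS per sample, normalized to
   reads per million (RPM) of each sample's PASS total.
3. **Differential usage** — for each gene's two most-used 3′UTR PASs
   (proximal pPAS, distal dPAS), the **relative expression difference**

   RED = log₂[(dPAS/pPAS)ₜᵣₜ] − log₂[(dPAS/pPAS)ₖₜₗ]

   with p-values from a two-sided Fisher exact test (no replicates) or
   a beta-binomial likelihood-ratio test (replicated designs). Genes
   are called **lengthened** when RED > log₂ 1.2 and p ≤ 0.05,
   **shortened** when RED < −log₂ 1.2 and p ≤ 0.05.
4. **qPCR validation arithmetic** — ΔΔCt fold changes and the
   long/total isoform-ratio change, the wet-lab readout whose sign
   matches RED.

See `vignettes/apa-quantification.Rmd` for the model, assumptions and
design choices.

## Worked example

The numbered scripts under `analysis/` run a complete desk-scale study:
simulate a 50-gene, 3-replicate overexpression experiment with 2
lengthened and 8 shortened genes planted (true RED ±1.5), count PASS
reads from the simulated SAM, call APA, and validate with idealized
qPCR.

```sh
Rscript analysis/01_simulate.R        # writes scratch/sim/
Rscript analysis/02_count_pass.R      # counts + RPM + bedGraph tracks
Rscript analysis/03_apa_test.R        # RED + beta-binomial LRT + calls
Rscript analysis/04_qpcr_validation.R # ddCt long/total check
```

Step 2 prints the per-sample QC — about 6% of reads are unassigned,
matching the simulated 5% background plus the tail of the ±10 nt
cleavage jitter that escapes the ±24 nt match:

```
  sample total_reads pass_reads unassigned_frac
1  ctl_1       78933      74141      0.06070972
2  ctl_2       62785      58953      0.06103369
...
```

Step 3 recovers the planted signal (true RED −1.5 genes called
shortened with RED estimates near −1.4, both lengthened genes found)
and reports honest imperfection — at 3 replicates with overdispersion
0.02 a few variable null genes are also called:

```
   gene_id   ppas_id   dpas_id        red      p_value       call
41    g041 g041_pas1 g041_pas2  1.6627259 8.768442e-04 lengthened
42    g042 g042_pas1 g042_pas2  1.7702781 1.919064e-03 lengthened
45    g045 g045_pas1 g045_pas2 -1.4276036 3.647080e-03  shortened
...
Summary: 3 lengthened, 10 shortened called (truth: 2 / 8)
Agreement with truth: 90.0%; RED RMSE on shifted genes: 0.369
```

Step 4 confirms that the qPCR long/total ratio change agrees in sign
with the true RED for all 10 shifted genes.

In code, the same analysis is three calls:

```r
library(quantapa)
pas <- load_pas_table("scratch/sim/pas.tsv")
tab <- run_pass_pipeline(sam_paths, pas)      # named vector of SAM/BAM
res <- apa_test(tab, build_gene_sets(pas), design)
```

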