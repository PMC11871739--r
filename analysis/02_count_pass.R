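#!/usr/bin/env Rscript
# Step 2 — PASS-read counting and RPM normalization.
#
# Consumes the simulated bundle from step 1: extracts each read's last
# aligned position from the per-sample SAM files, keeps reads inside the
# -100/+25 nt PAS windows whose LAP matches an annotated PAS within
# +/-24 nt, counts PASS reads per PAS and sample, and normalizes to
# reads per million. Also exports per-sample bedGraph tracks for genome
# browser inspection.

suppressMessages(library(quantapa))

sim_dir <- "scratch/sim"
pas <- load_pas_table(file.path(sim_dir, "pas.tsv"))
design <- read.delim(file.path(sim_dir, "design.tsv"))
sam <- setNames(file.path(sim_dir, paste0(design$sample, ".sam")),
                design$sample)

tab <- run_pass_pipeline(sam, pas)
print(tab)
cat("Per-sample QC:\n")
print(tab$qc)

dir.create("results/tracks", showWarnings = FALSE, recursive = TRUE)
write_count_table(tab, "results/pass_counts.tsv", "counts")
write.table(tab$qc, "results/pass_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (s in tab$samples)
  export_tracks(tab, pas, s, file.path("results/tracks", s))
cat("Counts -> results/pass_counts.tsv; QC -> results/pass_qc.tsv;",
    "tracks -> results/tracks/\n")
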