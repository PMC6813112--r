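#!/usr/bin/env Rscript
# Simulate the two study-sized whole-blood cohorts (C1: 19 GR + 21 NR,
# C2: 21 GR + 15 NR), writing counts, metadata, CBC tables and ground truth
# under results/data/. Optional first argument: master seed (default 1).

library(tnfblood)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
cfg <- run_config(seed = seed)
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dat <- tnfblood:::simulate_cohorts(cfg)
write_matrix_tsv(dat$reference$profiles, file.path(out, "reference_profiles.tsv"),
                 id_name = "cell_type")
for (nm in names(dat$cohorts)) {
  co <- dat$cohorts[[nm]]
  write_matrix_tsv(co$counts, file.path(out, sprintf("counts_%s.tsv", nm)),
                   id_name = "gene")
  write_meta_tsv(co$meta, file.path(out, sprintf("meta_%s.tsv", nm)))
  write_meta_tsv(co$cbc, file.path(out, sprintf("cbc_%s.tsv", nm)))
  write_truth(co$truth, file.path(out, sprintf("truth_%s.json", nm)))
  frac <- co$truth$fractions_mo3[, "neutrophils"] /
    co$truth$fractions_bl[, "neutrophils"]
  message(sprintf(
    "%s: %d subjects, %d genes; true MO3/BL neutrophil fraction ratio %.3f",
    nm, nrow(co$truth$fractions_bl), nrow(co$counts), mean(frac)))
}
message("wrote synthetic cohorts to ", out)
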