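#!/usr/bin/env Rscript
# Month-3 vs baseline treatment signature: per-cohort differential
# expression, cross-cohort concordance with a sign-flip permutation null,
# the neutrophil effect-vs-specificity correlation, and the paired
# neutrophil/WBC CBC ratio change. Deterministic given the seed (default 1).

library(tnfblood)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
cfg <- run_config(seed = seed, out_dir = file.path("results", "treatment"))
res <- run_treatment_analysis(cfg)

for (nm in names(res$effect_tables)) {
  et <- res$effect_tables[[nm]]
  message(sprintf("%s: %d genes tested, %d at FDR < %.2g (%d down at MO3)",
                  nm, nrow(et), sum(et$q.value < cfg$fdr_level),
                  cfg$fdr_level,
                  sum(et$q.value < cfg$fdr_level & et$effect < 0)))
}
message(sprintf(
  "cross-cohort MO3-BL concordance: rho = %.3f, permutation p = %.4g (%d perms)",
  res$concordance$rho, res$concordance$p.value, res$concordance$n_permutations))
for (nm in names(res$neutrophil_correlation))
  message(sprintf("%s: effect vs neutrophil specificity rho = %.3f",
                  nm, res$neutrophil_correlation[[nm]]$rho))
for (nm in names(res$cbc_ratio_change)) {
  cc <- res$cbc_ratio_change[[nm]]
  message(sprintf(
    "%s: neutrophil/WBC ratio at MO3 = %.1f%% of baseline [%.1f%%, %.1f%%], p = %.3g",
    nm, cc$estimate_pct, cc$ci_pct[1], cc$ci_pct[2], cc$p.value))
}
message("artifacts under ", cfg$out_dir)
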