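#!/usr/bin/env Rscript
# Baseline differences between good responders and non-responders:
# per-cohort GR-NR effects, all-gene and top-variable concordance,
# cell-type marker-set statistics combined across cohorts, and the
# innate/adaptive compartment summary.

library(tnfblood)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
cfg <- run_config(seed = seed, out_dir = file.path("results", "baseline"))
res <- run_baseline_response_analysis(cfg)

message(sprintf("all-gene GR-NR concordance: rho = %.3f, p = %.3g",
                res$concordance_all$rho, res$concordance_all$p.value))
message(sprintf("%s concordance: rho = %.3f, p = %.3g",
                res$concordance_variable$subset,
                res$concordance_variable$rho, res$concordance_variable$p.value))
tab <- res$innate_adaptive$sets
for (i in seq_len(nrow(tab)))
  message(sprintf("  %-12s (%s): mean GR-NR effect %+.3f, permutation p = %.3g",
                  tab$cell_type[i], tab$compartment[i], tab$mean_effect[i],
                  tab$p.value[i]))
message(sprintf("innate/adaptive sign pattern concordant: %s (%s)",
                res$innate_adaptive$concordant,
                res$innate_adaptive$direction))
message("artifacts under ", cfg$out_dir)
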