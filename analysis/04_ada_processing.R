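#!/usr/bin/env Rscript
# When the two high-affinity epitopes (123 and 85 nM) are already presented,
# can aggregates raise ADA through faster antigen processing (16.6-fold
# internalization or degradation) or through additional epitopes? Also
# verifies the subcellular steady-state identities that explain the answer.

library(aggimmuno)

# steady-state identities at constant plasma input
IR0 <- 14.4; DR0 <- 17.28
base <- subcellular_steady_state(1000, ada_subcellular())
up_ir <- subcellular_steady_state(1000, ada_subcellular(IR = 16.6 * IR0))
up_dr <- subcellular_steady_state(1000, ada_subcellular(DR = 16.6 * DR0))
cat(sprintf("Endosomal antigen: 16.6x IR -> %.4g-fold up; 16.6x DR -> %.4g-fold down\n",
            up_ir$E / base$E, base$E / up_dr$E))
cat(sprintf("Peptide pools under 16.6x DR change by %.2g%% (internalization-limited)\n",
            100 * max(abs(up_dr$P / base$P - 1))))
cat(sprintf("Surface complexes under 16.6x IR change by %.2g%% (supply-saturated)\n\n",
            100 * max(abs(up_ir$M / base$M - 1))))

run_preset_folds <- function(name) {
  scenarios <- build_preset(name)
  results <- lapply(scenarios, run_scenario)
  refs <- vapply(scenarios, function(s) s$reference, "")
  data.frame(
    preset = name,
    scenario = names(results),
    cumulative_ada = vapply(results, `[[`, 0, "cumulative_ada"),
    fold_vs_reference = vapply(names(results), function(nm)
      results[[nm]]$cumulative_ada / results[[refs[nm]]]$cumulative_ada, 0),
    row.names = NULL
  )
}

tab <- rbind(run_preset_folds("fig5"), run_preset_folds("fig6"))
write_results(tab, "results/ada_processing.csv")
print(tab, row.names = FALSE, digits = 4)

cat("\nWith high-affinity epitopes already on the surface, neither 16.6-fold",
    "processing-rate increases nor added epitopes change cumulative ADA",
    "materially: presentation is limited by MHC II loading and epitope",
    "affinity, not by antigen supply.\n")
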