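#!/usr/bin/env Rscript
# The induced high-affinity epitope hypothesis: starting from a low-affinity
# epitope set (1230 and 850 nM), does adding a 38 nM epitope raise ADA where
# faster internalization cannot? Runs the comparison at 40 mg biweekly and
# across the full dose range, and tracks affinity maturation of the response.

library(aggimmuno)

run_preset_folds <- function(name) {
  scenarios <- build_preset(name)
  results <- lapply(scenarios, run_scenario)
  refs <- vapply(scenarios, function(s) s$reference, "")
  list(results = results, tab = data.frame(
    scenario = names(results),
    dose_mg = vapply(scenarios, function(s) s$regimen$dose_mg, 0),
    cumulative_ada = vapply(results, `[[`, 0, "cumulative_ada"),
    fold_vs_reference = vapply(names(results), function(nm)
      results[[nm]]$cumulative_ada / results[[refs[nm]]]$cumulative_ada, 0),
    row.names = NULL
  ))
}

f7 <- run_preset_folds("fig7")
f8 <- run_preset_folds("fig8")
tab <- rbind(f7$tab, f8$tab)
write_results(tab, "results/ada_epitope_affinity.csv")
print(tab, row.names = FALSE, digits = 4)

hi <- tab$fold_vs_reference[tab$scenario == "plus_high_affinity"]
cat(sprintf(
  "\nAdding the 38 nM epitope raises cumulative ADA %.1f-fold at 40 mg, and at\nleast %.1f-fold at every dose from 0.04 to 40 mg, while 16.6-fold faster\ninternalization leaves ADA within %.2g%% of baseline.\n",
  hi,
  min(f8$tab$fold_vs_reference[grepl("plus_high_affinity", f8$tab$scenario)]),
  100 * max(abs(tab$fold_vs_reference[grepl("ir_x16.6", tab$scenario)] - 1))))

# affinity maturation under the default high-affinity scenario, tracked from
# the onset of a measurable response
res <- run_scenario(ada_scenario())
ma <- mean_ada_affinity(res, min_total = 1e-3 * res$final_ada)
write_results(ma, "results/ada_affinity_maturation.csv")
cat(sprintf(
  "\nAbundance-weighted mean ADA affinity rises from log10(Ka/M) = %.2f to %.2f\nover the treatment course (affinity maturation).\n",
  ma$mean_log10_Ka[1], ma$mean_log10_Ka[nrow(ma)]))
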