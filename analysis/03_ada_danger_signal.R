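#!/usr/bin/env Rscript
# T-cell-dependent pathway: how does the danger signal (LPS-equivalent, ng)
# that matures dendritic cells shape ADA production? Runs the danger-signal
# ladder, including the 5-fold aggregate-enhanced level above the 350 ng
# baseline, and reports cumulative ADA and fold changes.

library(aggimmuno)

scenarios <- build_preset("fig4")
results <- lapply(scenarios, run_scenario)

tab <- data.frame(
  scenario = names(results),
  danger_signal_ng = vapply(scenarios, function(s) s$cellular$danger_signal, 0),
  cumulative_ada = vapply(results, `[[`, 0, "cumulative_ada"),
  final_ada = vapply(results, `[[`, 0, "final_ada"),
  row.names = NULL
)
ref <- tab$cumulative_ada[tab$scenario == "ds_350"]
tab$fold_vs_350ng <- tab$cumulative_ada / ref
tab <- tab[order(tab$danger_signal_ng), ]
write_results(tab, "results/ada_danger_signal.csv")
print(tab, row.names = FALSE, digits = 4)

cat(sprintf(
  "\nCumulative ADA is monotone in the danger signal; raising it 5-fold above\nthe 350 ng baseline increases cumulative ADA %.1f-fold.\n",
  tab$fold_vs_350ng[tab$danger_signal_ng == 1750]))
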