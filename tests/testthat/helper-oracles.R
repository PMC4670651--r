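# Independent oracles used to validate the simulation engines.

N_AVOGADRO <- 6.02214076e23

# Relative conservation errors of a cross-linking state against the
# initial totals: aggregate (free + all complexes) and receptor
# (free + site-weighted complexes).
conservation_errors <- function(sim) {
  p <- sim$params
  f <- sim$final
  bound <- f[-(1:2)]
  agg <- f[[1]] + sum(bound)
  bcr <- f[[2]] + sum(seq_len(p$n) * bound)
  c(aggregate = abs(agg - p$Aga0) / max(p$Aga0, 1e-30),
    bcr = abs(bcr - p$BCR0) / max(p$BCR0, 1e-30))
}

# Stationary distribution of the valency-1 chain at integer copy numbers,
# by detailed balance on the birth-death chain over the bound count b:
# up-rate c*(A0-b)*(R0-b), down-rate k_off*b. Independent of the SSA code.
bimolecular_ctmc_stationary <- function(A0, R0, c_pair, k_off) {
  bmax <- min(A0, R0)
  w <- numeric(bmax + 1)
  w[1] <- 1
  for (b in seq_len(bmax)) {
    up <- c_pair * (A0 - (b - 1)) * (R0 - (b - 1))
    down <- k_off * b
    w[b + 1] <- w[b] * up / down
  }
  w / sum(w)
}

# per-pair stochastic binding rate for a virtual volume (litres)
pair_rate <- function(k_on, volume) {
  k_on * 1e12 / (N_AVOGADRO * volume)
}

quiet_run <- function(sc) run_scenario(sc)$cumulative_ada
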