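test_that("frozen dynamics: zero binding rate leaves the state unchanged", {
  p <- crosslink_params(n = 2, k_on = 1e-30, Ka = 1e-25, Aga0 = 1.66, BCR0 = 3.32)
  cfg <- ssa_config(p, volume = 1e-10, t_end = 1, seed = 11, n_replicates = 5)
  res <- simulate_ssa(cfg)
  expect_true(all(res$replicates[, "Aga"] == cfg$A0_count))
  expect_true(all(res$replicates[, "BCR"] == cfg$R0_count))
  expect_true(all(res$replicates[, c("C_1", "C_2")] == 0))
})

test_that("molecule counts are conserved exactly in every replicate", {
  p <- crosslink_params(n = 3, Ka = 1e-3, Aga0 = 1.66, BCR0 = 3.32)
  cfg <- ssa_config(p, volume = 1e-10, t_end = 0.5, seed = 5, n_replicates = 30)
  res <- simulate_ssa(cfg)
  reps <- res$replicates
  bound <- reps[, paste0("C_", 1:3), drop = FALSE]
  agg_total <- reps[, "Aga"] + rowSums(bound)
  bcr_total <- reps[, "BCR"] + bound %*% (1:3)
  expect_true(all(agg_total == cfg$A0_count))
  expect_true(all(bcr_total == cfg$R0_count))
})

test_that("valency-1 occupancy matches the analytic master-equation distribution", {
  # 2 aggregates + 2 receptors in a tiny volume: 3-state birth-death chain.
  # The volume sets the per-pair rate; 1e-15 L gives binding comparable to
  # dissociation so all three occupancy states are visited.
  vol <- 1e-15
  two_pM <- 2 / (N_AVOGADRO * vol) * 1e12
  p <- crosslink_params(n = 1, Ka = 1e-3, Aga0 = two_pM, BCR0 = two_pM)
  cfg <- ssa_config(p, volume = vol, t_end = 2, seed = 42, n_replicates = 400)
  expect_equal(cfg$A0_count, 2)
  res <- simulate_ssa(cfg)
  pi_b <- bimolecular_ctmc_stationary(2, 2, pair_rate(p$k_on, vol),
                                      p$k_off_i[1])
  mean_bound <- sum((0:2) * pi_b)
  se <- res$se[["C_1"]]
  expect_gt(se, 0)
  expect_lt(abs(res$mean[["C_1"]] - mean_bound) / se, 3)
})

test_that("ODE equilibrium matches the stochastic oracle within 3 standard errors", {
  # ~100 aggregates, ~200 receptors, valency 2
  vol <- 1e-10
  p <- crosslink_params(n = 2, Ka = 1e-3,
                        Aga0 = 100 / (N_AVOGADRO * vol) * 1e12,
                        BCR0 = 200 / (N_AVOGADRO * vol) * 1e12)
  cfg <- ssa_config(p, volume = vol, t_end = 2, seed = 19, n_replicates = 150)
  cmp <- validate_ssa(cfg)
  expect_equal(nrow(cmp), 4)
  expect_true(all(abs(cmp$z) < 3))
})

test_that("standard errors shrink roughly as 1/sqrt(replicates)", {
  vol <- 1e-10
  p <- crosslink_params(n = 2, Ka = 1e-3,
                        Aga0 = 100 / (N_AVOGADRO * vol) * 1e12,
                        BCR0 = 200 / (N_AVOGADRO * vol) * 1e12)
  se_at <- function(nrep, seed) {
    cfg <- ssa_config(p, volume = vol, t_end = 1, seed = seed,
                      n_replicates = nrep)
    simulate_ssa(cfg)$se[["C_1"]]
  }
  ratio <- se_at(40, 3) / se_at(160, 4)
  expect_gt(ratio, 1.3)  # ideal 2, allow sampling noise
  expect_lt(ratio, 3)
})

test_that("results are reproducible given the seed and capped in size", {
  p <- crosslink_params(n = 2, Ka = 1e-3, Aga0 = 1.66, BCR0 = 3.32)
  cfg <- ssa_config(p, volume = 1e-10, t_end = 0.5, seed = 7, n_replicates = 20)
  r1 <- simulate_ssa(cfg)
  r2 <- simulate_ssa(cfg)
  expect_identical(r1$replicates, r2$replicates)
  expect_error(ssa_config(p, volume = 1e-6, t_end = 1), "exceeds 1e4")
})
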