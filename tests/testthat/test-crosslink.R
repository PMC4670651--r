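test_that("initial aggregate concentration follows total * fraction / valency", {
  expect_equal(initial_aggregate_conc(1e5, 0.15, 10), 1500)
  expect_equal(initial_aggregate_conc(500, 0.02, 100), 0.1)
  expect_equal(initial_aggregate_conc(0, 0.1, 50), 0)
  expect_error(initial_aggregate_conc(-1, 0.1, 10), "Ag_total")
  expect_error(initial_aggregate_conc(100, 1.5, 10), "p must")
  expect_error(initial_aggregate_conc(100, 0.1, 0), "n must")
})

test_that("initial BCR concentration converts receptor counts to pM", {
  # 1e5 receptors/cell * 1e8 cells/L = 1e13 / L; / N_A -> 1.66e-11 mol/L
  expect_equal(bcr_initial_conc(1e5, 1e8, 1), 1e13 / 6.02214076e23 * 1e12,
               tolerance = 1e-12)
  expect_equal(bcr_initial_conc(1e5, 1e8, 0.01),
               bcr_initial_conc(1e5, 1e8, 1) / 100)
  expect_equal(bcr_initial_conc(123, 456, 0), 0)
  expect_error(bcr_initial_conc(1e5, 1e8, 1.2), "specific_fraction")
})

test_that("rate schedule is constant in binding and halves in dissociation", {
  rs <- rate_schedule(8.64e-3, 1e-5, 0.5, 4)
  expect_equal(rs$k_on, rep(8.64e-3, 4))
  expect_equal(rs$k_off[1], 864)
  expect_equal(rs$k_off[2], 432)
  expect_equal(rs$k_off, 864 * 0.5^(0:3))
  # no decay
  rs1 <- rate_schedule(8.64e-3, 1e-5, 1, 4)
  expect_true(all(rs1$k_off == rs1$k_off[1]))
  expect_error(rate_schedule(0, 1e-5, 0.5, 4), "k_on")
  expect_error(rate_schedule(8.64e-3, 1e-5, 0, 4), "decay_base")
})

test_that("mass-action derivatives match hand-derived fluxes and conserve totals", {
  # empty system
  p <- crosslink_params(n = 3, Ka = 1e-5, Aga0 = 0, BCR0 = 0)
  expect_equal(mass_action_rhs(rep(0, 5), p), rep(0, 5))

  # n = 1, 1 pM each, nothing bound: single bimolecular term k_on * A * R
  p1 <- crosslink_params(n = 1, Ka = 1e-5, Aga0 = 1, BCR0 = 1)
  d <- mass_action_rhs(c(1, 1, 0), p1)
  expect_equal(d[3], 8.64e-3)
  expect_equal(d[1], -8.64e-3)
  expect_equal(d[2], -8.64e-3)

  # conservation identities on random states
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    p <- crosslink_params(n = n, Ka = 10^stats::runif(1, -7, -3),
                          Aga0 = 1, BCR0 = 1)
    y <- stats::runif(n + 2, 0, 10)
    d <- mass_action_rhs(y, p)
    scale <- max(abs(d), 1)
    expect_lt(abs(d[1] + sum(d[-(1:2)])) / scale, 1e-12)
    expect_lt(abs(d[2] + sum(seq_len(n) * d[-(1:2)])) / scale, 1e-12)
  }

  expect_error(mass_action_rhs(rep(0, 4), p1), "length")
})

test_that("valency-1 equilibrium matches the closed-form quadratic root", {
  for (Ka in c(1e-7, 1e-5, 1e-3)) {
    for (Aga0 in c(0.1, 12, 1500)) {
      p <- crosslink_params(n = 1, Ka = Ka, Aga0 = Aga0, BCR0 = 5)
      sim <- simulate_crosslink(p, t_end = 1e4)
      expect_true(sim$equilibrium)
      analytic <- bimolecular_equilibrium(Ka, Aga0, 5)
      expect_equal(unname(sim$final[["C_1"]]), analytic, tolerance = 1e-6)
    }
  }
})

test_that("trajectories conserve totals and stay nonnegative over random scenarios", {
  grid <- random_grid(n_scenarios = 8, seed = 7)
  for (i in seq_len(nrow(grid))) {
    p <- crosslink_params(n = grid$n[i], Ka = grid$Ka[i], Aga0 = grid$Aga0[i],
                          specific_fraction = grid$specific_fraction[i])
    sim <- simulate_crosslink(p)
    err <- conservation_errors(sim)
    expect_lt(err[["aggregate"]], 1e-6)
    expect_lt(err[["bcr"]], 1e-6)
    expect_true(all(sim$states >= -1e-12))
  }
})

test_that("zero aggregate input leaves all species unbound", {
  p <- crosslink_params(n = 5, Ka = 1e-3, Aga0 = 0, specific_fraction = 1e-3)
  sim <- simulate_crosslink(p)
  expect_equal(unname(sum(sim$final[-(1:2)])), 0)
  expect_equal(unname(sim$final[["BCR"]]), p$BCR0)
})

test_that("STC sums complexes above the cross-link threshold", {
  # bare state, n = 3, bound = (1, 2, 3) pM
  state <- c(0.5, 0.2, 1, 2, 3)
  cells <- 1e8 * 1e-3
  r <- stc(state, s = 2, bcell_specific_conc = cells, n = 3)
  expect_equal(r$stc_conc, 5)
  expect_equal(stc(state, 1, cells, n = 3)$stc_conc, 6)  # all bound species
  expect_equal(stc(state, 3, cells, n = 3)$stc_conc, 3)
  expect_equal(r$stc_per_cell, 5e-12 * 6.02214076e23 / cells)
  # only the fully bound complex populated: same for every s
  state2 <- c(0, 0, 0, 0, 4)
  for (s in 1:3)
    expect_equal(stc(state2, s, cells, n = 3)$stc_conc, 4)
  expect_error(stc(state, 4, cells, n = 3), "s must")
  expect_error(stc(state, 2, 0, n = 3), "bcell_specific_conc")
})

test_that("STC per cell is nonincreasing in s and monotone in fraction and Ka", {
  sims <- lapply(c(1e-4, 1e-3, 1e-2), function(f)
    simulate_crosslink(crosslink_params(n = 20, Ka = 1e-5, Aga0 = 12,
                                        specific_fraction = f)))
  per_cell <- function(sim, s) stc(sim, s)$stc_per_cell
  # nonincreasing in s
  for (sim in sims) {
    v <- vapply(c(1, 2, 5, 10), per_cell, 0, sim = sim)
    expect_true(all(diff(v) <= 1e-12))
  }
  # nondecreasing in fraction
  v_f <- vapply(sims, per_cell, 0, s = 2)
  expect_true(all(diff(v_f) > 0))
  # nondecreasing in Ka
  v_ka <- vapply(c(1e-7, 1e-5, 1e-3), function(Ka) {
    per_cell(simulate_crosslink(crosslink_params(n = 20, Ka = Ka, Aga0 = 12,
                                                 specific_fraction = 1e-3)), 2)
  }, 0)
  expect_true(all(diff(v_ka) > 0))
})

test_that("sweep covers the grid and is deterministic", {
  sw <- sweep_stc(Ka = c(1e-5, 1e-3), Aga0 = c(0.1, 12),
                  specific_fraction = c(1e-4, 1e-3), s = c(2, 5), n = 20)
  expect_equal(nrow(sw), 2 * 2 * 2 * 2)
  expect_named(sw, c("Ka_pM_inv", "Aga0_pM", "specific_fraction", "s",
                     "stc_conc_pM", "stc_per_cell", "status"))
  expect_true(all(sw$status == "ok"))
  sw2 <- sweep_stc(Ka = c(1e-5, 1e-3), Aga0 = c(0.1, 12),
                   specific_fraction = c(1e-4, 1e-3), s = c(2, 5), n = 20)
  expect_identical(sw, sw2)
})

test_that("fraction threshold brackets the unit-STC crossing", {
  th <- fraction_threshold(Ka = 1e-3, Aga0 = 12, s = 2)
  expect_equal(th$status, "ok")
  # crossing is genuine: below target just under, above target just over
  per_cell <- function(f) {
    p <- crosslink_params(Ka = 1e-3, Aga0 = 12, specific_fraction = f)
    stc(simulate_crosslink(p), 2)$stc_per_cell
  }
  expect_gte(per_cell(th$fraction * 1.01), 1)
  expect_lt(per_cell(th$fraction * 0.95), 1)
})

test_that("fraction threshold reports unattainable and degenerate targets", {
  th <- fraction_threshold(Ka = 1e-7, Aga0 = 12, s = 2)
  expect_equal(th$status, "not_attained")
  expect_true(is.na(th$fraction))
  th0 <- fraction_threshold(Ka = 1e-3, Aga0 = 12, s = 2, target_count = 0)
  expect_equal(th0$status, "at_lower_bound")
  expect_equal(th0$fraction, 1e-7)
})
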