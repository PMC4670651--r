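test_that("plasma kinetics: zero dose is identically zero and ADA adds clearance", {
  reg0 <- ada_regimen(dose_mg = 0)
  pk <- ada_pk()
  out0 <- simulate_pk(reg0, pk, times = seq(0, 56, 0.5))
  expect_true(all(out0$conc_pM == 0))

  reg <- ada_regimen(dose_mg = 40)
  free <- simulate_pk(reg, pk, ada = 0, times = seq(0, 182, 0.5))
  # a large fixed ADA level must strictly reduce exposure
  loaded <- simulate_pk(reg, pk, ada = 1e5, times = seq(0, 182, 0.5))
  auc <- function(df) sum(diff(df$time) * (head(df$conc_pM, -1) +
                                             tail(df$conc_pM, -1)) / 2)
  expect_lt(auc(loaded), auc(free))
  expect_true(all(free$conc_pM >= 0))
})

test_that("terminal plasma slope equals the slow eigenvalue of the disposition system", {
  pk <- ada_pk()
  reg <- ada_regimen(dose_mg = 40, n_doses = 1)
  out <- simulate_pk(reg, pk, times = seq(0, 400, 1))
  late <- out[out$time >= 300, ]
  slope <- stats::coef(stats::lm(log(late$central) ~ late$time))[[2]]
  A <- matrix(c(-(pk$k10 + pk$k12), pk$k21, pk$k12, -pk$k21), 2, 2, byrow = TRUE)
  lambda_slow <- max(eigen(A, only.values = TRUE)$values)
  expect_equal(slope, lambda_slow, tolerance = 1e-4)
})

test_that("steady-state endosomal antigen scales with IR and inversely with DR", {
  IR0 <- 14.4; DR0 <- 17.28
  drug <- 1000
  base <- subcellular_steady_state(drug, ada_subcellular())
  # closed form E* = IR * C / DR
  expect_equal(base$E, IR0 * drug / DR0, tolerance = 1e-6)
  up_ir <- subcellular_steady_state(drug, ada_subcellular(IR = 16.6 * IR0))
  up_dr <- subcellular_steady_state(drug, ada_subcellular(DR = 16.6 * DR0))
  expect_equal(up_ir$E / base$E, 16.6, tolerance = 1e-6)
  expect_equal(base$E / up_dr$E, 16.6, tolerance = 1e-6)
  # peptide supply is internalization-limited: independent of DR
  expect_equal(up_dr$P, base$P, tolerance = 1e-6)
  # and proportional to IR
  expect_equal(up_ir$P / base$P, rep(16.6, 2), tolerance = 1e-6)
})

test_that("surface presentation rises with epitope affinity and respects MHC capacity", {
  sub <- ada_subcellular(epitopes = list(ada_epitope(123), ada_epitope(850)))
  ss <- subcellular_steady_state(1000, sub)
  expect_gt(ss$M[1], ss$M[2])  # 123 nM beats 850 nM at equal supply
  expect_lt(sum(ss$M), sub$mhc_total)
  # supply saturation: a 16.6-fold IR increase barely moves presentation
  ss_ir <- subcellular_steady_state(1000, ada_subcellular(
    IR = 16.6 * 14.4, epitopes = list(ada_epitope(123), ada_epitope(850))))
  expect_equal(ss_ir$M, ss$M, tolerance = 1e-3)
})

test_that("MHC capacity bound holds along a full scenario trajectory", {
  res <- run_scenario(ada_scenario())
  M <- as.matrix(res$trajectory[paste0("M_", 1:2)])
  expect_true(all(rowSums(M) <= res$scenario$subcellular$mhc_total))
  expect_true(all(as.matrix(res$trajectory[, -1]) >= -1e-8))
})

test_that("no danger signal means no DC maturation and no ADA", {
  cell0 <- ada_cellular(danger_signal = 0)
  expect_equal(dc_maturation(0, cell0), 0)
  res <- run_scenario(ada_scenario(cellular = cell0))
  expect_equal(res$cumulative_ada, 0)
  expect_equal(res$final_ada, 0)
})

test_that("total ADA is the sum of the 17 subgroups at every time point", {
  res <- run_scenario(ada_scenario())
  traj <- res$trajectory
  expect_equal(ncol(traj[grep("^ADA_[0-9]+$", names(traj))]), 17)
  expect_equal(traj$ADA_total,
               rowSums(traj[paste0("ADA_", 1:17)]), tolerance = 1e-12)
  # affinity ladder is strictly decreasing in Kd
  expect_true(all(diff(res$scenario$cellular$kd_ladder_pM) < 0))
})

test_that("cumulative ADA is monotone in the danger signal", {
  cums <- vapply(c(70, 350, 1750), function(ds)
    quiet_run(ada_scenario(cellular = ada_cellular(danger_signal = ds))), 0)
  expect_true(all(diff(cums) > 0))
})

test_that("a scenario compared with itself has unit fold change", {
  sc <- ada_scenario()
  fc <- ada_fold_change(sc, sc)
  expect_equal(fc$fold_change, 1)
  # fold change against a zero-ADA reference is an error, not Inf
  expect_error(ada_fold_change(sc, ada_scenario(
    cellular = ada_cellular(danger_signal = 0))), "no ADA")
})

test_that("ADA affinity matures: abundance-weighted mean affinity rises to a plateau", {
  res <- run_scenario(ada_scenario())
  ma <- mean_ada_affinity(res, min_total = 1e-3 * res$final_ada)
  m <- ma$mean_log10_Ka
  rise <- m[length(m)] - m[1]
  expect_gt(rise, 0.2)               # substantial net affinity gain
  expect_lt(max(cummax(m) - m), 0.05 * rise)  # no material retracement
})

test_that("modular stage simulators agree with the coupled run when forced", {
  sc <- ada_scenario(t_end = 56)
  res <- run_scenario(sc)
  traj <- res$trajectory
  # feed the coupled run's drug curve into the standalone subcellular module
  drug <- data.frame(time = traj$time, conc_pM = traj$conc_pM)
  sub_tr <- simulate_subcellular(drug, sc$subcellular, times = traj$time)
  expect_equal(sub_tr$E, traj$E, tolerance = 1e-4)
  expect_equal(sub_tr$M_1, traj$M_1, tolerance = 1e-4)
  # and the presented-complex curve into the standalone cellular module
  mbest <- data.frame(time = traj$time,
                      M_best = pmax(traj$M_1, traj$M_2))
  cell_tr <- simulate_cellular(mbest, sc$cellular, drug, times = traj$time)
  expect_equal(cell_tr$cum_ADA[nrow(cell_tr)], res$cumulative_ada,
               tolerance = 1e-3)
})
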