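# State layout for the coupled ADA system:
#   1 depot (pmol), 2 central (pmol), 3 peripheral (pmol),
#   4 E (endosomal antigen, a.u.),
#   5..(4+ne)            P_j  (peptide pools, a.u.)
#   (5+ne)..(4+2ne)      M_j  (surface complexes per APC)
#   then n_sub activated B cells, n_sub plasma cells, n_sub ADA, CumADA.
.ada_layout <- function(ne, ns) {
  i <- 4L
  list(
    D = 1L, C = 2L, P2 = 3L, E = 4L,
    P = i + seq_len(ne),
    M = i + ne + seq_len(ne),
    A = i + 2L * ne + seq_len(ns),
    PC = i + 2L * ne + ns + seq_len(ns),
    ADA = i + 2L * ne + 2L * ns + seq_len(ns),
    Cum = i + 2L * ne + 3L * ns + 1L,
    n_state = i + 2L * ne + 3L * ns + 1L
  )
}

.ada_state_names <- function(ne, ns) {
  c("depot", "central", "peripheral", "E",
    paste0("P_", seq_len(ne)), paste0("M_", seq_len(ne)),
    paste0("B_", seq_len(ns)), paste0("PC_", seq_len(ns)),
    paste0("ADA_", seq_len(ns)), "cum_ADA")
}

# Full coupled right-hand side. `drivers` allows a module to be run in
# isolation by forcing its inputs (functions of time) instead of coupling.
.ada_rhs <- function(t, y, ctx) {
  L <- ctx$layout
  sub <- ctx$sub
  cell <- ctx$cell
  pk <- ctx$pk
  ne <- length(sub$kd_nM)
  ns <- cell$n_subgroups

  ADA_tot <- sum(y[L$ADA])
  dy <- numeric(L$n_state)

  # whole-body PK (pmol)
  C_pM <- if (is.null(ctx$force_drug)) y[L$C] / pk$Vc else ctx$force_drug(t)
  if (is.null(ctx$force_drug)) {
    dy[L$D] <- -pk$ka * y[L$D]
    dy[L$C] <- pk$ka * y[L$D] - (pk$k10 + pk$k12) * y[L$C] +
      pk$k21 * y[L$P2] - pk$k_ada * ADA_tot * y[L$C]
    dy[L$P2] <- pk$k12 * y[L$C] - pk$k21 * y[L$P2]
  }

  # subcellular: endosomal antigen, peptide pools, MHC II loading
  E <- y[L$E]
  P <- y[L$P]
  M <- y[L$M]
  dy[L$E] <- sub$IR * C_pM - sub$DR * E
  dy[L$P] <- sub$copies * sub$DR * E - sub$peptide_decay * P
  mhc_free <- max(sub$mhc_total - sum(M), 0)
  dy[L$M] <- sub$k_load * mhc_free * P / (sub$K_m + P) -
    sub$k_surf * sub$kd_nM * M

  # cellular: DC maturation -> T help -> subgroup activation -> ADA
  M_best <- if (is.null(ctx$force_Mbest)) max(M, 0) else ctx$force_Mbest(t)
  dc <- dc_maturation(cell$danger_signal, cell)
  t_help <- cell$thelp_gain * dc * M_best / (cell$M50 + M_best)
  occ <- C_pM / (C_pM + cell$kd_ladder_pM)
  act <- cell$k_act * t_help * occ * cell$naive
  A <- y[L$A]
  mat <- cell$k_mat * A
  mat_in <- c(0, mat[-ns])
  mat_out <- c(mat[-ns], 0)
  dy[L$A] <- act + mat_in - mat_out - cell$k_pc * A
  dy[L$PC] <- cell$k_pc * A - cell$d_pc * y[L$PC]
  dy[L$ADA] <- cell$k_sec * y[L$PC] - cell$d_ada * y[L$ADA]
  dy[L$Cum] <- ADA_tot
  list(dy)
}

.ada_integrate <- function(y0, times, ctx, dose_times = NULL, dose_pmol = 0,
                           rel_tol = 1e-8, abs_tol = 1e-10) {
  if (is.null(names(y0)))
    names(y0) <- paste0("y", seq_along(y0))
  eventdat <- NULL
  if (!is.null(dose_times) && length(dose_times) > 0) {
    eventdat <- data.frame(var = names(y0)[1L], time = dose_times,
                           value = dose_pmol, method = "add",
                           stringsAsFactors = FALSE)
  }
  out <- deSolve::ode(
    y = y0, times = times, func = .ada_rhs, parms = ctx, method = "lsoda",
    rtol = rel_tol, atol = abs_tol,
    events = if (is.null(eventdat)) NULL else list(data = eventdat)
  )
  out
}

#' Simulate plasma drug kinetics for a regimen
#'
#' Two-compartment PK with first-order subcutaneous absorption and optional
#' ADA-mediated elimination. ADA can be a fixed level or a function of time.
#'
#' @param regimen an [ada_regimen()].
#' @param pk an [ada_pk()].
#' @param ada total-ADA level driving complex-mediated elimination: a scalar
#'   or a function of time. Default 0.
#' @param times output times (days). Default `seq(0, 182, 0.1)`.
#' @return data.frame with `time`, `depot`, `central`, `peripheral` (pmol)
#'   and `conc_pM` (central concentration).
#' @export
simulate_pk <- function(regimen, pk, ada = 0, times = seq(0, 182, by = 0.1)) {
  stopifnot(inherits(regimen, "ada_regimen"), inherits(pk, "ada_pk"))
  ada_fun <- if (is.function(ada)) ada else function(t) ada
  rhs <- function(t, y, p) {
    list(c(
      -pk$ka * y[1],
      pk$ka * y[1] - (pk$k10 + pk$k12) * y[2] + pk$k21 * y[3] -
        pk$k_ada * ada_fun(t) * y[2],
      pk$k12 * y[2] - pk$k21 * y[3]
    ))
  }
  later <- regimen$dose_times[regimen$dose_times > times[1]]
  eventdat <- if (length(later) > 0)
    data.frame(var = 1L, time = later, value = regimen$dose_pmol,
               method = "add") else NULL
  y0 <- c(depot = regimen$dose_pmol, central = 0, peripheral = 0)
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10,
                      events = if (is.null(eventdat)) NULL
                               else list(data = eventdat))
  df <- as.data.frame(out)
  names(df) <- c("time", "depot", "central", "peripheral")
  df$conc_pM <- df$central / pk$Vc
  df
}

#' Simulate the subcellular antigen-presentation module
#'
#' Endosomal antigen, per-epitope peptide pools and surface MHC II-peptide
#' complexes driven by a plasma drug concentration, which may be a constant
#' (useful for steady-state fold-change analyses) or a time course.
#'
#' @param drug constant plasma concentration (pM) or a data.frame with
#'   columns `time` and `conc_pM`.
#' @param sub an [ada_subcellular()].
#' @param times output times (days). Default `seq(0, 5, 0.01)`: the default
#'   rates (>= 1 day^-1) equilibrate well within 5 days of constant input.
#' @return data.frame with `time`, `E`, `P_j` and `M_j` columns.
#' @export
simulate_subcellular <- function(drug, sub, times = seq(0, 5, by = 0.01)) {
  stopifnot(inherits(sub, "ada_subcellular"))
  drug_fun <- if (is.data.frame(drug)) {
    stats::approxfun(drug$time, drug$conc_pM, rule = 2)
  } else {
    check_scalar(drug, "drug", lower = 0)
    function(t) drug
  }
  ne <- length(sub$kd_nM)
  cell0 <- ada_cellular(danger_signal = 0)  # cellular states stay at zero
  layout <- .ada_layout(ne, cell0$n_subgroups)
  ctx <- list(layout = layout, sub = sub, cell = cell0, pk = ada_pk(),
              force_drug = drug_fun, force_Mbest = NULL)
  y0 <- numeric(layout$n_state)
  out <- .ada_integrate(y0, times, ctx)
  df <- as.data.frame(out[, c(1L, 1L + c(layout$E, layout$P, layout$M))])
  names(df) <- c("time", "E", paste0("P_", seq_len(ne)),
                 paste0("M_", seq_len(ne)))
  df
}

#' Steady state of the subcellular module under constant drug input
#'
#' Integrates to late time and returns the final endosomal antigen, peptide
#' and surface-complex levels.
#'
#' @inheritParams simulate_subcellular
#' @param t_ss integration horizon (days). Default 30.
#' @return named list `E`, `P` (vector), `M` (vector).
#' @export
subcellular_steady_state <- function(drug, sub, t_ss = 30) {
  tr <- simulate_subcellular(drug, sub, times = c(0, t_ss))
  ne <- length(sub$kd_nM)
  last <- tr[nrow(tr), ]
  list(E = last$E,
       P = as.numeric(last[paste0("P_", seq_len(ne))]),
       M = as.numeric(last[paste0("M_", seq_len(ne))]))
}

#' Simulate the cellular activation module
#'
#' B-cell subgroup activation, affinity maturation, plasma-cell
#' differentiation and ADA secretion driven by a presented-complex level and
#' a drug concentration (for BCR occupancy), each a constant or a time course.
#'
#' @param M_best best-presented MHC II-peptide complex level (per APC):
#'   constant or data.frame with columns `time`, `M_best`.
#' @param cell an [ada_cellular()].
#' @param drug plasma drug concentration (pM): constant or data.frame with
#'   `time`, `conc_pM`.
#' @param times output times (days).
#' @return data.frame with `time`, per-subgroup `B_i`, `PC_i`, `ADA_i`,
#'   `ADA_total` and `cum_ADA`.
#' @export
simulate_cellular <- function(M_best, cell, drug,
                              times = seq(0, 182, by = 0.1)) {
  stopifnot(inherits(cell, "ada_cellular"))
  m_fun <- if (is.data.frame(M_best))
    stats::approxfun(M_best$time, M_best$M_best, rule = 2)
  else function(t) M_best
  drug_fun <- if (is.data.frame(drug))
    stats::approxfun(drug$time, drug$conc_pM, rule = 2)
  else function(t) drug
  ns <- cell$n_subgroups
  sub0 <- ada_subcellular()
  layout <- .ada_layout(length(sub0$kd_nM), ns)
  ctx <- list(layout = layout, sub = sub0, cell = cell, pk = ada_pk(),
              force_drug = drug_fun, force_Mbest = m_fun)
  y0 <- numeric(layout$n_state)
  out <- .ada_integrate(y0, times, ctx)
  cols <- 1L + c(layout$A, layout$PC, layout$ADA, layout$Cum)
  df <- as.data.frame(out[, c(1L, cols)])
  names(df) <- c("time", paste0("B_", seq_len(ns)), paste0("PC_", seq_len(ns)),
                 paste0("ADA_", seq_len(ns)), "cum_ADA")
  df$ADA_total <- rowSums(df[paste0("ADA_", seq_len(ns))])
  df
}

#' Run a full coupled ADA scenario
#'
#' Integrates the whole-body, subcellular and cellular modules as one
#' coupled ODE system: plasma drug feeds antigen presentation and B-cell
#' occupancy, presented complexes and danger signal drive T help and ADA
#' production, and total ADA feeds back on drug elimination.
#'
#' @param scenario an [ada_scenario()].
#' @param rel_tol,abs_tol solver tolerances.
#' @return object of class `ada_result`: list with `trajectory` (data.frame
#'   of all states plus `conc_pM` and `ADA_total`), `cumulative_ada`
#'   (time-integrated total ADA over the course), `final_ada`, and the
#'   `scenario`.
#' @export
run_scenario <- function(scenario, rel_tol = 1e-8, abs_tol = 1e-10) {
  stopifnot(inherits(scenario, "ada_scenario"))
  sub <- scenario$subcellular
  cell <- scenario$cellular
  ne <- length(sub$kd_nM)
  ns <- cell$n_subgroups
  layout <- .ada_layout(ne, ns)
  ctx <- list(layout = layout, sub = sub, cell = cell, pk = scenario$pk,
              force_drug = NULL, force_Mbest = NULL)
  y0 <- numeric(layout$n_state)
  y0[layout$D] <- scenario$regimen$dose_pmol
  times <- seq(0, scenario$t_end, by = scenario$dt_out)
  later <- scenario$regimen$dose_times[scenario$regimen$dose_times > 0]
  later <- later[later < scenario$t_end]
  out <- .ada_integrate(y0, times, ctx, dose_times = later,
                        dose_pmol = scenario$regimen$dose_pmol,
                        rel_tol = rel_tol, abs_tol = abs_tol)
  df <- as.data.frame(out)
  names(df) <- c("time", .ada_state_names(ne, ns))
  df$conc_pM <- df$central / scenario$pk$Vc
  df$ADA_total <- rowSums(df[paste0("ADA_", seq_len(ns))])
  structure(
    list(trajectory = df,
         cumulative_ada = df$cum_ADA[nrow(df)],
         final_ada = df$ADA_total[nrow(df)],
         scenario = scenario),
    class = "ada_result"
  )
}

#' @export
print.ada_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("ADA scenario '%s': %g mg q%gd x%d, danger signal %g ng\n",
              sc$name, sc$regimen$dose_mg, sc$regimen$interval_days,
              sc$regimen$n_doses, sc$cellular$danger_signal))
  cat(sprintf("  epitope Kd (nM): %s\n",
              paste(sc$subcellular$kd_nM, collapse = ", ")))
  cat(sprintf("  cumulative ADA %.4g (a.u. day), final ADA %.4g (a.u.)\n",
              x$cumulative_ada, x$final_ada))
  invisible(x)
}

#' Cumulative-ADA fold change between two scenarios
#'
#' @param scenario,reference [ada_scenario()] objects (or `ada_result`s).
#' @return list with `fold_change` and both `ada_result`s.
#' @export
ada_fold_change <- function(scenario, reference) {
  res <- if (inherits(scenario, "ada_result")) scenario
         else run_scenario(scenario)
  ref <- if (inherits(reference, "ada_result")) reference
         else run_scenario(reference)
  if (ref$cumulative_ada <= 0)
    stop_invalid("reference scenario produced no ADA; fold change undefined")
  list(fold_change = res$cumulative_ada / ref$cumulative_ada,
       scenario = res, reference = ref)
}

#' Abundance-weighted mean ADA affinity over time
#'
#' For each output time, the ADA-abundance-weighted mean of log10 association
#' constant (1/Kd) across the affinity ladder. Rises over a course of
#' treatment as the response affinity-matures.
#'
#' @param result an `ada_result` (or its trajectory data.frame).
#' @param cell the [ada_cellular()] parameters (taken from the result's
#'   scenario when available).
#' @param min_total times with total ADA below this are dropped (mean
#'   undefined at zero abundance). Default 1e-9.
#' @return data.frame with `time`, `ADA_total`, `mean_log10_Ka`.
#' @export
mean_ada_affinity <- function(result, cell = NULL, min_total = 1e-9) {
  if (inherits(result, "ada_result")) {
    cell <- result$scenario$cellular
    traj <- result$trajectory
  } else traj <- result
  if (is.null(cell)) stop_invalid("cell parameters required")
  ns <- cell$n_subgroups
  ada <- as.matrix(traj[paste0("ADA_", seq_len(ns))])
  tot <- rowSums(ada)
  log_ka <- -log10(cell$kd_ladder_pM * 1e-12)  # per-molar association
  keep <- tot > min_total
  data.frame(time = traj$time[keep], ADA_total = tot[keep],
             mean_log10_Ka = as.numeric(ada[keep, , drop = FALSE] %*% log_ka) /
               tot[keep])
}
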