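#' Configuration for the stochastic (Gillespie) cross-linking oracle
#'
#' The deterministic engine is validated against an exact direct-method
#' event simulation of the same reaction network at small copy numbers. The
#' virtual reaction volume converts concentrations (pM) to integer molecule
#' counts; per-molecule binding propensities divide the macroscopic rate by
#' the volume in pM-equivalents.
#'
#' @param params a [crosslink_params()] object.
#' @param volume virtual reaction volume (litres). Choose so initial counts
#'   are in the tens to thousands.
#' @param t_end simulated time (days).
#' @param seed RNG seed, recorded in the output.
#' @param n_replicates number of independent replicates.
#' @return object of class `ssa_config`.
#' @export
ssa_config <- function(params, volume, t_end, seed = 1L, n_replicates = 100L) {
  stopifnot(inherits(params, "crosslink_params"))
  check_scalar(volume, "volume", lower = 0, strict_lower = TRUE)
  check_scalar(t_end, "t_end", lower = 0, strict_lower = TRUE)
  check_scalar(n_replicates, "n_replicates", lower = 1, integer = TRUE)
  counts <- round(pM_to_molecules_per_L(c(params$Aga0, params$BCR0)) * volume)
  if (sum(counts) > 1e4)
    stop_invalid("initial molecule count ", sum(counts),
                 " exceeds 1e4; the oracle is for small instances")
  structure(
    list(params = params, volume = volume,
         A0_count = counts[1], R0_count = counts[2],
         t_end = t_end, seed = as.integer(seed),
         n_replicates = as.integer(n_replicates)),
    class = "ssa_config"
  )
}

# one direct-method trajectory; returns counts c(A, R, C_1..C_n) at t_end
.ssa_once <- function(config) {
  p <- config$params
  n <- p$n
  # 1 molecule in `volume` litres expressed in pM
  one_pM <- molecules_per_L_to_pM(1 / config$volume)
  c_bind <- p$k_on_i * one_pM      # per-pair rate, day^-1
  A <- config$A0_count
  R <- config$R0_count
  C <- integer(n)
  t <- 0
  i <- seq_len(n)
  repeat {
    Cprev <- c(A, C[-n])
    a_bind <- (n - i + 1) * c_bind * R * Cprev
    a_diss <- i * p$k_off_i * C
    a <- c(a_bind, a_diss)
    a0 <- sum(a)
    if (a0 <= 0) break  # absorbing state (e.g. k_on = 0 and nothing bound)
    t <- t + stats::rexp(1, a0)
    if (t > config$t_end) break
    j <- sample.int(2L * n, 1L, prob = a)
    if (j <= n) {           # binding step j: C_{j-1} + R -> C_j
      if (j == 1L) A <- A - 1L else C[j - 1L] <- C[j - 1L] - 1L
      C[j] <- C[j] + 1L
      R <- R - 1L
    } else {                # dissociation step j - n: C_j -> C_{j-1} + R
      jj <- j - n
      C[jj] <- C[jj] - 1L
      if (jj == 1L) A <- A + 1L else C[jj - 1L] <- C[jj - 1L] + 1L
      R <- R + 1L
    }
  }
  c(A, R, C)
}

#' Run the stochastic oracle
#'
#' Simulates `n_replicates` exact trajectories and returns per-species mean
#' counts and standard errors at `t_end`. Reproducible given the seed.
#'
#' @param config an [ssa_config()] object.
#' @return object of class `ssa_result`: list with `mean`, `se` (named
#'   numeric vectors over `Aga`, `BCR`, `C_1..C_n`), `replicates` (matrix),
#'   and the `config`.
#' @export
simulate_ssa <- function(config) {
  stopifnot(inherits(config, "ssa_config"))
  n <- config$params$n
  nm <- c("Aga", "BCR", paste0("C_", seq_len(n)))
  reps <- matrix(NA_real_, nrow = config$n_replicates, ncol = n + 2L,
                 dimnames = list(NULL, nm))
  set.seed(config$seed)
  for (r in seq_len(config$n_replicates)) reps[r, ] <- .ssa_once(config)
  structure(
    list(mean = colMeans(reps),
         se = apply(reps, 2L, stats::sd) / sqrt(nrow(reps)),
         replicates = reps, config = config),
    class = "ssa_result"
  )
}

#' Compare deterministic equilibrium with the stochastic oracle
#'
#' Converts the ODE state at `t_end` to expected counts in the oracle's
#' virtual volume and reports a z-score per species.
#'
#' @param config an [ssa_config()] object.
#' @param ... passed to [simulate_crosslink()].
#' @return data.frame with species, ODE expected count, SSA mean, SSA se, z.
#' @export
validate_ssa <- function(config, ...) {
  ssa <- simulate_ssa(config)
  # match the ODE initial condition to the oracle's rounded integer counts
  p <- config$params
  p_matched <- crosslink_params(
    n = p$n, k_on = p$k_on, Ka = p$Ka, decay_base = p$decay_base,
    Aga0 = molecules_per_L_to_pM(config$A0_count / config$volume),
    BCR0 = molecules_per_L_to_pM(config$R0_count / config$volume)
  )
  ode_sim <- simulate_crosslink(p_matched, times = c(0, config$t_end), ...)
  expected <- pM_to_molecules_per_L(ode_sim$final) * config$volume
  z <- ifelse(ssa$se > 0, (ssa$mean - expected) / ssa$se, 0)
  data.frame(species = names(expected), ode_count = as.numeric(expected),
             ssa_mean = as.numeric(ssa$mean), ssa_se = as.numeric(ssa$se),
             z = as.numeric(z), row.names = NULL)
}
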