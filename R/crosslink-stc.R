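#' Signal-transducing complex (STC) concentration and per-cell count
#'
#' An STC is an aggregate cross-linking at least `s` receptors:
#' `STC = sum_{i = s}^{n} C_i`. The per-cell count converts the STC
#' concentration to molecules per litre (Avogadro) and divides by the
#' antigen-specific B-cell concentration, i.e. the cells whose receptors make
#' up the modeled BCR pool.
#'
#' @param state a `crosslink_sim` object (its final state is used) or a
#'   numeric state vector `c(Aga, BCR, C_1..C_n)`.
#' @param s minimum cross-link number, integer in `[1, n]`.
#' @param bcell_specific_conc antigen-specific B cells per litre. If `NULL`
#'   and `state` is a simulation, taken from its parameters.
#' @param n valency; required when `state` is a bare vector.
#' @return object of class `stc_result`: list with `s`, `stc_conc` (pM) and
#'   `stc_per_cell`.
#' @export
stc <- function(state, s, bcell_specific_conc = NULL, n = NULL) {
  if (inherits(state, "crosslink_sim")) {
    if (is.null(bcell_specific_conc))
      bcell_specific_conc <- state$params$bcell_specific_conc
    n <- state$params$n
    state <- state$final
  }
  if (is.null(n)) stop("n must be supplied for a bare state vector")
  check_scalar(s, "s", lower = 1, upper = n, integer = TRUE)
  if (is.null(bcell_specific_conc) || is.na(bcell_specific_conc))
    stop_invalid("bcell_specific_conc is required")
  if (bcell_specific_conc <= 0)
    stop_invalid("bcell_specific_conc must be > 0")
  bound <- state[(2L + s):(2L + n)]
  stc_conc <- sum(bound)
  structure(
    list(s = as.integer(s), stc_conc = stc_conc,
         stc_per_cell = pM_to_molecules_per_L(stc_conc) / bcell_specific_conc),
    class = "stc_result"
  )
}

#' @export
print.stc_result <- function(x, ...) {
  cat(sprintf("STC (s >= %d): %.4g pM, %.4g per antigen-specific B cell\n",
              x$s, x$stc_conc, x$stc_per_cell))
  invisible(x)
}

#' Equilibrium STC sweep over affinity, aggregate level and B-cell fraction
#'
#' Runs the cross-linking model to equilibrium at every combination of the
#' supplied association constants, initial aggregate concentrations and
#' antigen-specific B-cell fractions, and tabulates the STC per cell for each
#' minimum cross-link number in `s`. Defaults are the physiological grid:
#' three affinity levels spanning naive to affinity-matured antibodies, three
#' aggregate levels spanning a 30 ug interferon-beta dose to a 40 mg mAb dose,
#' and a log-spaced fraction ladder up to the 1% upper bound.
#'
#' @param Ka association constants (pM^-1).
#' @param Aga0 initial aggregate concentrations (pM).
#' @param specific_fraction antigen-specific B-cell fractions.
#' @param s minimum cross-link numbers.
#' @param n valency. Default 100.
#' @param k_on per-site binding rate (pM^-1 day^-1).
#' @param decay_base dissociation decay base.
#' @param t_end equilibrium integration cap (days).
#' @param ... further arguments to [simulate_crosslink()].
#' @return data.frame with columns `Ka_pM_inv`, `Aga0_pM`, `specific_fraction`,
#'   `s`, `stc_conc_pM`, `stc_per_cell`, `status` (`"ok"`, `"capped"` when the
#'   time cap was hit before equilibrium, or `"failed"`).
#' @export
sweep_stc <- function(Ka = c(1e-7, 1e-5, 1e-3),
                      Aga0 = c(0.1, 12, 1500),
                      specific_fraction = 10^seq(-7, -2),
                      s = c(2, 5, 10),
                      n = 100, k_on = 8.64e-3, decay_base = 0.5,
                      t_end = 100, ...) {
  stopifnot(length(Ka) > 0, length(Aga0) > 0, length(specific_fraction) > 0,
            length(s) > 0)
  grid <- expand.grid(Ka = Ka, Aga0 = Aga0, specific_fraction = specific_fraction,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid) * length(s))
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    p <- crosslink_params(n = n, k_on = k_on, Ka = grid$Ka[g],
                          decay_base = decay_base, Aga0 = grid$Aga0[g],
                          specific_fraction = grid$specific_fraction[g])
    sim <- tryCatch(simulate_crosslink(p, t_end = t_end, ...), error = identity)
    failed <- inherits(sim, "error")
    for (sv in s) {
      k <- k + 1L
      if (failed) {
        rows[[k]] <- data.frame(
          Ka_pM_inv = grid$Ka[g], Aga0_pM = grid$Aga0[g],
          specific_fraction = grid$specific_fraction[g], s = sv,
          stc_conc_pM = NA_real_, stc_per_cell = NA_real_, status = "failed")
      } else {
        r <- stc(sim, sv)
        rows[[k]] <- data.frame(
          Ka_pM_inv = grid$Ka[g], Aga0_pM = grid$Aga0[g],
          specific_fraction = grid$specific_fraction[g], s = sv,
          stc_conc_pM = r$stc_conc, stc_per_cell = r$stc_per_cell,
          status = if (sim$equilibrium) "ok" else "capped")
      }
    }
  }
  do.call(rbind, rows)
}

#' Smallest antigen-specific fraction reaching a target STC count per cell
#'
#' Bisects (on a log scale) the antigen-specific B-cell fraction until the
#' equilibrium STC per cell reaches `target_count`. Monotonicity of the
#' per-cell count in the fraction is checked numerically at the bracket ends.
#'
#' @param Ka association constant (pM^-1).
#' @param Aga0 initial aggregate concentration (pM).
#' @param s minimum cross-link number.
#' @param n valency.
#' @param k_on,decay_base rate-schedule parameters.
#' @param target_count STC-per-cell target. Default 1.
#' @param bracket search interval for the fraction. Default `c(1e-7, 1e-2)`.
#' @param rel_tol relative bisection tolerance on the fraction. Default 1e-3.
#' @param ... further arguments to [simulate_crosslink()].
#' @return list with `fraction` (NA when not attained), `status`
#'   (`"ok"`, `"not_attained"`, or `"at_lower_bound"`), and `per_cell_at_upper`.
#' @export
fraction_threshold <- function(Ka, Aga0, s, n = 100, k_on = 8.64e-3,
                               decay_base = 0.5, target_count = 1,
                               bracket = c(1e-7, 1e-2), rel_tol = 1e-3, ...) {
  stopifnot(length(bracket) == 2, bracket[1] > 0, bracket[2] > bracket[1])
  per_cell <- function(f) {
    p <- crosslink_params(n = n, k_on = k_on, Ka = Ka, decay_base = decay_base,
                          Aga0 = Aga0, specific_fraction = f)
    stc(simulate_crosslink(p, ...), s)$stc_per_cell
  }
  if (target_count <= 0)
    return(list(fraction = bracket[1], status = "at_lower_bound",
                per_cell_at_upper = NA_real_))
  f_lo <- per_cell(bracket[1])
  f_hi <- per_cell(bracket[2])
  if (f_hi < f_lo)
    warning("STC per cell is not nondecreasing in the fraction over the bracket")
  if (f_hi < target_count)
    return(list(fraction = NA_real_, status = "not_attained",
                per_cell_at_upper = f_hi))
  if (f_lo >= target_count)
    return(list(fraction = bracket[1], status = "at_lower_bound",
                per_cell_at_upper = f_hi))
  lo <- log(bracket[1]); hi <- log(bracket[2])
  while ((hi - lo) > rel_tol) {
    mid <- (lo + hi) / 2
    if (per_cell(exp(mid)) >= target_count) hi <- mid else lo <- mid
  }
  list(fraction = exp(hi), status = "ok", per_cell_at_upper = f_hi)
}
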