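#' Initial aggregate concentration from total drug, aggregation fraction and valency
#'
#' An aggregate of valency `n` is formed by the combination of `n` monomers,
#' so a total monomer concentration `Ag_total` of which a fraction `p` is
#' aggregated yields an aggregate concentration `Ag_total * p / n`.
#'
#' @param Ag_total total therapeutic-protein concentration (pM), >= 0.
#' @param p aggregation fraction, in \[0, 1\].
#' @param n aggregate valency (monomers per aggregate), integer >= 1.
#' @return initial aggregate concentration (pM).
#' @examples
#' initial_aggregate_conc(1e5, 0.15, 10)  # 1500 pM
#' initial_aggregate_conc(500, 0.02, 100) # 0.1 pM
#' @export
initial_aggregate_conc <- function(Ag_total, p, n) {
  check_scalar(Ag_total, "Ag_total", lower = 0)
  check_scalar(p, "p", lower = 0, upper = 1)
  check_scalar(n, "n", lower = 1, integer = TRUE)
  Ag_total * p / n
}

#' Initial free-BCR concentration
#'
#' The initial B-cell-receptor concentration is the product of the number of
#' receptors per cell, the B-cell concentration per litre, and the fraction of
#' B cells specific for the antigen, converted to pM via Avogadro's constant.
#'
#' @param receptors_per_cell BCR copies per B cell (~1e5).
#' @param bcells_per_L B cells per litre (~1e8).
#' @param specific_fraction antigen-specific fraction of B cells, in \[0, 1\].
#' @return concentration (pM).
#' @examples
#' bcr_initial_conc(1e5, 1e8, 1)     # ~16.6 pM
#' bcr_initial_conc(1e5, 1e8, 1e-4)  # 0.01% antigen-specific
#' @export
bcr_initial_conc <- function(receptors_per_cell, bcells_per_L, specific_fraction) {
  check_scalar(receptors_per_cell, "receptors_per_cell", lower = 0)
  check_scalar(bcells_per_L, "bcells_per_L", lower = 0)
  check_scalar(specific_fraction, "specific_fraction", lower = 0, upper = 1)
  molecules_per_L_to_pM(receptors_per_cell * bcells_per_L * specific_fraction)
}

#' Per-step binding and dissociation rate schedule
#'
#' Binding rates are constant across steps (`k_i = k_on`); dissociation rates
#' decay exponentially with the number of receptors already bound,
#' `k_off_i = (k_on / Ka) * decay_base^(i - 1)`, reflecting stabilisation of
#' the complex by progressive cross-linking.
#'
#' @param k_on per-site binding rate (pM^-1 day^-1), > 0.
#' @param Ka association constant of the first binding step (pM^-1), > 0.
#' @param decay_base dissociation decay base per bound receptor, in (0, 1].
#' @param n valency.
#' @return list with numeric vectors `k_on` and `k_off`, each of length `n`.
#' @export
rate_schedule <- function(k_on, Ka, decay_base, n) {
  check_scalar(k_on, "k_on", lower = 0, strict_lower = TRUE)
  check_scalar(Ka, "Ka", lower = 0, strict_lower = TRUE)
  check_scalar(decay_base, "decay_base", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(n, "n", lower = 1, integer = TRUE)
  list(
    k_on = rep(k_on, n),
    k_off = (k_on / Ka) * decay_base^(seq_len(n) - 1)
  )
}

#' Parameters for the aggregate--BCR cross-linking model
#'
#' Bundles valency, rate schedule and initial conditions for the sequential
#' multivalent binding model. Concentrations are in pM, time in days.
#'
#' @param n aggregate valency (integer >= 1). Default 100, the upper end of
#'   reported aggregate sizes.
#' @param k_on per-site binding rate (pM^-1 day^-1). Default 8.64e-3.
#' @param Ka association constant k1/k-1 (pM^-1).
#' @param decay_base base of the exponential decay of the dissociation rate
#'   with the number of bound receptors. Default 0.5.
#' @param Aga0 initial aggregate concentration (pM).
#' @param BCR0 initial free-BCR concentration (pM). If `NULL`, computed from
#'   `receptors_per_cell`, `bcells_per_L` and `specific_fraction`.
#' @param receptors_per_cell BCR copies per B cell. Default 1e5.
#' @param bcells_per_L B cells per litre. Default 1e8.
#' @param specific_fraction antigen-specific fraction of B cells.
#' @return an object of class `crosslink_params`.
#' @examples
#' p <- crosslink_params(Ka = 1e-5, Aga0 = 12, specific_fraction = 1e-3)
#' @export
crosslink_params <- function(n = 100, k_on = 8.64e-3, Ka = 1e-5,
                             decay_base = 0.5, Aga0 = 12, BCR0 = NULL,
                             receptors_per_cell = 1e5, bcells_per_L = 1e8,
                             specific_fraction = NULL) {
  check_scalar(n, "n", lower = 1, integer = TRUE)
  check_scalar(Aga0, "Aga0", lower = 0)
  if (is.null(BCR0)) {
    if (is.null(specific_fraction))
      stop_invalid("either BCR0 or specific_fraction must be given")
    BCR0 <- bcr_initial_conc(receptors_per_cell, bcells_per_L, specific_fraction)
  } else {
    check_scalar(BCR0, "BCR0", lower = 0)
  }
  rates <- rate_schedule(k_on, Ka, decay_base, n)
  structure(
    list(
      n = as.integer(n), k_on = k_on, Ka = Ka, decay_base = decay_base,
      Aga0 = Aga0, BCR0 = BCR0,
      k_on_i = rates$k_on, k_off_i = rates$k_off,
      receptors_per_cell = receptors_per_cell,
      bcells_per_L = bcells_per_L,
      specific_fraction = specific_fraction,
      bcell_specific_conc = if (is.null(specific_fraction)) NA_real_
                            else bcells_per_L * specific_fraction
    ),
    class = "crosslink_params"
  )
}

#' @export
print.crosslink_params <- function(x, ...) {
  cat("Aggregate-BCR cross-linking parameters\n")
  cat(sprintf("  valency n            : %d\n", x$n))
  cat(sprintf("  k_on                 : %g pM^-1 day^-1\n", x$k_on))
  cat(sprintf("  Ka                   : %g pM^-1 (k_off_1 = %g day^-1)\n",
              x$Ka, x$k_off_i[1]))
  cat(sprintf("  dissociation decay   : %g per bound BCR\n", x$decay_base))
  cat(sprintf("  Aga0                 : %g pM\n", x$Aga0))
  cat(sprintf("  BCR0                 : %g pM\n", x$BCR0))
  invisible(x)
}
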