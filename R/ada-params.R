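#' Dosing regimen for the T-cell-dependent ADA model
#'
#' @param dose_mg dose per administration (mg). Default 40 (adalimumab-like
#'   case study); the dose-ranging analyses use 40, 4, 0.4 and 0.04 mg.
#' @param interval_days dosing interval (days). Default 14 (biweekly).
#' @param n_doses number of administrations. Default 13 (a ~6-month course).
#' @param mw molecular weight (g/mol) for the mg-to-pmol conversion.
#'   Default 150000 (IgG-class mAb).
#' @return object of class `ada_regimen`.
#' @export
ada_regimen <- function(dose_mg = 40, interval_days = 14, n_doses = 13,
                        mw = 150000) {
  check_scalar(dose_mg, "dose_mg", lower = 0)
  check_scalar(interval_days, "interval_days", lower = 0, strict_lower = TRUE)
  check_scalar(n_doses, "n_doses", lower = 1, integer = TRUE)
  check_scalar(mw, "mw", lower = 0, strict_lower = TRUE)
  structure(
    list(dose_mg = dose_mg, interval_days = interval_days,
         n_doses = as.integer(n_doses), mw = mw,
         dose_pmol = dose_mg * 1e9 / mw,
         dose_times = interval_days * (seq_len(n_doses) - 1)),
    class = "ada_regimen"
  )
}

#' An MHC II epitope of the therapeutic protein
#'
#' @param kd_nM dissociation constant of the peptide--MHC II interaction (nM).
#' @param copies copies of the epitope per drug molecule.
#' @return object of class `ada_epitope`.
#' @export
ada_epitope <- function(kd_nM, copies = 1) {
  check_scalar(kd_nM, "kd_nM", lower = 0, strict_lower = TRUE)
  check_scalar(copies, "copies", lower = 0, strict_lower = TRUE)
  structure(list(kd_nM = kd_nM, copies = copies), class = "ada_epitope")
}

#' Two-compartment pharmacokinetic parameters
#'
#' First-order absorption from a subcutaneous depot into a central
#' compartment, central--peripheral exchange, linear elimination, and an
#' ADA-complex-mediated elimination term proportional to total ADA times
#' drug. Amounts are in pmol; the central concentration (pmol / `Vc` litres
#' = pM) drives the subcellular module and B-cell antigen binding.
#'
#' @param ka absorption rate (day^-1).
#' @param k10 linear elimination rate (day^-1).
#' @param k12,k21 central-peripheral exchange rates (day^-1).
#' @param Vc central volume (L).
#' @param k_ada ADA-mediated elimination coefficient (day^-1 per ADA unit).
#' @return object of class `ada_pk`.
#' @export
ada_pk <- function(ka = 0.25, k10 = 0.05, k12 = 0.2, k21 = 0.2, Vc = 3,
                   k_ada = 1e-6) {
  for (nmv in c("ka", "k10", "k12", "k21", "k_ada"))
    check_scalar(get(nmv), nmv, lower = 0)
  check_scalar(Vc, "Vc", lower = 0, strict_lower = TRUE)
  structure(list(ka = ka, k10 = k10, k12 = k12, k21 = k21, Vc = Vc,
                 k_ada = k_ada),
            class = "ada_pk")
}

#' Subcellular antigen-processing parameters
#'
#' Endosomal antigen `E` follows `dE/dt = IR * C - DR * E` where `C` is the
#' plasma drug concentration (pM); each epitope's peptide pool follows
#' `dP_j/dt = copies_j * DR * E - peptide_decay * P_j`; surface MHC II-peptide
#' complexes load competitively onto a fixed surface capacity with a
#' saturable supply term and are lost at a rate proportional to the epitope's
#' MHC II dissociation constant (weaker binders fall off faster):
#' `dM_j/dt = k_load * MHC_free * P_j / (K_m + P_j) - k_surf * Kd_j * M_j`.
#'
#' @param IR internalization rate (day^-1). Default 14.4.
#' @param DR degradation rate (day^-1). Default 17.28.
#' @param epitopes list of [ada_epitope()] objects.
#' @param peptide_decay endosomal peptide loss rate (day^-1). Default 1.
#' @param mhc_total surface MHC II capacity (complexes per APC). Default 1e5.
#' @param k_load loading rate per free MHC II (day^-1). Default 0.05.
#' @param K_m peptide half-saturation of loading (peptide a.u.). Default 10.
#' @param k_surf surface loss coefficient (day^-1 nM^-1). Default 0.01.
#' @return object of class `ada_subcellular`.
#' @export
ada_subcellular <- function(IR = 14.4, DR = 17.28,
                            epitopes = list(ada_epitope(123), ada_epitope(85)),
                            peptide_decay = 1, mhc_total = 1e5,
                            k_load = 0.05, K_m = 10, k_surf = 0.01) {
  check_scalar(IR, "IR", lower = 0, strict_lower = TRUE)
  check_scalar(DR, "DR", lower = 0, strict_lower = TRUE)
  check_scalar(peptide_decay, "peptide_decay", lower = 0, strict_lower = TRUE)
  check_scalar(mhc_total, "mhc_total", lower = 0, strict_lower = TRUE)
  check_scalar(k_load, "k_load", lower = 0)
  check_scalar(K_m, "K_m", lower = 0, strict_lower = TRUE)
  check_scalar(k_surf, "k_surf", lower = 0, strict_lower = TRUE)
  stopifnot(length(epitopes) >= 1,
            all(vapply(epitopes, inherits, TRUE, "ada_epitope")))
  structure(
    list(IR = IR, DR = DR, epitopes = epitopes,
         kd_nM = vapply(epitopes, `[[`, 0, "kd_nM"),
         copies = vapply(epitopes, `[[`, 0, "copies"),
         peptide_decay = peptide_decay, mhc_total = mhc_total,
         k_load = k_load, K_m = K_m, k_surf = k_surf),
    class = "ada_subcellular"
  )
}

#' Cellular activation and ADA-production parameters
#'
#' Dendritic-cell maturation is a Hill function of the danger signal
#' (LPS-equivalent, ng). T help is proportional to mature DC times a
#' saturating function of the best-presented epitope (max over surface
#' MHC II-peptide complexes). B cells and ADA are split into `n_subgroups`
#' affinity subgroups on a geometric ladder of antigen-binding Kd; naive
#' cells sit mostly at the low-affinity end, activation of subgroup i scales
#' with T help and with drug occupancy at the subgroup's Kd, and activated
#' cells step up the ladder (affinity maturation) while differentiating into
#' antibody-secreting plasma cells.
#'
#' @param danger_signal danger-signal level (ng LPS-equivalent). Default 350.
#' @param ds_ec50 Hill EC50 of DC maturation (ng). Default 3500.
#' @param ds_hill Hill coefficient. Default 2.
#' @param thelp_gain T-help gain (scales activation). Default 1e4.
#' @param M50 half-saturation of T activation (complexes per APC). Default 5e5.
#' @param n_subgroups number of affinity subgroups. Default 17.
#' @param kd_low_pM highest-affinity (lowest Kd) rung of the ladder (pM).
#'   Default 1e2.
#' @param kd_high_pM lowest-affinity rung (pM). Default 1e6.
#' @param naive_pool naive B-cell pool size of the lowest-affinity subgroup
#'   (a.u.). Default 1.
#' @param naive_decay geometric decay of the naive pool per rung. Default 0.5.
#' @param k_act activation rate coefficient (day^-1). Default 1.
#' @param k_mat affinity-maturation transition rate up the ladder (day^-1).
#'   Default 0.5, strong enough that the maturation flux dominates the
#'   occupancy-weighted activation mix and the abundance-weighted mean ADA
#'   affinity rises over a course of treatment.
#' @param k_pc plasma-cell differentiation rate (day^-1). Default 0.2.
#' @param d_pc plasma-cell death rate (day^-1). Default 0.05.
#' @param k_sec ADA secretion rate per plasma cell (a.u. day^-1). Default 1.
#' @param d_ada ADA elimination rate (day^-1). Default 0.033 (IgG-like
#'   three-week half-life).
#' @return object of class `ada_cellular`; element `kd_ladder_pM` is the
#'   strictly decreasing ladder from `kd_high_pM` down to `kd_low_pM`.
#' @export
ada_cellular <- function(danger_signal = 350, ds_ec50 = 3500, ds_hill = 2,
                         thelp_gain = 1e4, M50 = 5e5, n_subgroups = 17,
                         kd_low_pM = 1e2, kd_high_pM = 1e6,
                         naive_pool = 1, naive_decay = 0.5,
                         k_act = 1, k_mat = 0.5, k_pc = 0.2, d_pc = 0.05,
                         k_sec = 1, d_ada = 0.033) {
  check_scalar(danger_signal, "danger_signal", lower = 0)
  check_scalar(ds_ec50, "ds_ec50", lower = 0, strict_lower = TRUE)
  check_scalar(ds_hill, "ds_hill", lower = 0, strict_lower = TRUE)
  check_scalar(n_subgroups, "n_subgroups", lower = 2, integer = TRUE)
  check_scalar(kd_low_pM, "kd_low_pM", lower = 0, strict_lower = TRUE)
  check_scalar(kd_high_pM, "kd_high_pM", lower = kd_low_pM, strict_lower = TRUE)
  ladder <- exp(seq(log(kd_high_pM), log(kd_low_pM), length.out = n_subgroups))
  structure(
    list(danger_signal = danger_signal, ds_ec50 = ds_ec50, ds_hill = ds_hill,
         thelp_gain = thelp_gain, M50 = M50,
         n_subgroups = as.integer(n_subgroups),
         kd_ladder_pM = ladder,
         naive = naive_pool * naive_decay^(seq_len(n_subgroups) - 1),
         k_act = k_act, k_mat = k_mat, k_pc = k_pc, d_pc = d_pc,
         k_sec = k_sec, d_ada = d_ada),
    class = "ada_cellular"
  )
}

#' Dendritic-cell maturation level for a danger signal
#'
#' @param danger_signal ng LPS-equivalent.
#' @param cell an [ada_cellular()] object.
#' @return maturation level in \[0, 1\].
#' @export
dc_maturation <- function(danger_signal, cell) {
  if (danger_signal <= 0) return(0)
  danger_signal^cell$ds_hill /
    (cell$ds_ec50^cell$ds_hill + danger_signal^cell$ds_hill)
}

#' Assemble a runnable ADA scenario
#'
#' @param name scenario label.
#' @param regimen an [ada_regimen()].
#' @param pk an [ada_pk()].
#' @param subcellular an [ada_subcellular()].
#' @param cellular an [ada_cellular()].
#' @param reference optional name of the reference scenario for fold-change
#'   reporting.
#' @param t_end simulation horizon (days). Default 182.
#' @param dt_out output grid spacing (days). Default 0.1.
#' @return object of class `ada_scenario`.
#' @export
ada_scenario <- function(name = "default",
                         regimen = ada_regimen(),
                         pk = ada_pk(),
                         subcellular = ada_subcellular(),
                         cellular = ada_cellular(),
                         reference = NULL,
                         t_end = 182, dt_out = 0.1) {
  stopifnot(inherits(regimen, "ada_regimen"), inherits(pk, "ada_pk"),
            inherits(subcellular, "ada_subcellular"),
            inherits(cellular, "ada_cellular"))
  check_scalar(t_end, "t_end", lower = 0, strict_lower = TRUE)
  structure(
    list(name = name, regimen = regimen, pk = pk, subcellular = subcellular,
         cellular = cellular, reference = reference,
         t_end = t_end, dt_out = dt_out),
    class = "ada_scenario"
  )
}
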