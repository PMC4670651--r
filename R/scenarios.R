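#' List the available scenario presets
#'
#' Presets are shipped as data files so every number they carry can be
#' audited directly; each corresponds to one of the package's headline
#' analyses (cross-linking sweep, danger-signal ladder, processing-rate
#' perturbations, epitope number, epitope affinity, dose ranging).
#'
#' @return character vector of preset names.
#' @export
list_presets <- function() {
  dir_path <- system.file("extdata", "presets", package = "aggimmuno")
  sort(sub("\\.yaml$", "", list.files(dir_path, pattern = "\\.yaml$")))
}

.read_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "aggimmuno")
  if (!nzchar(path) || !file.exists(path))
    stop_invalid("unknown preset '", name, "'; see list_presets()")
  yaml::read_yaml(path)
}

.scenario_from_spec <- function(spec, reference, dose_mg = 40) {
  IR0 <- 14.4
  DR0 <- 17.28
  kd <- spec$epitopes_kd_nM
  sub <- ada_subcellular(
    IR = IR0 * (spec$IR_mult %||% 1),
    DR = DR0 * (spec$DR_mult %||% 1),
    epitopes = if (is.null(kd)) list(ada_epitope(123), ada_epitope(85))
               else lapply(kd, ada_epitope)
  )
  ada_scenario(
    name = spec$name,
    regimen = ada_regimen(dose_mg = dose_mg),
    subcellular = sub,
    cellular = ada_cellular(danger_signal = spec$danger_signal %||% 350),
    reference = reference
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the runnable configurations of a named preset
#'
#' For ADA presets, returns a list of [ada_scenario()] objects (one per
#' condition, crossed with dose levels where the preset ranges over doses),
#' each carrying the name of its reference scenario. For the cross-linking
#' preset, returns the argument list for [sweep_stc()].
#'
#' @param name a preset name from [list_presets()].
#' @return a list of scenarios (class `ada_scenario`), or for
#'   `"fig2"` a list of sweep arguments.
#' @examples
#' \donttest{
#' length(build_preset("fig5"))  # 3 conditions
#' }
#' @export
build_preset <- function(name) {
  preset <- .read_preset(name)
  if (identical(preset$kind, "crosslink_sweep")) {
    return(list(
      Ka = as.numeric(preset$Ka_pM_inv),
      Aga0 = as.numeric(preset$Aga0_pM),
      specific_fraction = as.numeric(preset$specific_fraction),
      s = as.integer(preset$s),
      n = preset$valency, k_on = preset$k_on, decay_base = preset$decay_base,
      t_end = preset$t_end
    ))
  }
  if (!is.null(preset$doses_mg)) {
    out <- list()
    for (dose in preset$doses_mg) {
      ref <- sprintf("%s_%gmg", preset$reference_by_dose, dose)
      for (spec in preset$scenarios) {
        spec2 <- spec
        spec2$name <- sprintf("%s_%gmg", spec$name, dose)
        out[[spec2$name]] <- .scenario_from_spec(spec2, ref, dose_mg = dose)
      }
    }
    return(out)
  }
  out <- lapply(preset$scenarios, .scenario_from_spec,
                reference = preset$reference)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Random parameter grid for property-based testing
#'
#' Samples cross-linking scenarios inside the physiological bounds: total
#' drug 500 to 1e5 pM and association constant log-uniform, aggregation
#' fraction 2 to 15%, valency 10 to 100, antigen-specific fraction
#' log-uniform up to 1%.
#'
#' @param n_scenarios number of rows.
#' @param seed RNG seed (grid is reproducible given the seed).
#' @param ranges optional overrides: list with elements `Ag_total`, `p`,
#'   `n`, `Ka`, `specific_fraction`, each a length-2 range.
#' @return data.frame with columns `Ag_total`, `p`, `n`, `Ka`,
#'   `specific_fraction`, `Aga0`.
#' @export
random_grid <- function(n_scenarios = 10, seed = 1L, ranges = list()) {
  defaults <- list(
    Ag_total = c(500, 1e5), p = c(0.02, 0.15), n = c(10, 100),
    Ka = c(1e-7, 1e-3), specific_fraction = c(1e-7, 1e-2)
  )
  r <- utils::modifyList(defaults, ranges)
  for (nm in names(defaults))
    if (length(r[[nm]]) != 2 || r[[nm]][1] > r[[nm]][2])
      stop_invalid("invalid range for ", nm)
  set.seed(seed)
  runif_log <- function(lim) exp(stats::runif(n_scenarios, log(lim[1]), log(lim[2])))
  g <- data.frame(
    Ag_total = runif_log(r$Ag_total),
    p = stats::runif(n_scenarios, r$p[1], r$p[2]),
    n = sample(seq(r$n[1], r$n[2]), n_scenarios, replace = TRUE),
    Ka = runif_log(r$Ka),
    specific_fraction = runif_log(r$specific_fraction)
  )
  g$Aga0 <- mapply(initial_aggregate_conc, g$Ag_total, g$p, g$n)
  g
}
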