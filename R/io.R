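#' Load and validate a sweep/scenario configuration file
#'
#' Reads a YAML configuration, fills unspecified fields from the package
#' defaults, and validates ranges: the aggregation fraction must lie in the
#' physiological 2--15% window unless `allow_out_of_range` is set.
#'
#' @param path YAML file path.
#' @param allow_out_of_range skip the physiological range checks.
#' @return validated configuration list.
#' @export
load_config <- function(path, allow_out_of_range = FALSE) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$kind)) stop_invalid("config field 'kind' is required")
  if (identical(cfg$kind, "crosslink_sweep")) {
    # the valency key is spelled out: a bare `n` is a YAML 1.1 boolean
    defaults <- list(Ka_pM_inv = c(1e-7, 1e-5, 1e-3), Aga0_pM = c(0.1, 12, 1500),
                     specific_fraction = 10^seq(-7, -2), s = c(2, 5, 10),
                     valency = 100, k_on = 8.64e-3, decay_base = 0.5, t_end = 100)
    cfg <- utils::modifyList(defaults, cfg)
    if (!is.null(cfg$p) && !allow_out_of_range &&
        any(cfg$p < 0.02 | cfg$p > 0.15))
      stop_invalid("config field 'p' outside the physiological range [0.02, 0.15]")
    if (any(cfg$specific_fraction <= 0 | cfg$specific_fraction > 1))
      stop_invalid("config field 'specific_fraction' must be in (0, 1]")
    if (cfg$decay_base <= 0 || cfg$decay_base > 1)
      stop_invalid("config field 'decay_base' must be in (0, 1]")
  }
  cfg
}

# 10 significant digits gives byte-stable numeric output across runs
.format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

#' Write a result table with a reproducibility manifest
#'
#' Writes a CSV with fixed column order and numbers formatted at 10
#' significant digits (so identical runs produce identical bytes), plus a
#' JSON manifest recording the package version, seed, timestamp and an MD5
#' checksum of the result file.
#'
#' @param table a data.frame.
#' @param path output CSV path.
#' @param seed seed associated with the run (recorded only).
#' @param manifest_path manifest path; default `<path>.manifest.json`.
#' @return invisibly, the manifest list.
#' @export
write_results <- function(table, path, seed = NA_integer_,
                          manifest_path = paste0(path, ".manifest.json")) {
  stopifnot(is.data.frame(table))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- table
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], .format_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "aggimmuno",
    version = as.character(utils::packageVersion("aggimmuno")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = list(list(path = basename(path),
                      md5 = unname(tools::md5sum(path)),
                      rows = nrow(table)))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
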