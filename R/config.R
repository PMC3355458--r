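#' Analysis run configuration
#'
#' Bundles every tunable of the pipeline — filter specs, segmentation,
#' feature and classification thresholds, asymmetry flagging, generator
#' defaults and the seed — into one serialisable structure. Unknown keys
#' are rejected on construction and on load, so a typo in a config file
#' fails loudly instead of silently using a default.
#'
#' @param ... Named overrides of any default, nested as in the returned
#'   structure (e.g. `filters = list(accel_cutoff_hz = 3)`).
#' @return An object of class `ski_config` (nested named list).
#' @export
ski_config <- function(...) {
  base <- list(
    filters = list(accel_cutoff_hz = 2.0, gyro_cutoff_hz = 1.0,
                   order = 4L, zero_phase = TRUE),
    segmentation = list(min_prom_sidea = 0.1, min_prom_yaw = 20),
    features = list(sidea_min_g = 0.1, cv_max = 0.5,
                    poling_level_dps = 45, timing_prom_dps = 20),
    classify = unclass(rule_thresholds()),
    asymmetry = list(flag_threshold = 0.15, min_half_cycles = 3L),
    generator = list(duration_s = 20, trunk_lean_deg = 15,
                     asymmetry_ratio = 1.0, tap_marker = TRUE),
    seed = 1L,
    verbosity = 1L
  )
  merged <- merge_config(base, list(...), path = "")
  structure(merged, class = "ski_config")
}

merge_config <- function(base, override, path) {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste(path, unknown, sep = ".")), collapse = ", "),
         call. = FALSE)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]],
                                 paste(path, nm, sep = "."))
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated [ski_config()];
#'   `write_config()` invisibly returns `path`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(ski_config, raw)
}

#' @rdname read_config
#' @param config A [ski_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ski_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.ski_config <- function(x, ...) {
  cat("<ski_config>\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# helpers mapping a config onto the pipeline functions
config_filter_specs <- function(config) {
  list(accel = filter_spec(config$filters$accel_cutoff_hz,
                           config$filters$order, config$filters$zero_phase),
       gyro = filter_spec(config$filters$gyro_cutoff_hz,
                          config$filters$order, config$filters$zero_phase))
}

config_thresholds <- function(config) do.call(rule_thresholds, config$classify)
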