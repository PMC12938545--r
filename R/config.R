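#' Load and hash a pipeline run configuration
#'
#' Run configurations are YAML files with blocks `phantom` (arguments of
#' [phantom_spec()]), `plugs` (arguments of [plug_config()] plus
#' `n_plugs_per_scan`), `transfer` (depth-matching tolerance), `augment`
#' and `dataset` (patch ratio/size, target spacing). Unset keys fall back
#' to the packaged defaults (`inst/extdata/default_config.yaml`), whose
#' values mirror the simulated-cohort study conditions: sampling ranges
#' 2-20 mm / 0.35-1.0 / 1-20 mm, 50 plugs per scan, 0.8 mm isotropic
#' resampling.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A `run_config` list with elements `phantom` ([phantom_spec]),
#'   `plugs` ([plug_config]), `n_plugs_per_scan`, `transfer`, `augment`,
#'   `dataset`, and `hash`.
#' @export
load_run_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                          package = "plugsim"))
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  merged <- modifyList(defaults, user)
  cfg <- list(
    phantom = do.call(phantom_spec, merged$phantom %||% list()),
    plugs = do.call(plug_config, merged$plugs[setdiff(names(merged$plugs),
                                                      "n_plugs_per_scan")] %||% list()),
    n_plugs_per_scan = merged$plugs$n_plugs_per_scan %||% 50L,
    transfer = merged$transfer %||% list(tolerance_mm = 0.5),
    augment = merged$augment %||% list(smooth_sigma_range_mm = c(0, 0.8),
                                       noise_sigma_range_hu = c(0, 10)),
    dataset = merged$dataset %||% list(ratio = c(1, 1), patch_size = 96L,
                                       target_mm = 0.8))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config Any serializable R object.
#' @export
config_hash <- function(config) {
  config$hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_all(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_all) else x
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d plugs/scan, hash %s\n",
              x$n_plugs_per_scan, substr(x$hash, 1, 12)))
  print(x$phantom)
  invisible(x)
}
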