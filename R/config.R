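#' Read a simulator / pipeline configuration file
#'
#' YAML key-value configuration covering layout geometry, the response
#' model, chemistry and catalogue seeds, and session settings. Missing
#' keys fall back to package defaults, so a config may specify only
#' what it overrides.
#'
#' @param path YAML file path.
#' @return List with components `layout` (`chip_layout`), `model`
#'   (`response_model`), `chemistries`, `catalog`, and `session` (list
#'   of `seed`, `replicates`, `source`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lay_args <- cfg$layout %||% list()
  layout <- do.call(default_layout, lay_args)
  model <- do.call(response_model, cfg$response_model %||% list())
  chem_seed <- cfg$chemistry_seed %||% 1L
  cat_seed <- cfg$catalog_seed %||% 42L
  session <- utils::modifyList(
    list(seed = 1L, replicates = 3L, source = "signal"),
    cfg$session %||% list())
  list(layout = layout, model = model,
       chemistries = default_chemistries(chem_seed),
       catalog = default_catalog(cat_seed),
       session = session)
}

#' Write a template configuration file with all defaults spelled out
#'
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  cfg <- list(
    layout = list(slit_width_um = 25, slit_height_um = 500,
                  pitch_um = 750, px_per_aperture = 6L, px_gap = 4L),
    response_model = list(bulk_sensitivity = 250, dip_depth = 0.5,
                          dip_fwhm = 80, intensity_noise_sd = 0.005,
                          lambda_noise_sd = 0.04,
                          baseline_drift_rate = 0,
                          carryover_fraction = 0),
    chemistry_seed = 1L,
    catalog_seed = 42L,
    session = list(seed = 1L, replicates = 3L, source = "signal")
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
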