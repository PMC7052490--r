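#' Read a run configuration file
#'
#' Loads a YAML or JSON configuration (decided by extension) holding the
#' knobs of a search run. Recognised keys: `currency_compounds` (character
#' list replacing the default currency set), `weight_measure` (`mean`,
#' `median` or `sv`), `min_mean_expression` (unexpressed-gene threshold),
#' `max_reactions`, `top_k` and `criterion`. Unknown keys are rejected so
#' typos fail loudly. Missing keys fall back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for pure
#'   defaults.
#' @return A named list with all six keys populated.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    currency_compounds = default_currency_set(),
    weight_measure = "mean",
    min_mean_expression = 1,
    max_reactions = 8,
    top_k = 10,
    criterion = "bottleneck"
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "metaroutr_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "metaroutr_config_error")
  }
  utils::modifyList(defaults, cfg)
}
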