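#' Read a flat key-value experiment configuration
#'
#' Parses a plain-text configuration of `key = value` lines. `#` starts a
#' comment; blank lines are ignored; values holding commas become vectors;
#' numeric and logical values are auto-converted (`yes`/`no` map to
#' logical). Recognized keys:
#'
#' \describe{
#'   \item{`factor.<name>`}{levels of a design factor (`rcp`,
#'     `disturbance_response`, `forest_age`, `forest_type`,
#'     `harvest_intensity`, `salvage`, `material_usage`, `cascade`,
#'     `decarb_2050`); omitted factors keep the default levels.}
#'   \item{`run.n_patches`, `run.n_sites`, `run.seed`, `run.horizons`}{
#'     ensemble settings.}
#'   \item{`stand.<field>`}{overrides for [stand_params()] constants, e.g.
#'     `stand.npp_max`, `stand.carrying_capacity`, `stand.q10`.}
#' }
#'
#' @param path configuration file path.
#' @return named list of parsed values, class `forestmit_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop_config("malformed config line (expected key = value): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    low <- tolower(parts)
    if (all(low %in% c("yes", "no", "true", "false"))) {
      parts <- low %in% c("yes", "true")
    } else {
      num <- suppressWarnings(as.numeric(parts))
      if (!anyNA(num)) parts <- num
    }
    out[[key]] <- parts
  }
  class(out) <- c("forestmit_config", "list")
  out
}

#' Factor levels specified by a configuration
#'
#' @param config a [read_config()] list.
#' @return named list of levels for [enumerate_scenarios()], with defaults
#'   for factors the config does not mention.
#' @export
config_factor_levels <- function(config) {
  levels <- scenario_factor_levels()
  for (key in grep("^factor\\.", names(config), value = TRUE)) {
    f <- sub("^factor\\.", "", key)
    if (!f %in% names(levels)) stop_config("unknown factor in config: ", f)
    levels[[f]] <- config[[key]]
  }
  levels
}

config_run_args <- function(config) {
  args <- list()
  if (!is.null(config$`run.n_patches`))
    args$n_patches <- as.integer(config$`run.n_patches`)
  if (!is.null(config$`run.n_sites`))
    args$n_sites <- as.integer(config$`run.n_sites`)
  if (!is.null(config$`run.seed`)) args$seed <- as.integer(config$`run.seed`)
  if (!is.null(config$`run.horizons`)) args$horizons <- config$`run.horizons`
  stand_keys <- grep("^stand\\.", names(config), value = TRUE)
  if (length(stand_keys)) {
    pa <- config[stand_keys]
    names(pa) <- sub("^stand\\.", "", stand_keys)
    args$params_args <- pa
  }
  args
}
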