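# CSV dataset reading/writing and run-configuration handling.
# Dialect is fixed: comma separator, dot decimal, one mandatory header line.

DATASET_COLUMNS <- c("phi_deg", "theta_deg", "r_mm", "v_kv", "kerma")

#' Read a kerma dataset (or query) CSV
#'
#' Validates the header and every cell; a malformed value is reported with
#' its file line number and column name.
#'
#' @param path CSV file path.
#' @param require_kerma if `FALSE`, the `kerma` column is optional (query
#'   files carry positions and voltage only).
#' @return data frame with numeric columns.
#' @export
read_dataset_csv <- function(path, require_kerma = TRUE) {
  if (!file.exists(path)) abort(sprintf("dataset file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- if (require_kerma) DATASET_COLUMNS else setdiff(DATASET_COLUMNS, "kerma")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    abort(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  out <- raw
  for (col in names(raw)) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad) > 0L)
      abort(sprintf("malformed value %s at line %d, column %s",
                    dQuote(raw[[col]][bad[1L]]), bad[1L] + 1L, col))
    if (anyNA(vals))
      abort(sprintf("missing value at line %d, column %s",
                    which(is.na(vals))[1L] + 1L, col))
    out[[col]] <- vals
  }
  out
}

#' Write a kerma dataset CSV
#'
#' Values are written with 17 significant digits so a read/write round trip
#' preserves every double exactly.
#'
#' @param dataset data frame of numeric columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  fmt <- as.data.frame(lapply(dataset, function(col) {
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col
  }), check.names = FALSE)
  utils::write.table(fmt, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

default_run_config <- function() {
  list(
    grid = list(tangent_angles_deg = seq(0, 20, by = 2),
                polar_angles_deg = seq(0, 360, by = 15),
                distances_mm = c(250, 500, 750, 1000, 1250),
                voltages_kv = c(40, 60, 80, 100, 120, 140)),
    surrogate = list(noise_sigma = 0.04),
    training = list(width_k = 4L, max_layers = 2L, inner_split = 0.7,
                    growth = "compose", target_transform = "none",
                    pool_cap = 24L),
    split_fraction = 0.7,
    seed = 1L
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      abort(sprintf("unknown config key: %s", full))
    if (is.list(base[[key]]) && is.list(override[[key]]))
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    else base[[key]] <- override[[key]]
  }
  base
}

#' Load a run configuration
#'
#' Starts from the built-in defaults (the study grid, 4 percent noise,
#' width 4 / depth 2 training, 0.7 split), overlays a YAML or JSON config
#' file if given, then overlays explicit overrides. Unknown keys are
#' rejected. Precedence: override > file > default.
#'
#' @param path optional path to a `.yaml`/`.yml` or `.json` config file.
#' @param overrides optional named list applied last.
#' @return the merged configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    ext <- tolower(tools::file_ext(path))
    file_cfg <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      abort(sprintf("unsupported config format: .%s", ext)))
    cfg <- merge_config(cfg, file_cfg)
  }
  merge_config(cfg, overrides)
}

config_grid_spec <- function(cfg) {
  do.call(grid_spec, cfg$grid)
}

config_surrogate_params <- function(cfg) {
  do.call(surrogate_params, cfg$surrogate)
}

config_control <- function(cfg) {
  do.call(gmdh_control, cfg$training)
}
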