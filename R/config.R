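#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline. Stage parameters that the
#' reference recipe fixes are the defaults here: RBF scale sigma 5 mm,
#' F-beta loss at beta 1, learning rate 2e-4, at most 150 epochs, batch
#' size 1, 50-voxel cluster cut, rotation angles restricted to multiples of
#' 90 degrees. Test-scale defaults (small phantoms, reduced network) keep a
#' full run in CPU minutes.
#'
#' @param ... named overrides, e.g. \code{model = list(depth = 3)};
#'   unknown section or key names are rejected.
#' @param seed global seed fanned out to per-stage seeds by
#'   \code{derive_seed}.
#' @return a \code{run_config} nested list.
#' @export
run_config <- function(..., seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    phantom = list(n_slices = 12L, height = 96L, width = 96L,
                   pixel_spacing = 0.5, slice_spacing = 1.0, n_masses = 2L,
                   mass_radius_range = c(4, 8), site_profile = "H1"),
    preprocess = list(enabled = FALSE, r_close = 4L, r_open = 14L,
                      sigma_mm = 5, exclusion_mm = 5),
    patches = list(patch_h = 76L, patch_w = 76L, stride = 36L,
                   mass_fraction_threshold = 0.05),
    model = list(depth = 3L, base_channels = 8L, n_classes = 2L),
    training = list(learning_rate = 2e-4, max_epochs = 150L, beta = 1,
                    batch_size = 1L, augment = TRUE, per_epoch_n = NULL),
    fusion = list(scheme = "max_prob"),
    postprocess = list(threshold = 0.5, min_voxels = 50L, window = 3L,
                       connectivity = 26L),
    evaluate = list(folds = 5L, n_thresholds = 200L))
  over <- list(...)
  cfg <- defaults
  for (sec in names(over)) {
    if (!sec %in% names(defaults))
      stop("unknown config section '", sec, "'; valid sections: ",
           paste(names(defaults), collapse = ", "))
    if (sec == "seed") { cfg$seed <- as.integer(over$seed); next }
    for (key in names(over[[sec]])) {
      if (!key %in% names(defaults[[sec]]))
        stop("unknown config key '", sec, ".", key, "'; valid keys: ",
             paste(names(defaults[[sec]]), collapse = ", "))
      cfg[[sec]][key] <- list(over[[sec]][[key]])
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$training$learning_rate <= 0)
    stop("invalid value for training.learning_rate: must be > 0")
  if (cfg$training$max_epochs < 1)
    stop("invalid value for training.max_epochs: must be >= 1")
  if (cfg$postprocess$threshold < 0 || cfg$postprocess$threshold > 1)
    stop("invalid value for postprocess.threshold: must lie in [0, 1]")
  if (cfg$preprocess$sigma_mm <= 0)
    stop("invalid value for preprocess.sigma_mm: must be > 0")
  schemes <- c("majority", "max_prob", "sum_prob", "connectivity")
  if (!cfg$fusion$scheme %in% schemes)
    stop("invalid value for fusion.scheme: must be one of ",
         paste(schemes, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Load / save a pipeline configuration
#'
#' Configurations are stored as JSON (nested sections) or INI-style text
#' (\code{[section]} headers, \code{key = value} lines; values parsed as
#' JSON scalars/vectors). Missing keys take their defaults; unknown keys
#' are rejected. An empty file yields the all-defaults configuration.
#'
#' @param path config file; extension \code{.json} selects JSON, anything
#'   else is parsed as INI.
#' @return a \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    raw <- parse_ini(path)
  }
  seed <- if (!is.null(raw$seed)) raw$seed else 1L
  raw$seed <- NULL
  do.call(run_config, c(raw, list(seed = seed)))
}

parse_ini <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^[;#]", lines)]
  out <- list(); sec <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      parsed <- tryCatch(jsonlite::fromJSON(val), error = function(e) val)
      if (is.null(sec)) out[[key]] <- parsed else out[[sec]][[key]] <- parsed
    }
  }
  out
}

#' @rdname load_config
#' @param config a \code{run_config} to serialize.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
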