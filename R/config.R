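config_schema <- function() {
  list(
    seed = list(type = "integer", default = 1L),
    out_dir = list(type = "character", default = "covrf-out"),
    kernel_bank = list(
      orientations = list(type = "integer", default = 4L),
      scales = list(type = "integer", default = 4L),
      skews = list(type = "integer", default = 3L),
      derivative_set = list(type = "character",
                            default = c("par", "perp", "mixed")),
      sigma_base = list(type = "numeric", default = 1),
      supersample_resolution = list(type = "integer", default = 81L)),
    neuron = list(
      mu = list(type = "numeric", default = 2, positive = TRUE),
      theta_thr = list(type = "numeric", default = 1),
      theta_reset = list(type = "numeric", default = 0),
      mu_r = list(type = "numeric", default = 0),
      dt = list(type = "numeric", default = 1, positive = TRUE),
      surrogate_slope = list(type = "numeric", default = 10)),
    temporal_scales = list(
      K = list(type = "integer", default = 4L),
      mu_min = list(type = "numeric", default = 1, positive = TRUE),
      mu_max = list(type = "numeric", default = 4, positive = TRUE),
      spacing = list(type = "character", default = "endpoint")),
    simulator = list(
      resolution = list(type = "integer", default = 300L),
      factor = list(type = "integer", default = 8L),
      n_frames = list(type = "integer", default = 50L),
      noise_rate = list(type = "numeric", default = 5),
      noise_convention = list(type = "character", default = "per_movie"),
      threshold = list(type = "numeric", default = 0.115, positive = TRUE),
      start_size = list(type = "numeric", default = 17, positive = TRUE),
      translation_scale = list(type = "numeric", default = 0.50)),
    network = list(
      n_scale_channels = list(type = "integer", default = 4L),
      kernels_per_block = list(type = "integer", default = 144L),
      kernel_size = list(type = "integer", default = 9L),
      n_output_shapes = list(type = "integer", default = 3L),
      variant = list(type = "character", default = "LI"),
      init = list(type = "character", default = "rf"),
      mf_frames = list(type = "integer", default = 8L),
      use_batchnorm = list(type = "logical", default = FALSE),
      head_weighting = list(type = "character", default = "softmax")),
    training = list(
      epochs = list(type = "integer", default = 50L),
      batch_size = list(type = "integer", default = 16L),
      learning_rate = list(type = "numeric", default = 1e-3),
      n_runs = list(type = "integer", default = 5L),
      validation_fraction = list(type = "numeric", default = 0.2)))
}

is_leaf_spec <- function(x) is.list(x) && !is.null(x$type)

validate_section <- function(values, schema, path = character()) {
  out <- list()
  for (nm in names(schema)) {
    spec <- schema[[nm]]
    here <- paste(c(path, nm), collapse = ".")
    if (is_leaf_spec(spec)) {
      v <- if (!is.null(values[[nm]])) values[[nm]] else spec$default
      v <- switch(spec$type,
        integer = {
          if (!is.numeric(v) || any(v != round(v))) {
            stop("config: field '", here, "' must be an integer")
          }
          as.integer(v)
        },
        numeric = {
          if (!is.numeric(v)) stop("config: field '", here,
                                   "' must be numeric")
          as.numeric(v)
        },
        logical = {
          if (!is.logical(v)) stop("config: field '", here,
                                   "' must be logical")
          v
        },
        character = as.character(v))
      if (isTRUE(spec$positive) && any(v <= 0)) {
        stop("config: field '", here, "' must be positive")
      }
      out[[nm]] <- v
    } else {
      out[[nm]] <- validate_section(
        if (!is.null(values[[nm]])) values[[nm]] else list(),
        spec, c(path, nm))
    }
  }
  extra <- setdiff(names(values), names(schema))
  if (length(extra)) {
    stop("config: unknown key(s) ",
         paste(paste(c(path, ""), collapse = "."), extra, sep = "",
               collapse = ", "),
         "; valid keys here: ", paste(names(schema), collapse = ", "))
  }
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills every missing field with its
#' documented default (so the returned object carries full provenance of the
#' run parameters), rejects unknown keys, and validates types and simple
#' constraints (e.g. positive time constants).
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return a validated nested configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  values <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("load_config: no such file: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  structure(validate_section(values, config_schema()), class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  # stable content hash of the fully-defaulted configuration
  s <- yaml::as.yaml(unclass(config))
  raw <- utf8ToInt(s)
  h <- 5381
  for (ch in raw) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest
#'
#' Records the seed, the configuration (and its hash), the package version
#' and the artifact paths of a finished run as JSON, so figure-style outputs
#' can be regenerated from the manifest alone. Artifacts that do not exist at
#' manifest time are listed with a warning entry.
#'
#' @param outputs character vector of artifact paths the run produced.
#' @param config the `run_config` of the run.
#' @param path output JSON path.
#' @return invisibly, the manifest list.
#' @export
run_manifest <- function(outputs, config, path) {
  missing <- outputs[!file.exists(outputs)]
  manifest <- list(
    package = "covrf",
    version = as.character(utils::packageVersion("covrf")),
    seed = config$seed,
    config_hash = config_hash(config),
    config = unclass(config),
    artifacts = as.list(outputs),
    warnings = if (length(missing)) {
      as.list(paste("missing artifact:", missing))
    } else list())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
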