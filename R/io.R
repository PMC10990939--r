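# Configuration loading and result writing: YAML configs validated against a
# fixed schema, CSV/JSON outputs with a content-hash manifest.

config_schema <- function() {
  list(
    stage = list(type = "character", default = NULL, required = TRUE),
    seed = list(type = "numeric", default = 1),
    out_dir = list(type = "character", default = "results"),
    inputs = list(type = "list", default = list()),
    geometry = list(type = "list", default = list(),
                    keys = c("height", "width", "thickness", "n_fractions",
                             "bottom_probe_height")),
    thermal = list(type = "list", default = list(),
                   keys = c("T_cold", "T_hot")),
    solver = list(type = "list", default = list(),
                  keys = c("nx", "ny", "n_steps")),
    network = list(type = "list", default = list(),
                   keys = c("N_x", "N_y", "delta_T", "Q_in_nl_s", "Z",
                            "repeats")))
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, rejects unknown keys (top-level and within the typed
#' blocks), fills documented defaults, and returns a validated `run_config`.
#' Valid stages are the pipeline stages: `"synth"`, `"fit_soret"`,
#' `"simulate_chamber"`, `"build_table"`, `"simulate_network"`,
#' `"fit_rates"`, `"react_network"`.
#'
#' @param path path to a YAML file.
#' @return an object of class `run_config` (a named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  sch <- config_schema()
  unknown <- setdiff(names(raw), names(sch))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- list()
  for (nm in names(sch)) {
    spec <- sch[[nm]]
    val <- raw[[nm]] %||% spec$default
    if (is.null(val) && isTRUE(spec$required)) {
      stop("config key '", nm, "' is required")
    }
    if (!is.null(val) && spec$type == "numeric" && !is.numeric(val)) {
      stop("config key '", nm, "' must be numeric")
    }
    if (!is.null(val) && spec$type == "list" && !is.null(spec$keys)) {
      bad <- setdiff(names(val), spec$keys)
      if (length(bad)) {
        stop("unknown keys in config block '", nm, "': ",
             paste(bad, collapse = ", "))
      }
    }
    cfg[[nm]] <- val
  }
  stages <- c("synth", "fit_soret", "simulate_chamber", "build_table",
              "simulate_network", "fit_rates", "react_network")
  if (!cfg$stage %in% stages) {
    stop("unknown stage '", cfg$stage, "'; must be one of: ",
         paste(stages, collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write result tables with a content-hash manifest
#'
#' Writes each element of `tables` to `out_dir`: data.frames as CSV,
#' everything else as JSON. A `manifest.json` records the md5 hash of every
#' file plus the resolved configuration, making reruns verifiable
#' bit-for-bit for deterministic stages.
#'
#' @param tables named list of data.frames / lists.
#' @param out_dir output directory (created if missing).
#' @param config optional `run_config` to embed in the manifest.
#' @param force overwrite existing files (otherwise a collision errors).
#' @return invisibly, the manifest list.
#' @export
write_results <- function(tables, out_dir, config = NULL, force = FALSE) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) stop("tables must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (nm in names(tables)) {
    x <- tables[[nm]]
    fn <- file.path(out_dir,
                    paste0(nm, if (is.data.frame(x)) ".csv" else ".json"))
    if (file.exists(fn) && !force) {
      stop("output exists (use force = TRUE): ", fn)
    }
    if (is.data.frame(x)) {
      utils::write.csv(x, fn, row.names = FALSE)
    } else {
      jsonlite::write_json(x, fn, digits = NA, auto_unbox = TRUE,
                           null = "null")
    }
    entries[[nm]] <- list(file = basename(fn),
                          md5 = unname(tools::md5sum(fn)))
  }
  manifest <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version =
                     as.character(utils::packageVersion("thermotrap")),
                   config = if (!is.null(config)) unclass(config),
                   files = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
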