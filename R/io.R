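# Readers and writers for the package's plain-text interchange formats:
# long-format trajectory CSV, and fluid/device presets as YAML or JSON.

.required_cols <- c("strip_id", "capillary_id", "time_s", "height_mm",
                    "length_mm")

#' Read observed trajectories from a long-format CSV
#'
#' Expected schema: columns `strip_id`, `capillary_id`, `time_s`,
#' `height_mm`, `length_mm` (extra columns such as `fluid` and `device` are
#' carried through as trajectory attributes). Malformed rows (non-finite
#' time or height, negative height) are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Named list of [trajectory()] objects, one per
#'   `strip_id`/`capillary_id` pair, named `"<strip_id>/<capillary_id>"`.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path))
    stop(sprintf("dataset not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.required_cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("dataset %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$height_mm) |
                 df$height_mm < 0)
  if (length(bad) > 0L)
    stop(sprintf("malformed rows in %s at line(s): %s", path,
                 paste(utils::head(bad + 1L, 20L), collapse = ", ")),
         call. = FALSE)
  trajectories_from_data(df)
}

#' @rdname read_trajectories
#' @param df A data frame in the long schema (e.g. from
#'   [simulate_experiment()]).
#' @export
trajectories_from_data <- function(df) {
  stopifnot(all(.required_cols %in% names(df)))
  key <- paste(df$strip_id, df$capillary_id, sep = "/")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    tr <- trajectory(t = d$time_s, H = d$height_mm, L = d$length_mm,
                     strip_id = d$strip_id[1], capillary_id = d$capillary_id[1])
    if ("fluid" %in% names(d)) attr(tr, "fluid_name") <- d$fluid[1]
    if ("device" %in% names(d)) attr(tr, "device_name") <- d$device[1]
    tr
  })
  out[order(names(out))]
}

# --- preset serialization ---------------------------------------------------

.fluid_to_list <- function(fl) {
  list(name = fl$name, rho_g_ml = fl$rho / 1000, mu_cp = pas_to_cp(fl$mu),
       gamma_cos_theta = fl$gamma_cos_theta,
       assumed = isTRUE(attr(fl, "assumed")))
}

.fluid_from_list <- function(x) {
  fl <- fluid_properties(x$name, rho = x$rho_g_ml, mu = x$mu_cp,
                         gamma_cos_theta = x$gamma_cos_theta)
  attr(fl, "assumed") <- isTRUE(x$assumed)
  fl
}

.device_to_list <- function(d) unclass(d)

.device_from_list <- function(x) {
  device_config(strip_length = x$strip_length, n_loops = x$n_loops,
                loop_length = x$loop_length, loop_diameter = x$loop_diameter,
                loop_entry_height = x$loop_entry_height,
                vertical_extent = x$vertical_extent, name = x$name)
}

#' Write and read fluid/device presets as YAML or JSON
#'
#' Serializes named preset lists to a single document with top-level keys
#' `fluids` and `devices`. The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`). Presets round-trip unchanged.
#'
#' @param fluids Named list of [fluid_properties()].
#' @param devices Named list of [device_config()].
#' @param path Output/input file path.
#' @return `write_presets`: the path, invisibly. `read_presets`: list with
#'   elements `fluids` and `devices`.
#' @examples
#' p <- file.path(tempdir(), "presets.yaml")
#' write_presets(fluid_presets(), device_presets(), p)
#' read_presets(p)$fluids$water
#' @export
write_presets <- function(fluids, devices, path) {
  doc <- list(fluids = lapply(fluids, .fluid_to_list),
              devices = lapply(devices, .device_to_list))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported preset format: use .yaml, .yml or .json",
              call. = FALSE)
  invisible(path)
}

#' @rdname write_presets
#' @export
read_presets <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
         else stop("unsupported preset format: use .yaml, .yml or .json",
                   call. = FALSE)
  list(fluids = lapply(doc$fluids, .fluid_from_list),
       devices = lapply(doc$devices, .device_from_list))
}
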