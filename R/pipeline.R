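# Reproducible simulate -> analyze -> report pipeline. One config drives all
# stages; every artifact records the seed and a hash of the resolved config
# so mismatched analyze/report inputs are detectable.

#' Experiment configuration
#'
#' Assembles and validates the single configuration object that drives the
#' pipeline. Fluid and device entries are names resolved against
#' [fluid_presets()] / [device_presets()], or inline definition lists in the
#' preset serialization schema (see [write_presets()]).
#'
#' @param fluids Character vector of preset names, or named list of inline
#'   fluid definitions.
#' @param devices Character vector of preset names, or named list of inline
#'   device definitions.
#' @param bore_diameter_mm Circular bore diameter, mm.
#' @param schedule List with `t_start`, `t_end`, `interval` (s).
#' @param noise List with `sigma_H`, `sigma_t`, `replicate_cv`.
#' @param n_capillaries Capillaries per strip.
#' @param window_inv_H Reciprocal-height analysis window, 1/mm.
#' @param comparison_timepoint Readout time for cross-device statistics, s.
#' @param seed Integer master seed.
#' @return A validated object of class `experiment_config`.
#' @examples
#' experiment_config(fluids = "water", devices = c("straight", "loop1"),
#'                   schedule = list(t_start = 0, t_end = 60, interval = 2))
#' @export
experiment_config <- function(fluids = c("water", "PRP", "WB"),
                              devices = c("straight", "loop1", "loop2"),
                              bore_diameter_mm = 0.2,
                              schedule = list(t_start = 0, t_end = 600,
                                              interval = 5),
                              noise = list(sigma_H = 0.5, sigma_t = 0.05,
                                           replicate_cv = 0.03),
                              n_capillaries = 10L,
                              window_inv_H = c(0.0125, 0.06),
                              comparison_timepoint = 30,
                              seed = 1L) {
  cfg <- structure(
    list(fluids = fluids, devices = devices,
         bore_diameter_mm = bore_diameter_mm, schedule = schedule,
         noise = noise, n_capillaries = as.integer(n_capillaries),
         window_inv_H = window_inv_H,
         comparison_timepoint = comparison_timepoint,
         seed = as.integer(seed)),
    class = "experiment_config")
  validate_config(cfg)
  cfg
}

#' @rdname experiment_config
#' @param cfg An `experiment_config` (or plain list in the same shape).
#' @return `validate_config`: `cfg` invisibly; errors list every offending
#'   field.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  known_f <- names(fluid_presets())
  known_d <- names(device_presets())
  if (is.character(cfg$fluids)) {
    bad <- setdiff(cfg$fluids, known_f)
    if (length(bad)) add(sprintf("fluids: unknown preset(s) %s",
                                 paste(bad, collapse = ", ")))
  } else if (!is.list(cfg$fluids)) add("fluids: must be names or a list")
  if (is.character(cfg$devices)) {
    bad <- setdiff(cfg$devices, known_d)
    if (length(bad)) add(sprintf("devices: unknown preset(s) %s",
                                 paste(bad, collapse = ", ")))
  } else if (!is.list(cfg$devices)) add("devices: must be names or a list")
  if (!is.numeric(cfg$bore_diameter_mm) || cfg$bore_diameter_mm <= 0)
    add("bore_diameter_mm: must be a positive number")
  s <- cfg$schedule
  if (!is.list(s) ||
      (is.null(s$times) && (is.null(s$t_end) || is.null(s$interval))))
    add("schedule: needs t_end and interval (or explicit times)")
  nz <- cfg$noise
  for (f in c("sigma_H", "sigma_t", "replicate_cv"))
    if (!is.null(nz[[f]]) && (!is.numeric(nz[[f]]) || nz[[f]] < 0))
      add(sprintf("noise.%s: must be >= 0", f))
  if (!is.numeric(cfg$n_capillaries) || cfg$n_capillaries < 1)
    add("n_capillaries: must be >= 1")
  w <- cfg$window_inv_H
  if (!is.numeric(w) || length(w) != 2L || w[1] >= w[2] || w[1] <= 0)
    add("window_inv_H: must be c(lower, upper) with 0 < lower < upper")
  if (!is.numeric(cfg$comparison_timepoint) || cfg$comparison_timepoint <= 0)
    add("comparison_timepoint: must be a positive time in s")
  if (length(problems) > 0L)
    stop(paste(c("invalid experiment configuration:",
                 paste0("  - ", problems)), collapse = "\n"), call. = FALSE)
  invisible(cfg)
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path Config file; fields as in [experiment_config()]; omitted
#'   fields take the defaults.
#' @return A validated `experiment_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("unsupported config format: use .yaml, .yml or .json",
                   call. = FALSE)
  defaults <- formals(experiment_config)
  args <- lapply(stats::setNames(nm = names(defaults)), function(f)
    if (!is.null(raw[[f]])) raw[[f]] else eval(defaults[[f]]))
  do.call(experiment_config, args)
}

.resolve_config <- function(cfg) {
  geom <- circular_bore(cfg$bore_diameter_mm)
  fluids <- if (is.character(cfg$fluids)) fluid_presets(geom)[cfg$fluids]
            else lapply(cfg$fluids, .fluid_from_list)
  devices <- if (is.character(cfg$devices)) device_presets()[cfg$devices]
             else lapply(cfg$devices, .device_from_list)
  sched <- if (!is.null(cfg$schedule$times))
             sampling_schedule(times = cfg$schedule$times)
           else sampling_schedule(cfg$schedule$t_start %||% 0,
                                  cfg$schedule$t_end, cfg$schedule$interval)
  nz <- noise_model(sigma_H = cfg$noise$sigma_H %||% 0.5,
                    sigma_t = cfg$noise$sigma_t %||% 0.05,
                    replicate_cv = cfg$noise$replicate_cv %||% 0.03,
                    seed = cfg$seed)
  list(geom = geom, fluids = fluids, devices = devices, schedule = sched,
       noise = nz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.log_line <- function(con, ..., quiet = FALSE) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  if (!quiet) message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Simulate stage: generate a dataset from a configuration
#'
#' Writes `dataset.csv`, `truth.json` (ground-truth sidecar), `config.json`
#' (the resolved configuration) and `run.log` into `out_dir`, creating it if
#' needed. Deterministic: the same config yields byte-identical CSV output.
#'
#' @param cfg An [experiment_config()] or path to a YAML/JSON config file.
#' @param out_dir Output directory.
#' @param quiet Suppress console logging.
#' @return Invisibly, a list with the dataset, truth and file paths.
#' @export
run_simulate <- function(cfg, out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "at")
  on.exit(close(logf))
  hash <- .config_hash(cfg)
  .log_line(logf, sprintf("simulate: seed=%d config_hash=%s mcfrise=%s",
                          cfg$seed, hash,
                          as.character(utils::packageVersion("mcfrise"))),
            quiet = quiet)
  res <- .resolve_config(cfg)
  csv_path <- file.path(out_dir, "dataset.csv")
  sidecar_path <- file.path(out_dir, "truth.json")
  exp <- simulate_experiment(res$fluids, res$devices, res$geom, res$schedule,
                             res$noise, cfg$n_capillaries,
                             csv_path = csv_path, sidecar_path = sidecar_path)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(c(unclass(cfg), list(config_hash = hash)), cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(logf, sprintf("simulate: wrote %d rows to %s", nrow(exp$data),
                          csv_path), quiet = quiet)
  invisible(list(data = exp$data, truth = exp$truth,
                 paths = list(dataset = csv_path, truth = sidecar_path,
                              config = cfg_path)))
}

#' Analyze stage: velocity profiles, fits and group statistics
#'
#' For every strip: per-capillary finite-difference velocity profiles,
#' restricted to the reciprocal-height analysis window, pooled per strip;
#' per-fluid surface-parameter estimates from the straight-strip end-of-run
#' heights (the schedule must run long enough to saturate); per-strip
#' viscosity fits against the model with the fitted wetting product; and,
#' across devices, one-way ANOVA with Tukey HSD on the capillary heights at
#' the comparison timepoint. With a single device group the ANOVA section
#' is omitted with a warning.
#'
#' @param dataset A long-format data frame or CSV path (schema of
#'   [read_trajectories()]).
#' @param cfg The [experiment_config()] used to generate (or describing) the
#'   dataset.
#' @param out_path Optional path for the JSON analysis report.
#' @return An object of class `analysis_report` (list): `window`,
#'   `equilibrium` (per fluid x device), `surface_fits`, `viscosity_fits`,
#'   `comparisons` (per fluid), `config_hash`.
#' @export
run_analyze <- function(dataset, cfg, out_path = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  validate_config(cfg)
  df <- if (is.character(dataset)) {
    trajs <- read_trajectories(dataset)
    utils::read.csv(dataset, stringsAsFactors = FALSE)
  } else dataset
  if (!all(c("fluid", "device") %in% names(df)))
    stop("dataset needs 'fluid' and 'device' columns for the analysis stage",
         call. = FALSE)
  res <- .resolve_config(cfg)
  geom <- res$geom
  window <- cfg$window_inv_H

  fluids_present <- intersect(names(res$fluids), unique(df$fluid))
  devices_present <- intersect(names(res$devices), unique(df$device))

  # end-of-run heights per strip/capillary (equilibrium estimates)
  t_max <- max(df$time_s)
  eq_rows <- list(); surface_fits <- list()
  for (fn in fluids_present) {
    for (dn in devices_present) {
      d <- df[df$fluid == fn & df$device == dn, , drop = FALSE]
      if (nrow(d) == 0L) next
      last_H <- vapply(split(d, d$capillary_id), function(x)
        x$height_mm[which.max(x$time_s)], numeric(1))
      eq_rows[[paste(fn, dn)]] <- data.frame(
        fluid = fn, device = dn, n = length(last_H),
        H_eq_mean = mean(last_H), H_eq_sd = stats::sd(last_H))
    }
    straight <- df[df$fluid == fn & df$device == "straight", , drop = FALSE]
    if (nrow(straight) > 0L) {
      last_H <- vapply(split(straight, straight$capillary_id), function(x)
        x$height_mm[which.max(x$time_s)], numeric(1))
      surface_fits[[fn]] <- estimate_surface_params(
        last_H, rho = res$fluids[[fn]]$rho / 1000, geom = geom,
        fluid_name = fn)
    }
  }
  equilibrium <- do.call(rbind, c(eq_rows, list(make.row.names = FALSE)))

  # pooled windowed velocity profiles + viscosity fits per strip
  profiles <- list(); visc_fits <- list()
  for (fn in fluids_present) {
    fl <- res$fluids[[fn]]
    if (!is.null(surface_fits[[fn]]))
      fl$gamma_cos_theta <- surface_fits[[fn]]$gamma_cos_theta_hat
    for (dn in devices_present) {
      d <- df[df$fluid == fn & df$device == dn, , drop = FALSE]
      if (nrow(d) == 0L) next
      trajs <- trajectories_from_data(d)
      prof_list <- lapply(trajs, finite_difference_velocity)
      pooled <- do.call(rbind, lapply(prof_list, as.data.frame))
      pooled <- velocity_profile(pooled$t_mid, pooled$H_mid, pooled$v,
                                 source = "observed",
                                 strip_id = paste(fn, dn, sep = "_"))
      windowed <- suppressWarnings(reciprocal_window_filter(pooled, window))
      key <- paste(fn, dn, sep = "_")
      profiles[[key]] <- windowed
      visc_fits[[key]] <- tryCatch(
        c(fit_viscosity(windowed, fl, geom, res$devices[[dn]]),
          list(fluid = fn, device = dn,
               mu_true_cp = pas_to_cp(res$fluids[[fn]]$mu))),
        error = function(e) list(fluid = fn, device = dn,
                                 error = conditionMessage(e)))
    }
  }

  # cross-device statistics at the comparison timepoint
  comparisons <- list()
  if (length(devices_present) < 2L) {
    warning("fewer than two device groups: ANOVA section omitted")
  } else {
    for (fn in fluids_present) {
      groups <- lapply(stats::setNames(nm = devices_present), function(dn) {
        d <- df[df$fluid == fn & df$device == dn, , drop = FALSE]
        vapply(split(d, d$capillary_id), function(x) {
          i <- which.min(abs(x$time_s - cfg$comparison_timepoint))
          x$height_mm[i]
        }, numeric(1))
      })
      groups <- groups[vapply(groups, length, integer(1)) >= 2L]
      comparisons[[fn]] <- if (length(groups) >= 2L) {
        tryCatch(tukey_hsd(groups), error = function(e) {
          warning(sprintf("comparison for %s not computed: %s", fn,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      } else NULL
    }
  }

  report <- structure(
    list(window = list(inv_H = window,
                       heights_mm = c(1 / window[2], 1 / window[1])),
         comparison_timepoint = cfg$comparison_timepoint,
         equilibrium = equilibrium,
         surface_fits = surface_fits,
         viscosity_fits = visc_fits,
         profiles = profiles,
         comparisons = comparisons,
         config_hash = .config_hash(cfg)),
    class = "analysis_report")
  if (!is.null(out_path)) {
    jsonlite::write_json(.report_to_json(report), out_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.report_to_json <- function(rep) {
  list(
    window = rep$window,
    comparison_timepoint = rep$comparison_timepoint,
    equilibrium = rep$equilibrium,
    surface_fits = lapply(rep$surface_fits, function(sf)
      sf[c("fluid", "gamma_cos_theta_hat", "gamma_cos_theta_sd",
           "H_eq_mean", "H_eq_sd", "n_replicates")]),
    viscosity_fits = lapply(rep$viscosity_fits, function(vf)
      vf[intersect(names(vf),
                   c("fluid", "device", "mu_hat", "rss", "n_points",
                     "mu_true_cp", "error"))]),
    comparisons = lapply(rep$comparisons, function(cmp) {
      if (is.null(cmp)) return(NULL)
      list(groups = cmp$groups, n = cmp$n, means = cmp$means, F = cmp$F,
           df_between = cmp$df_between, df_within = cmp$df_within, p = cmp$p,
           shapiro_p = cmp$shapiro_p, tukey = cmp$tukey)
    }),
    config_hash = rep$config_hash)
}

#' Report stage: render a human-readable summary
#'
#' @param report An `analysis_report` from [run_analyze()], or the path to
#'   its JSON serialization.
#' @param file Optional path; when given the summary is also written there.
#' @return The summary lines, invisibly.
#' @export
run_report <- function(report, file = NULL) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  lines <- character(0)
  push <- function(...) lines <<- c(lines, sprintf(...))
  push("== capillary-rise analysis report ==")
  w <- report$window
  push("analysis window: 1/H in [%g, %g] 1/mm (heights %.3g-%.3g mm)",
       w$inv_H[1], w$inv_H[2], w$heights_mm[1], w$heights_mm[2])
  push("")
  push("-- equilibrium heights (end of run) --")
  eq <- report$equilibrium
  if (!is.null(eq) && nrow(as.data.frame(eq)) > 0) {
    eq <- as.data.frame(eq)
    for (i in seq_len(nrow(eq)))
      push("  %-6s %-9s H_eq = %6.1f +/- %4.1f mm (n = %d)",
           eq$fluid[i], eq$device[i], eq$H_eq_mean[i], eq$H_eq_sd[i], eq$n[i])
  } else push("  not computed")
  push("")
  push("-- surface parameters (from straight strips) --")
  if (length(report$surface_fits) > 0) {
    for (sf in report$surface_fits)
      push("  %-6s gamma*cos(theta) = %.4g +/- %.2g N/m",
           sf$fluid, sf$gamma_cos_theta_hat, sf$gamma_cos_theta_sd)
  } else push("  not computed")
  push("")
  push("-- fitted viscosities --")
  if (length(report$viscosity_fits) > 0) {
    for (vf in report$viscosity_fits) {
      if (!is.null(vf$error)) push("  %-16s not fitted (%s)",
                                   paste(vf$fluid, vf$device), vf$error)
      else push("  %-6s %-9s mu = %6.3g cP (true %.3g)", vf$fluid, vf$device,
                vf$mu_hat, vf$mu_true_cp)
    }
  } else push("  not computed")
  push("")
  push("-- group comparisons at t = %g s (ANOVA + Tukey HSD) --",
       report$comparison_timepoint %||% NA)
  if (length(report$comparisons) > 0) {
    for (fn in names(report$comparisons)) {
      cmp <- report$comparisons[[fn]]
      if (is.null(cmp)) { push("  %-6s not computed", fn); next }
      push("  %-6s F(%d, %d) = %.4g, p = %.3g", fn, cmp$df_between,
           cmp$df_within, cmp$F, cmp$p)
      tukey <- as.data.frame(cmp$tukey)
      for (i in seq_len(nrow(tukey)))
        push("    %-18s diff = %7.2f mm, p_adj = %.3g",
             tukey$comparison[i], tukey$diff[i], tukey$p_adj[i])
    }
  } else push("  not computed")
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Overlay plot of observed velocities and model prediction
#'
#' Plots observed (1/H, dH/dt) points with the model prediction line(s),
#' the standard diagnostic view of capillary-rise data.
#'
#' @param profile An observed `velocity_profile`.
#' @param fluid,geom,device Model configuration for the overlay.
#' @param settings A [model_settings()].
#' @param ... Passed to [plot()].
#' @return Invisibly, the predicted profile used for the overlay.
#' @export
plot_velocity_overlay <- function(profile, fluid, geom, device,
                                  settings = model_settings(), ...) {
  H_eq <- equilibrium_height(fluid, geom, settings)
  H_grid <- seq(min(profile$H_mid), min(max(profile$H_mid), H_eq * 0.999),
                length.out = 200)
  pred <- predict_velocity_curve(fluid, geom, device, H_grid, settings)
  plot(profile$inv_H, profile$v, xlab = "1/H (1/mm)", ylab = "dH/dt (mm/s)",
       pch = 16, col = "grey40", ...)
  graphics::lines(pred$inv_H, pred$v, col = "firebrick", lwd = 2)
  invisible(pred)
}
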