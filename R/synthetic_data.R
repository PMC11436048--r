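# Seeded generator of height/length time series with the statistical
# structure the analysis pipeline assumes: 10 replicate capillaries per
# strip, fixed-interval time-lapse sampling with timestamp jitter, additive
# height-measurement noise, and replicate-to-replicate spread modelled as a
# coefficient of variation on the wetting product.

#' Measurement-noise model for synthetic strips
#'
#' @param sigma_H Additive height noise SD, mm. Default 0.5 mm, on the order
#'   of the pixel-level annotation scatter seen in time-lapse strip imaging.
#' @param sigma_t Timestamp jitter SD, s (image-capture timing wobble).
#' @param replicate_cv Coefficient of variation applied to the wetting
#'   product gamma*cos(theta) across the capillaries of a strip (bore-to-bore
#'   coating variability).
#' @param seed Integer master seed; identical seed and configuration give
#'   bitwise-identical output.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(sigma_H = 0.5, sigma_t = 0.05, seed = 42)
#' @export
noise_model <- function(sigma_H = 0.5, sigma_t = 0.05, replicate_cv = 0.03,
                        seed = 1L) {
  if (sigma_H < 0 || sigma_t < 0 || replicate_cv < 0)
    stop("noise SDs and replicate_cv must be >= 0", call. = FALSE)
  structure(list(sigma_H = sigma_H, sigma_t = sigma_t,
                 replicate_cv = replicate_cv, seed = as.integer(seed)),
            class = "noise_model")
}

#' Time-lapse sampling schedule
#'
#' @param t_start,t_end Window in s (`t_start >= 0`).
#' @param interval Fixed sampling interval, s; ignored when `times` given.
#' @param times Explicit strictly increasing timepoint vector, s.
#' @return An object of class `sampling_schedule` with element `times`.
#' @examples
#' sampling_schedule(0, 30, interval = 1)
#' @export
sampling_schedule <- function(t_start = 0, t_end = 30, interval = 1,
                              times = NULL) {
  if (is.null(times)) {
    if (t_start < 0 || t_end <= t_start || interval <= 0)
      stop("need t_start >= 0, t_end > t_start, interval > 0", call. = FALSE)
    times <- seq(t_start, t_end, by = interval)
  }
  if (any(diff(times) <= 0) || times[1] < 0)
    stop("schedule times must be strictly increasing and start >= 0",
         call. = FALSE)
  structure(list(times = times), class = "sampling_schedule")
}

#' Phenomenological viscosity ramp of a stimulated blood sample
#'
#' Stand-in for coagulation/platelet activation: after an onset time the
#' effective viscosity rises linearly at `ramp_rate` until it saturates at
#' `mu_max`. This is a deliberately simple emulation of "blood thickens
#' after stimulation" -- no mechanistic clotting kinetics are modelled.
#'
#' @param mu_baseline Unstimulated viscosity, cP.
#' @param mu_max Saturated viscosity, cP (`>= mu_baseline`).
#' @param onset_time Ramp start, s.
#' @param ramp_rate Ramp slope, cP/s (`>= 0`).
#' @return An object of class `stimulation_profile`; callable viscosity via
#'   [mu_at()].
#' @examples
#' prof <- stimulation_profile(6, 60, onset_time = 5, ramp_rate = 2)
#' mu_at(prof, c(0, 10, 60))
#' @export
stimulation_profile <- function(mu_baseline, mu_max = mu_baseline,
                                onset_time = 0, ramp_rate = 0) {
  if (mu_baseline <= 0)
    stop("invalid profile: baseline viscosity must be positive", call. = FALSE)
  if (mu_max < mu_baseline)
    stop("invalid profile: mu_max must be >= mu_baseline", call. = FALSE)
  if (ramp_rate < 0 || onset_time < 0)
    stop("invalid profile: ramp_rate and onset_time must be >= 0",
         call. = FALSE)
  structure(list(mu_baseline = mu_baseline, mu_max = mu_max,
                 onset_time = onset_time, ramp_rate = ramp_rate),
            class = "stimulation_profile")
}

#' @rdname stimulation_profile
#' @param profile A `stimulation_profile`.
#' @param t Times, s.
#' @return `mu_at`: viscosity in cP at each time (monotone non-decreasing).
#' @export
mu_at <- function(profile, t) {
  stopifnot(inherits(profile, "stimulation_profile"))
  pmin(profile$mu_max,
       profile$mu_baseline + profile$ramp_rate * pmax(0, t - profile$onset_time))
}

#' Fluid presets
#'
#' Named [fluid_properties()] for the liquids used in strip testing. Water,
#' PRP (platelet-rich plasma) and WB (whole blood) carry literature density
#' and viscosity values as used in the source experiments; their wetting
#' products are calibrated from the measured straight-strip equilibrium
#' heights (76.3, 75.4 and 72.7 mm) in the standard 200 micron bore. HBS,
#' PPP and RBC presets carry documented assumed values (flagged via the
#' `assumed` attribute) -- their densities/viscosities were not reported.
#'
#' @param geom Geometry used to calibrate wetting products from equilibrium
#'   heights; the standard circular 200 micron bore by default.
#' @return Named list of `fluid_properties`.
#' @examples
#' fluid_presets()$water
#' @export
fluid_presets <- function(geom = circular_bore(0.2)) {
  cal <- function(name, rho, mu, H_eq, assumed = FALSE) {
    fl <- fluid_properties(name, rho = rho, mu = mu,
                           gamma_cos_theta =
                             estimate_gamma_cos_theta(H_eq, rho, geom))
    attr(fl, "assumed") <- assumed
    attr(fl, "H_eq_calibration") <- H_eq
    fl
  }
  list(
    water = cal("water", rho = 0.998, mu = 1.04, H_eq = 76.3),
    PRP   = cal("PRP",   rho = 1.025, mu = 1.7,  H_eq = 75.4),
    WB    = cal("WB",    rho = 1.055, mu = 6,    H_eq = 72.7),
    # assumed values: typical saline buffer, platelet-poor plasma and packed
    # red-cell suspensions; not measured in the calibration experiments
    HBS   = cal("HBS", rho = 1.005, mu = 1.05, H_eq = 78, assumed = TRUE),
    PPP   = cal("PPP", rho = 1.025, mu = 1.3,  H_eq = 75, assumed = TRUE),
    RBC   = cal("RBC", rho = 1.09,  mu = 10,   H_eq = 72, assumed = TRUE))
}

#' Device presets
#'
#' The three strip formats: a 100 mm straight strip, a 150 mm strip with a
#' single loop (loop region 43 mm, diameter 14 mm) and a 160 mm strip with
#' two loops (loop region 58 mm total, diameter 9 mm). Strip lengths are
#' chosen so all formats share a 100 mm vertical measurement extent.
#'
#' @return Named list of [device_config()].
#' @examples
#' device_presets()$loop1
#' @export
device_presets <- function() {
  list(
    straight = device_config(strip_length = 100, n_loops = 0,
                             vertical_extent = 100, name = "straight"),
    loop1 = device_config(strip_length = 150, n_loops = 1, loop_length = 43,
                          loop_diameter = 14, loop_entry_height = 10,
                          vertical_extent = 100, name = "loop1"),
    loop2 = device_config(strip_length = 160, n_loops = 2, loop_length = 58,
                          loop_diameter = 9, loop_entry_height = 10,
                          vertical_extent = 100, name = "loop2"))
}

# Derived per-capillary seed: a few multiplicative-congruential mixing steps
# (Lehmer multiplier 48271, modulus 2^31 - 1; exact in double arithmetic).
# Gives each (strip, capillary) its own stream so changing the replicate
# count of one strip never shifts the draws of another.
.derive_seed <- function(seed, strip_index, cap_index) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (x in c(strip_index, cap_index)) {
    s <- (s * 48271) %% m
    s <- (s + as.numeric(x) * 69621 + 1) %% m
  }
  as.integer((s * 48271) %% m)
}

#' Simulate one strip of replicate capillaries
#'
#' For each capillary: draw a wetting-product multiplier from
#' `Normal(1, replicate_cv)`, integrate the noiseless rise model, sample it
#' at jittered timestamps, add height noise, and clamp heights to
#' `[0, vertical_extent]`. Recorded timestamps are the actual (jittered)
#' capture times, as with real time-lapse imaging. Each capillary uses its
#' own derived RNG stream, so output is deterministic under the master seed
#' and independent of how many other capillaries are generated.
#'
#' @inheritParams instantaneous_velocity
#' @param schedule A [sampling_schedule()].
#' @param noise A [noise_model()].
#' @param n_capillaries Replicate capillaries per strip (10 in the standard
#'   film).
#' @param strip_id Label; `strip_index` seeds the per-strip RNG streams.
#' @param strip_index Integer stream index of this strip.
#' @return List of [trajectory()] objects, one per capillary, each carrying
#'   attribute `gamma_multiplier` (the true replicate multiplier).
#' @examples
#' water <- fluid_presets()$water
#' trajs <- simulate_strip(water, circular_bore(0.2), device_presets()$straight,
#'                         sampling_schedule(0, 10, 1), noise_model(seed = 7),
#'                         n_capillaries = 3)
#' @export
simulate_strip <- function(fluid, geom, device, schedule, noise,
                           n_capillaries = 10L,
                           settings = model_settings(),
                           strip_id = device$name, strip_index = 1L) {
  stopifnot(inherits(schedule, "sampling_schedule"),
            inherits(noise, "noise_model"))
  lapply(seq_len(n_capillaries), function(i) {
    set.seed(.derive_seed(noise$seed, strip_index, i))
    mult <- max(stats::rnorm(1, 1, noise$replicate_cv), 0.05)
    t_nom <- schedule$times
    t_obs <- t_nom + stats::rnorm(length(t_nom), 0, noise$sigma_t)
    t_obs <- pmax(sort(t_obs), 0)
    # enforce strictly increasing capture times
    eps <- 1e-9 + max(t_obs) * 1e-12
    for (j in seq_along(t_obs)[-1])
      if (t_obs[j] <= t_obs[j - 1]) t_obs[j] <- t_obs[j - 1] + eps
    fl <- fluid
    fl$gamma_cos_theta <- fluid$gamma_cos_theta * mult
    traj <- integrate_rise(fl, geom, device, settings, t_grid = t_obs,
                           strip_id = strip_id,
                           capillary_id = sprintf("cap%02d", i))
    H <- traj$H + stats::rnorm(nrow(traj), 0, noise$sigma_H)
    H <- pmin(pmax(H, 0), device$vertical_extent)
    out <- trajectory(t = t_obs, H = H, L = H + device$loop_length,
                      strip_id = strip_id,
                      capillary_id = sprintf("cap%02d", i),
                      device = device, fluid = fluid)
    attr(out, "gamma_multiplier") <- mult
    attr(out, "reached_top") <- attr(traj, "reached_top")
    out
  })
}

#' Simulate a full multi-fluid, multi-device experiment
#'
#' Generates the full factorial design fluids x devices x capillaries x
#' timepoints as a long-format data frame, with a ground-truth sidecar
#' recording every generating parameter for parameter-recovery testing.
#' Optionally writes the dataset as CSV and the sidecar as JSON.
#'
#' @param fluids Named list of [fluid_properties()].
#' @param devices Named list of [device_config()].
#' @param geom A [capillary_geometry()].
#' @param schedule A [sampling_schedule()].
#' @param noise A [noise_model()].
#' @param n_capillaries Capillaries per strip.
#' @param settings A [model_settings()].
#' @param csv_path,sidecar_path Optional output paths.
#' @return List with `data` (long data frame: `fluid`, `device`, `strip_id`,
#'   `capillary_id`, `time_s`, `height_mm`, `length_mm`) and `truth` (the
#'   generating parameters, including per-capillary wetting multipliers).
#' @examples
#' exp <- simulate_experiment(fluid_presets()[c("water", "WB")],
#'                            device_presets()["straight"],
#'                            schedule = sampling_schedule(0, 5, 1),
#'                            noise = noise_model(seed = 3),
#'                            n_capillaries = 2)
#' head(exp$data)
#' @export
simulate_experiment <- function(fluids, devices, geom = circular_bore(0.2),
                                schedule = sampling_schedule(0, 30, 1),
                                noise = noise_model(),
                                n_capillaries = 10L,
                                settings = model_settings(),
                                csv_path = NULL, sidecar_path = NULL) {
  stopifnot(is.list(fluids), is.list(devices))
  rows <- list(); mults <- list()
  strip_index <- 0L
  for (fn in names(fluids)) {
    for (dn in names(devices)) {
      strip_index <- strip_index + 1L
      strip_id <- paste(fn, dn, sep = "_")
      trajs <- simulate_strip(fluids[[fn]], geom, devices[[dn]], schedule,
                              noise, n_capillaries, settings,
                              strip_id = strip_id, strip_index = strip_index)
      mults[[strip_id]] <- vapply(trajs, attr, numeric(1), "gamma_multiplier")
      rows[[strip_id]] <- do.call(rbind, lapply(trajs, function(tr) {
        data.frame(fluid = fn, device = dn, strip_id = strip_id,
                   capillary_id = attr(tr, "capillary_id"),
                   time_s = tr$t, height_mm = tr$H, length_mm = tr$L)
      }))
    }
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  truth <- list(
    seed = noise$seed,
    noise = unclass(noise),
    n_capillaries = n_capillaries,
    schedule = schedule$times,
    geometry = list(a_mm = m_to_mm(geom$a), b_mm = m_to_mm(geom$b),
                    dh_mm = m_to_mm(geom$dh)),
    fluids = lapply(fluids, function(fl)
      list(rho_g_ml = fl$rho / 1000, mu_cp = pas_to_cp(fl$mu),
           gamma_cos_theta = fl$gamma_cos_theta)),
    devices = lapply(devices, function(d) unclass(d)),
    gamma_multipliers = mults)
  if (!is.null(csv_path))
    utils::write.csv(data, csv_path, row.names = FALSE)
  if (!is.null(sidecar_path))
    jsonlite::write_json(truth, sidecar_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  list(data = data, truth = truth)
}

#' Rise trajectory under a time-varying (stimulated) viscosity
#'
#' Integrates a generalized front-propagation model
#' \eqn{d\ell/dt = k(t) (P_0 - \rho g z(\ell)) / \ell} where \eqn{\ell} is
#' the total wetted length, \eqn{k(t) = d_h^2/(32 \mu(t))} follows the
#' viscosity ramp, and the meniscus elevation \eqn{z(\ell)} is the front
#' position before the loop, constant at `loop_entry_height` inside the
#' loop, and \eqn{\ell - L_{loop}} after it (where the model reduces to the
#' looped-strip balance). Captures the regime where a steep viscosity ramp
#' stalls the front inside the loop region.
#'
#' @inheritParams simulate_strip
#' @param profile A [stimulation_profile()].
#' @param noise Optional [noise_model()]; `NULL` for a noiseless trajectory.
#' @param capillary_id,strip_index Labels/stream index when noise is added.
#' @return A [trajectory()] with `H` the meniscus elevation and `L` the
#'   wetted length; attribute `stalled_in_loop` is `TRUE` when the front
#'   ends the schedule still inside the loop region.
#' @examples
#' wb <- fluid_presets()$WB
#' prof <- stimulation_profile(6, 120, onset_time = 2, ramp_rate = 20)
#' tr <- stimulated_viscosity_trajectory(wb, prof, circular_bore(0.2),
#'                                       device_presets()$loop1,
#'                                       sampling_schedule(0, 30, 1))
#' attr(tr, "stalled_in_loop")
#' @export
stimulated_viscosity_trajectory <- function(fluid, profile, geom, device,
                                            schedule,
                                            noise = NULL,
                                            settings = model_settings(),
                                            capillary_id = "cap1",
                                            strip_index = 1L) {
  stopifnot(inherits(profile, "stimulation_profile"),
            inherits(schedule, "sampling_schedule"),
            inherits(device, "device_config"))
  P0 <- capillary_pressure(fluid, geom)
  rho_g <- fluid$rho * settings$g
  H_eq_m <- P0 / rho_g
  entry_m <- mm_to_m(device$loop_entry_height)
  L_m <- mm_to_m(device$loop_length)
  cap_z <- min(H_eq_m * (1 - settings$eps_eq), mm_to_m(device$vertical_extent))

  z_of_l <- function(l) {
    if (device$n_loops == 0L) return(l)
    if (l <= entry_m) l
    else if (l <= entry_m + L_m) entry_m
    else l - L_m
  }
  # smooth in l except at the loop entry/exit corners (which lsoda steps
  # over); the elevation clamp is applied to the monotone solution afterwards
  rhs <- function(t, y, parms) {
    l <- y[1]
    mu_t <- cp_to_pas(mu_at(profile, t))
    k <- geom$dh^2 / (32 * mu_t)
    z <- z_of_l(l)
    list(max(k * (P0 - rho_g * z) / l, 0))
  }
  times <- schedule$times
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  sol <- deSolve::ode(y = c(l = mm_to_m(settings$H0)), times = times,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = settings$rel_tol, atol = settings$abs_tol)
  l_m <- sol[, "l"]
  if (prepend) l_m <- l_m[-1]
  z_m <- pmin(vapply(l_m, z_of_l, numeric(1)), cap_z)
  H <- m_to_mm(z_m)
  L <- pmin(m_to_mm(l_m), device$strip_length)
  t_obs <- schedule$times
  if (!is.null(noise)) {
    set.seed(.derive_seed(noise$seed, strip_index, 1L))
    H <- pmin(pmax(H + stats::rnorm(length(H), 0, noise$sigma_H), 0),
              device$vertical_extent)
  }
  out <- trajectory(t = t_obs, H = H, L = L, strip_id = device$name,
                    capillary_id = capillary_id, device = device,
                    fluid = fluid)
  final_l <- l_m[length(l_m)]
  attr(out, "stalled_in_loop") <-
    device$n_loops > 0L && final_l > entry_m && final_l < entry_m + L_m
  out
}
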