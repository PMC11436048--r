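# Pressure-balance model of capillary rise in straight and looped strips.
#
# Driving Laplace pressure for an elliptical bore with semi-axes a, b:
#   P0 = (1/a + 1/b) * gamma * cos(theta)
# Quasi-steady Poiseuille balance against gravity and viscous friction over
# the full wetted length L gives the meniscus velocity
#   dH/dt = k * (P0 - rho * g * H) / (H + L_loop),   k = dh^2 / (32 mu)
# with L_loop = 0 for a straight strip. Flow stops at the equilibrium height
# H_eq = P0 / (rho * g), which is independent of the loop: loops add path
# length (friction) but no hydrostatic head.

# Ellipse hydraulic diameter 4A/P with Ramanujan's second perimeter
# approximation; exact (2a) in the circular limit. Inputs/outputs in metres.
.dh_ellipse <- function(a, b) {
  h <- (a - b)^2 / (a + b)^2
  perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  4 * pi * a * b / perim
}

# Mobility k = dh^2/(32 mu), m^2 / (Pa s)
.mobility <- function(fluid, geom) geom$dh^2 / (32 * fluid$mu)

#' Hydraulic diameter of an elliptical capillary
#'
#' Computes 4 area / perimeter for the elliptical cross-section, using
#' Ramanujan's second approximation for the ellipse perimeter (relative error
#' below 1e-6 even for strongly eccentric bores). For a circular bore the
#' result is exactly the diameter `2 a`.
#'
#' @param geom A [capillary_geometry()].
#' @return Hydraulic diameter in mm.
#' @examples
#' hydraulic_diameter(circular_bore(0.2))  # 0.2 mm
#' @export
hydraulic_diameter <- function(geom) {
  stopifnot(inherits(geom, "capillary_geometry"))
  m_to_mm(.dh_ellipse(geom$a, geom$b))
}

#' Laplace driving pressure of an elliptical capillary
#'
#' The wetting pressure drawing liquid into the bore,
#' \eqn{P_0 = (1/a + 1/b)\,\gamma\cos\theta}. In the circular limit
#' `a == b == r` this reduces to the familiar \eqn{2\gamma\cos\theta/r}.
#'
#' @param fluid A [fluid_properties()].
#' @param geom A [capillary_geometry()].
#' @return Capillary pressure in Pa (non-negative).
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' capillary_pressure(water, circular_bore(0.2))  # 747 Pa
#' @export
capillary_pressure <- function(fluid, geom) {
  stopifnot(inherits(fluid, "fluid_properties"),
            inherits(geom, "capillary_geometry"))
  if (geom$a <= 0 || geom$b <= 0)
    stop("invalid geometry: semi-axes must be positive", call. = FALSE)
  (1 / geom$a + 1 / geom$b) * fluid$gamma_cos_theta
}

#' Equilibrium capillary rise height
#'
#' Height at which the hydrostatic head balances the Laplace pressure,
#' \eqn{H_{eq} = P_0/(\rho g)}. Independent of strip path length, so looped
#' and straight devices share the same equilibrium -- the design property
#' that lets loops slow flow without changing the endpoint.
#'
#' @inheritParams capillary_pressure
#' @param settings A [model_settings()] (supplies g).
#' @return Equilibrium height in mm.
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' equilibrium_height(water, circular_bore(0.2))  # 76.3 mm
#' @export
equilibrium_height <- function(fluid, geom, settings = model_settings()) {
  P0 <- capillary_pressure(fluid, geom)
  m_to_mm(P0 / (fluid$rho * settings$g))
}

#' Estimate the wetting product from an observed equilibrium height
#'
#' Inverts the equilibrium relation to recover \eqn{\gamma\cos\theta} from a
#' measured equilibrium height in a straight strip:
#' \eqn{\widehat{\gamma\cos\theta} = \rho g H_{eq} / (1/a + 1/b)}. Only the
#' product of surface tension and contact-angle cosine is identifiable from
#' a single equilibrium height; no attempt is made to separate the two.
#'
#' @param H_eq_obs Observed equilibrium height, mm (positive).
#' @param rho Fluid density in g/mL.
#' @param geom A [capillary_geometry()].
#' @param settings A [model_settings()].
#' @return Estimated gamma*cos(theta) in N/m. Round-trips with
#'   [equilibrium_height()] to machine precision.
#' @examples
#' estimate_gamma_cos_theta(76.3, rho = 0.998, geom = circular_bore(0.2))
#' @export
estimate_gamma_cos_theta <- function(H_eq_obs, rho, geom,
                                     settings = model_settings()) {
  stopifnot(inherits(geom, "capillary_geometry"))
  if (!is.numeric(H_eq_obs) || any(H_eq_obs < 0))
    stop("invalid observation: equilibrium height must be positive",
         call. = FALSE)
  gml_to_kgm3(rho) * settings$g * mm_to_m(H_eq_obs) /
    (1 / geom$a + 1 / geom$b)
}

#' Instantaneous meniscus rise velocity
#'
#' Evaluates the pressure-balance velocity
#' \eqn{dH/dt = k\,(P_0 - \rho g H)/(H + L_{loop})} with
#' \eqn{k = d_h^2/(32\mu)}. For a straight strip the wetted length equals the
#' height; a looped strip adds `loop_length` of purely frictional path.
#' Positive below the equilibrium height, zero at it, negative above.
#'
#' @param H Meniscus height(s), mm. Vectorized.
#' @inheritParams equilibrium_height
#' @param device A [device_config()]; its `loop_length` sets the extra path.
#' @return Velocity in mm/s.
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' straight <- device_config(100)
#' instantaneous_velocity(53.1, water, circular_bore(0.2), straight)
#' @export
instantaneous_velocity <- function(H, fluid, geom, device,
                                   settings = model_settings()) {
  stopifnot(inherits(device, "device_config"))
  if (any(H < 0)) stop("heights must be non-negative", call. = FALSE)
  L_loop <- device$loop_length
  if (L_loop == 0 && any(H == 0))
    stop("singular input: velocity is unbounded at H = 0 in a straight strip",
         call. = FALSE)
  P0 <- capillary_pressure(fluid, geom)
  k <- .mobility(fluid, geom)
  H_m <- mm_to_m(H)
  m_to_mm(k * (P0 - fluid$rho * settings$g * H_m) /
            (H_m + mm_to_m(L_loop)))
}

#' Affine reciprocal-height law of a straight strip
#'
#' In a straight strip the model is exactly affine in 1/H:
#' \eqn{v = (k P_0)\,(1/H) - k \rho g}. Returns the slope and intercept in
#' interface units, the line practitioners overlay on (1/H, dH/dt) plots.
#'
#' @inheritParams equilibrium_height
#' @return Named numeric vector: `slope` (mm^2/s) and `intercept` (mm/s,
#'   negative).
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' affine_coefficients(water, circular_bore(0.2))
#' @export
affine_coefficients <- function(fluid, geom, settings = model_settings()) {
  P0 <- capillary_pressure(fluid, geom)
  k <- .mobility(fluid, geom)
  c(slope = k * P0 * MM_PER_M^2,                  # m^2/s -> mm^2/s
    intercept = -m_to_mm(k * fluid$rho * settings$g))
}

#' Integrate the rise model over a time grid
#'
#' Solves the pressure-balance ODE from `settings$H0` with a stiff-safe
#' adaptive solver (lsoda), clamping the solution once it saturates at
#' `(1 - eps_eq) * H_eq` or reaches the measurable vertical extent of the
#' device, whichever is lower. When the equilibrium height exceeds the
#' vertical extent the trajectory is flagged as having reached the top
#' (attribute `reached_top`).
#'
#' @inheritParams instantaneous_velocity
#' @param t_grid Output times in s, strictly increasing, starting at >= 0.
#' @param strip_id,capillary_id Labels passed to the [trajectory()].
#' @return A [trajectory()] sampled at `t_grid` with `L = H + loop_length`.
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' traj <- integrate_rise(water, circular_bore(0.2), device_config(100),
#'                        t_grid = seq(0, 10, by = 0.5))
#' @export
integrate_rise <- function(fluid, geom, device, settings = model_settings(),
                           t_grid, strip_id = "strip1", capillary_id = "cap1") {
  stopifnot(inherits(device, "device_config"))
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0) || t_grid[1] < 0)
    stop("invalid schedule: t_grid must be strictly increasing and start >= 0",
         call. = FALSE)
  P0 <- capillary_pressure(fluid, geom)
  k <- .mobility(fluid, geom)
  rho_g <- fluid$rho * settings$g
  H_eq_m <- P0 / rho_g
  H0_m <- mm_to_m(settings$H0)
  if (H0_m >= H_eq_m)
    stop("'H0' must lie below the equilibrium height", call. = FALSE)
  L_m <- mm_to_m(device$loop_length)
  cap_m <- min(H_eq_m * (1 - settings$eps_eq),
               mm_to_m(device$vertical_extent))

  times <- t_grid
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)

  # the raw ODE is smooth and asymptotes to H_eq from below; the saturation
  # clamp (equilibrium neighbourhood or strip top) is applied to the
  # monotone solution afterwards, which is equivalent to stopping the front
  # there and keeps the solver away from a rate discontinuity
  rhs <- function(t, y, parms) {
    H <- y[1]
    list(max(k * (P0 - rho_g * H) / (H + L_m), 0))
  }
  sol <- deSolve::ode(y = c(H = H0_m), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = settings$rel_tol, atol = settings$abs_tol)
  H_m <- pmin(sol[, "H"], cap_m)
  if (prepend) H_m <- H_m[-1]
  H <- m_to_mm(H_m)
  traj <- trajectory(t = t_grid, H = H, L = H + device$loop_length,
                     strip_id = strip_id, capillary_id = capillary_id,
                     device = device, fluid = fluid)
  attr(traj, "reached_top") <-
    H_eq_m > mm_to_m(device$vertical_extent) &&
    max(H) >= device$vertical_extent * (1 - 1e-6)
  traj
}

#' Time for the meniscus to first reach a target height
#'
#' Quadrature companion to [integrate_rise()]: separating variables in the
#' rise ODE gives
#' \eqn{t(H) = \int_{H_0}^{H} (h + L_{loop}) / (k (P_0 - \rho g h))\, dh},
#' evaluated with adaptive quadrature. Serves as an independent check on the
#' ODE solution and as a fast design query ("when does the front reach the
#' readout height?").
#'
#' @param H_target Target height, mm; must satisfy
#'   `H0 <= H_target < min(H_eq, vertical_extent)`.
#' @inheritParams instantaneous_velocity
#' @return Time in s.
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' time_to_height(53.1, water, circular_bore(0.2), device_config(100))
#' @export
time_to_height <- function(H_target, fluid, geom, device,
                           settings = model_settings()) {
  stopifnot(inherits(device, "device_config"))
  P0 <- capillary_pressure(fluid, geom)
  k <- .mobility(fluid, geom)
  rho_g <- fluid$rho * settings$g
  H_eq <- m_to_mm(P0 / rho_g)
  if (H_target >= min(H_eq, device$vertical_extent))
    stop(sprintf(
      "unreachable height: H_target = %g mm is at or above min(H_eq = %.3g, vertical extent = %g) mm",
      H_target, H_eq, device$vertical_extent), call. = FALSE)
  if (H_target < settings$H0)
    stop("'H_target' must be >= the integration start height H0",
         call. = FALSE)
  if (H_target == settings$H0) return(0)
  L_m <- mm_to_m(device$loop_length)
  integrand <- function(h) (h + L_m) / (k * (P0 - rho_g * h))
  stats::integrate(integrand, mm_to_m(settings$H0), mm_to_m(H_target),
                   rel.tol = 1e-10, abs.tol = 0)$value
}

#' Residence time of the advancing front in the loop region
#'
#' Time the liquid front spends traversing the looped stimulation zone --
#' the interval during which a blood sample is exposed to dried stimulus
#' before entering the vertical measurement zone. The front position
#' \eqn{\ell} obeys \eqn{d\ell/dt = k (P_0 - \rho g z(\ell)) / \ell}; inside
#' the loop the meniscus elevation is approximated as constant at
#' `loop_entry_height` (the loop diameter, 9--14 mm, is small against the
#' equilibrium height), which yields the closed form
#' \deqn{t = (\ell_2^2 - \ell_1^2) / (2 k (P_0 - \rho g z_{loop}))}
#' with \eqn{\ell_1} = `loop_entry_height` and
#' \eqn{\ell_2 = \ell_1 +} `loop_length`.
#'
#' @inheritParams instantaneous_velocity
#' @return Residence time in s (0 for `loop_length = 0`).
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' dev <- device_config(150, n_loops = 1, loop_length = 43,
#'                      loop_diameter = 14, loop_entry_height = 20)
#' loop_residence_time(water, circular_bore(0.2), dev)
#' @export
loop_residence_time <- function(fluid, geom, device,
                                settings = model_settings()) {
  stopifnot(inherits(device, "device_config"))
  if (device$loop_length == 0) return(0)
  if (device$n_loops < 1L)
    stop("residence time is defined for looped devices (n_loops >= 1)",
         call. = FALSE)
  P0 <- capillary_pressure(fluid, geom)
  k <- .mobility(fluid, geom)
  rho_g <- fluid$rho * settings$g
  z_m <- mm_to_m(device$loop_entry_height)
  if (z_m >= P0 / rho_g)
    stop("stalled front: loop entry height is at or above the equilibrium height",
         call. = FALSE)
  l1 <- mm_to_m(device$loop_entry_height)
  l2 <- l1 + mm_to_m(device$loop_length)
  (l2^2 - l1^2) / (2 * k * (P0 - rho_g * z_m))
}
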