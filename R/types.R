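#' Fluid properties of a sample liquid
#'
#' Bundles the physical properties of a liquid drawn into a microcapillary:
#' density, dynamic viscosity and the wetting product \eqn{\gamma\cos\theta}
#' (surface tension times cosine of the contact angle). Only the product is
#' identifiable from an equilibrium capillary height, so the product is the
#' primary field; separate `gamma` and `theta` may be supplied instead, in
#' which case the product is derived from them.
#'
#' @param name Label for the fluid (e.g. `"water"`, `"WB"`).
#' @param rho Density in g/mL (typical blood-component range 0.99--1.10).
#' @param mu Dynamic viscosity in centipoise (cP).
#' @param gamma_cos_theta Product of surface tension (N/m) and the cosine of
#'   the contact angle. Non-negative; zero means no wetting drive.
#' @param gamma Optional surface tension in N/m, used with `theta`.
#' @param theta Optional contact angle in degrees, used with `gamma`.
#'
#' @return An object of class `fluid_properties`: a list with fields `name`,
#'   `rho` (kg/m^3), `mu` (Pa.s), `gamma_cos_theta` (N/m), and, when given,
#'   `gamma` (N/m) and `theta` (degrees).
#' @examples
#' fluid_properties("water", rho = 0.998, mu = 1.04, gamma_cos_theta = 0.03735)
#' fluid_properties("water", rho = 0.998, mu = 1.04, gamma = 0.0728, theta = 59.1)
#' @export
fluid_properties <- function(name, rho, mu, gamma_cos_theta = NULL,
                             gamma = NULL, theta = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("'rho' must be a single positive density in g/mL", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("'mu' must be a single positive viscosity in cP", call. = FALSE)

  if (!is.null(gamma) && !is.null(theta)) {
    derived <- gamma * cos(theta * pi / 180)
    if (!is.null(gamma_cos_theta) &&
        abs(derived - gamma_cos_theta) > 1e-12) {
      stop("'gamma_cos_theta' is inconsistent with gamma*cos(theta)",
           call. = FALSE)
    }
    gamma_cos_theta <- derived
  }
  if (is.null(gamma_cos_theta))
    stop("supply 'gamma_cos_theta', or both 'gamma' and 'theta'",
         call. = FALSE)
  if (gamma_cos_theta < 0)
    stop("'gamma_cos_theta' must be >= 0 (non-wetting liquids not modelled)",
         call. = FALSE)

  structure(
    list(name = name,
         rho = gml_to_kgm3(rho),
         mu = cp_to_pas(mu),
         gamma_cos_theta = gamma_cos_theta,
         gamma = gamma, theta = theta),
    class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties> %s\n", x$name))
  cat(sprintf("  rho              %.4g g/mL\n", x$rho / 1000))
  cat(sprintf("  mu               %.4g cP\n", pas_to_cp(x$mu)))
  cat(sprintf("  gamma*cos(theta) %.4g N/m\n", x$gamma_cos_theta))
  invisible(x)
}

#' Elliptical capillary bore geometry
#'
#' Cross-section of one capillary of a microcapillary film, described by the
#' semi-axes of an ellipse. The hydraulic diameter `dh` (4 area / perimeter)
#' controls the viscous resistance term of the rise model; it is derived from
#' the axes with Ramanujan's second perimeter approximation unless supplied
#' directly (e.g. when measured microscopically). In the circular limit
#' `a == b` the derived `dh` is exactly the bore diameter `2 a`.
#'
#' @param a Semi-major axis in mm.
#' @param b Semi-minor axis in mm (must satisfy `0 < b <= a`).
#' @param dh Optional hydraulic diameter in mm; derived when `NULL`.
#' @return An object of class `capillary_geometry` with fields `a`, `b`,
#'   `dh`, all in metres.
#' @examples
#' circular_bore(0.2)               # the standard 200 micron bore
#' capillary_geometry(a = 0.1, b = 0.05)
#' @export
capillary_geometry <- function(a, b, dh = NULL) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L)
    stop("'a' and 'b' must be single numbers (mm)", call. = FALSE)
  if (a <= 0 || b <= 0)
    stop("invalid geometry: semi-axes must be positive", call. = FALSE)
  if (b > a)
    stop("invalid geometry: require b <= a (semi-minor <= semi-major)",
         call. = FALSE)
  a_m <- mm_to_m(a); b_m <- mm_to_m(b)
  geom <- structure(list(a = a_m, b = b_m, dh = NULL),
                    class = "capillary_geometry")
  geom$dh <- if (is.null(dh)) .dh_ellipse(a_m, b_m) else mm_to_m(dh)
  if (geom$dh <= 0)
    stop("invalid geometry: hydraulic diameter must be positive",
         call. = FALSE)
  geom
}

#' @rdname capillary_geometry
#' @param diameter Bore diameter in mm for a circular capillary.
#' @export
circular_bore <- function(diameter = 0.2) {
  capillary_geometry(a = diameter / 2, b = diameter / 2)
}

#' @export
print.capillary_geometry <- function(x, ...) {
  cat("<capillary_geometry>\n")
  cat(sprintf("  semi-axes a = %.4g mm, b = %.4g mm\n",
              m_to_mm(x$a), m_to_mm(x$b)))
  cat(sprintf("  hydraulic diameter %.4g mm\n", m_to_mm(x$dh)))
  invisible(x)
}

#' Test-strip device configuration
#'
#' Describes one microcapillary film test strip: its total length, how many
#' loops are coiled into the stimulation zone near the inlet, the extra path
#' length those loops add, and the vertical extent available for height
#' measurement. For a looped strip the total wetted length exceeds the
#' meniscus height by `loop_length` once the front has passed the loop:
#' L(t) = H(t) + L_loop.
#'
#' @param strip_length Total strip length in mm.
#' @param n_loops Integer number of loops (0, 1 or 2).
#' @param loop_length Total extra path length of the looped region, mm
#'   (0 for a straight strip).
#' @param loop_diameter Nominal loop diameter in mm (metadata; 0 if none).
#' @param loop_entry_height Elevation of the looped region above the
#'   reservoir surface, mm. Used by residence-time calculations only.
#' @param vertical_extent Maximum measurable height, mm. Must leave room for
#'   the loop: `vertical_extent <= strip_length - loop_length`.
#' @param name Optional device label.
#' @return An object of class `device_config` (lengths stored in mm).
#' @examples
#' device_config(strip_length = 100, n_loops = 0)
#' device_config(strip_length = 150, n_loops = 1, loop_length = 43,
#'               loop_diameter = 14, loop_entry_height = 10)
#' @export
device_config <- function(strip_length, n_loops = 0L, loop_length = 0,
                          loop_diameter = 0, loop_entry_height = 10,
                          vertical_extent = strip_length - loop_length,
                          name = NULL) {
  n_loops <- as.integer(n_loops)
  if (!n_loops %in% 0:2)
    stop("'n_loops' must be 0, 1 or 2", call. = FALSE)
  if (loop_length < 0)
    stop("'loop_length' must be >= 0", call. = FALSE)
  if (n_loops == 0L && loop_length != 0)
    stop("a straight strip (n_loops = 0) must have loop_length = 0",
         call. = FALSE)
  if (n_loops > 0L && loop_length <= 0)
    stop("a looped strip needs loop_length > 0", call. = FALSE)
  if (vertical_extent > strip_length - loop_length + 1e-9)
    stop("'vertical_extent' cannot exceed strip_length - loop_length",
         call. = FALSE)
  if (n_loops > 0L && loop_entry_height + loop_diameter > vertical_extent)
    stop("loop_entry_height + loop_diameter must fit within vertical_extent",
         call. = FALSE)
  if (is.null(name))
    name <- if (n_loops == 0L) "straight" else sprintf("loop%d", n_loops)
  structure(
    list(name = name, strip_length = strip_length, n_loops = n_loops,
         loop_length = loop_length, loop_diameter = loop_diameter,
         loop_entry_height = loop_entry_height,
         vertical_extent = vertical_extent),
    class = "device_config")
}

#' @export
print.device_config <- function(x, ...) {
  cat(sprintf("<device_config> %s\n", x$name))
  cat(sprintf("  strip %g mm, %d loop(s), L_loop %g mm, vertical extent %g mm\n",
              x$strip_length, x$n_loops, x$loop_length, x$vertical_extent))
  invisible(x)
}

#' Numerical settings of the rise model
#'
#' @param g Gravitational acceleration, m/s^2.
#' @param H0 Initial meniscus height for trajectory integration, mm. The rise
#'   velocity of a straight strip diverges as H -> 0, so integration starts
#'   from a small positive height.
#' @param rel_tol,abs_tol Integration tolerances passed to the ODE solver.
#' @param eps_eq Saturation fraction: trajectories are clamped once within
#'   `eps_eq * H_eq` of equilibrium to keep the stiff tail well-behaved.
#' @return An object of class `model_settings`.
#' @examples
#' model_settings()
#' @export
model_settings <- function(g = 9.81, H0 = 0.1, rel_tol = 1e-8,
                           abs_tol = 1e-10, eps_eq = 1e-6) {
  if (g <= 0) stop("'g' must be positive", call. = FALSE)
  if (H0 <= 0) stop("'H0' must be positive (the model is singular at H = 0)",
                    call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0 || eps_eq <= 0)
    stop("tolerances must be positive", call. = FALSE)
  structure(list(g = g, H0 = H0, rel_tol = rel_tol, abs_tol = abs_tol,
                 eps_eq = eps_eq),
            class = "model_settings")
}

#' Per-capillary rise trajectory
#'
#' A time series of meniscus height H(t) and total wetted length L(t) for one
#' capillary of a strip, either observed or produced by the model.
#'
#' @param t Sample times, s; strictly increasing.
#' @param H Meniscus heights above the reservoir surface, mm; non-negative.
#' @param L Total wetted lengths, mm; defaults to `H + device$loop_length`
#'   when a device is given (the measurement-zone relation), else `H`.
#' @param strip_id,capillary_id Labels.
#' @param device Optional [device_config()] reference.
#' @param fluid Optional [fluid_properties()] reference.
#' @return An object of class `trajectory`: a data frame with columns `t`,
#'   `H`, `L` and attributes `strip_id`, `capillary_id`, `device`, `fluid`.
#' @examples
#' trajectory(t = 0:3, H = c(0.1, 20, 30, 36))
#' @export
trajectory <- function(t, H, L = NULL, strip_id = "strip1",
                       capillary_id = "cap1", device = NULL, fluid = NULL) {
  if (length(t) != length(H))
    stop("'t' and 'H' must have equal length", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("invalid trajectory: times must be strictly increasing",
         call. = FALSE)
  if (any(H < 0))
    stop("invalid trajectory: heights must be non-negative", call. = FALSE)
  if (is.null(L)) {
    L <- if (!is.null(device)) H + device$loop_length else H
  }
  structure(
    data.frame(t = t, H = H, L = L),
    strip_id = strip_id, capillary_id = capillary_id,
    device = device, fluid = fluid,
    class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> strip %s, capillary %s, %d samples, t = [%g, %g] s\n",
              attr(x, "strip_id"), attr(x, "capillary_id"), nrow(x),
              min(x$t), max(x$t)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
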