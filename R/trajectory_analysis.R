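# Data-analysis chain for height time series: finite-difference velocities,
# reciprocal-height windowing, model overlays, surface/viscosity fits and
# replicate-group statistics.

#' Finite-difference velocity profile of a trajectory
#'
#' Converts a height time series to instantaneous superficial velocities by
#' dividing the height change of each consecutive sample pair by the elapsed
#' time between the actual timestamps. Each velocity is assigned to the
#' midpoint height and midpoint time of its pair (second-order accurate for
#' smooth trajectories).
#'
#' @param traj A [trajectory()] with at least two samples.
#' @return An object of class `velocity_profile`: a data frame with columns
#'   `t_mid` (s), `H_mid` (mm), `inv_H` (1/mm) and `v` (mm/s), and attribute
#'   `source = "observed"`.
#' @examples
#' traj <- trajectory(t = c(10, 12), H = c(40, 43))
#' finite_difference_velocity(traj)  # v = 1.5 mm/s at H_mid = 41.5 mm
#' @export
finite_difference_velocity <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2L)
    stop("invalid trajectory: need at least two samples", call. = FALSE)
  dt <- diff(traj$t)
  if (any(dt == 0))
    stop("invalid trajectory: duplicate timestamps", call. = FALSE)
  n <- nrow(traj)
  H_mid <- (traj$H[-1] + traj$H[-n]) / 2
  velocity_profile(
    t_mid = (traj$t[-1] + traj$t[-n]) / 2,
    H_mid = H_mid,
    v = diff(traj$H) / dt,
    source = "observed",
    strip_id = attr(traj, "strip_id"),
    capillary_id = attr(traj, "capillary_id"))
}

#' @rdname finite_difference_velocity
#' @param t_mid,H_mid,v Profile point coordinates (s, mm, mm/s).
#' @param source `"observed"` or `"predicted"`.
#' @param strip_id,capillary_id Labels.
#' @export
velocity_profile <- function(t_mid, H_mid, v, source = c("observed", "predicted"),
                             strip_id = NULL, capillary_id = NULL) {
  source <- match.arg(source)
  if (any(!is.finite(v)))
    stop("velocities must be finite", call. = FALSE)
  structure(
    data.frame(t_mid = t_mid, H_mid = H_mid, inv_H = 1 / H_mid, v = v),
    source = source, strip_id = strip_id, capillary_id = capillary_id,
    class = c("velocity_profile", "data.frame"))
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> %s, %d points\n", attr(x, "source"), nrow(x)))
  hw <- attr(x, "height_window")
  if (!is.null(hw))
    cat(sprintf("  analysis window: heights %.3g-%.3g mm\n", hw[1], hw[2]))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Restrict a velocity profile to a reciprocal-height window
#'
#' Keeps profile points whose reciprocal height 1/H lies inside a closed
#' window (1/mm). Velocities at very small heights are dominated by timing
#' noise and the model is singular there; very large heights approach
#' equilibrium where the model underestimates drag, so analysis is
#' restricted to an intermediate band. The default window 0.0125--0.06 1/mm
#' corresponds to heights of 16.7--80 mm.
#'
#' @param profile A `velocity_profile`.
#' @param window_inv_H Numeric length-2, lower < upper, in 1/mm.
#' @return The filtered `velocity_profile`, with attribute `height_window`
#'   giving the equivalent closed height window `(1/upper, 1/lower)` in mm.
#'   Warns (does not error) when no point survives.
#' @examples
#' prof <- velocity_profile(t_mid = 1:3, H_mid = c(10, 50, 100), v = c(9, 2, 1))
#' reciprocal_window_filter(prof)  # only the 50 mm point survives
#' @export
reciprocal_window_filter <- function(profile, window_inv_H = c(0.0125, 0.06)) {
  stopifnot(inherits(profile, "velocity_profile"))
  if (length(window_inv_H) != 2L || window_inv_H[1] >= window_inv_H[2])
    stop("'window_inv_H' must be c(lower, upper) with lower < upper",
         call. = FALSE)
  keep <- profile$inv_H >= window_inv_H[1] & profile$inv_H <= window_inv_H[2]
  out <- profile[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no profile points fall inside the reciprocal-height window")
  attrs <- attributes(profile)
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       attrs[setdiff(names(attrs), c("names", "row.names"))])
  attr(out, "height_window") <- c(1 / window_inv_H[2], 1 / window_inv_H[1])
  attr(out, "window_inv_H") <- window_inv_H
  out
}

#' Model-predicted velocity profile
#'
#' Evaluates the pressure-balance velocity on a grid of heights, returning a
#' `velocity_profile` with `source = "predicted"` suitable for overlaying on
#' observed (1/H, dH/dt) data. For a straight device the points lie exactly
#' on the affine line given by [affine_coefficients()].
#'
#' @param H_grid Heights in mm, inside (0, H_eq).
#' @inheritParams instantaneous_velocity
#' @return A `velocity_profile` (its `t_mid` column holds the model time at
#'   which each height is first reached, from [time_to_height()]).
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' predict_velocity_curve(water, circular_bore(0.2), device_config(100),
#'                        H_grid = seq(20, 70, by = 10))
#' @export
predict_velocity_curve <- function(fluid, geom, device,
                                   H_grid, settings = model_settings()) {
  H_eq <- equilibrium_height(fluid, geom, settings)
  if (any(H_grid <= 0) || any(H_grid >= H_eq))
    stop("'H_grid' must lie strictly inside (0, H_eq)", call. = FALSE)
  v <- instantaneous_velocity(H_grid, fluid, geom, device, settings)
  t_mid <- vapply(
    H_grid,
    function(h) if (h <= settings$H0) 0
                else time_to_height(h, fluid, geom, device, settings),
    numeric(1))
  velocity_profile(t_mid = t_mid, H_mid = H_grid, v = v, source = "predicted")
}

#' Estimate surface parameters from replicate equilibrium heights
#'
#' Pools per-replicate equilibrium heights observed in straight strips into
#' a single wetting-product estimate via the mean height, with the
#' replicate dispersion propagated linearly (the estimator is linear in the
#' height, so the relative SD carries over).
#'
#' @param equilibria Per-replicate equilibrium heights, mm (all positive).
#' @param rho Fluid density, g/mL.
#' @param geom A [capillary_geometry()].
#' @param fluid_name Label recorded in the fit.
#' @param settings A [model_settings()].
#' @return An object of class `surface_fit`: list with `fluid`,
#'   `gamma_cos_theta_hat` (N/m), `gamma_cos_theta_sd`, `H_eq_mean`,
#'   `H_eq_sd` (mm), `equilibria` and `n_replicates`.
#' @examples
#' estimate_surface_params(c(75.1, 76.9, 77.4), rho = 0.998,
#'                         geom = circular_bore(0.2), fluid_name = "water")
#' @export
estimate_surface_params <- function(equilibria, rho, geom,
                                    fluid_name = "fluid",
                                    settings = model_settings()) {
  if (length(equilibria) < 1L || any(!is.finite(equilibria)) ||
      any(equilibria <= 0))
    stop("invalid observation: equilibrium heights must be positive",
         call. = FALSE)
  H_mean <- mean(equilibria)
  H_sd <- if (length(equilibria) > 1L) stats::sd(equilibria) else 0
  gct <- estimate_gamma_cos_theta(H_mean, rho, geom, settings)
  structure(
    list(fluid = fluid_name,
         gamma_cos_theta_hat = gct,
         gamma_cos_theta_sd = gct * H_sd / H_mean,
         H_eq_mean = H_mean, H_eq_sd = H_sd,
         equilibria = equilibria,
         n_replicates = length(equilibria)),
    class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("<surface_fit> %s: gamma*cos(theta) = %.4g +/- %.2g N/m (n = %d, H_eq = %.3g +/- %.2g mm)\n",
              x$fluid, x$gamma_cos_theta_hat, x$gamma_cos_theta_sd,
              x$n_replicates, x$H_eq_mean, x$H_eq_sd))
  invisible(x)
}

#' Fit a viscosity to an observed velocity profile
#'
#' With density, wetting product and geometry fixed, the model velocity is
#' proportional to 1/mu; the fit is a bounded scalar least-squares problem
#' on velocity-space residuals (heights carry roughly uniform measurement
#' noise, so residuals are taken in v, not in 1/H). Only profile points
#' strictly below the equilibrium height contribute.
#'
#' @param profile A `velocity_profile` with at least 3 usable points.
#' @inheritParams instantaneous_velocity
#' @param bounds Search interval for mu, cP.
#' @return List with `mu_hat` (cP), `rss` (residual sum of squares,
#'   (mm/s)^2) and `n_points`.
#' @examples
#' water <- fluid_properties("water", 0.998, 1.04, gamma_cos_theta = 0.03735)
#' dev <- device_config(100)
#' prof <- predict_velocity_curve(water, circular_bore(0.2), dev,
#'                                H_grid = seq(20, 70, by = 5))
#' fit_viscosity(prof, water, circular_bore(0.2), dev)$mu_hat  # 1.04
#' @export
fit_viscosity <- function(profile, fluid, geom, device,
                          settings = model_settings(),
                          bounds = c(0.1, 1000)) {
  stopifnot(inherits(profile, "velocity_profile"))
  H_eq <- equilibrium_height(fluid, geom, settings)
  use <- profile$H_mid > 0 & profile$H_mid < H_eq
  if (sum(use) < 3L)
    stop("unfittable: need at least 3 profile points below the equilibrium height",
         call. = FALSE)
  H <- profile$H_mid[use]; v_obs <- profile$v[use]
  # v(H; mu) = c(H)/mu, with c(H) independent of mu: evaluate once at mu = 1 cP
  unit_fluid <- fluid
  unit_fluid$mu <- cp_to_pas(1)
  c_H <- instantaneous_velocity(H, unit_fluid, geom, device, settings)
  obj <- function(mu) sum((v_obs - c_H / mu)^2)
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-10)
  list(mu_hat = opt$minimum, rss = opt$objective, n_points = sum(use))
}

#' One-way analysis of variance across replicate groups
#'
#' Compares height measurements across device groups (e.g. straight vs one
#' vs two loops) with a standard fixed-effects one-way ANOVA, as used to
#' test whether loop addition shifts the height reached at a fixed readout
#' time. Delegates to [stats::aov()].
#'
#' @param groups Named list of numeric vectors, one per group; at least two
#'   groups of at least two values each, with positive within-group
#'   variance.
#' @return An object of class `group_comparison`: list with `groups`, `n`,
#'   `F`, `df_between`, `df_within`, `p`, the group means, per-group
#'   Shapiro-Wilk normality p-values (reported only, gating nothing), and a
#'   `tukey` data frame (filled by [tukey_hsd()]; `NULL` here).
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups) {
  g <- .check_groups(groups)
  fit <- stats::aov(y ~ grp, data = g$data)
  tab <- summary(fit)[[1]]
  shapiro_p <- vapply(g$groups, function(v) {
    if (length(v) >= 3L && stats::var(v) > 0)
      stats::shapiro.test(v)$p.value else NA_real_
  }, numeric(1))
  structure(
    list(groups = names(g$groups),
         n = vapply(g$groups, length, integer(1)),
         means = vapply(g$groups, mean, numeric(1)),
         F = tab[1, "F value"],
         df_between = tab[1, "Df"], df_within = tab[2, "Df"],
         p = tab[1, "Pr(>F)"],
         shapiro_p = shapiro_p,
         tukey = NULL,
         aov_fit = fit),
    class = "group_comparison")
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' All pairwise group mean differences with studentized-range adjusted
#' p-values, the post hoc companion to [one_way_anova()]. Delegates to
#' [stats::TukeyHSD()].
#'
#' @inheritParams one_way_anova
#' @return A `group_comparison` whose `tukey` element is a data frame with
#'   columns `comparison`, `diff`, `lwr`, `upr`, `p_adj`
#'   (one row per unordered group pair).
#' @examples
#' tukey_hsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))$tukey
#' @export
tukey_hsd <- function(groups) {
  cmp <- one_way_anova(groups)
  tk <- stats::TukeyHSD(cmp$aov_fit)$grp
  cmp$tukey <- data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL)
  cmp
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two values", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                levels = names(groups))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0)
    stop("degenerate data: zero within-group variance", call. = FALSE)
  list(groups = groups, data = data.frame(y = y, grp = grp))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", paste(x$groups, collapse = " / ")))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    print.data.frame(x$tukey, digits = 4)
  }
  invisible(x)
}
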