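# Shared fixtures: the calibrated water configuration (wetting product set
# so a 200 micron circular bore equilibrates at 76.3 mm) and the three
# device formats.

water_fixture <- function() {
  fluid_properties("water", rho = 0.998, mu = 1.04,
                   gamma_cos_theta = 0.03735)
}

bore200 <- function() circular_bore(0.2)

straight_dev <- function() device_config(strip_length = 100, n_loops = 0,
                                         vertical_extent = 100)

loop1_dev <- function() device_config(strip_length = 150, n_loops = 1,
                                      loop_length = 43, loop_diameter = 14,
                                      loop_entry_height = 10,
                                      vertical_extent = 100)

loop2_dev <- function() device_config(strip_length = 160, n_loops = 2,
                                      loop_length = 58, loop_diameter = 9,
                                      loop_entry_height = 10,
                                      vertical_extent = 100)

# draw a random physically sensible model configuration (used by the
# property-style tests)
random_configuration <- function() {
  rho <- runif(1, 0.95, 1.10)
  mu <- runif(1, 0.8, 8)
  r <- runif(1, 0.05, 0.25)        # semi-axis, mm
  b <- r * runif(1, 0.5, 1)
  geom <- capillary_geometry(a = r, b = b)
  gct <- runif(1, 0.02, 0.06)
  fluid <- fluid_properties("rand", rho = rho, mu = mu,
                            gamma_cos_theta = gct)
  H_eq <- equilibrium_height(fluid, geom)
  loop <- runif(1, 20, 60)
  device <- device_config(strip_length = 2 * H_eq + loop + 20, n_loops = 1,
                          loop_length = loop, loop_diameter = 9,
                          loop_entry_height = min(10, 0.3 * H_eq),
                          vertical_extent = 2 * H_eq)
  list(fluid = fluid, geom = geom, device = device, H_eq = H_eq)
}
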