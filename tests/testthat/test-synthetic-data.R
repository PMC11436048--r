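# Synthetic-data generator: presets, determinism, noise structure,
# experiment assembly and stimulated (viscosity-ramp) trajectories.

test_that("fluid presets carry the literature densities and viscosities", {
  p <- fluid_presets()
  expect_equal(p$water$rho, 998)
  expect_equal(p$water$mu, 1.04e-3)
  expect_equal(p$PRP$rho, 1025); expect_equal(p$PRP$mu, 1.7e-3)
  expect_equal(p$WB$rho, 1055);  expect_equal(p$WB$mu, 6e-3)
  # wetting products calibrated to the straight-strip equilibria
  g <- bore200()
  expect_equal(equilibrium_height(p$water, g), 76.3, tolerance = 1e-9)
  expect_equal(equilibrium_height(p$WB, g), 72.7, tolerance = 1e-9)
  # undocumented fluids are flagged as assumed
  expect_false(isTRUE(attr(p$water, "assumed")))
  expect_true(attr(p$HBS, "assumed"))
  expect_true(attr(p$PPP, "assumed"))
  expect_true(attr(p$RBC, "assumed"))
})

test_that("device presets satisfy their invariants", {
  d <- device_presets()
  expect_equal(d$straight$loop_length, 0)
  expect_equal(d$loop1$loop_length, 43)
  expect_equal(d$loop1$loop_diameter, 14)
  expect_equal(d$loop2$n_loops, 2L)
  expect_equal(d$loop2$loop_length, 58)
  expect_equal(d$loop2$loop_diameter, 9)
  # all formats share the same measurable vertical extent
  expect_equal(unique(vapply(d, `[[`, 1, "vertical_extent")), 100)
})

test_that("zero noise reproduces the deterministic model exactly", {
  p <- fluid_presets(); g <- bore200(); st <- straight_dev()
  sched <- sampling_schedule(0, 10, 0.5)
  nz <- noise_model(sigma_H = 0, sigma_t = 0, replicate_cv = 0, seed = 1)
  trajs <- simulate_strip(p$water, g, st, sched, nz, n_capillaries = 3)
  ref <- integrate_rise(p$water, g, st, t_grid = sched$times)
  for (tr in trajs) {
    expect_identical(tr$t, ref$t)
    expect_identical(tr$H, ref$H)
  }
})

test_that("the generator is deterministic under seed and streams are independent", {
  p <- fluid_presets(); g <- bore200(); st <- straight_dev()
  sched <- sampling_schedule(0, 8, 1)
  nz <- noise_model(seed = 99)
  a <- simulate_strip(p$water, g, st, sched, nz, n_capillaries = 4)
  b <- simulate_strip(p$water, g, st, sched, nz, n_capillaries = 4)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))

  # changing the replicate count does not shift earlier capillaries
  c6 <- simulate_strip(p$water, g, st, sched, nz, n_capillaries = 6)
  expect_identical(as.data.frame(a[[2]]), as.data.frame(c6[[2]]))
  # different strips draw from different streams
  d <- simulate_strip(p$water, g, st, sched, nz, n_capillaries = 4,
                      strip_index = 2L)
  expect_false(identical(a[[1]]$H, d[[1]]$H))
  # different seeds differ
  e <- simulate_strip(p$water, g, st, sched, noise_model(seed = 100), 4)
  expect_false(identical(a[[1]]$H, e[[1]]$H))
})

test_that("height noise SD is recovered at a fixed late timepoint", {
  p <- fluid_presets(); g <- bore200(); st <- straight_dev()
  # sample once, late, far into saturation; replicate_cv 0 isolates sigma_H
  sched <- sampling_schedule(times = c(0, 100))
  nz <- noise_model(sigma_H = 0.5, sigma_t = 0, replicate_cv = 0, seed = 5)
  trajs <- simulate_strip(p$water, g, st, sched, nz, n_capillaries = 200)
  lastH <- vapply(trajs, function(tr) tr$H[nrow(tr)], numeric(1))
  expect_equal(sd(lastH), 0.5, tolerance = 0.15)   # Monte-Carlo error
  expect_equal(mean(lastH), 76.3, tolerance = 0.15)
})

test_that("experiments assemble the full factorial design with a faithful sidecar", {
  p <- fluid_presets()[c("water", "PRP", "WB")]
  d <- device_presets()
  sched <- sampling_schedule(times = seq(0.5, 10, length.out = 20))
  exp <- simulate_experiment(p, d, schedule = sched,
                             noise = noise_model(seed = 2),
                             n_capillaries = 10)
  expect_equal(nrow(exp$data), 3 * 3 * 10 * 20)
  expect_setequal(unique(exp$data$fluid), c("water", "PRP", "WB"))
  expect_setequal(unique(exp$data$device), c("straight", "loop1", "loop2"))

  # sidecar round-trips through JSON unchanged
  sidecar <- file.path(tempdir(), "truth.json")
  csv <- file.path(tempdir(), "dataset.csv")
  exp2 <- simulate_experiment(p["water"], d["straight"], schedule = sched,
                              noise = noise_model(seed = 2),
                              n_capillaries = 2,
                              csv_path = csv, sidecar_path = sidecar)
  truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  expect_equal(truth$fluids$water$gamma_cos_theta,
               p$water$gamma_cos_theta)
  expect_equal(truth$fluids$water$mu_cp, 1.04)
  expect_equal(truth$seed, 2)
  expect_equal(unname(unlist(truth$gamma_multipliers)),
               unname(unlist(exp2$truth$gamma_multipliers)))
  # and the CSV re-reads to the same dataset
  redata <- read.csv(csv)
  expect_equal(redata$height_mm, exp2$data$height_mm)
})

test_that("zero-noise pipeline recovers sidecar parameters to < 0.1%", {
  p <- fluid_presets()["water"]
  d <- device_presets()["straight"]
  g <- bore200()
  sched <- sampling_schedule(times = c(seq(0.2, 30, by = 0.05), 120))
  exp <- simulate_experiment(p, d, g, sched,
                             noise_model(0, 0, 0, seed = 1),
                             n_capillaries = 3)
  trajs <- trajectories_from_data(exp$data)
  lastH <- vapply(trajs, function(tr) tr$H[nrow(tr)], numeric(1))
  sf <- estimate_surface_params(lastH, rho = 0.998, geom = g)
  expect_equal(sf$gamma_cos_theta_hat, p$water$gamma_cos_theta,
               tolerance = 1e-3)
  prof <- finite_difference_velocity(trajs[[1]])
  wprof <- reciprocal_window_filter(prof)
  fit <- fit_viscosity(wprof, p$water, g, d$straight)
  expect_equal(fit$mu_hat, 1.04, tolerance = 1e-3)
})

test_that("viscosity ramps slow and stall the stimulated front", {
  p <- fluid_presets(); g <- bore200(); l1 <- loop1_dev()
  sched <- sampling_schedule(0, 30, 1)

  # flat profile reproduces the unstimulated looped-front trajectory
  flat <- stimulation_profile(mu_baseline = 6)
  tr_flat <- stimulated_viscosity_trajectory(p$WB, flat, g, l1, sched)
  expect_true(all(diff(tr_flat$L) >= 0))
  expect_false(attr(tr_flat, "stalled_in_loop"))

  # stronger stimulation -> strictly lower heights after onset
  ramp6 <- stimulation_profile(6, mu_max = 6 * 2, onset_time = 2,
                               ramp_rate = 2)
  ramp12 <- stimulation_profile(6, mu_max = 6 * 4, onset_time = 2,
                                ramp_rate = 4)
  t1 <- stimulated_viscosity_trajectory(p$WB, ramp6, g, l1, sched)
  t2 <- stimulated_viscosity_trajectory(p$WB, ramp12, g, l1, sched)
  late <- sched$times > 4
  expect_true(all(t2$L[late] < t1$L[late]))
  expect_true(all(t2$H[late] <= t1$H[late]))
  expect_true(all(t1$L[late] < tr_flat$L[late]))

  # a steep enough ramp leaves the front inside the loop region
  clot <- stimulation_profile(6, mu_max = 6000, onset_time = 1,
                              ramp_rate = 2000)
  t3 <- stimulated_viscosity_trajectory(p$WB, clot, g, l1, sched)
  expect_true(attr(t3, "stalled_in_loop"))
  expect_lt(max(t3$L), 10 + 43)   # never exits the loop region
  expect_equal(max(t3$H), 10, tolerance = 1e-6)  # meniscus held at entry

  expect_error(stimulation_profile(0, 6), "baseline")
  expect_error(stimulation_profile(6, 3), "mu_max")
})

test_that("mu_at follows a saturating linear ramp", {
  prof <- stimulation_profile(6, 60, onset_time = 5, ramp_rate = 2)
  expect_equal(mu_at(prof, c(0, 5, 10, 100)), c(6, 6, 16, 60))
  expect_true(all(diff(mu_at(prof, seq(0, 60, 0.5))) >= 0))
})
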