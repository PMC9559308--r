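test_that("gas hold-up correlation evaluates correctly and increases with v_s", {
  expect_identical(gas_holdup(0, D = 5.3), 0)
  # frozen direct evaluations of the correlation
  expect_equal(gas_holdup(0.215, D = 5.3, g = 9.81), 0.1711544641, tolerance = 1e-8)
  expect_equal(gas_holdup(0.1, D = 5.3, g = 9.81), 0.09712696396, tolerance = 1e-8)
  vs <- seq(0.01, 0.5, length.out = 100)
  expect_true(all(diff(gas_holdup(vs, D = 5.3)) > 0))
  expect_true(all(gas_holdup(vs, D = 5.3) < 1))
  expect_error(gas_holdup(-0.1, D = 5.3), "non-negative")
  expect_error(gas_holdup(0.1, D = -1), "positive")
})

test_that("dispersion density is the convex combination of phase densities", {
  expect_equal(dispersion_density(0, 1030, 1.2), 1030)
  expect_equal(dispersion_density(1 - 1e-12, 1030, 1.2), 1.2, tolerance = 1e-6)
  expect_equal(dispersion_density(0.1711544641, 1030, 1.2), 853.9162874,
               tolerance = 1e-8)
  eps <- runif(50)
  rho <- dispersion_density(eps * 0.99, 1030, 1.2)
  expect_true(all(rho >= 1.2 & rho <= 1030))
  expect_error(dispersion_density(1.2), "\\[0, 1\\)")
})

test_that("baseline tracks the bottom pressure of periodic and drifting signals", {
  t <- 0:7199
  tri <- 2e5 + 1e5 * (2 * abs((t %% 300) / 300 - 0.5) - 0.5) * 2
  tr <- sensor_trace("d", t, rep(2e5, length(t)))
  expect_equal(baseline_pressure(tr), rep(2e5, length(t)))
  tr2 <- sensor_trace("d", t, tri)
  base <- baseline_pressure(tr2)
  mid <- 2000:5200
  expect_true(all(abs(base[mid] - max(tri)) < 0.02 * max(tri)))
  # rising envelope: baseline follows with bounded lag
  env <- 2e5 + 5 * t + 1e4 * sin(2 * pi * t / 120)
  base3 <- baseline_pressure(sensor_trace("d", t, env))
  expect_true(all(base3[mid] <= max(env)))
  expect_true(all(diff(base3[mid]) >= -1e-9))
  expect_error(baseline_pressure(sensor_trace("d", 0:100, rep(1e5, 101))),
               "nsufficient")
})

test_that("Pascal's law position conversion and clipping", {
  expect_equal(pressure_to_position(2e5, 2e5, 1000), 0)
  expect_equal(pressure_to_position(2e5 - 88290, 2e5, 900, g = 9.81), 10)
  H <- 16; rho <- 900
  expect_equal(pressure_to_position(2e5 - 0.5 * rho * 9.81 * H, 2e5, rho), H / 2)
  expect_equal(pressure_to_position(2e5 + 500, 2e5, rho), 0)  # noise at bottom
  expect_equal(pressure_to_position(0.5e5, 2e5, rho, H_L = 16), 16)
  expect_error(pressure_to_position(1e5, 2e5, -1), "positive")
})

test_that("finite-difference axial velocity recovers linear and sinusoidal motion", {
  t <- 0:499
  expect_equal(axial_velocity(t, rep(3, 500), smooth = 0), rep(0, 500))
  expect_equal(axial_velocity(t, 0.2 * t, smooth = 0), rep(0.2, 500))
  A <- 2; om <- 2 * pi / 100
  v <- axial_velocity(t, A * sin(om * t), smooth = 0)
  truth <- A * om * cos(om * t)
  interior <- 2:499
  expect_lt(max(abs(v - truth)[interior]), A * om^3 / 6 * 1.01)
  expect_error(axial_velocity(c(0, 1, 1, 2), 1:4), "increasing")
})

test_that("noise-free round trip recovers the true trajectory within 1% of H_L", {
  spec <- ref("spec")
  sim <- ref("clean_device")
  kin <- process_trace(sim$trace, spec$geometry, spec$Q_g)
  H <- spec$H_L(sim$truth$t_s)
  rel <- (kin$z_m - sim$truth$z_m) / H
  expect_lt(sqrt(mean(rel^2)), 0.01)
})

test_that("slow headspace offsets leave the recovered positions essentially unchanged", {
  spec <- ref("spec")
  sim <- ref("clean_device")
  kin <- process_trace(sim$trace, spec$geometry, spec$Q_g)
  H <- spec$H_L(sim$truth$t_s)
  # a back-pressure step of +21 kPa: the baseline absorbs it (the small
  # residual comes from the gas-velocity pressure correction, which
  # cannot distinguish an offset from real pressurisation)
  tr2 <- sim$trace
  tr2$P_Pa <- tr2$P_Pa + 21000
  kin2 <- process_trace(tr2, spec$geometry, spec$Q_g)
  expect_lt(sqrt(mean(((kin2$z_m - kin$z_m) / H)^2)), 0.01)
  # a slow drift, period 8 hr > 2x the 1-hr baseline window
  tr3 <- sim$trace
  tr3$P_Pa <- tr3$P_Pa + 6000 + 5000 * sin(2 * pi * tr3$t_s / (8 * 3600))
  kin3 <- process_trace(tr3, spec$geometry, spec$Q_g)
  expect_lt(sqrt(mean(((kin3$z_m - kin$z_m) / H)^2)), 0.01)
})

test_that("zero gas flow gives zero hold-up and pure-liquid density", {
  t <- 0:7199
  z <- 8 + 7.9 * sin(2 * pi * t / 500)
  P <- 1.2e5 + 1030 * 9.81 * (16 - z)
  tr <- sensor_trace("d", t, P)
  geom <- reactor_geometry(5.3, 30)
  kin <- process_trace(tr, geom, profile_function(0))
  expect_true(all(kin$eps == 0))
  expect_true(all(kin$rho_f == 1030))
  expect_lt(sqrt(mean((kin$z_m - z)^2)) / 16, 0.01)
})

test_that("device selection picks densities closest to the dispersion", {
  rho_p <- c(a = 850, b = 900, c = 950)
  expect_identical(select_devices(rho_p, 930), "c")
  expect_identical(select_devices(rho_p, 875), c("a", "b"))
  expect_identical(select_devices(rho_p, 930, pool_all = TRUE), c("a", "b", "c"))
})
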