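make_kin <- function(t, z, v, eps = 0.1, P = 2e5, T_K = 306, id = "d") {
  k <- data.frame(device_id = id, t_s = t, z_m = z, v_z_m_per_s = v,
                  eps = eps, rho_f = dispersion_density(eps), P_Pa = P,
                  T_K = T_K)
  class(k) <- c("axial_kinematics", "data.frame")
  k
}

test_that("step liquid height recovers the pressure swing and warns on confinement", {
  rho <- 1000; H <- 16
  t <- 0:3599
  z <- runif(length(t), 0, H)
  z[1] <- 0; z[2] <- H
  kin <- make_kin(t, z, 0, eps = 0, P = 1.2e5 + rho * 9.81 * (H - z))
  kin$rho_f <- rho
  expect_equal(step_liquid_height(kin, 0, 3600), H)
  # device stuck in the bottom half: underestimates, flagged
  z2 <- runif(length(t), 0, H / 2)
  kin2 <- make_kin(t, z2, 0, eps = 0, P = 1.2e5 + rho * 9.81 * (H - z2))
  kin2$rho_f <- rho
  expect_warning(H2 <- step_liquid_height(kin2, 0, 3600, H_prev = H),
                 "traverse")
  expect_lt(H2, 0.6 * H)
  expect_error(step_liquid_height(kin, 5000, 6000), "no samples")
})

test_that("interface velocity statistics pool samples in the capture band", {
  t <- 0:999
  z <- seq(0, 10, length.out = 1000)
  st <- interface_velocity_stats(make_kin(t, z, 0.5), c(2.5, 5, 7.5), 0, 1000)
  expect_equal(st$v_mean, rep(0.5, 3))
  expect_equal(st$n, rep(50, 3))  # 0.5 m band over a 10 m sweep of 1000 samples
  # symmetric up/down field: the magnitude statistic is unchanged
  st2 <- interface_velocity_stats(make_kin(t, z, rep(c(0.5, -0.5), 500)),
                                  c(2.5, 5, 7.5), 0, 1000)
  expect_equal(st2$v_mean, rep(0.5, 3))
  # empty window reports zero counts, not an error
  st3 <- interface_velocity_stats(make_kin(t, z, 0.5), c(5), 2000, 3000)
  expect_equal(st3$n, 0L)
})

test_that("interface flows scale with open area and speed", {
  A <- pi * 5.3^2 / 4
  expect_equal(interface_flows(0, A, 0.1), 0)
  expect_equal(interface_flows(0.4, A, 0.1711544641), 3.657170593,
               tolerance = 1e-8)
  expect_equal(interface_flows(0.8, A, 0.2), 2 * interface_flows(0.4, A, 0.2))
})

test_that("autozone applies the residence-time rule and its limits", {
  # tau = (1+1)/1 = 2 s > 1.5 s: no merge
  expect_equal(autozone(c(1, 1), 1, tau_crit = 1.5), list(1L, 2L))
  # tau = 2/2 = 1 s <= 1.5 s: merge
  expect_equal(autozone(c(1, 1), 2, tau_crit = 1.5), list(1:2))
  # infinite flows: the whole column is one zone
  K <- 20
  expect_equal(autozone(rep(1, K), rep(Inf, K - 1)), list(1:20))
  # zero flow isolates every compartment
  expect_equal(length(autozone(rep(1, 3), c(0, 0))), 3L)
})

test_that("zoning is monotone: scaling flows up never adds zones", {
  set.seed(42)
  for (rep in 1:25) {
    K <- sample(5:40, 1)
    V <- runif(K, 2, 12)
    Q <- runif(K - 1, 0.5, 12)
    n0 <- length(autozone(V, Q, tau_crit = 1.5))
    for (c_scale in c(1.5, 3, 10)) {
      n1 <- length(autozone(V, Q * c_scale, tau_crit = 1.5))
      expect_lte(n1, n0)
    }
  }
})

test_that("built steps conserve volume and respect the zone partition", {
  model <- ref("model")
  A <- ref("spec")$geometry$A
  for (s in model$steps[c(1, 16, 32)]) {
    expect_equal(sum(s$V), (1 - s$eps_mean) * A * s$H_L,
                 tolerance = 1e-3)
    expect_equal(sum(s$zV), sum(s$V), tolerance = 1e-12)
    expect_identical(unlist(s$zones), seq_along(s$V))
    expect_true(all(s$n_samples >= 30))
    expect_true(all(s$Q >= 0))
    expect_equal(length(s$Q), length(s$V) - 1L)
  }
  # 32 hr of data at a 1-hr update interval gives 32 steps
  expect_length(model$steps, 32L)
})

test_that("uniform velocity field yields near-uniform interface flows", {
  # speed incommensurate with the 1 Hz sampling so positions do not
  # lock onto a lattice that misses capture bands
  spec <- piecewise_plant(block_speeds = 0.83, block_height = 99, H = 16)
  ds <- plant_dataset(spec, n_devices = 2, seed = 3, duration = 2 * 3600,
                      noise_P = 0)
  model <- build_dynamic_model(ds$truths, spec$geometry)
  s <- model$steps[[1]]
  expect_equal(length(s$V), 32L)  # 16 m / 0.5 m
  expect_lt(max(abs(s$Q / median(s$Q) - 1)), 0.1)
})

test_that("prescribed piecewise-constant speeds are recovered in the flows", {
  speeds <- c(0.6, 1.2, 2.0, 1.4)
  spec <- piecewise_plant(block_speeds = speeds, block_height = 4, H = 16)
  ds <- plant_dataset(spec, n_devices = 3, seed = 4, duration = 2 * 3600,
                      noise_P = 0)
  model <- build_dynamic_model(ds$truths, spec$geometry)
  s <- model$steps[[1]]
  A <- spec$geometry$A
  internal <- s$interfaces[-c(1, length(s$interfaces))]
  block <- floor(internal / 4) + 1
  interior <- abs(internal - 4 * round(internal / 4)) > 0.3  # off block edges
  expect_true(all(s$n_samples[interior] >= 30))
  v_hat <- s$Q[interior] / (A * (1 - s$eps[pmin(block, 4)][interior]) / 2)
  expect_lt(max(abs(v_hat / speeds[block[interior]] - 1)), 0.1)
})
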