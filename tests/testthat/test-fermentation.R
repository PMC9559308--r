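test_that("specific growth rate reproduces its Monod limits", {
  p <- kinetic_params()
  expect_equal(specific_growth_rate(10, 0.01, p$K_p, p), 0)
  expect_equal(specific_growth_rate(1e6, 1e6, 0, p), p$mu_max,
               tolerance = 1e-4)
  expect_equal(specific_growth_rate(p$K_s, p$K_o, 0, p), p$mu_max / 4)
  # product above the critical concentration: death (negative growth)
  expect_lt(specific_growth_rate(10, 0.01, 1.5 * p$K_p, p), 0)
})

test_that("reaction rates follow the yield structure", {
  p <- kinetic_params(mu_max = 0.4, K_s = 0.05, K_o = 0.001, K_p = 150,
                      Y_px = 1.2, r_xp = 0.08, Y_xs = 0.3, Y_ps = 0.5,
                      Y_so = 3, r_ms = 0.02, r_mo = 0.01)
  # saturating conditions, gates fully open (K_gate = 0): literal equations
  r <- reaction_rates(1e9, 1e9, 0, p, K_gate = 0, K_gate_o = 0)
  mu <- p$mu_max
  r_p <- 1.2 * mu + 0.08
  r_s <- mu / 0.3 + r_p / 0.5 + 0.02
  expect_equal(r$mu, mu, tolerance = 1e-6)
  expect_equal(r$r_p, r_p, tolerance = 1e-6)
  expect_equal(r$r_s, r_s, tolerance = 1e-6)
  expect_equal(r$r_o, r_s / 3 + 0.01, tolerance = 1e-6)
  # all-zero maintenance/production and mu = 0 gives all-zero rates
  p0 <- kinetic_params(r_xp = 0, r_ms = 0, r_mo = 0)
  r0 <- reaction_rates(10, 0.01, p0$K_p, p0)
  expect_equal(unlist(r0), c(mu = 0, r_p = 0, r_s = 0, r_o = 0))
  # substrate uptake increases with growth rate
  rs <- sapply(c(0, 1, 5, 50), function(Cs)
    reaction_rates(Cs, 1e9, 0, p)$r_s)
  expect_true(all(diff(rs) > 0))
})

test_that("kLa correlation and Henry-law saturation evaluate correctly", {
  expect_identical(local_kla(0), 0)
  expect_equal(local_kla(1), 0.288)
  expect_equal(local_kla(0.215), 0.06192)
  expect_equal(oxygen_saturation(101325), 0.010056)
  expect_equal(oxygen_saturation(2 * 101325), 2 * 0.010056)
  expect_equal(oxygen_saturation(101325, x_o2 = 0), 0)
  expect_error(oxygen_saturation(-1), "positive")
})

test_that("a single closed zone matches an independent RK4 oracle", {
  p <- kinetic_params()
  tf <- list(kla = 120, C_sat = 0.008)
  s0 <- list(C_x = 2, C_s = 20, C_p = 5, C_o = 0.008)
  out <- simulate_step(list(V = 50, Q = numeric(0)), s0, tf, p,
                       dt = 3600, n_out = 36, rtol = 1e-10, atol = 1e-12)
  # fixed-step RK4 on the same closed-system equations
  rk4 <- function(y, h, nstep) {
    f <- function(y) {
      r <- reaction_rates(y[2], y[4], y[3], p)
      c(r$mu * y[1], -r$r_s * y[1], r$r_p * y[1],
        tf$kla * (tf$C_sat - y[4]) - r$r_o * y[1])
    }
    for (i in seq_len(nstep)) {
      k1 <- f(y); k2 <- f(y + h / 2 * k1)
      k3 <- f(y + h / 2 * k2); k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  oracle <- rk4(c(2, 20, 5, 0.008), h = 1 / 36000, nstep = 36000)
  final <- c(out$C_x[37], out$C_s[37], out$C_p[37], out$C_o[37])
  expect_equal(final, oracle, tolerance = 1e-5)
})

test_that("compiled and R integration engines agree", {
  model <- ref("model")
  spec <- ref("spec")
  s <- model$steps[[1]]
  tf <- transfer_field(s, spec$geometry, spec$Q_g, spec$kla_coeff)
  a <- simulate_step(s, spec$initial, tf, spec$params, feed_rate = 0.4,
                     rtol = 1e-8, atol = 1e-10, engine = "compiled")
  b <- simulate_step(s, spec$initial, tf, spec$params, feed_rate = 0.4,
                     rtol = 1e-8, atol = 1e-10, engine = "R")
  for (v in c("C_x", "C_s", "C_p", "C_o"))
    expect_equal(a[[v]], b[[v]], tolerance = 1e-6)
})

test_that("oxygen relaxes monotonically to saturation without consumers", {
  p <- kinetic_params()
  tf <- list(kla = 150, C_sat = 0.01)
  out <- simulate_step(list(V = 50, Q = numeric(0)),
                       list(C_x = 0, C_s = 0, C_p = 0, C_o = 0),
                       tf, p, dt = 3600, n_out = 30)
  expect_true(all(diff(out$C_o) >= -1e-8))  # solver wiggle near saturation
  expect_equal(out$C_o[31], 0.01, tolerance = 1e-6)
  expect_true(all(out$C_o <= 0.01 * (1 + 1e-6)))
})

test_that("without reactions the step reduces to the tracer problem", {
  V <- c(10, 20, 15); Q <- c(0.5, 0.8)
  p <- kinetic_params()
  # oxygen and substrate zero so every reaction term vanishes; kla = 0
  out <- simulate_step(list(V = V, Q = Q),
                       list(C_x = c(3, 0, 0), C_s = 0, C_p = c(0, 0, 4),
                            C_o = 0),
                       list(kla = 0, C_sat = 0.01), p, dt = 7200, n_out = 20)
  mass_x <- out$C_x %*% V
  mass_p <- out$C_p %*% V
  expect_lt(max(abs(mass_x / mass_x[1] - 1)), 1e-9)
  expect_lt(max(abs(mass_p / mass_p[1] - 1)), 1e-9)
  # concentrations homogenise toward mass/volume
  expect_equal(out$C_x[21, ], rep(30 / 45, 3), tolerance = 1e-3)
})

test_that("re-binning conserves mass and splits volumes proportionally", {
  # identical geometries: identity map
  s <- list(V = c(5, 10, 5))
  st <- list(a = c(1, 2, 3), b = c(0, 1, 0))
  expect_equal(rebin_state(st, s, s), st)
  # one compartment split in half by a new interface: fifty-fifty
  out <- rebin_state(list(c = c(2)), list(V = 10), list(V = c(5, 5)))
  expect_equal(out$c, c(2, 2))  # same concentration, half the mass each
  m <- out$c * c(5, 5)
  expect_equal(sum(m), 2 * 10)
  # random consecutive geometries conserve every species' mass to 1e-12
  set.seed(99)
  for (i in 1:50) {
    n0 <- sample(2:12, 1); n1 <- sample(2:12, 1)
    V0 <- runif(n0, 1, 20); V1 <- runif(n1, 1, 20)
    C0 <- list(x = runif(n0, 0, 5), s = runif(n0, 0, 30))
    C1 <- rebin_state(C0, list(V = V0), list(V = V1))
    for (v in names(C0))
      expect_equal(sum(C1[[v]] * V1), sum(C0[[v]] * V0), tolerance = 1e-12)
  }
})

test_that("fed substrate is fully accounted for across a step", {
  V <- c(30, 40); Q <- 2
  p <- kinetic_params()
  s0 <- list(C_x = 1, C_s = 5, C_p = 1, C_o = 0.005)
  n <- 600
  out <- simulate_step(list(V = V, Q = Q), s0,
                       list(kla = 100, C_sat = 0.01), p, feed_rate = 0.3,
                       dt = 1800, n_out = n, rtol = 1e-11, atol = 1e-13)
  fed <- 0.3 * 1800
  s_end <- sum(out$C_s[n + 1, ] * V)
  s_start <- sum(5 * V)
  # consumed = integral of r_s * C_x * V (Simpson on the output grid)
  rs_cx <- sapply(seq_len(n + 1), function(i) {
    r <- reaction_rates(out$C_s[i, ], out$C_o[i, ], out$C_p[i, ], p)
    sum(r$r_s * out$C_x[i, ] * V)
  })
  h <- out$t_hr[2] - out$t_hr[1]
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  consumed <- sum(w * rs_cx) * h / 3
  expect_equal(s_start + fed - consumed, s_end, tolerance = 1e-6)
})

test_that("raising flows to extreme values reproduces ideal mixing", {
  model <- ref("model")
  spec <- ref("spec")
  sub <- model; sub$steps <- model$steps[1:4]
  run <- simulate_fermentation(sub, spec$F_s, spec$Q_g, spec$params,
                               initial = spec$initial,
                               kla_coeff = spec$kla_coeff,
                               flow_multiplier = 1e3, n_out = 2,
                               rtol = 1e-6, atol = 1e-9)
  tr <- run$trajectory
  last <- tr[tr$t_hr == max(tr$t_hr), ]
  for (v in c("C_x", "C_s", "C_p"))
    expect_lt(diff(range(last[[v]])) / max(mean(last[[v]]), 1e-6), 0.01)
})

test_that("DO stays within physical bounds over the full reference run", {
  run <- ref("run")
  tr <- run$trajectory
  spec <- ref("spec")
  csat_max <- oxygen_saturation(max(sapply(ref("model")$steps,
                                           function(s) max(s$z_P))))
  expect_true(all(tr$C_o >= -1e-9))
  expect_true(all(tr$C_o <= csat_max * (1 + 1e-6)))
  expect_true(all(tr$C_x >= 0 & tr$C_s >= -1e-8 & tr$C_p >= 0))
})

test_that("feed reallocation preserves the total fed substrate", {
  spec <- ref("spec")
  f2 <- modify_profile(spec$F_s, 0.07, 6, 13)
  f3 <- modify_profile(f2, -0.07, 23, 30)
  tt <- seq(0, 32 * 3600, by = 60)
  total0 <- sum(spec$F_s(tt)) * 60
  total3 <- sum(f3(tt)) * 60
  expect_equal(total3, total0, tolerance = 1e-10)
  expect_gt(sum(f3(seq(6, 13, by = 1 / 60) * 3600)),
            sum(spec$F_s(seq(6, 13, by = 1 / 60) * 3600)))
})

test_that("rerunning the reference simulation is deterministic", {
  spec <- ref("spec")
  sub <- ref("model"); sub$steps <- sub$steps[1:2]
  r1 <- simulate_fermentation(sub, spec$F_s, spec$Q_g, spec$params,
                              initial = spec$initial, kla_coeff = spec$kla_coeff)
  r2 <- simulate_fermentation(sub, spec$F_s, spec$Q_g, spec$params,
                              initial = spec$initial, kla_coeff = spec$kla_coeff)
  expect_identical(r1$summary, r2$summary)
})
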