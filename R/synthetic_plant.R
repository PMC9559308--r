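#' Reference virtual-plant scenario
#'
#' Packaged ground-truth scenario of an industrial-scale bubble-column
#' fed-batch: a 5.3 m diameter column whose gassed liquid height ramps
#' from 16 m to 26 m over a 32 hr process, with a feed-rate profile
#' that ramps up early and tapers late, a gas-flow profile with a
#' late-process rampdown, a slowly drifting headspace pressure, a
#' single-peak axial circulation field (strong mid-column motion, weak
#' ends) whose intensity follows the gas flow, and Monod/Luedeking-Piret
#' truth kinetics.  All synthetic datasets and every packaged test
#' fixture derive from this spec plus a seed.
#'
#' @param noise_P pressure-noise standard deviation of the simulated
#'   sensor devices, Pa.
#' @param obs_cv coefficient of variation of the simulated offline
#'   observations.
#' @return A `plant_spec` list with fields `geometry`, `t_end` (s),
#'   `H_L` (function of t, m), `P_head` (function of t, Pa), `Q_g`
#'   (function of t, Nm^3/s), `F_s` (function of t, kg/s), `speed`
#'   (function(z, t), m/s), `switch_rate` (1/s), `params` (truth
#'   kinetics), `kla_coeff` ((1/hr)/(m/s)), `initial` (start
#'   concentrations, kg/m^3), `noise_P`, `obs_cv`.
#' @export
reference_plant <- function(noise_P = 200, obs_cv = 0.05) {
  t_end <- 32 * 3600
  geometry <- reactor_geometry(D = 5.3, H_total = 30, probe_clearance = 5.85)
  H_L <- function(t) 16 + 10 * t / t_end
  P_head <- function(t) 121325 + 2000 * sin(2 * pi * t / (8 * 3600))
  Q_g <- profile_function(data.frame(
    t_s = c(0, 5, 18, 32) * 3600, value = c(3.8, 4.75, 4.75, 1.8)))
  F_s <- profile_function(data.frame(
    t_s = c(0, 6, 9, 14, 26, 32) * 3600,
    value = c(0.25, 0.35, 1.3, 1.85, 1.85, 1.5)))
  Qg_ref <- 4.75
  speed <- function(z, t) {
    zh <- pmin(pmax(z / H_L(t), 0), 1)
    (0.25 + 2.1 * sin(pi * zh)^0.7) * (Q_g(t) / Qg_ref)^(2 / 3)
  }
  structure(list(
    geometry = geometry, t_end = t_end, H_L = H_L, P_head = P_head,
    Q_g = Q_g, F_s = F_s, speed = speed, switch_rate = 1 / 30,
    params = kinetic_params(), kla_coeff = 3000,
    initial = list(C_x = 1.5, C_s = 8, C_p = 10, C_o = 0.01),
    noise_P = noise_P, obs_cv = obs_cv
  ), class = "plant_spec")
}

## scalar column-mean dispersion density at time t (two fixed-point passes)
plant_fluid_density <- function(spec, t, T_K = 306) {
  H <- spec$H_L(t)
  Ph <- spec$P_head(t)
  A <- spec$geometry$A
  rho <- rep(dyncomp_constants$rho_l, length(t))
  for (i in 1:3) {
    P_mid <- Ph + rho * dyncomp_constants$g * H / 2
    v_s <- superficial_gas_velocity(spec$Q_g(t), P_mid, T_K, A)
    eps <- gas_holdup(v_s, spec$geometry$D)
    rho <- dispersion_density(eps)
  }
  list(rho_f = rho, eps = eps, v_s = v_s)
}

#' Simulate a flow-following sensor device
#'
#' Random-walk particle model of a flow-follower: the particle moves
#' with the local axial speed of the prescribed velocity field, in a
#' direction that switches randomly (telegraph process, equal up/down
#' occupancy) and reflects at the vessel bottom and the rising liquid
#' surface.  The emitted pressure is hydrostatic,
#' \eqn{P(t) = P_{head}(t) + \rho_f(t) g (H_L(t) - z(t))} plus Gaussian
#' sensor noise, with the instantaneous column-mean dispersion density
#' \eqn{\rho_f(t)}; temperature is constant at 306 K.
#'
#' @param spec a `plant_spec` (see [reference_plant()]).
#' @param device_id device label.
#' @param rho_p device density, kg/m^3 (metadata only; slip is not
#'   modelled).
#' @param duration trace length, s (default: the full process).
#' @param dt sampling interval, s (default 1, as logged by the devices).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param noise_P pressure noise sd, Pa (default: from the spec).
#' @param z0 start height, m (default: mid-column).
#' @return List with `trace` (a [sensor_trace()]) and `truth` (an
#'   `axial_kinematics` data.frame with the exact `z_m`, `v_z_m_per_s`,
#'   `eps`, `rho_f` used in generation).
#' @export
simulate_flow_follower <- function(spec, device_id = "dev1", rho_p = 950,
                                   duration = NULL, dt = 1, seed = NULL,
                                   noise_P = NULL, z0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) duration <- spec$t_end
  if (duration > spec$t_end) stop("duration exceeds the plant horizon")
  if (is.null(noise_P)) noise_P <- spec$noise_P
  t <- seq(0, duration - dt, by = dt)
  n <- length(t)
  H <- spec$H_L(t)
  if (is.null(z0)) z0 <- H[1L] / 2
  p_switch <- 1 - exp(-spec$switch_rate * dt)
  u <- stats::runif(n)
  z <- numeric(n)
  v <- numeric(n)
  zi <- z0
  dir <- if (stats::runif(1) < 0.5) -1 else 1
  for (i in seq_len(n)) {
    if (u[i] < p_switch) dir <- -dir
    si <- spec$speed(zi, t[i])
    v[i] <- dir * si
    z[i] <- zi
    zi <- zi + dir * si * dt
    Hi <- H[min(i + 1L, n)]
    if (zi < 0) { zi <- -zi; dir <- 1 }
    if (zi > Hi) { zi <- 2 * Hi - zi; dir <- -1 }
    zi <- min(max(zi, 0), Hi)
  }
  fl <- plant_fluid_density(spec, t)
  P <- spec$P_head(t) + fl$rho_f * dyncomp_constants$g * (H - z)
  if (noise_P > 0) P <- P + stats::rnorm(n, 0, noise_P)
  P <- pmax(P, spec$P_head(t))  # device cannot read below headspace pressure
  trace <- sensor_trace(device_id, t, P, T_K = 306, rho_p = rho_p)
  truth <- data.frame(device_id = device_id, t_s = t, z_m = z,
                      v_z_m_per_s = v, eps = fl$eps, rho_f = fl$rho_f,
                      P_Pa = P, T_K = 306)
  class(truth) <- c("axial_kinematics", "data.frame")
  list(trace = trace, truth = truth)
}

#' Generate the full flow-follower dataset of a plant scenario
#'
#' @param spec a `plant_spec`.
#' @param n_devices number of devices.
#' @param rho_p device density (kg/m^3), recycled over devices.
#' @param seed RNG seed; per-device seeds are derived from it.
#' @param ... passed to [simulate_flow_follower()].
#' @return List with `traces` and `truths`, each a named list by device.
#' @export
plant_dataset <- function(spec, n_devices = 3, rho_p = 950, seed = 1, ...) {
  rho_p <- rep_len(rho_p, n_devices)
  ids <- sprintf("dev%d", seq_len(n_devices))
  sims <- lapply(seq_len(n_devices), function(i)
    simulate_flow_follower(spec, device_id = ids[i], rho_p = rho_p[i],
                           seed = seed * 1000L + i, ...))
  list(traces = stats::setNames(lapply(sims, `[[`, "trace"), ids),
       truths = stats::setNames(lapply(sims, `[[`, "truth"), ids))
}

#' Sample noisy offline observations from a fermentation run
#'
#' Emulates the offline sampling of a fed-batch: height-averaged
#' biomass, substrate and product concentrations plus the probe-height
#' dissolved oxygen at `n_times` uniformly spaced times, with
#' multiplicative lognormal noise of coefficient of variation `cv`
#' (mean-one noise factors).
#'
#' @param run a `fermentation_run` (see [simulate_fermentation()]).
#' @param probe_height DO probe height, m (recorded in the output).
#' @param n_times number of sampling times.
#' @param cv observation coefficient of variation; 0 gives exact values.
#' @param seed RNG seed.
#' @param t_range sampling window, hr (default: from 1 hr to the end).
#' @return data.frame of class `observation_set` with columns `t_hr`,
#'   `variable` (biomass/substrate/product/DO), `value` (kg/m^3),
#'   `height_m` (NA except for DO).
#' @export
make_observations <- function(run, probe_height = 5.85, n_times = 15,
                              cv = 0.05, seed = NULL,
                              t_range = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- run$summary
  if (is.null(t_range)) t_range <- c(max(1, s$t_hr[1L]), max(s$t_hr))
  tt <- seq(t_range[1L], t_range[2L], length.out = n_times)
  ip <- function(col) stats::approx(s$t_hr, s[[col]], xout = tt, rule = 2)$y
  vals <- c(ip("C_x_avg"), ip("C_s_avg"), ip("C_p_avg"), ip("C_o_probe"))
  vars <- rep(c("biomass", "substrate", "product", "DO"), each = n_times)
  if (cv > 0) {
    sl2 <- log(1 + cv^2)
    vals <- vals * stats::rlnorm(length(vals), -sl2 / 2, sqrt(sl2))
  }
  out <- data.frame(t_hr = rep(tt, 4L), variable = vars, value = vals,
                    height_m = ifelse(vars == "DO", probe_height, NA_real_))
  class(out) <- c("observation_set", "data.frame")
  out
}
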