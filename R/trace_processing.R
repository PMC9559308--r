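#' Construct a flow-following sensor trace
#'
#' A sensor trace holds the 1 Hz pressure/temperature log of one
#' flow-following device together with its (ballast-adjusted) density.
#'
#' @param device_id character scalar identifying the device.
#' @param t time since inoculation, s; strictly increasing, nominally 1 Hz.
#' @param P absolute pressure, Pa; strictly positive.
#' @param T_K temperature, K. A scalar is recycled.
#' @param rho_p device density, kg/m^3.
#' @return A `data.frame` of class `sensor_trace` with columns
#'   `device_id`, `t_s`, `P_Pa`, `T_K` and attribute `rho_p`.
#' @export
sensor_trace <- function(device_id, t, P, T_K = 306, rho_p = 950) {
  stopifnot(length(t) >= 2L, length(P) == length(t))
  if (any(diff(t) <= 0)) stop("trace times must be strictly increasing")
  if (any(!is.finite(P)) || any(P <= 0)) stop("pressures must be finite and positive")
  if (length(T_K) == 1L) T_K <- rep(T_K, length(t))
  out <- data.frame(device_id = as.character(device_id), t_s = as.numeric(t),
                    P_Pa = as.numeric(P), T_K = as.numeric(T_K))
  attr(out, "rho_p") <- rho_p
  class(out) <- c("sensor_trace", "data.frame")
  out
}

#' Gas hold-up from superficial gas velocity
#'
#' Heterogeneous-regime hold-up correlation for bubble columns:
#' \deqn{\epsilon = \frac{v_s}{0.25 + 0.45 (g v_s D)^{1/3}}}
#'
#' @param v_s superficial gas velocity, m/s (vectorised, >= 0).
#' @param D column diameter, m.
#' @param g gravitational acceleration, m/s^2.
#' @return Gas volume fraction in [0, 1); 0 where `v_s = 0`.
#' @examples
#' gas_holdup(0.215, D = 5.3)  # ~0.171
#' @export
gas_holdup <- function(v_s, D, g = dyncomp_constants$g) {
  if (any(v_s < 0)) stop("v_s must be non-negative")
  if (D <= 0) stop("D must be positive")
  ifelse(v_s == 0, 0, v_s / (0.25 + 0.45 * (g * v_s * D)^(1 / 3)))
}

#' Density of the gas-liquid dispersion
#'
#' Volume-weighted mean of the liquid and gas densities,
#' \eqn{\rho_f = (1-\epsilon)\rho_l + \epsilon \rho_g}.
#'
#' @param eps gas hold-up, in [0, 1) (vectorised).
#' @param rho_l liquid density, kg/m^3.
#' @param rho_g gas density, kg/m^3.
#' @return Dispersion density, kg/m^3.
#' @export
dispersion_density <- function(eps, rho_l = dyncomp_constants$rho_l,
                               rho_g = dyncomp_constants$rho_g) {
  if (any(eps < 0 | eps >= 1)) stop("eps must lie in [0, 1)")
  if (rho_l <= rho_g || rho_g < 0) stop("require rho_l > rho_g >= 0")
  (1 - eps) * rho_l + eps * rho_g
}

## O(n) centred rolling extreme (max/min) with partial windows at the
## edges, using the two-pass block prefix/suffix scan.  `width` in samples.
rolling_extreme <- function(x, width, which = c("max", "min")) {
  which <- match.arg(which)
  n <- length(x)
  w <- max(1L, as.integer(width))
  if (w >= n) return(rep(if (which == "max") max(x) else min(x), n))
  cfun <- if (which == "max") cummax else cummin
  block <- (seq_len(n) - 1L) %/% w
  pref <- stats::ave(x, block, FUN = cfun)
  suff <- rev(stats::ave(rev(x), rev(block), FUN = cfun))
  trailing <- function(v_pref, v_suff) {
    out <- v_pref                       # partial head windows
    i <- w:n
    lo <- i - w + 1L
    out[i] <- if (which == "max") pmax(v_suff[lo], v_pref[i]) else
      pmin(v_suff[lo], v_pref[i])
    out
  }
  tw <- trailing(pref, suff)
  # leading (forward) window maxima on the reversed series for the tail
  xr <- rev(x)
  pref_r <- stats::ave(xr, block, FUN = cfun)
  suff_r <- rev(stats::ave(rev(xr), rev(block), FUN = cfun))
  twr <- rev(trailing(pref_r, suff_r))  # twr[j] = extreme of x[j .. min(n, j+w-1)]
  h2 <- (w - 1L) %/% 2L
  h1 <- w - 1L - h2
  i <- seq_len(n)
  out <- numeric(n)
  head_i <- i[i + h2 <= n]
  out[head_i] <- tw[head_i + h2]
  tail_i <- i[i + h2 > n]
  if (length(tail_i)) out[tail_i] <- twr[pmax(1L, tail_i - h1)]
  out
}

## centred rolling mean with partial windows, exact via cumulative sums
rolling_mean <- function(x, width) {
  n <- length(x)
  w <- max(1L, as.integer(width))
  if (w >= 2L * n) return(rep(mean(x), n))
  h2 <- (w - 1L) %/% 2L
  h1 <- w - 1L - h2
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - h1)
  hi <- pmin(n, seq_len(n) + h2)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Dynamic bottom-pressure baseline of a sensor trace
#'
#' The pressure a device would read at the vessel bottom drifts with
#' headspace pressure and liquid-volume growth.  Provided the device
#' visits the bottom at least once per `window_max`, the rolling maximum
#' of the measured pressure tracks that bottom pressure; a rolling mean
#' then removes the staircase artifacts of the maximum filter.
#'
#' @param trace a [sensor_trace()] (or any data.frame with `t_s`, `P_Pa`).
#' @param window_max rolling-maximum window, s (default 3600).
#' @param window_smooth rolling-mean smoothing window, s (default 600).
#' @return Numeric baseline series, Pa, same length as the trace.
#' @export
baseline_pressure <- function(trace, window_max = 3600, window_smooth = 600) {
  t <- trace$t_s; P <- trace$P_Pa
  if (diff(range(t)) < window_max)
    stop("trace duration is shorter than the rolling-maximum window: ",
         "insufficient data for baseline estimation")
  dt <- stats::median(diff(t))
  w_max <- max(1L, round(window_max / dt))
  w_sm <- max(1L, round(window_smooth / dt))
  rolling_mean(rolling_extreme(P, w_max, "max"), w_sm)
}

#' Axial position from hydrostatic pressure (Pascal's law)
#'
#' \eqn{z(t) = (P_{max} - P(t)) / (\rho_f g)}, with \eqn{z = 0} at the
#' vessel bottom.  Small negative pressure differences (noise while the
#' device sits at the bottom) are clipped to \eqn{z = 0}; if `H_L` is
#' given, positions are clipped to the instantaneous liquid height.
#'
#' @param P measured pressure, Pa (vectorised).
#' @param P_max bottom-pressure baseline, Pa (scalar or vector).
#' @param rho_f dispersion density, kg/m^3 (scalar or vector, > 0).
#' @param g gravitational acceleration, m/s^2.
#' @param H_L optional instantaneous liquid height, m, used as upper clip.
#' @return Axial position, m above the vessel bottom.
#' @export
pressure_to_position <- function(P, P_max, rho_f, g = dyncomp_constants$g,
                                 H_L = NULL) {
  if (any(rho_f <= 0)) stop("rho_f must be positive")
  z <- (P_max - P) / (rho_f * g)
  z <- pmax(z, 0)
  if (!is.null(H_L)) z <- pmin(z, H_L)
  z
}

#' Axial velocity by finite differencing of the position series
#'
#' Central finite differences of `z` with respect to `t` after an
#' optional centred moving-average pre-smoothing of `z` (suppresses the
#' 1 Hz pressure noise); the endpoints use one-sided differences.
#'
#' @param t time, s (strictly increasing, >= 3 samples).
#' @param z axial position, m.
#' @param smooth pre-smoothing window for `z`, s; 0 disables smoothing.
#' @return Axial velocity series, m/s, same length as `z`.
#' @export
axial_velocity <- function(t, z, smooth = 5) {
  n <- length(t)
  if (n < 3L) stop("at least 3 samples are required")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (smooth > 0) {
    dt <- stats::median(diff(t))
    w <- max(1L, round(smooth / dt))
    if (w > 1L) z <- rolling_mean(z, w)
  }
  v <- numeric(n)
  v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (z[2] - z[1]) / (t[2] - t[1])
  v[n] <- (z[n] - z[n - 1]) / (t[n] - t[n - 1])
  v
}

#' Superficial gas velocity corrected to local conditions
#'
#' Converts a normalised gas flow (at `P_ref`, `T_ref`) to the actual
#' superficial velocity at the local pressure and temperature by
#' ideal-gas scaling: \eqn{v_s = Q_g (P_{ref}/P)(T/T_{ref}) / A}.
#'
#' @param Q_g gas volumetric flow at reference conditions, Nm^3/s.
#' @param P_local local absolute pressure, Pa.
#' @param T_local local temperature, K.
#' @param A column cross-sectional area, m^2.
#' @param P_ref,T_ref reference conditions of the normalised flow.
#' @return Superficial gas velocity, m/s.
#' @export
superficial_gas_velocity <- function(Q_g, P_local, T_local, A,
                                     P_ref = dyncomp_constants$P_ref,
                                     T_ref = dyncomp_constants$T_ref) {
  if (any(P_local <= 0)) stop("P_local must be positive")
  Q_g * (P_ref / P_local) * (T_local / T_ref) / A
}

#' Process a sensor trace into axial kinematics
#'
#' Full reconstruction pipeline for one device: the gas-flow profile is
#' converted to a superficial gas velocity at in-situ conditions, which
#' gives the instantaneous gas hold-up and dispersion density; the
#' rolling-maximum baseline absorbs headspace-pressure and volume-growth
#' drift; Pascal's law turns the baseline-corrected pressure into axial
#' position; finite differencing yields the axial velocity.
#'
#' The pressure used in the gas-velocity correction is, by default, the
#' device pressure averaged over the baseline window.  Because the
#' device sweeps the whole liquid height within that window, this
#' approximates the column-mean pressure, which is the quantity
#' consistent with the single instantaneous dispersion density that
#' Pascal's law assumes.  `vs_correction = "instantaneous"` uses the raw
#' local device pressure instead.
#'
#' @param trace a [sensor_trace()].
#' @param geometry a [reactor_geometry()].
#' @param gas_profile function of time (s) returning normalised gas flow
#'   Q_g, Nm^3/s (see [profile_function()]).
#' @param window_max,window_smooth baseline windows, s.
#' @param smooth_z velocity pre-smoothing window, s.
#' @param vs_correction `"window_mean"` (default) or `"instantaneous"`.
#' @param rho_l,rho_g,g physical constants.
#' @return A `data.frame` of class `axial_kinematics` with columns
#'   `device_id`, `t_s`, `z_m`, `v_z_m_per_s`, `eps`, `rho_f`, `P_Pa`,
#'   `T_K` and attribute `H_L_est` (baseline-derived liquid-height series).
#' @export
process_trace <- function(trace, geometry, gas_profile,
                          window_max = 3600, window_smooth = 600,
                          smooth_z = 5,
                          vs_correction = c("window_mean", "instantaneous"),
                          rho_l = dyncomp_constants$rho_l,
                          rho_g = dyncomp_constants$rho_g,
                          g = dyncomp_constants$g) {
  vs_correction <- match.arg(vs_correction)
  t <- trace$t_s; P <- trace$P_Pa
  if (diff(range(t)) < window_max)
    stop("trace does not cover the baseline window")
  Q_g <- gas_profile(t)
  dt <- stats::median(diff(t))
  P_corr <- if (vs_correction == "window_mean")
    rolling_mean(P, max(1L, round(window_max / dt))) else P
  v_s <- superficial_gas_velocity(Q_g, P_corr, trace$T_K, geometry$A)
  eps <- gas_holdup(v_s, geometry$D, g)
  rho_f <- dispersion_density(eps, rho_l, rho_g)
  base_max <- baseline_pressure(trace, window_max, window_smooth)
  base_min <- rolling_mean(rolling_extreme(P, max(1L, round(window_max / dt)), "min"),
                           max(1L, round(window_smooth / dt)))
  H_est <- pmax((base_max - base_min) / (rho_f * g), 0)
  z <- pressure_to_position(P, base_max, rho_f, g, H_L = H_est)
  v_z <- axial_velocity(t, z, smooth = smooth_z)
  out <- data.frame(device_id = trace$device_id, t_s = t, z_m = z,
                    v_z_m_per_s = v_z, eps = eps, rho_f = rho_f,
                    P_Pa = P, T_K = trace$T_K)
  attr(out, "H_L_est") <- H_est
  attr(out, "rho_p") <- attr(trace, "rho_p")
  class(out) <- c("axial_kinematics", "data.frame")
  out
}

#' Select devices by density match to the dispersion
#'
#' Flow-followers track the liquid best when their density is close to
#' the gas-liquid dispersion density.  Given the device densities and a
#' time-averaged dispersion density, returns the devices whose density
#' is closest (all devices sharing the minimal distance).
#'
#' @param rho_p named numeric vector of device densities, kg/m^3
#'   (names are device ids).
#' @param rho_f_mean time-averaged dispersion density, kg/m^3.
#' @param pool_all if `TRUE`, return every device.
#' @return Character vector of selected device ids.
#' @export
select_devices <- function(rho_p, rho_f_mean, pool_all = FALSE) {
  if (is.null(names(rho_p))) stop("rho_p must be named by device id")
  if (pool_all) return(names(rho_p))
  d <- abs(rho_p - rho_f_mean)
  names(rho_p)[d == min(d)]
}
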