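#' Gassed liquid height over an update-step window
#'
#' The liquid height during an update step is obtained from the spread
#' of pressures the devices encountered: provided a device visits both
#' the bottom and the surface within the window,
#' \eqn{H_L = (P_{max} - P_{min}) / (\rho_f g)}.
#'
#' @param kins one `axial_kinematics` data.frame or a list of them
#'   (pooled); must carry `P_Pa` and `rho_f` columns.
#' @param t_start,t_end window bounds, s.
#' @param rho_f dispersion density to use, kg/m^3; default is the mean
#'   of the per-sample densities in the window.
#' @param H_prev previous step's height, m; if given and the largest
#'   position swing covers less than 90% of it, a warning is raised
#'   (device likely did not traverse the full height).
#' @param g gravitational acceleration, m/s^2.
#' @return Liquid height, m.
#' @export
step_liquid_height <- function(kins, t_start, t_end, rho_f = NULL,
                               H_prev = NULL, g = dyncomp_constants$g) {
  if (inherits(kins, "data.frame")) kins <- list(kins)
  pool <- do.call(rbind, lapply(kins, function(k)
    k[k$t_s >= t_start & k$t_s < t_end, c("P_Pa", "rho_f")]))
  if (is.null(pool) || nrow(pool) == 0L) stop("no samples in window")
  if (is.null(rho_f)) rho_f <- mean(pool$rho_f)
  H <- (max(pool$P_Pa) - min(pool$P_Pa)) / (rho_f * g)
  if (!is.null(H_prev) && H < 0.9 * H_prev)
    warning(sprintf(
      "pressure swing in window [%g, %g) covers only %.0f%% of the previous liquid height; devices may not traverse the full column",
      t_start, t_end, 100 * H / H_prev))
  H
}

#' Mean axial speed and sample count at compartment interfaces
#'
#' Pools velocity samples from all devices that fall within a capture
#' band centred on each internal interface and reports the mean speed
#' |v_z| and the sample count (counts of zero are reported, not errors).
#'
#' @param kins one or a list of `axial_kinematics` data.frames.
#' @param interfaces internal interface heights, m (ascending).
#' @param t_start,t_end window bounds, s.
#' @param capture_band band width, m (samples with
#'   `|z - z_interface| <= capture_band/2` are used).
#' @return data.frame with columns `height`, `v_mean`, `n`, `eps_mean`.
#' @export
interface_velocity_stats <- function(kins, interfaces, t_start, t_end,
                                     capture_band = 0.5) {
  if (capture_band <= 0) stop("capture_band must be positive")
  if (is.unsorted(interfaces)) stop("interfaces must be sorted ascending")
  if (inherits(kins, "data.frame")) kins <- list(kins)
  pool <- do.call(rbind, lapply(kins, function(k)
    k[k$t_s >= t_start & k$t_s < t_end,
      c("z_m", "v_z_m_per_s", "eps")]))
  out <- data.frame(height = interfaces, v_mean = NA_real_,
                    n = 0L, eps_mean = NA_real_)
  if (is.null(pool) || nrow(pool) == 0L) return(out)
  half <- capture_band / 2
  for (i in seq_along(interfaces)) {
    sel <- abs(pool$z_m - interfaces[i]) <= half
    out$n[i] <- sum(sel)
    if (out$n[i] > 0L) {
      out$v_mean[i] <- mean(abs(pool$v_z_m_per_s[sel]))
      out$eps_mean[i] <- mean(pool$eps[sel])
    }
  }
  out
}

#' Bidirectional interface exchange flows
#'
#' The exchange flow through an interface is carried by the liquid
#' phase only, so the mean axial speed is scaled by the open area
#' \eqn{A (1-\epsilon)} and split symmetrically between the upward and
#' downward directions (zero net axial flow in a closed column):
#' \eqn{Q = A (1-\epsilon) \langle|v_z|\rangle / 2}.
#'
#' @param v_mean mean |v_z| per interface, m/s.
#' @param A column cross-sectional area, m^2.
#' @param eps gas hold-up at each interface.
#' @return Exchange flow per interface, m^3/s (one direction).
#' @export
interface_flows <- function(v_mean, A, eps) {
  if (any(eps < 0 | eps >= 1)) stop("eps must lie in [0, 1)")
  A * (1 - eps) * v_mean / 2
}

#' Automatic zoning of initial compartments
#'
#' Merges the fine initial compartments bottom-up into ideally mixed
#' zones.  A zone may grow by appending the next compartment as long as
#' its residence time, the zone volume over the smallest internal
#' exchange flow, does not exceed the critical residence time
#' `tau_crit`; a single compartment always forms a valid zone.
#'
#' @param V initial compartment volumes, m^3 (bottom to top).
#' @param Q internal interface flows, m^3/s (`length(V) - 1`).
#' @param tau_crit critical local residence time, s.
#' @return List of integer vectors, each a contiguous run of initial
#'   compartment indices forming one zone (a partition of `seq_along(V)`).
#' @examples
#' autozone(c(1, 1), Q = 1, tau_crit = 1.5)  # tau = 2 s: two zones
#' autozone(c(1, 1), Q = 2, tau_crit = 1.5)  # tau = 1 s: one zone
#' @export
autozone <- function(V, Q, tau_crit = dyncomp_constants$tau_crit) {
  K <- length(V)
  stopifnot(length(Q) == K - 1L, tau_crit > 0)
  if (K == 1L) return(list(1L))
  zones <- list()
  start <- 1L
  for (k in seq_len(K - 1L)) {
    # candidate zone start..k+1; internal interfaces start..k
    tau <- sum(V[start:(k + 1L)]) / min(Q[start:k])
    if (!is.finite(tau) || tau > tau_crit) {
      zones[[length(zones) + 1L]] <- start:k
      start <- k + 1L
    }
  }
  zones[[length(zones) + 1L]] <- start:K
  zones
}

## aggregate a step's initial compartments into its zones
zone_aggregate <- function(step) {
  z <- step$zones
  nz <- length(z)
  first <- vapply(z, function(i) i[1L], integer(1))
  last <- vapply(z, function(i) i[length(i)], integer(1))
  step$zV <- vapply(z, function(i) sum(step$V[i]), numeric(1))
  # flow retained at a zone boundary is the flow of that boundary interface
  step$zQ <- if (nz > 1L) step$Q[last[-nz]] else numeric(0)
  step$z_bounds <- step$interfaces[c(first, last[nz] + 1L)]
  wmean <- function(x, i) sum(x[i] * step$V[i]) / sum(step$V[i])
  step$z_eps <- vapply(z, function(i) wmean(step$eps, i), numeric(1))
  step$z_P <- vapply(z, function(i) wmean(step$P, i), numeric(1))
  step$z_T <- vapply(z, function(i) wmean(step$T, i), numeric(1))
  step$z_mid <- (step$z_bounds[-1L] + step$z_bounds[-(nz + 1L)]) / 2
  step
}

## interpolate per-compartment means over empty compartments
fill_gaps <- function(x, mids) {
  ok <- !is.na(x)
  if (all(ok)) return(x)
  if (!any(ok)) stop("no samples in any compartment")
  if (sum(ok) == 1L) return(rep(x[ok], length(x)))
  stats::approx(mids[ok], x[ok], xout = mids, rule = 2)$y
}

#' Build one compartment-model update step
#'
#' Lays interfaces every `dz0` from the bottom to the step's liquid
#' height, estimates interface exchange flows from the pooled velocity
#' samples, assigns per-compartment gas hold-up, pressure and
#' temperature, and zones the result.  Interfaces with fewer than
#' `min_samples` velocity samples are dropped, locally coarsening the
#' grid (the two adjacent compartments merge); two consecutive
#' deficient interfaces raise an error.
#'
#' @param kins one or a list of `axial_kinematics`.
#' @param geometry a [reactor_geometry()].
#' @param t_start,t_end window bounds, s.
#' @param dz0 initial compartment height, m.
#' @param tau_crit critical residence time, s.
#' @param min_samples minimum velocity samples per retained interface.
#' @param capture_band interface capture band, m (default `dz0`).
#' @param j step index stored in the result.
#' @param H_prev previous step height, m (for the traverse warning).
#' @return A `compartment_step` list with fields `j`, `t_start`,
#'   `t_end`, `H_L`, `eps_mean`, `interfaces`, `V`, `Q`, `n_samples`,
#'   `eps`, `P`, `T`, `zones` and the zone aggregates `zV`, `zQ`,
#'   `z_bounds`, `z_eps`, `z_P`, `z_T`, `z_mid`.
#' @export
build_step <- function(kins, geometry, t_start, t_end,
                       dz0 = dyncomp_constants$dz0,
                       tau_crit = dyncomp_constants$tau_crit,
                       min_samples = dyncomp_constants$min_samples,
                       capture_band = dz0, j = 1L, H_prev = NULL) {
  if (inherits(kins, "data.frame")) kins <- list(kins)
  H_L <- step_liquid_height(kins, t_start, t_end, H_prev = H_prev)
  A <- geometry$A
  nfull <- floor(H_L / dz0 + 1e-9)
  rem <- H_L - nfull * dz0
  interfaces <- if (rem < 0.25 * dz0)
    c(seq(0, dz0 * (nfull - 1L), by = dz0), H_L)
  else c(seq(0, dz0 * nfull, by = dz0), H_L)
  K <- length(interfaces) - 1L

  internal <- interfaces[-c(1L, K + 1L)]
  st <- interface_velocity_stats(kins, internal, t_start, t_end, capture_band)
  bad <- st$n < min_samples
  if (any(bad)) {
    runs <- rle(bad)
    if (any(runs$lengths[runs$values] >= 2L))
      stop(sprintf(
        "step %d: consecutive interfaces near z = %.2f m have fewer than %d velocity samples even after local coarsening",
        j, internal[which(bad)[1L]], min_samples))
    keep <- !bad
    internal <- internal[keep]
    st <- st[keep, , drop = FALSE]
    interfaces <- c(0, internal, H_L)
    K <- length(interfaces) - 1L
  }

  pool <- do.call(rbind, lapply(kins, function(k)
    k[k$t_s >= t_start & k$t_s < t_end, c("z_m", "eps", "P_Pa", "T_K")]))
  idx <- pmin(pmax(findInterval(pool$z_m, interfaces,
                                rightmost.closed = TRUE), 1L), K)
  mids <- (interfaces[-1L] + interfaces[-(K + 1L)]) / 2
  agg <- function(x) {
    m <- rep(NA_real_, K)
    s <- tapply(x, factor(idx, levels = seq_len(K)), mean)
    m[!is.na(s)] <- s[!is.na(s)]
    fill_gaps(m, mids)
  }
  eps_k <- agg(pool$eps)
  P_k <- agg(pool$P_Pa)
  T_k <- agg(pool$T_K)

  h_k <- diff(interfaces)
  V <- (1 - eps_k) * A * h_k
  eps_if <- st$eps_mean
  na_if <- is.na(eps_if)
  if (any(na_if))
    eps_if[na_if] <- (eps_k[-K][na_if] + eps_k[-1L][na_if]) / 2
  Q <- interface_flows(st$v_mean, A, eps_if)
  eps_mean <- sum(eps_k * h_k) / H_L

  step <- list(j = j, t_start = t_start, t_end = t_end, H_L = H_L,
               eps_mean = eps_mean, interfaces = interfaces, V = V, Q = Q,
               n_samples = st$n, eps = eps_k, P = P_k, T = T_k)
  step$zones <- autozone(V, Q, tau_crit)
  step <- zone_aggregate(step)
  class(step) <- "compartment_step"
  step
}

#' Build the dynamic compartment model
#'
#' Splits the process duration into update steps of `dt_update` seconds
#' and builds one zoned compartment step per window; within a step the
#' liquid volume and all exchange flows are held constant.
#'
#' @param kins one or a list of `axial_kinematics`.
#' @param geometry a [reactor_geometry()].
#' @param dz0 initial compartment height, m (default 0.5).
#' @param dt_update update-step duration, s (default 3600).
#' @param tau_crit critical local residence time, s (default 1.5).
#' @param min_samples minimum velocity samples per interface (default 30).
#' @param capture_band interface capture band, m (default `dz0`).
#' @param t_range optional two-vector restricting the modelled window, s.
#' @return A `dyncomp_model`: list with `steps` (list of
#'   `compartment_step`), `geometry`, `tau_crit`.
#' @export
build_dynamic_model <- function(kins, geometry,
                                dz0 = dyncomp_constants$dz0,
                                dt_update = dyncomp_constants$dt_update,
                                tau_crit = dyncomp_constants$tau_crit,
                                min_samples = dyncomp_constants$min_samples,
                                capture_band = dz0, t_range = NULL) {
  if (inherits(kins, "data.frame")) kins <- list(kins)
  if (is.null(t_range)) {
    t_range <- range(unlist(lapply(kins, function(k) range(k$t_s))))
    # samples stamp interval starts: the last one covers one more interval
    t_range[2L] <- t_range[2L] + stats::median(diff(kins[[1L]]$t_s))
  }
  J <- floor((t_range[2L] - t_range[1L]) / dt_update + 1e-9)
  if (J < 1L) stop("kinematics span less than one update step")
  steps <- vector("list", J)
  H_prev <- NULL
  for (j in seq_len(J)) {
    t0 <- t_range[1L] + (j - 1L) * dt_update
    steps[[j]] <- build_step(kins, geometry, t0, t0 + dt_update,
                             dz0 = dz0, tau_crit = tau_crit,
                             min_samples = min_samples,
                             capture_band = capture_band, j = j,
                             H_prev = H_prev)
    H_prev <- steps[[j]]$H_L
  }
  structure(list(steps = steps, geometry = geometry, tau_crit = tau_crit),
            class = "dyncomp_model")
}

#' @export
print.compartment_step <- function(x, ...) {
  cat(sprintf(
    "Compartment step %d [%.0f, %.0f) s: H_L = %.2f m, %d initial compartments, %d zones, mean eps = %.3f\n",
    x$j, x$t_start, x$t_end, x$H_L, length(x$V), length(x$zones), x$eps_mean))
  invisible(x)
}

#' @export
print.dyncomp_model <- function(x, ...) {
  J <- length(x$steps)
  H <- vapply(x$steps, `[[`, numeric(1), "H_L")
  nz <- vapply(x$steps, function(s) length(s$zones), integer(1))
  cat(sprintf(
    "Dynamic compartment model: %d update steps, H_L %.1f -> %.1f m, %d-%d zones per step, tau_crit = %.2f s\n",
    J, H[1L], H[J], min(nz), max(nz), x$tau_crit))
  invisible(x)
}

#' Flow map of a dynamic model
#'
#' Long-format table of the retained zone-boundary exchange flows over
#' the process, suitable for a flow-map plot (step time vs. interface
#' height, coloured by flow).
#'
#' @param model a `dyncomp_model`.
#' @return data.frame with `step`, `t_mid_hr`, `height_m`, `Q_m3_per_s`.
#' @export
flow_map <- function(model) {
  do.call(rbind, lapply(model$steps, function(s) {
    nz <- length(s$zV)
    if (nz < 2L) return(NULL)
    data.frame(step = s$j, t_mid_hr = (s$t_start + s$t_end) / 2 / 3600,
               height_m = s$z_bounds[2:nz], Q_m3_per_s = s$zQ)
  }))
}
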