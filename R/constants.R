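#' Physical and model constants
#'
#' Central table of the physical constants and model defaults used across
#' the package: gravitational acceleration, broth liquid density, gas
#' density, normalised gas reference conditions, oxygen mole fraction in
#' air, Henry coefficient for oxygen in water at 306 K, the kLa
#' correlation coefficient and the discretisation defaults of the
#' compartment model.  Every function taking one of these as an argument
#' defaults to the value stored here, so a study-wide override only needs
#' to be made in one place.
#'
#' @format A named list:
#' \describe{
#'   \item{g}{gravitational acceleration, m/s^2 (9.81)}
#'   \item{rho_l}{broth liquid density, kg/m^3 (1030)}
#'   \item{rho_g}{gas (air) density at process conditions, kg/m^3 (1.2)}
#'   \item{P_ref}{reference pressure for normalised gas flows, Pa (101325)}
#'   \item{T_ref}{reference temperature for normalised gas flows, K (298.15)}
#'   \item{x_o2}{mole fraction of oxygen in air (0.2095)}
#'   \item{H_cp}{Henry coefficient for O2 in water at 306 K, mol/L/atm (0.0015)}
#'   \item{M_o2}{molar mass of O2, kg/mol (0.032)}
#'   \item{kla_coeff}{kLa correlation coefficient, (1/hr)/(m/s) (0.288)}
#'   \item{dz0}{initial compartment height, m (0.5)}
#'   \item{dt_update}{model update-step duration, s (3600)}
#'   \item{tau_crit}{critical local residence time for zoning, s (1.5)}
#'   \item{min_samples}{minimum velocity samples per interface (30)}
#' }
#' @export
dyncomp_constants <- list(
  g           = 9.81,
  rho_l       = 1030,
  rho_g       = 1.2,
  P_ref       = 101325,
  T_ref       = 298.15,
  x_o2        = 0.2095,
  H_cp        = 0.0015,
  M_o2        = 0.032,
  kla_coeff   = 0.288,
  dz0         = 0.5,
  dt_update   = 3600,
  tau_crit    = 1.5,
  min_samples = 30
)

#' Reactor geometry descriptor
#'
#' @param D column diameter, m.
#' @param H_total total vessel height, m.
#' @param probe_clearance height of the DO/pH probe above the bottom, m.
#' @return An object of class `reactor_geometry` with fields `D`,
#'   `H_total`, `probe_clearance`, `A` (cross-sectional area, m^2) and
#'   `bottom_shape` (always `"cylindrical"`; the bottom head is modelled
#'   as a straight cylinder).
#' @examples
#' reactor_geometry(D = 5.3, H_total = 30)
#' @export
reactor_geometry <- function(D, H_total, probe_clearance = 5.85) {
  stopifnot(is.numeric(D), length(D) == 1L, D > 0)
  stopifnot(is.numeric(H_total), length(H_total) == 1L, H_total > 0)
  if (probe_clearance < 0 || probe_clearance > H_total)
    stop("probe_clearance must lie within [0, H_total]")
  structure(list(
    D = D, H_total = H_total, probe_clearance = probe_clearance,
    A = pi * D^2 / 4, bottom_shape = "cylindrical"
  ), class = "reactor_geometry")
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat(sprintf(
    "Bubble column geometry: D = %.2f m (A = %.2f m2), H_total = %.1f m, probe at %.2f m\n",
    x$D, x$A, x$H_total, x$probe_clearance))
  invisible(x)
}
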