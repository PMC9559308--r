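#' Linear-interpolation profile from a two-column table
#'
#' Operating profiles (feed rate, gas flow, headspace pressure) are
#' given as time/value tables; between rows the value is linearly
#' interpolated, outside the table range the nearest value is held.
#'
#' @param df data.frame whose first column is time (s) and second the value,
#'   or a numeric scalar for a constant profile.
#' @return A function of time (s) returning the interpolated value.
#' @export
profile_function <- function(df) {
  if (is.numeric(df) && length(df) == 1L) {
    v <- df
    return(function(t) rep(v, length(t)))
  }
  stopifnot(is.data.frame(df), ncol(df) >= 2L)
  if (nrow(df) == 1L) {
    v <- df[[2L]][1L]
    return(function(t) rep(v, length(t)))
  }
  stats::approxfun(df[[1L]], df[[2L]], rule = 2)
}

#' Read flow-follower traces from a delimited-text file
#'
#' Expects a CSV with header `device_id,t_s,P_Pa,T_K`; one file may hold
#' several devices.  Device densities are supplied separately (they are
#' a property of the device, not a time series).
#'
#' @param path CSV file path.
#' @param rho_p named numeric vector of device densities, kg/m^3; the
#'   names must cover every `device_id` in the file.
#' @return Named list of [sensor_trace()] objects.
#' @export
read_traces <- function(path, rho_p) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("device_id", "t_s", "P_Pa", "T_K")
  if (!all(need %in% names(df)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$device_id)
  missing <- setdiff(ids, names(rho_p))
  if (length(missing))
    stop("no device density given for: ", paste(missing, collapse = ", "))
  out <- lapply(ids, function(id) {
    d <- df[df$device_id == id, ]
    d <- d[order(d$t_s), ]
    sensor_trace(id, d$t_s, d$P_Pa, d$T_K, rho_p = rho_p[[id]])
  })
  names(out) <- ids
  out
}

#' Read an operating profile CSV
#'
#' @param path CSV with a time column `t_s` and one value column.
#' @return A profile function of time (s); see [profile_function()].
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"t_s" %in% names(df)) stop("profile file must have a t_s column")
  val <- setdiff(names(df), "t_s")[1L]
  profile_function(df[, c("t_s", val)])
}

#' Write axial kinematics to CSV
#'
#' @param kins one `axial_kinematics` data.frame or a list of them.
#' @param path output CSV path.
#' @export
write_kinematics <- function(kins, path) {
  if (inherits(kins, "axial_kinematics")) kins <- list(kins)
  df <- do.call(rbind, lapply(kins, function(k)
    k[, c("device_id", "t_s", "z_m", "v_z_m_per_s", "eps", "rho_f",
          "P_Pa", "T_K")]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read axial kinematics from CSV
#'
#' @param path CSV written by [write_kinematics()].
#' @return Named list of `axial_kinematics` data.frames, one per device.
#' @export
read_kinematics <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  ids <- unique(df$device_id)
  out <- lapply(ids, function(id) {
    k <- df[df$device_id == id, ]
    k <- k[order(k$t_s), ]
    class(k) <- c("axial_kinematics", "data.frame")
    k
  })
  names(out) <- ids
  out
}

#' Serialize a dynamic compartment model to JSON
#'
#' @param model a `dyncomp_model` (see [build_dynamic_model()]).
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  payload <- list(
    schema = "dyncomp-model/1",
    tau_crit = model$tau_crit,
    geometry = list(D = model$geometry$D, H_total = model$geometry$H_total,
                    probe_clearance = model$geometry$probe_clearance),
    steps = lapply(model$steps, function(s) {
      s$zones <- lapply(s$zones, as.integer)
      unclass(s)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dynamic compartment model from JSON
#'
#' @param path file written by [write_model()].
#' @return A `dyncomp_model` object.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(p$schema, "dyncomp-model/1"))
    stop("unrecognised model schema: ", p$schema)
  geom <- reactor_geometry(p$geometry$D, p$geometry$H_total,
                           p$geometry$probe_clearance)
  steps <- lapply(p$steps, function(s) {
    s$zones <- lapply(s$zones, as.integer)
    class(s) <- "compartment_step"
    s
  })
  structure(list(steps = steps, geometry = geom, tau_crit = p$tau_crit),
            class = "dyncomp_model")
}
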