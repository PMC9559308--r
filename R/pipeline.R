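#' Load and validate a run configuration
#'
#' Configurations are JSON (or an equivalent R list) with optional
#' blocks `geometry` (`D`, `H_total`, `probe_clearance`), `algorithm`
#' (`dz0`, `dt_update`, `tau_crit`, `min_samples`, `window_max`,
#' `window_smooth`, `kla_coeff`), `files` (paths to `traces`,
#' `gas_profile`, `feed_profile`, `observations`, `model`,
#' `kinematics`), `rho_p` (named device densities), `synth`, `mix` and
#' `scenario` blocks.  Missing algorithm constants default to the
#' packaged values; non-positive constants are rejected by name.
#'
#' @param config path to a JSON file or a named list.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  alg <- config$algorithm
  defaults <- list(dz0 = dyncomp_constants$dz0,
                   dt_update = dyncomp_constants$dt_update,
                   tau_crit = dyncomp_constants$tau_crit,
                   min_samples = dyncomp_constants$min_samples,
                   window_max = 3600, window_smooth = 600,
                   kla_coeff = dyncomp_constants$kla_coeff)
  for (nm in names(defaults))
    if (is.null(alg[[nm]])) alg[[nm]] <- defaults[[nm]]
  for (nm in names(defaults))
    if (!is.numeric(alg[[nm]]) || alg[[nm]] <= 0)
      stop("config field algorithm$", nm, " must be a positive number")
  config$algorithm <- alg
  if (!is.null(config$geometry))
    config$geometry <- as.list(config$geometry)
  class(config) <- c("run_config", "list")
  config
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dyncomp-output/1 config=%s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write/read kinetic parameters as JSON
#'
#' @param params a [kinetic_params()].
#' @param path file path.
#' @return `write_params` returns the path; `read_params` the
#'   [kinetic_params()].
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(kinetic_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

cfg_geometry <- function(config) {
  g <- config$geometry
  if (is.null(g)) g <- list(D = 5.3, H_total = 30, probe_clearance = 5.85)
  reactor_geometry(g$D, g$H_total,
                   if (is.null(g$probe_clearance)) 5.85 else g$probe_clearance)
}

#' Run one pipeline stage
#'
#' Thin orchestration layer over the package functions, used by the
#' command-line script.  Stages: `synth` writes a synthetic input
#' bundle from the reference plant; `process` converts trace CSVs to
#' kinematics; `build` constructs and serializes the dynamic
#' compartment model; `mix` runs the feeding-point mixing-time scan;
#' `simulate` runs the fed-batch simulation under a scenario; `fit`
#' calibrates kinetic parameters against observations.  Every output
#' CSV carries a schema/config-hash comment header, and a
#' `manifest_<stage>.json` records inputs, seed and timing.
#'
#' @param config a config list/path (see [load_config()]).
#' @param command one of `synth`, `process`, `build`, `mix`,
#'   `simulate`, `fit`.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for the stochastic stages.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config, command = c("synth", "process", "build",
                                             "mix", "simulate", "fit"),
                         out_dir = ".", seed = 1) {
  command <- match.arg(command)
  config <- load_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  t0 <- Sys.time()
  alg <- config$algorithm
  paths <- list()
  out <- function(name) file.path(out_dir, name)

  if (command == "synth") {
    spec <- reference_plant()
    dur <- config$synth$duration_s
    if (is.null(dur)) dur <- spec$t_end
    nd <- config$synth$n_devices
    if (is.null(nd)) nd <- 3
    ds <- plant_dataset(spec, n_devices = nd, seed = seed, duration = dur)
    tr <- do.call(rbind, lapply(ds$traces, function(x) as.data.frame(x)))
    paths$traces <- write_stamped_csv(tr, out("traces.csv"), hash)
    grid <- seq(0, spec$t_end, by = 600)
    paths$gas_profile <- write_stamped_csv(
      data.frame(t_s = grid, Q_g_Nm3_per_s = spec$Q_g(grid)),
      out("gas_profile.csv"), hash)
    paths$feed_profile <- write_stamped_csv(
      data.frame(t_s = grid, F_s_kg_per_s = spec$F_s(grid)),
      out("feed_profile.csv"), hash)
    paths$headspace_profile <- write_stamped_csv(
      data.frame(t_s = grid, P_head_Pa = spec$P_head(grid)),
      out("headspace_profile.csv"), hash)
    paths$truth_params <- write_params(spec$params, out("truth_params.json"))
    truth <- do.call(rbind, lapply(ds$truths, as.data.frame))
    paths$truth_kinematics <- write_stamped_csv(
      truth[, c("device_id", "t_s", "z_m", "v_z_m_per_s")],
      out("truth_kinematics.csv"), hash)
  } else if (command == "process") {
    rho_p <- unlist(config$rho_p)
    traces <- read_traces(config$files$traces, rho_p)
    geom <- cfg_geometry(config)
    gas <- read_profile(config$files$gas_profile)
    kins <- lapply(traces, process_trace, geometry = geom, gas_profile = gas,
                   window_max = alg$window_max,
                   window_smooth = alg$window_smooth)
    rho_f_mean <- mean(unlist(lapply(kins, function(k) mean(k$rho_f))))
    sel <- select_devices(rho_p, rho_f_mean,
                          pool_all = isTRUE(config$pool_all_devices))
    paths$kinematics <- out("kinematics.csv")
    write_kinematics(kins[sel], paths$kinematics)
  } else if (command == "build") {
    kins <- read_kinematics(config$files$kinematics)
    geom <- cfg_geometry(config)
    model <- build_dynamic_model(kins, geom, dz0 = alg$dz0,
                                 dt_update = alg$dt_update,
                                 tau_crit = alg$tau_crit,
                                 min_samples = alg$min_samples)
    paths$model <- write_model(model, out("model.json"))
    paths$flow_map <- write_stamped_csv(flow_map(model), out("flow_map.csv"), hash)
  } else if (command == "mix") {
    model <- read_model(config$files$model)
    fh <- config$mix$feed_heights
    if (is.null(fh)) fh <- c(0, 7.5, 12.5, 17.5, Inf)
    scan <- feed_point_scan(model, fh)
    paths$mixing_times <- write_stamped_csv(scan, out("mixing_times.csv"), hash)
  } else if (command == "simulate") {
    model <- read_model(config$files$model)
    gas <- read_profile(config$files$gas_profile)
    feed <- read_profile(config$files$feed_profile)
    sc <- config$scenario
    if (!is.null(sc$feed_delta))
      feed <- modify_profile(feed, sc$feed_delta$delta,
                             sc$feed_delta$t_start_hr, sc$feed_delta$t_end_hr)
    params <- if (!is.null(config$files$params))
      read_params(config$files$params) else kinetic_params()
    fp <- if (!is.null(sc$feed_points)) as.data.frame(sc$feed_points) else NULL
    fm <- if (!is.null(sc$flow_multiplier)) sc$flow_multiplier else 1
    run <- simulate_fermentation(model, feed, gas, params,
                                 feed_points = fp, flow_multiplier = fm,
                                 kla_coeff = alg$kla_coeff)
    paths$trajectory <- write_stamped_csv(run$trajectory,
                                          out("trajectory.csv"), hash)
    paths$summary <- write_stamped_csv(run$summary, out("summary.csv"), hash)
  } else if (command == "fit") {
    model <- read_model(config$files$model)
    gas <- read_profile(config$files$gas_profile)
    feed <- read_profile(config$files$feed_profile)
    obs <- utils::read.csv(config$files$observations, comment.char = "#")
    init <- if (!is.null(config$files$params))
      read_params(config$files$params) else kinetic_params()
    fit_names <- config$fit$parameters
    if (is.null(fit_names)) fit_names <- c("mu_max", "K_p", "Y_px")
    fit <- fit_parameters(init, model, feed, gas, obs,
                          fit_names = fit_names,
                          kla_coeff = alg$kla_coeff)
    paths$fitted_params <- write_params(fit$params, out("fitted_params.json"))
    paths$fit_diagnostics <- write_stamped_csv(
      data.frame(sse = fit$sse, converged = fit$converged,
                 evaluations = fit$evaluations),
      out("fit_diagnostics.csv"), hash)
  }

  manifest <- list(stage = command, config_hash = hash, seed = seed,
                   outputs = unlist(paths),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   package_version = as.character(utils::packageVersion("dyncomp")))
  mpath <- out(sprintf("manifest_%s.json", command))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  paths$manifest <- mpath
  invisible(paths)
}
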