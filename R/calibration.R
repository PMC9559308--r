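## simulated counterparts of an observation table
sim_at_observations <- function(run, obs) {
  s <- run$summary
  ip <- function(col, tt) stats::approx(s$t_hr, s[[col]], xout = tt, rule = 2)$y
  col <- c(biomass = "C_x_avg", substrate = "C_s_avg",
           product = "C_p_avg", DO = "C_o_probe")
  unknown <- setdiff(unique(obs$variable), names(col))
  if (length(unknown)) stop("unknown observation variable: ",
                            paste(unknown, collapse = ", "))
  vapply(seq_len(nrow(obs)), function(i)
    ip(col[[obs$variable[i]]], obs$t_hr[i]), numeric(1))
}

#' Weighted sum of squared errors between simulation and observations
#'
#' Runs the fed-batch simulation with the candidate parameters and
#' compares it with the observation set: biomass, substrate and product
#' observations are matched against the volume-weighted height-average
#' concentration, DO observations against the zone containing the probe
#' height.  Per-variable weights (default: the reciprocal variance of
#' the observed values of each variable) put the heterogeneous scales
#' on a common footing; `weights = "none"` gives the plain unweighted
#' SSE.  A failed simulation returns a large finite penalty.
#'
#' @param params a [kinetic_params()] candidate.
#' @param model a `dyncomp_model`.
#' @param feed_profile,gas_profile profile functions of time (s).
#' @param obs an `observation_set` (columns `t_hr`, `variable`, `value`).
#' @param weights named per-variable weights, `NULL` for 1/variance,
#'   or `"none"`.
#' @param initial initial state passed to [simulate_fermentation()].
#' @param n_out,rtol,atol simulation resolution/tolerances (moderate
#'   defaults: the objective is evaluated many times during a fit).
#' @param ... further arguments to [simulate_fermentation()].
#' @return Scalar SSE (>= 0).
#' @export
sse_objective <- function(params, model, feed_profile, gas_profile, obs,
                          weights = NULL,
                          initial = list(C_x = 1.5, C_s = 8, C_p = 10,
                                         C_o = 0.01),
                          n_out = 2, rtol = 1e-6, atol = 1e-9, ...) {
  if (is.null(obs) || nrow(obs) == 0L) stop("observation set is empty")
  w <- if (identical(weights, "none")) {
    stats::setNames(rep(1, 4), c("biomass", "substrate", "product", "DO"))
  } else if (is.null(weights)) {
    v <- tapply(obs$value, obs$variable, stats::var)
    v[!is.finite(v) | v <= 0] <- 1
    1 / v
  } else weights
  run <- tryCatch(
    simulate_fermentation(model, feed_profile, gas_profile, params,
                          initial = initial, n_out = n_out,
                          rtol = rtol, atol = atol, ...),
    error = function(e) NULL)
  if (is.null(run)) return(1e12)
  sim <- sim_at_observations(run, obs)
  sum(w[obs$variable] * (sim - obs$value)^2)
}

#' Fit kinetic parameters by derivative-free SSE minimisation
#'
#' Nelder-Mead simplex minimisation of [sse_objective()] over a chosen
#' subset of the kinetic parameters.  By default the search runs in
#' log-parameter space, which keeps the parameters positive without
#' imposing stoichiometric constraints; `log_scale = FALSE` searches
#' the raw values.
#'
#' @param init a [kinetic_params()] giving the starting point and the
#'   fixed values of parameters not being fitted.
#' @param model,feed_profile,gas_profile,obs as in [sse_objective()].
#' @param fit_names names of the parameters to optimise.
#' @param log_scale search in log space (default `TRUE`).
#' @param maxit maximum objective evaluations.
#' @param reltol simplex convergence tolerance.
#' @param ... passed to [sse_objective()].
#' @return List: `params` (fitted [kinetic_params()]), `sse`,
#'   `converged` (logical; `FALSE` means the evaluation budget was
#'   exhausted and the best-so-far point is returned), `evaluations`.
#' @export
fit_parameters <- function(init, model, feed_profile, gas_profile, obs,
                           fit_names = c("mu_max", "K_p", "Y_px"),
                           log_scale = TRUE, maxit = 250, reltol = 1e-6,
                           ...) {
  stopifnot(all(fit_names %in% names(init)))
  theta0 <- unlist(init[fit_names])
  if (log_scale) theta0 <- log(theta0)
  objective <- function(theta) {
    p <- init
    vals <- if (log_scale) exp(theta) else theta
    if (any(!is.finite(vals)) || any(vals <= 0)) return(1e12)
    p[fit_names] <- as.list(vals)
    sse_objective(p, model, feed_profile, gas_profile, obs, ...)
  }
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  best <- init
  vals <- if (log_scale) exp(opt$par) else opt$par
  best[fit_names] <- as.list(vals)
  if (opt$convergence != 0)
    warning("optimizer stopped on its evaluation budget; returning best-so-far")
  list(params = best, sse = opt$value, converged = opt$convergence == 0,
       evaluations = opt$counts[["function"]])
}

#' Parameter-recovery report over an ensemble of fits
#'
#' Summarises how well an ensemble of fits (e.g. over noise
#' realisations) recovers a known truth: per-parameter relative bias,
#' relative RMSE and the median relative error, flagging parameters
#' with relative RMSE above 50% as practically unidentifiable on the
#' given observation design.
#'
#' @param truth the true [kinetic_params()].
#' @param fits list (length >= 2) of fitted [kinetic_params()].
#' @param fit_names parameters to report (default: all).
#' @return data.frame with `parameter`, `truth`, `rel_bias`,
#'   `rel_rmse`, `median_rel_err`, `unidentifiable`.
#' @export
recovery_report <- function(truth, fits, fit_names = names(truth)) {
  if (length(fits) < 2L) stop("at least 2 fits are required")
  rel <- sapply(fit_names, function(nm)
    vapply(fits, function(f) f[[nm]] / truth[[nm]] - 1, numeric(1)))
  rel <- matrix(rel, nrow = length(fits),
                dimnames = list(NULL, fit_names))
  data.frame(
    parameter = fit_names,
    truth = unlist(truth[fit_names]),
    rel_bias = colMeans(rel),
    rel_rmse = sqrt(colMeans(rel^2)),
    median_rel_err = apply(abs(rel), 2L, stats::median),
    unidentifiable = sqrt(colMeans(rel^2)) > 0.5,
    row.names = NULL)
}
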