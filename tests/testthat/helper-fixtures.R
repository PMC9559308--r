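# Shared fixtures, memoised so the reference scenario is generated,
# processed and compartmentalised once per test run.

ref <- local({
  cache <- new.env(parent = emptyenv())
  function(what) {
    if (!is.null(cache[[what]])) return(cache[[what]])
    val <- switch(what,
      spec = reference_plant(),
      data = plant_dataset(ref("spec"), n_devices = 3, seed = 1),
      kins = {
        spec <- ref("spec")
        lapply(ref("data")$traces, process_trace, geometry = spec$geometry,
               gas_profile = spec$Q_g)
      },
      model = build_dynamic_model(ref("kins"), ref("spec")$geometry),
      run = {
        spec <- ref("spec")
        simulate_fermentation(ref("model"), spec$F_s, spec$Q_g, spec$params,
                              initial = spec$initial,
                              kla_coeff = spec$kla_coeff,
                              n_out = 2, rtol = 1e-6, atol = 1e-9)
      },
      clean_device = simulate_flow_follower(ref("spec"), "clean", seed = 7,
                                            noise_P = 0),
      stop("unknown fixture: ", what))
    cache[[what]] <- val
    val
  }
})

# closed-form two-zone tracer transient: equal volumes V, exchange Q,
# unit-mass pulse in zone 1
two_zone_closed_form <- function(t, V, Q) {
  C_inf <- 1 / (2 * V)
  x <- exp(-2 * Q * t / V)
  cbind(C_inf * (1 + x), C_inf * (1 - x))
}

# matrix-exponential transient oracle for an arbitrary V/Q chain
matexp_transient <- function(t, V, Q, C0) {
  n <- length(V)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    M[i, i] <- M[i, i] - Q[i] / V[i]
    M[i, i + 1] <- M[i, i + 1] + Q[i] / V[i]
    M[i + 1, i + 1] <- M[i + 1, i + 1] - Q[i] / V[i + 1]
    M[i + 1, i] <- M[i + 1, i] + Q[i] / V[i + 1]
  }
  t(vapply(t, function(tt)
    as.numeric(Matrix::expm(M * tt) %*% C0), numeric(n)))
}

# analytic 95% mixing time of the equal-volume two-zone system by
# root-finding on the closed-form deviation metric
two_zone_tm95_analytic <- function(V, Q) {
  thr <- abs(log10(0.95))
  mfun <- function(t) {
    C <- two_zone_closed_form(t, V, Q)
    cn <- C / (1 / (2 * V))
    sqrt(0.5 * log10(cn[, 1])^2 + 0.5 * log10(cn[, 2])^2) - thr
  }
  stats::uniroot(mfun, c(1e-9, 1e5 * V / Q), tol = 1e-12)$root
}

# plant spec with a piecewise-constant (in z) speed field and constant
# liquid height, for interface-flow recovery checks
piecewise_plant <- function(block_speeds = c(0.6, 1.2, 2.0, 1.4),
                            block_height = 4, H = 16) {
  spec <- reference_plant()
  spec$H_L <- function(t) rep(H, length(t))
  spec$Q_g <- profile_function(4.75)
  spec$P_head <- function(t) rep(121325, length(t))
  force(block_speeds); force(block_height)
  spec$speed <- function(z, t) {
    i <- pmin(floor(z / block_height) + 1, length(block_speeds))
    block_speeds[pmax(i, 1)]
  }
  spec
}
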