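#' Global network parameters
#'
#' `coupling_c` linearly rescales all long-range inputs relative to local
#' dynamics; `velocity_v` (m/s) converts tract lengths into transmission
#' delays (`mm / (m/s) = ms`).  Exploration bounds are coupling 0.01-1.0
#' and velocity 10-100 m/s.
#'
#' @param coupling_c global coupling scale (>= 0; 0 decouples the network)
#' @param velocity_v conduction velocity in m/s (> 0)
#' @return a `global_params` list
#' @export
global_params <- function(coupling_c = 0.05, velocity_v = 60) {
  if (coupling_c < 0 || velocity_v <= 0)
    vs_abort("need coupling_c >= 0 and velocity_v > 0", "parameter")
  structure(list(coupling_c = coupling_c, velocity_v = velocity_v),
            class = "global_params")
}

#' Simulation configuration
#'
#' Defaults follow the modelling protocol this package reproduces:
#' integration step 0.0122 ms, 240 s (4 min) of signal, additive Gaussian
#' white noise of SD 1 (scaled by `sqrt(dt)` inside the integrator), 10 s
#' of discarded burn-in, mean field recorded at a 1 ms stride
#' (block-averaged).  `noise_mask` selects which of the six state families
#' receive noise; the default is all six, with `membrane_only = c(TRUE,
#' FALSE, FALSE, TRUE, FALSE, FALSE)` as the common alternative.
#'
#' @param dt integration step (ms)
#' @param duration simulated signal length after burn-in (s)
#' @param noise_sd white-noise amplitude per state equation
#' @param seed RNG seed (integer)
#' @param burn_in discarded initial transient (s)
#' @param record_dt recording stride of the mean field (ms)
#' @param noise_mask logical length-6 vector over families
#'   (xi, eta, tau, alpha, beta, gamma)
#' @param weight_transform scaling of connection weights before they
#'   enter the coupling term: `"normalize"` (divide by the largest
#'   weight, the default -- raw streamline capacities span orders of
#'   magnitude and would swamp the local dynamics), `"log"`
#'   (`log1p` then divide by the largest transformed weight) or `"raw"`
#' @return a `sim_config` list
#' @export
sim_config <- function(dt = 0.0122, duration = 240, noise_sd = 1,
                       seed = 42L, burn_in = 10, record_dt = 1,
                       noise_mask = rep(TRUE, 6),
                       weight_transform = c("normalize", "log", "raw")) {
  weight_transform <- match.arg(weight_transform)
  if (dt <= 0) vs_abort("dt must be > 0", "parameter")
  if (duration <= burn_in || burn_in < 0)
    vs_abort("need duration > burn_in >= 0", "parameter")
  if (noise_sd < 0) vs_abort("noise_sd must be >= 0", "parameter")
  if (length(noise_mask) != 6) vs_abort("noise_mask must have length 6", "parameter")
  structure(list(dt = dt, duration = duration, noise_sd = noise_sd,
                 seed = as.integer(seed), burn_in = burn_in,
                 record_dt = record_dt, noise_mask = as.logical(noise_mask),
                 weight_transform = weight_transform),
            class = "sim_config")
}

#' Convert tract lengths into integer-step transmission delays
#'
#' Delay in ms is `length_mm / velocity_v` (mm divided by m/s is ms),
#' rounded to the nearest integer number of integration steps (ties away
#' from zero) with a minimum of 1 step on every nonzero-length edge, so
#' the history-buffer convention always looks strictly into the past.
#'
#' @param conn a `connectome`
#' @param velocity_v conduction velocity (m/s, > 0)
#' @param dt integration step (ms, > 0)
#' @return a `delay_matrix` list with `delays_steps` (integer matrix),
#'   `velocity_v`, `dt`
#' @export
compute_delays <- function(conn, velocity_v, dt) {
  if (velocity_v <= 0 || dt <= 0)
    vs_abort("velocity_v and dt must be > 0", "parameter")
  bad <- which(conn$weights > 0 & conn$lengths <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    vs_abort("zero length on a nonzero-weight edge", "zero_length_edge")
  delay_ms <- conn$lengths / velocity_v
  steps <- matrix(as.integer(round(delay_ms / dt)), nrow(delay_ms))
  nz <- conn$weights > 0
  steps[nz & steps < 1L] <- 1L
  steps[!nz] <- 0L
  structure(list(delays_steps = steps, velocity_v = velocity_v, dt = dt),
            class = "delay_matrix")
}

#' Stochastic Heun integration of a generic additive-noise SDE
#'
#' Reference R implementation of the scheme used by the compiled network
#' integrator, exposed for convergence and calibration testing.
#' Predictor: `x + dt * f(x) + E`; corrector: `x + dt/2 * (f(x) +
#' f(pred)) + E`, with one shared Gaussian increment
#' `E = noise_sd * sqrt(dt) * Z` per step (Stratonovich-consistent for
#' additive noise; order 2 deterministically when `noise_sd = 0`).
#'
#' @param drift_fn function(state, t) returning the drift vector
#' @param x0 initial state vector
#' @param dt step size
#' @param n_steps number of steps
#' @param noise_sd additive noise amplitude (scalar or per-component)
#' @param seed optional RNG seed
#' @return matrix `(n_steps + 1) x length(x0)` of states, row 1 = `x0`
#' @export
heun_integrate <- function(drift_fn, x0, dt, n_steps, noise_sd = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(x0)
  out <- matrix(NA_real_, n_steps + 1, d)
  out[1, ] <- x <- as.numeric(x0)
  sq <- sqrt(dt)
  for (k in seq_len(n_steps)) {
    f1 <- drift_fn(x, (k - 1) * dt)
    if (any(!is.finite(f1)))
      vs_abort(sprintf("non-finite drift at step %d", k), "integration")
    E <- if (all(noise_sd == 0)) 0 else noise_sd * sq * rnorm(d)
    xp <- x + dt * f1 + E
    f2 <- drift_fn(xp, k * dt)
    x <- x + dt / 2 * (f1 + f2) + E
    out[k + 1, ] <- x
  }
  out
}

default_initial_state <- function(p, m, n_regions) {
  # uniform box of half-width 0.5 around the family nullcline values at x0
  M <- length(m$IE)
  NM <- n_regions * M
  ref <- c(p$x0, p$c - p$d * p$x0^2, 0, p$x0, p$c - p$d_inh * p$x0^2, 0)
  st <- matrix(0, 6, NM)
  for (f in 1:6) st[f, ] <- ref[f] + runif(NM, -0.5, 0.5)
  st
}

#' Simulate the delay-coupled SJ3D network over a connectome
#'
#' For each region the excitatory membrane equations receive the afferent
#' input `coupling_c * sum_j w_ij * x_j(t - dt_ij)`, where `x_j` is the
#' quadrature-weighted excitatory mean field of region j and the delays
#' come from [compute_delays()].  Integration uses the stochastic Heun
#' scheme with independent Gaussian noise per region, state family and
#' step, drawn from a generator seeded by `cfg$seed`; initial conditions
#' are drawn from the same seeded stream (uniform box around the membrane
#' rest point).  The burn-in transient is discarded; output is the
#' recorded (block-averaged) mean field.  Deterministic given
#' `(cfg$seed, inputs)`.
#'
#' @param conn a `connectome`
#' @param p an `sj3d_params`
#' @param g a `global_params`
#' @param cfg a `sim_config`
#' @param zero_delay if `TRUE`, ignore tract lengths and couple with the
#'   minimum one-step lag the history convention supports (the `v -> Inf`
#'   limit under the delay-clamping rule)
#' @param init_state optional 6 x (regions * modes) initial-state matrix
#' @return a `neural_trajectory` with `times` (s), `values`
#'   (regions x samples), and provenance fields
#' @export
simulate_network <- function(conn, p, g, cfg, zero_delay = FALSE,
                             init_state = NULL) {
  validate_connectome(conn)
  m <- derive_modes(p$mu, p$sigma, p$n_modes)
  n <- n_regions(conn)
  if (zero_delay) {
    steps <- matrix(1L, n, n)
    steps[conn$weights == 0] <- 0L
    dl <- list(delays_steps = steps)
  } else {
    dl <- compute_delays(conn, g$velocity_v, cfg$dt)
  }
  record_every <- max(1L, as.integer(round(cfg$record_dt / cfg$dt)))
  burn_steps <- as.integer(round(cfg$burn_in * 1000 / cfg$dt))
  n_steps <- burn_steps + as.integer(round(cfg$duration * 1000 / cfg$dt))
  if (is.null(init_state)) {
    init_state <- with_seed(derive_seed(cfg$seed, 1L),
                            default_initial_state(p, m, n))
  }
  noise6 <- cfg$noise_sd * as.numeric(cfg$noise_mask)
  wt <- if (is.null(cfg$weight_transform)) "normalize" else cfg$weight_transform
  w_cpl <- switch(wt,
    normalize = if (max(conn$weights) > 0) conn$weights / max(conn$weights)
                else conn$weights,
    log = { lw <- log1p(conn$weights)
            if (max(lw) > 0) lw / max(lw) else lw },
    raw = conn$weights)
  res <- .sj3d_network_heun(w_cpl, dl$delays_steps,
                            unclass(p), m$IE, m$II, m$mode_weights,
                            g$coupling_c, cfg$dt, n_steps, burn_steps,
                            record_every, noise6,
                            as.numeric(derive_seed(cfg$seed, 2L)),
                            init_state)
  structure(list(times = as.numeric(res$times),
                 values = res$values, final_state = res$final_state,
                 dt_record = record_every * cfg$dt,
                 params = p, global = g, config = cfg,
                 region_ids = conn$region_ids),
            class = "neural_trajectory")
}

#' Write / read a neural trajectory
#'
#' Delimited text (regions x samples, 17 significant digits) plus a JSON
#' header carrying the recording step, seed and global parameter values.
#'
#' @param traj a `neural_trajectory`
#' @param path file stem; writes `<path>.tsv` and `<path>.json`
#' @return the path, invisibly
#' @export
write_trajectory <- function(traj, path) {
  writeLines(vapply(seq_len(nrow(traj$values)), function(i)
    paste(sprintf("%.17g", traj$values[i, ]), collapse = "\t"), ""),
    paste0(path, ".tsv"))
  hdr <- list(dt_record_ms = traj$dt_record,
              t0_s = traj$times[1], region_ids = traj$region_ids,
              coupling_c = traj$global$coupling_c,
              velocity_v = traj$global$velocity_v,
              seed = traj$config$seed)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
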