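# Shared fixtures: all inputs are generated in code (no stored data).

# noise on the membrane potentials only -- the configuration used for all
# coarse-step (dt = 0.1 ms) runs; see the methods vignette
membrane_mask <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)

# small connectome for fast network tests
tiny_connectome <- function(n = 6, seed = 101, density = 0.7,
                            shell_radius = 70) {
  generate_connectome(connectome_spec(n_regions = n, density = density,
                                      shell_radius = shell_radius,
                                      seed = seed))
}

# hand-built 2x2 toy (smallest valid instance)
toy2 <- function() {
  connectome(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 50, 50, 0), 2))
}

# fast coarse-step configuration
fast_cfg <- function(duration = 5, seed = 7, noise_sd = 1, burn_in = 1,
                     dt = 0.1, ...) {
  sim_config(dt = dt, duration = duration, burn_in = burn_in,
             noise_sd = noise_sd, seed = seed, noise_mask = membrane_mask,
             ...)
}

# independent term-by-term R transcription of the six mode-level equations,
# written against scalars (no vectorization) so it cannot share bugs with
# the package implementation
oracle_sj3d_deriv <- function(state, p, m, afferent = 0) {
  M <- length(m$IE)
  w <- m$mode_weights
  xbar <- 0; abar <- 0
  for (k in 1:M) {
    xbar <- xbar + w[k] * state$xi[k]
    abar <- abar + w[k] * state$alpha[k]
  }
  d <- list(xi = numeric(M), eta = numeric(M), tau = numeric(M),
            alpha = numeric(M), beta = numeric(M), gamma = numeric(M))
  for (k in 1:M) {
    xi <- state$xi[k]; eta <- state$eta[k]; tau <- state$tau[k]
    al <- state$alpha[k]; be <- state$beta[k]; ga <- state$gamma[k]
    d$xi[k] <- eta - p$a * xi^3 + p$b * xi^2 - tau +
      p$K11 * (xbar - xi) - p$K21 * (abar - xi) + m$IE[k] + afferent
    d$eta[k] <- p$c - p$d * xi^2 - eta
    d$tau[k] <- p$r * p$s * (xi - p$x0) - p$r * tau
    d$alpha[k] <- be - p$a * al^3 + p$b_inh * al^2 - ga +
      p$K12 * (xbar - al) + m$II[k]
    d$beta[k] <- p$c - p$d_inh * al^2 - be
    d$gamma[k] <- p$r * p$s * (al - p$x0) - p$r * ga
  }
  d
}

random_node_state <- function(M, scale = 2) {
  node_state(runif(M, -scale, scale), runif(M, -scale, scale),
             runif(M, -scale, scale), runif(M, -scale, scale),
             runif(M, -scale, scale), runif(M, -scale, scale))
}
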