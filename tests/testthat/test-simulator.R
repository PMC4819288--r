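test_that("compute_delays converts mm and m/s into integration steps", {
  l <- matrix(c(0, 60, 60, 0), 2)
  w <- matrix(c(0, 1, 1, 0), 2)
  cn <- connectome(w, l)
  # 60 mm at 60 m/s is exactly 1 ms
  d <- compute_delays(cn, 60, dt = 1)
  expect_equal(d$delays_steps, matrix(c(0L, 1L, 1L, 0L), 2))
  # 100 mm at 10 m/s = 10 ms -> round(10 / 0.0122) = 820 steps
  cn2 <- connectome(w, matrix(c(0, 100, 100, 0), 2))
  d2 <- compute_delays(cn2, 10, dt = 0.0122)
  expect_equal(d2$delays_steps[1, 2], 820L)
  # near-infinite velocity clamps every nonzero edge to 1 step
  d3 <- compute_delays(cn2, 1e9, dt = 0.0122)
  expect_equal(d3$delays_steps[1, 2], 1L)
  expect_equal(d3$delays_steps[1, 1], 0L)
  # zero length under nonzero weight is rejected
  expect_error(
    compute_delays(structure(list(weights = w, lengths = matrix(0, 2, 2),
                                  region_ids = c("a", "b")),
                             class = "connectome"), 60, 1),
    class = "vs_error_zero_length_edge")
})

test_that("deterministic Heun is second order on dx/dt = -x", {
  drift <- function(x, t) -x
  err <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    n <- round(1 / dt)
    out <- heun_integrate(drift, 1, dt, n, noise_sd = 0)
    abs(out[n + 1, 1] - exp(-1))
  }, 1)
  expect_gt(err[1] / err[2], 3.6)
  expect_lt(err[1] / err[2], 4.4)
  expect_gt(err[2] / err[3], 3.6)
  expect_lt(err[2] / err[3], 4.4)
})

test_that("pure-noise increments match the additive-noise variance formula", {
  drift <- function(x, t) rep(0, length(x))
  dt <- 0.25
  out <- heun_integrate(drift, rep(0, 1e5), dt, 1, noise_sd = 1, seed = 99)
  v <- var(out[2, ])
  expect_lt(abs(v / dt - 1), 0.02)  # ~4 sigma of the n = 1e5 variance estimate
  # zero drift, zero noise: identity
  out0 <- heun_integrate(drift, c(1, 2), 0.1, 10, noise_sd = 0)
  expect_equal(out0[11, ], c(1, 2))
})

test_that("zero-coupling network equals isolated nodes integrated in R", {
  cn <- tiny_connectome(n = 6, seed = 31)
  p <- sj3d_params()
  m <- derive_modes(p$mu, p$sigma, p$n_modes)
  dt <- 0.1
  n_steps <- 200
  set.seed(5)
  init <- virtualstroke:::default_initial_state(p, m, 6)
  cfg <- sim_config(dt = dt, duration = n_steps * dt / 1000, noise_sd = 0,
                    burn_in = 0, record_dt = dt, seed = 1)
  traj <- simulate_network(cn, p, global_params(0, 60), cfg,
                           init_state = init)
  for (i in 1:6) {
    # isolated-node reference integrated by the R Heun implementation;
    # state vector layout per node: (xi, eta, tau, alpha, beta, gamma) x modes
    v0 <- as.vector(sapply(1:6, function(f) init[f, ((i - 1) * 3 + 1):(i * 3)]))
    drift <- function(x, t)
      state_to_vector(sj3d_derivatives(vector_to_state(x), p, m))
    out <- heun_integrate(drift, v0, dt, n_steps, noise_sd = 0)
    mf <- out[-1, 1:3] %*% m$mode_weights
    expect_lt(max(abs(traj$values[i, ] - mf)), 1e-12)
  }
})

test_that("simulation is deterministic given the seed", {
  cn <- tiny_connectome()
  cfg <- fast_cfg(duration = 2, seed = 17)
  a <- simulate_network(cn, sj3d_params(), global_params(0.2, 40), cfg)
  b <- simulate_network(cn, sj3d_params(), global_params(0.2, 40), cfg)
  expect_identical(a$values, b$values)
  cfg2 <- fast_cfg(duration = 2, seed = 18)
  c2 <- simulate_network(cn, sj3d_params(), global_params(0.2, 40), cfg2)
  expect_false(identical(a$values, c2$values))
})

test_that("relabeling regions permutes noise-free trajectories exactly", {
  cn <- tiny_connectome(n = 6, seed = 77)
  p <- sj3d_params()
  m <- derive_modes(p$mu, p$sigma, p$n_modes)
  set.seed(9)
  init <- virtualstroke:::default_initial_state(p, m, 6)
  cfg <- sim_config(dt = 0.1, duration = 1, noise_sd = 0, burn_in = 0,
                    seed = 1)
  t1 <- simulate_network(cn, p, global_params(0.3, 30), cfg,
                         init_state = init)
  perm <- c(3, 1, 6, 2, 5, 4)
  cnp <- connectome(cn$weights[perm, perm], cn$lengths[perm, perm],
                    region_ids = cn$region_ids[perm])
  # permute the initial state blocks consistently
  blocks <- as.vector(vapply(perm, function(i) ((i - 1) * 3 + 1):(i * 3),
                             integer(3)))
  t2 <- simulate_network(cnp, p, global_params(0.3, 30), cfg,
                         init_state = init[, blocks])
  expect_equal(t2$values, t1$values[perm, ], tolerance = 1e-13)
})

test_that("coupling enters only as the product c * w (raw transform)", {
  w <- matrix(0.4, 6, 6); diag(w) <- 0
  l <- matrix(80, 6, 6); diag(l) <- 0
  cn1 <- connectome(w, l)
  cn2 <- connectome(2 * w, l)
  cfg <- fast_cfg(duration = 2, seed = 4, weight_transform = "raw")
  p <- sj3d_params()
  a <- simulate_network(cn1, p, global_params(0.2, 50), cfg)
  b <- simulate_network(cn2, p, global_params(0.1, 50), cfg)
  expect_identical(a$values, b$values)
})

test_that("huge velocity and the explicit zero-delay mode coincide", {
  cn <- tiny_connectome(n = 6, seed = 13)
  p <- sj3d_params()
  cfg <- fast_cfg(duration = 2, seed = 3)
  a <- simulate_network(cn, p, global_params(0.3, 1e9), cfg)
  b <- simulate_network(cn, p, global_params(0.3, 60), cfg, zero_delay = TRUE)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("noise-free trajectories settle onto the stable equilibrium", {
  p <- sj3d_params(mu = 0.5, sigma = 0, K11 = 0.1, K12 = 0.1, K21 = 0.1)
  eq <- find_equilibrium(p)
  expect_true(eq$stable)
  m <- derive_modes(p$mu, p$sigma, p$n_modes)
  cn <- tiny_connectome(n = 6, seed = 55)
  # 6 families x (6 regions * 3 modes), perturbed off the equilibrium
  init <- matrix(0, 6, 18)
  for (f in 1:6) init[f, ] <- rep(eq$state[[f]], 6) + 0.05
  # near-zero coupling keeps each node near its isolated equilibrium
  cfg <- sim_config(dt = 0.05, duration = 2.5, noise_sd = 0, burn_in = 0,
                    seed = 1)
  tr <- simulate_network(cn, p, global_params(1e-10, 60), cfg,
                         init_state = init)
  mf_eq <- sum(m$mode_weights * eq$state$xi)
  expect_lt(max(abs(tr$values[, ncol(tr$values)] - mf_eq)), 1e-6)
})

test_that("divergent parameter regimes raise a divergence error", {
  cn <- tiny_connectome()
  cfg <- sim_config(dt = 0.5, duration = 3, noise_sd = 3, burn_in = 0,
                    seed = 2)  # coarse step + strong noise on all families
  expect_error(simulate_network(cn, sj3d_params(), global_params(0.9, 60), cfg),
               "divergence")
})

test_that("trajectory serialization writes matrix plus JSON header", {
  cn <- tiny_connectome()
  tr <- simulate_network(cn, sj3d_params(), global_params(0.2, 60),
                         fast_cfg(duration = 2))
  stem <- tempfile()
  write_trajectory(tr, stem)
  vals <- do.call(rbind, lapply(strsplit(readLines(paste0(stem, ".tsv")), "\t"),
                                as.numeric))
  expect_equal(vals, unname(tr$values))
  hdr <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(hdr$coupling_c, 0.2)
  expect_equal(hdr$seed, tr$config$seed)
})
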