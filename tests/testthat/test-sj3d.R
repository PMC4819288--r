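test_that("derive_modes matches the 3-point Gauss-Hermite rule mapped to N(mu, sigma^2)", {
  m <- derive_modes(2.2, 0.3, 3)
  # physicists' 3-point Hermite nodes 0, +/-sqrt(3/2); x = mu + sqrt(2) sigma t
  expect_equal(sort(m$IE), sort(2.2 + sqrt(2) * 0.3 * c(-sqrt(1.5), 0, sqrt(1.5))),
               tolerance = 1e-12)
  expect_equal(sort(m$mode_weights), sort(c(1 / 6, 2 / 3, 1 / 6)),
               tolerance = 1e-12)
  expect_identical(m$IE, m$II)
  # quadrature reproduces the first two moments of the input-current law
  for (M in 2:6) {
    mm <- derive_modes(1.5, 0.4, M)
    expect_equal(sum(mm$mode_weights * mm$IE), 1.5, tolerance = 1e-10)
    expect_equal(sum(mm$mode_weights * (mm$IE - 1.5)^2), 0.4^2,
                 tolerance = 1e-10)
  }
})

test_that("derive_modes normalization and degenerate cases", {
  set.seed(1)
  for (i in 1:20) {
    M <- sample(1:7, 1)
    mm <- derive_modes(runif(1, -3, 3), runif(1, 0, 2), M)
    expect_equal(sum(mm$mode_weights), 1, tolerance = 1e-12)
    expect_true(all(mm$mode_weights >= 0))
    expect_length(mm$IE, M)
  }
  m0 <- derive_modes(2.2, 0, 3)
  expect_equal(m0$IE, rep(2.2, 3))
  expect_equal(m0$mode_weights, rep(1 / 3, 3))
  m1 <- derive_modes(2.2, 0.3, 1)
  expect_equal(m1$IE, 2.2)  # single mode reduces to the plain mean field
  expect_error(derive_modes(2.2, 0.3, 0), class = "vs_error_parameter")
})

test_that("sj3d_derivatives matches an independent term-wise evaluation", {
  p <- sj3d_params()
  m <- derive_modes(p$mu, p$sigma, p$n_modes)
  # all-zero state, zero afferent
  z <- node_state(rep(0, 3), rep(0, 3), rep(0, 3),
                  rep(0, 3), rep(0, 3), rep(0, 3))
  expect_equal(unclass(sj3d_derivatives(z, p, m)),
               unclass(oracle_sj3d_deriv(z, p, m)), tolerance = 1e-14)
  # 100 random states, random couplings and afferents
  set.seed(42)
  for (i in 1:100) {
    pp <- sj3d_params(K11 = runif(1), K12 = runif(1), K21 = runif(1),
                      mu = runif(1, 0, 3), sigma = runif(1, 0, 1))
    mm <- derive_modes(pp$mu, pp$sigma, pp$n_modes)
    st <- random_node_state(3)
    aff <- runif(1, -1, 1)
    got <- state_to_vector(sj3d_derivatives(st, pp, mm, aff))
    want <- unlist(oracle_sj3d_deriv(st, pp, mm, aff), use.names = FALSE)
    expect_lt(max(abs(got - want)), 1e-10)
  }
  expect_error(
    sj3d_derivatives(node_state(c(NaN, 0, 0), rep(0, 3), rep(0, 3),
                                rep(0, 3), rep(0, 3), rep(0, 3)), p, m),
    class = "vs_error_propagation")
})

test_that("K21 = 0 decouples inhibitory state from excitatory derivatives", {
  p <- sj3d_params(K21 = 0)
  m <- derive_modes(p$mu, p$sigma, p$n_modes)
  set.seed(7)
  st <- random_node_state(3)
  st2 <- st
  st2$alpha <- st$alpha + rnorm(3)
  st2$beta <- st$beta + rnorm(3)
  st2$gamma <- st$gamma + rnorm(3)
  d1 <- sj3d_derivatives(st, p, m)
  d2 <- sj3d_derivatives(st2, p, m)
  expect_identical(d1$xi, d2$xi)
  expect_identical(d1$eta, d2$eta)
  expect_identical(d1$tau, d2$tau)
})

test_that("K12 = K21 = 0 makes the cross-block Jacobian identically zero", {
  p <- sj3d_params(K12 = 0, K21 = 0)
  m <- derive_modes(p$mu, p$sigma, p$n_modes)
  set.seed(8)
  st <- random_node_state(3)
  base <- state_to_vector(sj3d_derivatives(st, p, m))
  M <- 3
  exc_idx <- 1:(3 * M); inh_idx <- (3 * M + 1):(6 * M)
  for (j in seq_len(6 * M)) {
    v <- state_to_vector(st); v[j] <- v[j] + 0.37
    d <- state_to_vector(sj3d_derivatives(vector_to_state(v), p, m))
    if (j %in% inh_idx) expect_identical(d[exc_idx], base[exc_idx])
    if (j %in% exc_idx) expect_identical(d[inh_idx], base[inh_idx])
  }
})

test_that("finite-difference Jacobian matches the analytic linearization", {
  # analytic Jacobian of the six families for a single mode set
  analytic_jacobian <- function(st, p, m) {
    M <- length(m$IE); w <- m$mode_weights
    n <- 6 * M
    J <- matrix(0, n, n)
    ix <- function(f, k) (f - 1) * M + k
    for (q in 1:M) {
      xi <- st$xi[q]; al <- st$alpha[q]
      for (k in 1:M) {
        J[ix(1, q), ix(1, k)] <- p$K11 * w[k] - p$K21 * 0 +
          (if (k == q) -3 * p$a * xi^2 + 2 * p$b * xi - p$K11 + p$K21 else 0)
        J[ix(1, q), ix(4, k)] <- -p$K21 * w[k]
        J[ix(4, q), ix(1, k)] <- p$K12 * w[k]
      }
      J[ix(1, q), ix(2, q)] <- 1
      J[ix(1, q), ix(3, q)] <- -1
      J[ix(2, q), ix(1, q)] <- -2 * p$d * xi
      J[ix(2, q), ix(2, q)] <- -1
      J[ix(3, q), ix(1, q)] <- p$r * p$s
      J[ix(3, q), ix(3, q)] <- -p$r
      J[ix(4, q), ix(4, q)] <- J[ix(4, q), ix(4, q)] -
        3 * p$a * al^2 + 2 * p$b_inh * al - p$K12
      J[ix(4, q), ix(5, q)] <- 1
      J[ix(4, q), ix(6, q)] <- -1
      J[ix(5, q), ix(4, q)] <- -2 * p$d_inh * al
      J[ix(5, q), ix(5, q)] <- -1
      J[ix(6, q), ix(4, q)] <- p$r * p$s
      J[ix(6, q), ix(6, q)] <- -p$r
    }
    J
  }
  set.seed(11)
  for (i in 1:5) {
    p <- sj3d_params(K11 = runif(1), K12 = runif(1), K21 = runif(1))
    m <- derive_modes(p$mu, p$sigma, p$n_modes)
    st <- random_node_state(3, scale = 1.5)
    Jfd <- virtualstroke:::sj3d_jacobian_fd(st, p, m, h = 1e-6)
    Jan <- analytic_jacobian(st, p, m)
    expect_lt(max(abs(Jfd - Jan)) / max(1, max(abs(Jan))), 1e-4)
  }
})

test_that("find_equilibrium returns a machine-precision root at defaults", {
  p <- sj3d_params()
  eq <- find_equilibrium(p)
  expect_true(eq$converged)
  expect_lt(eq$residual, 1e-10)
  d <- sj3d_derivatives(eq$state, p)
  expect_lt(max(abs(state_to_vector(d))), 1e-9)
})

test_that("uncoupled sigma=0 equilibrium separates into single-population roots", {
  p <- sj3d_params(K11 = 0, K12 = 0, K21 = 0, sigma = 0, n_modes = 1)
  eq <- find_equilibrium(p)
  expect_true(eq$converged)
  # excitatory block reduces to a scalar cubic in xi:
  # (c - d xi^2) - a xi^3 + b xi^2 - s (xi - x0) + mu = 0
  froot <- function(xi, b2, d2)
    (p$c - d2 * xi^2) - p$a * xi^3 + b2 * xi^2 - p$s * (xi - p$x0) + p$mu
  xi_star <- uniroot(function(x) froot(x, p$b, p$d), c(-5, 5),
                     tol = 1e-14)$root
  al_star <- uniroot(function(x) froot(x, p$b_inh, p$d_inh), c(-5, 5),
                     tol = 1e-14)$root
  expect_equal(eq$state$xi, xi_star, tolerance = 1e-8)
  expect_equal(eq$state$alpha, al_star, tolerance = 1e-8)
  expect_equal(eq$state$eta, p$c - p$d * xi_star^2, tolerance = 1e-8)
})

test_that("shifting x0 moves the equilibrium membrane value monotonically", {
  xs <- seq(-1.8, -1.4, length.out = 5)
  eqs <- vapply(xs, function(x0v) {
    p <- sj3d_params(x0 = x0v, mu = 0.5, sigma = 0,
                     K11 = 0.1, K12 = 0.1, K21 = 0.1)
    eq <- find_equilibrium(p)
    expect_true(eq$converged)
    mean(eq$state$xi)
  }, 1)
  # shifting the slow-variable nullcline moves the crossing monotonically
  expect_true(all(diff(eqs) < 0) || all(diff(eqs) > 0))
})

test_that("parameters serialize to flat JSON and back", {
  p <- sj3d_params(K12 = 0.123, mu = 2.5)
  path <- tempfile(fileext = ".json")
  sj3d_params_to_json(p, path)
  expect_equal(sj3d_params_from_json(path), p)
})
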