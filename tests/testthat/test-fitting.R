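test_that("amplitude_range enumerates local extrema across regions", {
  # two regions whose interior turning points are {-1, 2} and {0, 5}
  b <- bold_series(rbind(c(0, -1, 1, 2, 0), c(1, 0, 3, 5, 1)), tr = 2)
  a <- amplitude_range(b)
  expect_equal(a$min, -1)
  expect_equal(a$max, 5)
  expect_equal(a$mean_amplitude, mean(c((2 - (-1)) / 2, (5 - 0) / 2)))
  # constant series: zero amplitude, not an error
  a0 <- amplitude_range(bold_series(matrix(3, 1, 10), tr = 2))
  expect_equal(a0$max - a0$min, 0)
  expect_equal(a0$mean_amplitude, 0)
  # sinusoid of amplitude A: global max - min = 2A
  tt <- seq(0, 200, by = 2)
  s <- bold_series(matrix(1.7 * sin(2 * pi * 0.0625 * tt), 1), tr = 2)
  as <- amplitude_range(s)
  expect_equal(as$max - as$min, 2 * 1.7, tolerance = 1e-2)
})

test_that("spectrum is exact for bin-aligned sinusoids and bounded by fs/2", {
  n <- 120
  tt <- (0:(n - 1)) * 2
  for (nr in c(1, 4)) {
    x <- matrix(rep(sin(2 * pi * 0.05 * tt), nr), nrow = nr, byrow = TRUE)
    sp <- spectrum(bold_series(x, tr = 2))
    expect_equal(sp$peak_freq, 0.05)  # exact bin: 0.05 / (0.5/120) = 12
  }
  sp <- spectrum(bold_series(matrix(rnorm(64), 2, 32), tr = 2))
  expect_equal(max(sp$freqs), 0.25)  # TR 2 s -> fs/2 = 0.25 Hz
  expect_true(all(sp$power >= 0))
  expect_error(spectrum(bold_series(matrix(1:4, 1), tr = 2)),
               class = "vs_error_input")
})

test_that("white-noise spectra are flat within Monte-Carlo error", {
  set.seed(10)
  n <- 128
  acc <- NULL
  for (s in 1:10) {
    sp <- spectrum(bold_series(matrix(rnorm(8 * n), 8, n), tr = 2))
    acc <- rbind(acc, sp$power[-1])
  }
  m <- colMeans(acc)
  se <- apply(acc, 2, sd) / sqrt(nrow(acc))
  grand <- mean(m)
  expect_true(all(abs(m - grand) < 4 * pmax(se, 1e-12)))
})

test_that("fc_matrix is an exact Pearson correlation with flagged degeneracies", {
  set.seed(2)
  x <- matrix(rnorm(30), 3, 10)
  fc <- fc_matrix(bold_series(x, tr = 2))
  # manual Pearson for the (1,2) pair
  manual <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  expect_equal(fc[1, 2], manual(x[1, ], x[2, ]), tolerance = 1e-12)
  expect_equal(fc[1, 3], manual(x[1, ], x[3, ]), tolerance = 1e-12)
  expect_true(isSymmetric(unclass(fc)))
  expect_equal(diag(fc), rep(1, 3))
  # duplicated region and negated region
  y <- rbind(x[1, ], x[1, ], -x[1, ])
  fc2 <- fc_matrix(bold_series(y, tr = 2))
  expect_equal(fc2[1, 2], 1)
  expect_equal(fc2[1, 3], -1)
  # zero-variance region flagged
  z <- rbind(x[1, ], rep(1, 10))
  expect_warning(fc3 <- fc_matrix(bold_series(z, tr = 2)),
                 class = "vs_warning_zero_variance")
  expect_true(is.na(fc3[1, 2]))
  expect_equal(diag(fc3), rep(1, 2))
})

test_that("fc_matrix invariants hold on random inputs (property)", {
  set.seed(77)
  for (i in 1:25) {
    nr <- sample(3:10, 1); nc <- sample(5:40, 1)
    fc <- fc_matrix(bold_series(matrix(rnorm(nr * nc), nr, nc), tr = 2))
    expect_true(isSymmetric(unclass(fc)))
    expect_equal(diag(fc), rep(1, nr))
    expect_true(all(fc >= -1 - 1e-12 & fc <= 1 + 1e-12))
  }
})

test_that("fc_similarity compares upper triangles and reports Fisher z", {
  set.seed(5)
  a <- fc_matrix(bold_series(matrix(rnorm(50), 5, 10), tr = 2))
  expect_equal(fc_similarity(a, a)$similarity, 1)
  neg <- -unclass(a); diag(neg) <- 1
  expect_equal(fc_similarity(a, neg)$similarity, -1)
  expect_equal(fc_similarity(a, a)$fisher_z, atanh(1 - 1e-15))
  expect_error(fc_similarity(a, matrix(0, 3, 3)), class = "vs_error_input")
  # null distribution: similarity of independent random symmetric matrices
  sims <- vapply(1:100, function(s) {
    set.seed(s)
    m1 <- matrix(rnorm(400), 20); m1 <- (m1 + t(m1)) / 2; diag(m1) <- 1
    m2 <- matrix(rnorm(400), 20); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 1
    fc_similarity(m1, m2)$similarity
  }, 1)
  expect_lt(abs(mean(sims)), 3 / sqrt(100 * choose(20, 2)))
})

test_that("pool_fc_reference is the Fisher-z average on the correlation scale", {
  set.seed(6)
  a <- fc_matrix(bold_series(matrix(rnorm(60), 4, 15), tr = 2))
  expect_equal(unclass(pool_fc_reference(list(a))), unclass(a),
               tolerance = 1e-12)
  neg <- -unclass(a); diag(neg) <- 1
  pooled0 <- pool_fc_reference(list(unclass(a), neg))
  expect_equal(pooled0[upper.tri(pooled0)],
               rep(0, sum(upper.tri(pooled0))), tolerance = 1e-12)
  # three toy 3x3 matrices vs the closed form
  mk <- function(r) matrix(c(1, r, r, r, 1, r, r, r, 1), 3)
  rs <- c(0.2, 0.5, -0.1)
  pooled <- pool_fc_reference(lapply(rs, mk))
  expect_equal(pooled[1, 2], tanh(mean(atanh(rs))), tolerance = 1e-12)
  expect_error(pool_fc_reference(list()), class = "vs_error_input")
})

test_that("select_range finds the high plateau flanked by a variance jump", {
  # step along the coupling axis: low for c < 0.5, high plateau above
  cax <- seq(0.1, 1, by = 0.1)
  vax <- seq(10, 50, by = 10)
  vm <- structure(list(
    coupling_axis = cax, velocity_axis = vax,
    variance = outer(rep(1, 5), ifelse(cax < 0.5, 0.01, 1.0)),
    seed = 1), class = "variance_map")
  sel <- select_range(vm)
  expect_false(sel$empty)
  expect_equal(sel$coupling_range, c(0.5, 1))
  expect_equal(sel$velocity_range, c(10, 50))
  expect_equal(sel$quality, 1)
  jumps <- sel$boundary_cells$coupling_jumps
  expect_true(all(jumps[, 2] == 4))  # the step sits between columns 4 and 5
  # monotone rescaling leaves the selection unchanged (quantile threshold)
  vm2 <- vm; vm2$variance <- vm$variance^3 * 10
  sel2 <- select_range(vm2)
  expect_equal(sel2$coupling_range, sel$coupling_range)
  # flat nonzero map: whole grid, quality 1, no-boundary warning
  vm3 <- vm; vm3$variance <- matrix(0.5, 5, 10)
  expect_warning(sel3 <- select_range(vm3), class = "vs_warning_no_boundary")
  expect_equal(sel3$coupling_range, range(cax))
  expect_equal(sel3$quality, 1)
  # two disjoint plateaus: larger wins; equal sizes break toward low coupling
  v4 <- outer(rep(1, 5), c(1, 1, 1, 0.01, 0.01, 0.01, 1, 1, 1, 0.01))
  vm4 <- vm; vm4$variance <- v4
  sel4 <- select_range(vm4)
  expect_equal(sel4$coupling_range, c(0.1, 0.3))
})

test_that("explore_global maps are reproducible and vanish in the clamped regime", {
  cn <- tiny_connectome(n = 6, seed = 41)
  p_stable <- sj3d_params(mu = 0.5, sigma = 0, K11 = 0.1, K12 = 0.1,
                          K21 = 0.1)
  cfg <- sim_config(dt = 0.1, duration = 3, burn_in = 2, noise_sd = 0,
                    seed = 9)
  vm <- explore_global(cn, p_stable, c(0.01, 0.05), c(20, 60), cfg)
  expect_true(all(vm$variance < 1e-6))  # fluctuation-free fixed-point regime
  cfg2 <- fast_cfg(duration = 3, burn_in = 1, seed = 9)
  vm1 <- explore_global(cn, sj3d_params(), c(0.05, 0.4), c(20, 60), cfg2)
  vm2 <- explore_global(cn, sj3d_params(), c(0.05, 0.4), c(20, 60), cfg2)
  expect_identical(vm1$variance, vm2$variance)
  expect_true(all(vm1$variance > 0))
  expect_error(explore_global(cn, sj3d_params(), c(0.005, 0.5), c(20, 60), cfg2),
               class = "vs_error_parameter")
})

test_that("fit_parameters self-fit selects the generating grid point with rank 1", {
  cn <- tiny_connectome(n = 8, seed = 61)
  p <- sj3d_params()
  hrf <- make_gamma_hrf(length = 12)
  cfg <- fast_cfg(duration = 34, burn_in = 2, seed = 2024, noise_sd = 0.3)
  grids <- list(coupling = c(0.1, 0.3, 0.5), velocity = c(20, 60))
  # target generated at the grid point (0.3, 60) under the same seed policy
  traj <- simulate_network(cn, p, global_params(0.3, 60), cfg)
  target <- neural_to_bold(traj, hrf, tr = 2)
  ref_fc <- suppressWarnings(fc_matrix(virtualstroke:::drop_transient(target)))
  fr <- fit_parameters(cn, p, grids, target, ref_fc, cfg, hrf = hrf)
  expect_equal(fr$selected$coupling, 0.3)
  expect_equal(fr$selected$velocity, 60)
  row <- fr$candidates[fr$candidates$coupling == 0.3 &
                         fr$candidates$velocity == 60 &
                         fr$candidates$stage == "global", ]
  expect_equal(row$rank_amplitude, 1)
  expect_equal(row$rank_frequency, 1)
  expect_equal(row$rank_phase, 1)
  expect_equal(row$amplitude_distance, 0)
  expect_equal(row$phase_similarity, 1)
  # determinism of the whole fit
  fr2 <- fit_parameters(cn, p, grids, target, ref_fc, cfg, hrf = hrf)
  expect_identical(fr$candidates, fr2$candidates)
})

test_that("tied candidates break toward lower coupling", {
  # an all-zero-weight connectome makes every candidate identical
  w <- matrix(0, 4, 4)
  l <- matrix(30, 4, 4); diag(l) <- 0
  cn <- connectome(w, l)
  p <- sj3d_params()
  hrf <- make_gamma_hrf(length = 12)
  cfg <- fast_cfg(duration = 20, burn_in = 1, seed = 5, noise_sd = 0.3)
  traj <- simulate_network(cn, p, global_params(0.9, 60), cfg)
  target <- neural_to_bold(traj, hrf, tr = 2)
  ref_fc <- suppressWarnings(fc_matrix(virtualstroke:::drop_transient(target)))
  fr <- fit_parameters(cn, p, list(coupling = c(0.2, 0.6), velocity = 60),
                       target, ref_fc, cfg, hrf = hrf)
  expect_true(all(fr$candidates$combined_rank[fr$candidates$stage == "global"] ==
                    fr$candidates$combined_rank[1]))
  expect_equal(fr$selected$coupling, 0.2)
})

test_that("variance maps round-trip through the text + JSON container", {
  vm <- structure(list(coupling_axis = c(0.1, 0.5), velocity_axis = c(20, 60),
                       variance = matrix(c(0.1, 0.2, 0.3, 0.4), 2),
                       seed = 9L), class = "variance_map")
  stem <- tempfile()
  write_variance_map(vm, stem)
  back <- read_variance_map(stem)
  expect_identical(back$variance, vm$variance)
  expect_equal(back$coupling_axis, vm$coupling_axis)
  expect_equal(back$velocity_axis, vm$velocity_axis)
  expect_equal(back$seed, 9)
})
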