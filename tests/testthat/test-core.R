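test_that("energy is zero for a perfect piecewise fit and counts unit residuals", {
  set.seed(21)
  labels <- matrix(sample(1:2, 36, replace = TRUE), 6, 6)
  means <- c(0.3, 0.9)
  g <- image_grid(matrix(means[labels], 6, 6))
  b <- build_polynomial_basis(g, 2)
  st <- list(membership = list(labels = labels, count = 2L),
             means = means, coefficients = rep(0, b$count))
  expect_equal(evaluate_energy(g, b, st), 0)

  g0 <- image_grid(matrix(0, 6, 6))
  st0 <- list(membership = list(labels = matrix(1L, 6, 6), count = 1L),
              means = 1, coefficients = rep(0, b$count))
  expect_equal(evaluate_energy(g0, b, st0), 36)  # m masked pixels
})

test_that("energy matches a pixel-by-pixel loop on random instances", {
  for (seed in 22:24) {
    g <- random_grid(8, 8, seed, mask_frac = 0.8)
    b <- build_polynomial_basis(g, 2)
    set.seed(seed + 100)
    labels <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
    means <- runif(3); w <- rnorm(b$count, sd = 0.2)
    st <- list(membership = list(labels = labels, count = 3L),
               means = means, coefficients = w)
    e <- evaluate_energy(g, b, st)
    expect_lt(abs(e - oracle_energy(g, b, labels, means, w)) / e, 1e-12)
  }
})

test_that("energy checks dimensions", {
  g <- random_grid(6, 6, 25)
  b <- build_polynomial_basis(g, 1)
  st <- list(membership = list(labels = matrix(1L, 6, 6), count = 1L),
             means = 0.5, coefficients = rep(0, 7))
  expect_error(evaluate_energy(g, b, st), "length")
})

test_that("coefficient update solves the normal equations", {
  # zero residual -> zero coefficients
  g <- image_grid(matrix(0.4, 7, 7))
  b <- build_polynomial_basis(g, 2)
  u <- list(labels = matrix(1L, 7, 7), count = 1L)
  expect_equal(update_coefficients(g, b, u, means = 0.4), rep(0, b$count),
               tolerance = 1e-14)
  # degree-0 basis: single coefficient is the residual mean
  set.seed(26)
  g2 <- random_grid(9, 9, 26)
  b0 <- build_polynomial_basis(g2, 0)
  w0 <- update_coefficients(g2, b0, list(labels = matrix(1L, 9, 9), count = 1L),
                            means = 0.25)
  expect_equal(w0, mean(g2$intensities) - 0.25, tolerance = 1e-12)
})

test_that("coefficient update agrees with a generic least-squares oracle", {
  for (seed in 27:29) {
    g <- random_grid(10, 10, seed, mask_frac = 0.85)
    b <- build_polynomial_basis(g, 2)
    set.seed(seed + 200)
    labels <- matrix(sample(1:2, 100, replace = TRUE), 10, 10)
    means <- runif(2)
    u <- list(labels = labels, count = 2L)
    w <- update_coefficients(g, b, u, means)
    expect_lt(max(abs(w - oracle_w(g, b, labels, means))), 1e-8)
    # unique minimizer: any perturbation increases the energy
    e_hat <- evaluate_energy(g, b, list(membership = u, means = means,
                                        coefficients = w))
    for (k in 1:5) {
      wp <- w + rnorm(length(w), sd = 0.01)
      expect_gte(evaluate_energy(g, b, list(membership = u, means = means,
                                            coefficients = wp)), e_hat)
    }
  }
})

test_that("means update is the per-class mean of the bias-corrected image", {
  g <- image_grid(matrix(7, 5, 5))
  b <- build_polynomial_basis(g, 1)
  u <- list(labels = matrix(1L, 5, 5), count = 1L)
  expect_equal(update_means(g, b, u, rep(0, 3)), 7)
  # values {2, 4} with bias 1 -> mean of {1, 3} = 2
  g2 <- image_grid(matrix(c(2, 4), 4, 4))
  b2 <- build_polynomial_basis(g2, 0)
  u2 <- list(labels = matrix(1L, 4, 4), count = 1L)
  expect_equal(update_means(g2, b2, u2, coefficients = 1), 2)
  # random instance vs loop oracle
  for (seed in 30:31) {
    g3 <- random_grid(9, 8, seed, mask_frac = 0.8)
    b3 <- build_polynomial_basis(g3, 2)
    set.seed(seed + 300)
    labels <- matrix(sample(1:3, 72, replace = TRUE), 9, 8)
    w <- rnorm(b3$count, sd = 0.1)
    got <- update_means(g3, b3, list(labels = labels, count = 3L), w)
    expect_equal(got, oracle_means(g3, b3, labels, w, 3), tolerance = 1e-12)
  }
})

test_that("means update retains the previous value for empty classes", {
  g <- random_grid(6, 6, 32)
  b <- build_polynomial_basis(g, 1)
  labels <- matrix(1L, 6, 6)  # class 2 empty
  u <- list(labels = labels, count = 2L)
  got <- update_means(g, b, u, rep(0, 3), previous = c(0.1, 0.77))
  expect_equal(got[2], 0.77)
  expect_equal(got[1], mean(g$intensities))
  expect_error(update_means(g, b, u, rep(0, 3)), "empty tissue class")
})

test_that("membership update is the exhaustive per-pixel argmin", {
  g <- image_grid(matrix(10, 4, 4))
  b <- build_polynomial_basis(g, 1)
  m <- update_membership(g, b, means = c(9, 20), coefficients = rep(0, 3))
  expect_true(all(m$labels == 1L))  # residuals 1 vs 100
  # exact tie -> smallest index
  g5 <- image_grid(matrix(5, 4, 4))
  m5 <- update_membership(g5, b, means = c(4, 6), coefficients = rep(0, 3))
  expect_true(all(m5$labels == 1L))
  for (seed in 33:35) {
    g2 <- random_grid(12, 12, seed, mask_frac = 0.7)
    b2 <- build_polynomial_basis(g2, 2)
    set.seed(seed + 400)
    means <- sort(runif(3)); w <- rnorm(b2$count, sd = 0.1)
    got <- update_membership(g2, b2, means, w)
    expect_identical(got$labels, oracle_labels(g2, b2, means, w))
  }
})

test_that("initialization is the deterministic quantile rule", {
  v <- 0.37
  g <- image_grid(matrix(v, 8, 8))
  b <- build_polynomial_basis(g, 3)
  st <- initialize_state(g, b, 1)
  expect_equal(st$means, v)
  expect_equal(st$coefficients, rep(0, 10))
  expect_equal(st$energy_trace, 0)
  # uniformly spread intensities, N = 2 -> quartile means
  g2 <- image_grid(matrix(seq(0, 1, length.out = 400), 20, 20))
  st2 <- initialize_state(g2, build_polynomial_basis(g2, 2), 2)
  expect_equal(st2$means, c(0.25, 0.75), tolerance = 0.01)
  expect_equal(st2$means, sort(st2$means))
  # bit-identical determinism
  g3 <- random_grid(10, 10, 36)
  b3 <- build_polynomial_basis(g3, 2)
  expect_identical(initialize_state(g3, b3, 3), initialize_state(g3, b3, 3))
  # more classes than distinct intensities
  expect_error(initialize_state(g, b, 2), "degenerate input")
})

test_that("noiseless model-matched phantoms are recovered exactly", {
  for (geom in c("uniform_disk", "concentric_three_tissue")) {
    n <- if (geom == "uniform_disk") 1L else 3L
    sp <- phantom_spec(shape = c(64, 64), geometry = geom, noise_sd = 0,
                       cupping = list(kind = "polynomial", tau_target = 16),
                       seed = 37)
    rec <- recovery_experiment(sp, solver_config(n_tissues = n, eps = 1e-10,
                                                 max_iter = 400))
    expect_lt(rec$energy_trace[length(rec$energy_trace)],
              1e-10 * rec$energy_trace[1])
    expect_lt(rec$bias_rmse, 1e-6)
    expect_equal(rec$label_accuracy, 1)
  }
})

test_that("a huge eps stops after one iteration, converged", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48), seed = 38))
  res <- run_correction(ph$image, solver_config(n_tissues = 1, eps = 10))
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
})

test_that("energy never increases across sub-updates or iterations", {
  ph <- make_phantom(phantom_spec(
    shape = c(48, 48), geometry = "concentric_three_tissue",
    cupping = list(kind = "polynomial", tau_target = 16),
    noise_sd = 0.02, seed = 39))
  g <- image_grid((ph$image$intensities - min(ph$image$intensities[ph$image$mask])) /
                    diff(range(ph$image$intensities[ph$image$mask])),
                  ph$image$mask)
  b <- build_polynomial_basis(g, 3)
  st <- initialize_state(g, b, 3)
  e <- evaluate_energy(g, b, st)
  for (it in 1:8) {
    st$coefficients <- update_coefficients(g, b, st$membership, st$means)
    e_w <- evaluate_energy(g, b, st)
    expect_lte(e_w, e * (1 + 1e-9))
    st$means <- update_means(g, b, st$membership, st$coefficients,
                             previous = st$means)
    e_c <- evaluate_energy(g, b, st)
    expect_lte(e_c, e_w * (1 + 1e-9))
    st$membership <- update_membership(g, b, st$means, st$coefficients)
    e_u <- evaluate_energy(g, b, st)
    expect_lte(e_u, e_c * (1 + 1e-9))
    e <- e_u
  }
  # and along a full solver run
  res <- run_correction(ph$image, solver_config(n_tissues = 3))
  expect_true(all(diff(res$energy_trace) <=
                    1e-9 * res$energy_trace[-length(res$energy_trace)]))
})

test_that("corrected + bias_field reconstructs the input exactly", {
  ph <- make_phantom(phantom_spec(shape = c(56, 56), noise_sd = 0.01, seed = 40))
  res <- run_correction(ph$image, solver_config(n_tissues = 1))
  expect_lt(max(abs(res$corrected + res$bias_field - ph$image$intensities)),
            1e-12)
  expect_lt(abs(mean(res$bias_field[ph$image$mask])), 1e-10)
})

test_that("permuting the initial tissue ordering changes labels only", {
  ph <- make_phantom(phantom_spec(
    shape = c(64, 64), geometry = "concentric_three_tissue",
    cupping = list(kind = "polynomial", tau_target = 16),
    noise_sd = 0.01, seed = 41))
  ra <- run_correction(ph$image,
                       solver_config(n_tissues = 3, init_means = c(0.2, 0.5, 0.9)))
  rb <- run_correction(ph$image,
                       solver_config(n_tissues = 3, init_means = c(0.9, 0.2, 0.5)))
  expect_lt(max(abs(ra$bias_field - rb$bias_field)), 1e-10)
  expect_lt(max(abs(ra$corrected - rb$corrected)), 1e-10)
  expect_false(identical(ra$state$membership$labels, rb$state$membership$labels))
})

test_that("scaling the input scales the estimated bias field exactly", {
  ph <- make_phantom(phantom_spec(shape = c(56, 56), noise_sd = 0.01, seed = 42))
  r1 <- run_correction(ph$image, solver_config(n_tissues = 1))
  r2 <- run_correction(image_grid(2.5 * ph$image$intensities, ph$image$mask),
                       solver_config(n_tissues = 1))
  expect_lt(max(abs(r2$bias_field - 2.5 * r1$bias_field)), 1e-10)
})

test_that("bias RMSE shrinks monotonically with the noise level", {
  sds <- c(0.05, 0.02, 0.01, 0.005)
  rmse <- vapply(sds, function(s) {
    sp <- phantom_spec(shape = c(96, 96), geometry = "uniform_disk",
                       cupping = list(kind = "polynomial", tau_target = 20),
                       noise_sd = s, seed = 43)
    recovery_experiment(sp, solver_config(n_tissues = 1))$bias_rmse
  }, 0)
  expect_true(all(diff(rmse) < 0))
})
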